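#' Split an ensemble into strong and weak responder populations
#'
#' Computes each member's weighted mean response for one therapy/timepoint
#' and partitions the ensemble: members with mean above `hi_cut` form the
#' strong-responder group, members below `lo_cut` the weak-responder group;
#' members in `[lo_cut, hi_cut]` are excluded. The conventional cuts for
#' the rituximab contrast are 48 (strong) and the observed clinical mean
#' 44.75 (weak).
#'
#' @param ensemble a [build_ensemble()] result (or plain list of `vpop`
#'   fits).
#' @param therapy,months the response column to summarize.
#' @param hi_cut,lo_cut response cuts (ACR-N %); `hi_cut >= lo_cut`.
#' @return list with elements `strong`, `weak` (lists of `vpop` fits),
#'   `means` (all member means), `excluded` (indices), and logical flags
#'   `empty_strong`, `empty_weak` (a warning is also emitted when a group
#'   comes back empty).
#' @export
split_ensemble_by_response <- function(ensemble, therapy, months,
                                       hi_cut = 48, lo_cut = 44.75) {
  if (hi_cut < lo_cut) stop("hi_cut must be >= lo_cut")
  members <- if (inherits(ensemble, "vpop_ensemble")) ensemble$members
  else ensemble
  means <- vapply(members, function(m) {
    x <- response_column(m$cohort, therapy, months)
    weighted_mean_response(x, m$weights)
  }, 0)
  strong <- means > hi_cut
  weak <- means < lo_cut
  out <- list(strong = members[strong], weak = members[weak],
              means = means, excluded = which(!strong & !weak),
              empty_strong = !any(strong), empty_weak = !any(weak))
  if (out$empty_strong) warning("strong-responder group is empty")
  if (out$empty_weak) warning("weak-responder group is empty")
  out
}

iqr_range <- function(v) stats::quantile(v, c(0.25, 0.75), names = FALSE,
                                         type = 7)

#' Contrast axes weights between responder groups
#'
#' For each mechanistic axis, the median and interquartile range of the
#' fitted upper-bin probabilities within each group, with axes ordered by
#' decreasing absolute difference between the group medians — the axes at
#' the top are the mechanistic discriminators of strong vs. weak response.
#'
#' @param strong,weak non-empty lists of `vpop` fits.
#' @return data.frame of class `group_contrast` with columns `axis`,
#'   `median_strong`, `q1_strong`, `q3_strong`, `median_weak`, `q1_weak`,
#'   `q3_weak`, `median_diff`.
#' @export
contrast_groups <- function(strong, weak) {
  if (!length(strong) || !length(weak))
    stop("both groups must be non-empty")
  pmat <- function(g) do.call(rbind, lapply(g, function(m) m$solution$p))
  ps <- pmat(strong)
  pw <- pmat(weak)
  qs <- apply(ps, 2L, iqr_range)
  qw <- apply(pw, 2L, iqr_range)
  df <- data.frame(
    axis = colnames(ps),
    median_strong = apply(ps, 2L, stats::median),
    q1_strong = qs[1L, ], q3_strong = qs[2L, ],
    median_weak = apply(pw, 2L, stats::median),
    q1_weak = qw[1L, ], q3_weak = qw[2L, ],
    row.names = NULL)
  df$median_diff <- df$median_strong - df$median_weak
  df <- df[order(abs(df$median_diff), decreasing = TRUE), ]
  rownames(df) <- NULL
  class(df) <- c("group_contrast", "data.frame")
  df
}

#' @export
print.group_contrast <- function(x, ...) {
  cat("Axes-weight contrast (ordered by |median difference|):\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Recompute population statistics for scenario responses
#'
#' Applies a fixed, previously calibrated weight vector to one or more
#' scenario response columns (e.g. pathway on/off variants simulated for
#' the same VPs) and recomputes weighted mean, SD and bin fractions. The
#' weights are not re-optimized.
#'
#' @param w named normalized weight vector (names = VP ids).
#' @param responses named numeric vector, or matrix with rownames = VP ids
#'   (one column per scenario).
#' @param bins bin table (`lo`, `hi`, optionally `label`).
#' @param clip passed to [bin_fractions()].
#' @return a [population_stats()]-style list, one element per scenario
#'   column, each with `scenario`, `mean`, `sd`, `fractions`.
#' @export
restat_scenario <- function(w, responses, bins, clip = TRUE) {
  if (is.null(dim(responses))) {
    responses <- as.matrix(responses)
    colnames(responses) <- "scenario"
  }
  ids <- rownames(responses)
  if (!is.null(ids) && !is.null(names(w))) {
    idx <- match(names(w), ids)
    if (anyNA(idx))
      stop("alignment error: scenario responses missing for vp_id ",
           names(w)[which(is.na(idx))[1L]])
    responses <- responses[idx, , drop = FALSE]
  } else if (nrow(responses) != length(w))
    stop("alignment error: ", nrow(responses), " scenario rows for ",
         length(w), " weights")
  out <- lapply(colnames(responses), function(sc) {
    x <- responses[, sc]
    list(scenario = sc, therapy = sc, months = NA_real_,
         mean = weighted_mean_response(x, w),
         sd = weighted_sd_response(x, w, n = length(x)),
         fractions = bin_fractions(x, w, bins, clip = clip))
  })
  structure(out, class = "population_stats")
}

#' Drop highly correlated mediators from an analyte panel
#'
#' Mediators whose pairwise absolute Pearson correlation exceeds `rho_cut`
#' are grouped into correlated sets (connected components of the
#' thresholded correlation graph); within each set only the analyte with
#' the lowest mean absolute correlation to all other analytes in the panel
#' is retained (ties broken by column order). Singletons are always
#' retained. A constant analyte has no defined correlation; it is treated
#' as uncorrelated, retained and reported in the `flagged` attribute.
#'
#' @param mediators numeric matrix/data.frame, one column per analyte.
#' @param rho_cut correlation threshold in `(0, 1)`, default 0.8.
#' @return character vector of retained analyte names, with attributes
#'   `components` (list of correlated sets) and `flagged` (constant
#'   analytes).
#' @export
prune_correlated_mediators <- function(mediators, rho_cut = 0.8) {
  mediators <- as.matrix(mediators)
  if (ncol(mediators) < 2L) stop("need at least 2 analytes")
  if (rho_cut <= 0 || rho_cut >= 1) stop("rho_cut must lie in (0, 1)")
  nm <- colnames(mediators)
  const <- apply(mediators, 2L, function(v) stats::sd(v) == 0)
  cm <- suppressWarnings(abs(stats::cor(mediators)))
  cm[is.na(cm)] <- 0          # constant columns: undefined -> uncorrelated
  diag(cm) <- 0
  adj <- cm > rho_cut
  # connected components by breadth-first search
  comp <- rep(NA_integer_, ncol(cm))
  cur <- 0L
  for (v in seq_along(comp)) {
    if (!is.na(comp[v])) next
    cur <- cur + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1L]
      queue <- queue[-1L]
      if (!is.na(comp[u])) next
      comp[u] <- cur
      queue <- c(queue, which(adj[u, ] & is.na(comp)))
    }
  }
  mean_abs <- rowSums(cm) / (ncol(cm) - 1L)
  keep <- logical(ncol(cm))
  sets <- list()
  for (g in unique(comp)) {
    idx <- which(comp == g)
    if (length(idx) == 1L) {
      keep[idx] <- TRUE
    } else {
      sets[[length(sets) + 1L]] <- nm[idx]
      keep[idx[which.min(mean_abs[idx])]] <- TRUE
    }
  }
  structure(nm[keep], components = sets, flagged = nm[const])
}

#' Exhaustive best-subset weighted regression
#'
#' Evaluates every size-`k` subset of candidate analytes as predictors of
#' the response in a prevalence-weighted least-squares fit and returns the
#' subset with the highest weighted R-squared. The adjusted R-squared and
#' BIC are computed with the Kish effective sample size of the weights
#' (`n_eff`), since the weighted cohort does not contain N independent
#' patients: `adjR2 = 1 - (1 - R2)(n_eff - 1)/(n_eff - k - 1)` and
#' `BIC = n_eff log(RSS_w / n_eff) + (k + 1) log(n_eff)`.
#'
#' @param mediators numeric matrix/data.frame of candidate analytes.
#' @param response numeric response vector (e.g. ACR-N to one therapy).
#' @param w prevalence weights; `NULL` for an unweighted fit.
#' @param k model size (number of analytes).
#' @param budget maximal number of subsets to enumerate (default 1e5);
#'   exceeding it is an error advising correlation pruning first.
#' @return an object of class `biomarker_model`: `analytes`,
#'   `coefficients` (intercept first), `r_squared`, `adj_r_squared`, `bic`,
#'   `k`, `n_eff`.
#' @export
best_subset_regression <- function(mediators, response, w = NULL, k = 5,
                                   budget = 1e5) {
  X <- as.matrix(mediators)
  y <- as.numeric(response)
  n <- length(y)
  if (k < 1) stop("k must be >= 1")
  if (ncol(X) < k) stop("fewer candidate analytes than k")
  if (n < k + 2) stop("need N >= k + 2 observations")
  if (is.null(w)) w <- rep(1 / n, n)
  if (length(w) != n) stop("weights / response length mismatch")
  n_subsets <- choose(ncol(X), k)
  if (n_subsets > budget)
    stop("budget error: ", format(n_subsets, big.mark = ","),
         " subsets of size ", k,
         " exceed the enumeration budget; prune correlated analytes first")
  ybar <- sum(w * y) / sum(w)
  tss <- sum(w * (y - ybar)^2)
  subsets <- utils::combn(ncol(X), k)
  best_rss <- Inf
  best_j <- NULL
  best_fit <- NULL
  for (jj in seq_len(ncol(subsets))) {
    cols <- subsets[, jj]
    fit <- stats::lm.wfit(cbind(1, X[, cols, drop = FALSE]), y, w)
    rss <- sum(w * fit$residuals^2)
    if (is.null(best_j) || rss < best_rss - 1e-12 * max(1, rss)) {
      best_rss <- rss
      best_j <- cols
      best_fit <- fit
    }
  }
  n_eff <- effective_sample_size(w)
  r2 <- 1 - best_rss / tss
  structure(
    list(analytes = colnames(X)[best_j],
         coefficients = stats::setNames(best_fit$coefficients,
                                        c("(Intercept)", colnames(X)[best_j])),
         r_squared = r2,
         adj_r_squared = 1 - (1 - r2) * (n_eff - 1) / (n_eff - k - 1),
         bic = n_eff * log(best_rss / n_eff) + (k + 1) * log(n_eff),
         k = k, n_eff = n_eff),
    class = "biomarker_model")
}

#' @export
print.biomarker_model <- function(x, ...) {
  cat(sprintf("Best size-%d biomarker model: %s\n", x$k,
              paste(x$analytes, collapse = " + ")))
  cat(sprintf("  R2 %.4f, adj R2 %.4f, BIC %.2f (n_eff %.1f)\n",
              x$r_squared, x$adj_r_squared, x$bic, x$n_eff))
  invisible(x)
}

#' Analyte selection frequency across an ensemble of biomarker models
#'
#' Counts, for every analyte, how many per-VPop best-subset models include
#' it — the stability of a multianalyte biomarker across alternate virtual
#' populations.
#'
#' @param models list of [best_subset_regression()] results.
#' @return data.frame with columns `analyte`, `count`, `fraction`, sorted
#'   by decreasing frequency.
#' @export
analyte_selection_frequency <- function(models) {
  if (!length(models)) stop("need at least one model")
  picks <- unlist(lapply(models, function(m) m$analytes))
  tab <- sort(table(picks), decreasing = TRUE)
  data.frame(analyte = names(tab), count = as.integer(tab),
             fraction = as.integer(tab) / length(models),
             row.names = NULL, stringsAsFactors = FALSE)
}
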