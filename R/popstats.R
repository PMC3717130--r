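#' Weighted population mean response
#'
#' @param x numeric response vector (ACR-N %).
#' @param w normalized prevalence weights, same length.
#' @return `sum(w * x)`.
#' @export
weighted_mean_response <- function(x, w) {
  if (length(x) != length(w)) stop("x and w lengths differ")
  sum(w * x)
}

#' Weighted population standard deviation
#'
#' `sqrt(N * sum(w_i (x_i - xbar)^2) / (N - 1))` with the weighted mean
#' `xbar` and the cohort size N; reduces to the classical sample SD when
#' the weights are uniform.
#'
#' @param x numeric response vector.
#' @param w normalized prevalence weights.
#' @param n cohort size N used in the calibration (defaults to `length(x)`).
#' @return weighted SD (same units as `x`).
#' @export
weighted_sd_response <- function(x, w, n = length(x)) {
  if (length(x) != length(w)) stop("x and w lengths differ")
  if (n < 2) stop("need N >= 2")
  xbar <- sum(w * x)
  sqrt(n * sum(w * (x - xbar)^2) / (n - 1))
}

# assign responses to bins: half-open [lo, hi); edge bins extended to
# +/- Inf when clip = TRUE, else out-of-range responses are an error.
assign_bins <- function(x, bins, clip = TRUE, vp_ids = NULL) {
  lo <- bins$lo
  hi <- bins$hi
  if (clip) {
    lo[1L] <- -Inf
    hi[length(hi)] <- Inf
  }
  idx <- rep(NA_integer_, length(x))
  for (b in seq_len(nrow(bins)))
    idx[x >= lo[b] & (x < hi[b] | (b == nrow(bins) & x <= hi[b]))] <- b
  if (anyNA(idx)) {
    i <- which(is.na(idx))[1L]
    id <- if (!is.null(vp_ids)) vp_ids[i] else paste0("row ", i)
    stop("coverage error: response ", x[i], " for ", id,
         " falls outside all bins")
  }
  idx
}

#' Weighted response-bin fractions
#'
#' Sums the prevalence weight of the VPs whose response falls in each target
#' bin. Bins are half-open `[lo, hi)` with the lowest bin open below and the
#' highest closed above; by default the edge bins absorb out-of-range
#' responses (set `clip = FALSE` to make those an error).
#'
#' @param x numeric response vector.
#' @param w normalized prevalence weights.
#' @param bins data.frame with columns `lo`, `hi` (and optionally `label`).
#' @param clip extend the edge bins to +/- Inf (default TRUE).
#' @return numeric vector of fractions, one per bin, summing to 1.
#' @export
bin_fractions <- function(x, w, bins, clip = TRUE) {
  if (length(x) != length(w)) stop("x and w lengths differ")
  idx <- assign_bins(x, bins, clip = clip, vp_ids = names(w))
  f <- vapply(seq_len(nrow(bins)), function(b) sum(w[idx == b]), 0)
  if ("label" %in% names(bins)) names(f) <- bins$label
  f
}

#' Trial mean and SD from a binned response distribution
#'
#' Reconstructs the trial mean and standard deviation from reported bin
#' counts, placing every patient at the midpoint of their response bin:
#' `mean = sum(c_b n_b) / N_T` and
#' `sd = sqrt(sum(n_b (c_b - mean)^2) / (N_T - 1))`.
#'
#' @param target a [trial_target()] (its `bins$mid` and `bins$count` are
#'   used).
#' @return named numeric vector `c(mean = , sd = )`.
#' @export
trial_stats_from_bins <- function(target) {
  n <- target$bins$count
  c_b <- target$bins$mid
  n_t <- target$n_trial
  if (n_t < 2) stop("need N_T >= 2")
  m <- sum(c_b * n) / n_t
  s <- sqrt(sum(n * (c_b - m)^2) / (n_t - 1))
  c(mean = m, sd = s)
}

#' Weighted population statistics against a set of targets
#'
#' For each trial target, computes the weighted mean, weighted SD and
#' weighted bin fractions of the corresponding cohort response column.
#'
#' @param cohort a [vp_cohort()].
#' @param w normalized prevalence weights aligned to the cohort.
#' @param targets list of [trial_target()] objects.
#' @param clip passed to [bin_fractions()].
#' @return an object of class `population_stats`: a list with one element
#'   per target (`therapy`, `months`, `mean`, `sd`, `fractions`).
#' @export
population_stats <- function(cohort, w, targets, clip = TRUE) {
  if (inherits(targets, "trial_target")) targets <- list(targets)
  out <- lapply(targets, function(t) {
    x <- response_column(cohort, t$therapy, t$months)
    list(therapy = t$therapy, months = t$months,
         mean = weighted_mean_response(x, w),
         sd = weighted_sd_response(x, w, n = length(x)),
         fractions = bin_fractions(x, w, t$bins, clip = clip))
  })
  structure(out, class = "population_stats")
}

#' @export
print.population_stats <- function(x, ...) {
  for (s in x)
    cat(sprintf("%s @ %g mo: mean %.2f, sd %.2f, bins [%s]\n",
                s$therapy, s$months, s$mean, s$sd,
                paste(sprintf("%.3f", s$fractions), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.population_stats <- function(x, ...) {
  do.call(rbind, lapply(x, function(s)
    data.frame(therapy = s$therapy, months = s$months, mean = s$mean,
               sd = s$sd,
               bin_label = if (is.null(names(s$fractions)))
                 seq_along(s$fractions) else names(s$fractions),
               fraction = as.numeric(s$fractions), row.names = NULL)))
}
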