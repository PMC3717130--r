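#' Two-sided Welch t-test p-value from summary statistics
#'
#' Compares the weighted virtual-population mean (represented by its Kish
#' effective sample size) to the reported trial mean. Welch's
#' unequal-variance form is used so that variance agreement is scored only
#' once, by the separate F-test.
#'
#' @param vpop_mean,vpop_sd,n_eff weighted VPop mean, SD and effective
#'   sample size.
#' @param trial_mean,trial_sd,n_trial trial mean, SD and patient count.
#' @return two-sided p-value in `[0, 1]`. If both SDs are zero the p-value
#'   is 1 when the means agree and 0 otherwise (documented convention).
#' @export
mean_pvalue <- function(vpop_mean, vpop_sd, n_eff, trial_mean, trial_sd,
                        n_trial) {
  if (n_eff <= 1 || n_trial <= 1) stop("need both sample sizes > 1")
  if (vpop_sd < 0 || trial_sd < 0) stop("sds must be >= 0")
  v1 <- vpop_sd^2 / n_eff
  v2 <- trial_sd^2 / n_trial
  if (v1 + v2 == 0) return(if (vpop_mean == trial_mean) 1 else 0)
  tt <- (vpop_mean - trial_mean) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n_eff - 1) + v2^2 / (n_trial - 1))
  2 * stats::pt(-abs(tt), df)
}

#' Two-sided variance-ratio F-test p-value
#'
#' `F = vpop_sd^2 / trial_sd^2` on `(n_eff - 1, n_trial - 1)` degrees of
#' freedom; the two-sided p-value doubles the smaller tail and is capped at
#' 1, so it is invariant to swapping the two groups.
#'
#' @inheritParams mean_pvalue
#' @return two-sided p-value in `[0, 1]`.
#' @export
sd_pvalue <- function(vpop_sd, n_eff, trial_sd, n_trial) {
  if (n_eff <= 1 || n_trial <= 1) stop("need both sample sizes > 1")
  if (vpop_sd <= 0 || trial_sd <= 0)
    stop("degenerate variance: sds must be > 0 for the F-test")
  f <- (vpop_sd / trial_sd)^2
  lo <- stats::pf(f, n_eff - 1, n_trial - 1)
  min(1, 2 * min(lo, 1 - lo))
}

#' Chi-squared p-value for the binned response distribution
#'
#' Observed trial bin counts are compared to expected counts
#' `e_b = N_T * f_b` from the weighted VPop bin fractions; expected counts
#' are floored at `1e-6 * N_T` and renormalized to `N_T` so the statistic
#' stays finite when a bin carries no weight. Degrees of freedom are
#' `B - 1`.
#'
#' @param fractions weighted bin fractions (summing to 1).
#' @param target a [trial_target()] supplying `bins$count` and `n_trial`.
#' @return upper-tail chi-squared p-value.
#' @export
bins_pvalue <- function(fractions, target) {
  n_b <- target$bins$count
  if (length(fractions) != length(n_b))
    stop("fraction / bin count length mismatch")
  if (length(n_b) < 2L) stop("degenerate binning: need at least 2 bins")
  n_t <- target$n_trial
  e <- pmax(n_t * fractions, 1e-6 * n_t)
  e <- e * n_t / sum(e)
  stat <- sum((n_b - e)^2 / e)
  stats::pchisq(stat, df = length(n_b) - 1, lower.tail = FALSE)
}

#' Fisher's method composite goodness-of-fit
#'
#' Aggregates the per-statistic p-values: `X = -2 sum(log p)` is referred to
#' a chi-squared distribution with `2k` degrees of freedom. The optimization
#' objective is `sum(log p)`, a strictly increasing transform of the
#' composite at fixed k. p-values are floored at 1e-300 before taking logs
#' so the objective stays finite off-optimum; an exact zero p-value yields
#' the sentinel objective `-Inf` (worst possible score), never an error.
#'
#' @param p numeric vector of p-values in `[0, 1]`, at least one.
#' @return list with elements `composite` (Fisher p-value) and `objective`
#'   (`sum(log p)`).
#' @export
composite_gof <- function(p) {
  if (!length(p)) stop("no p-values to combine")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (any(p == 0))
    return(list(composite = 0, objective = -Inf))
  lp <- log(pmax(p, 1e-300))
  obj <- sum(lp)
  x <- -2 * obj
  list(composite = stats::pchisq(x, df = 2 * length(p), lower.tail = FALSE),
       objective = obj)
}

#' Score a virtual population against its trial targets
#'
#' Builds the full goodness-of-fit report for one weight vector: for every
#' therapy/timepoint target the t-test (weighted mean), F-test (weighted
#' SD) and chi-squared test (binned distribution) p-values, plus the Fisher
#' composite and the `sum(log p)` objective over all included statistics.
#'
#' @param pop a [population_stats()] result.
#' @param targets list of [trial_target()] objects (same order as `pop`).
#' @param n_eff effective sample size representing the weighted VPop in the
#'   t- and F-tests (Kish by default upstream; may be set to the trial N).
#'   A scalar, or one value per target.
#' @param include character subset of `c("mean", "sd", "bins")` entering the
#'   composite.
#' @return an object of class `gof_report`: a data.frame with columns
#'   `therapy, months, statistic, p_value` and attributes `composite`,
#'   `objective`, `included`, `n_eff`.
#' @export
gof_report <- function(pop, targets, n_eff,
                       include = c("mean", "sd", "bins")) {
  include <- match.arg(include, several.ok = TRUE)
  if (inherits(targets, "trial_target")) targets <- list(targets)
  ne <- rep_len(n_eff, length(targets))
  rows <- list()
  for (i in seq_along(targets)) {
    t <- targets[[i]]
    s <- pop[[i]]
    if ("mean" %in% include)
      rows[[length(rows) + 1L]] <- data.frame(
        therapy = t$therapy, months = t$months, statistic = "mean",
        p_value = mean_pvalue(s$mean, s$sd, ne[i], t$mean, t$sd, t$n_trial))
    if ("sd" %in% include)
      rows[[length(rows) + 1L]] <- data.frame(
        therapy = t$therapy, months = t$months, statistic = "sd",
        p_value = sd_pvalue(s$sd, ne[i], t$sd, t$n_trial))
    if ("bins" %in% include)
      rows[[length(rows) + 1L]] <- data.frame(
        therapy = t$therapy, months = t$months, statistic = "bins",
        p_value = bins_pvalue(s$fractions, t))
  }
  df <- do.call(rbind, rows)
  cg <- composite_gof(df$p_value)
  structure(df, class = c("gof_report", "data.frame"),
            composite = cg$composite, objective = cg$objective,
            included = include, n_eff = ne)
}

#' @export
print.gof_report <- function(x, ...) {
  cat("Goodness-of-fit report\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(sprintf("composite p = %.4g, objective (sum log p) = %.4g, n_eff = %.1f\n",
              attr(x, "composite"), attr(x, "objective"),
              attr(x, "n_eff")[1L]))
  invisible(x)
}

#' Write a goodness-of-fit report to CSV
#' @param report a `gof_report`
#' @param path output CSV path
#' @return `path`, invisibly.
#' @export
write_gof <- function(report, path) {
  df <- as.data.frame(report)
  df <- rbind(df, data.frame(therapy = "composite", months = NA,
                             statistic = "composite",
                             p_value = attr(report, "composite")),
              data.frame(therapy = "composite", months = NA,
                         statistic = "objective",
                         p_value = attr(report, "objective")))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
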