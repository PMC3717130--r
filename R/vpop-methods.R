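#' @export
print.vpop <- function(x, ...) {
  cat("Calibrated virtual population\n")
  cat(sprintf("  %d VPs, %d axes, %d target(s)\n", length(x$weights),
              length(x$solution$p), length(x$targets)))
  cat(sprintf("  composite goodness-of-fit p = %.4g (threshold %g): %s\n",
              x$composite, x$settings$threshold,
              if (x$composite > x$settings$threshold) "valid" else "not valid"))
  cat(sprintf("  objective sum(log p) = %.4g; best restart %d (seed %d)%s\n",
              x$objective, x$best_restart, x$seed,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Summarize a calibrated virtual population
#'
#' Prints the fitted upper-bin probabilities, the weighted population
#' statistics next to their trial targets, and the goodness-of-fit
#' p-values.
#'
#' @param object a `vpop` fit from [calibrate_vpop()].
#' @param ... unused.
#' @return invisibly, a list with components `solution`, `comparison`
#'   (data.frame of fitted vs. target statistics) and `gof`.
#' @export
summary.vpop <- function(object, ...) {
  comp <- do.call(rbind, lapply(seq_along(object$targets), function(i) {
    t <- object$targets[[i]]
    s <- object$stats[[i]]
    data.frame(therapy = t$therapy, months = t$months,
               vpop_mean = s$mean, trial_mean = t$mean,
               vpop_sd = s$sd, trial_sd = t$sd,
               row.names = NULL)
  }))
  print(object)
  cat("\nFitted upper-bin probabilities:\n")
  print(round(object$solution$p, 4))
  if (!is.null(object$solution$pairs)) {
    cat("Correlated pairs:\n")
    print(object$solution$pairs)
  }
  cat("\nPopulation vs. trial statistics:\n")
  print(comp, row.names = FALSE, digits = 4)
  cat("\n")
  print(object$gof)
  invisible(list(solution = object$solution, comparison = comp,
                 gof = object$gof))
}

#' Fitted axes-weight coefficients
#'
#' @param object a `vpop` fit.
#' @param ... unused.
#' @return named vector of upper-bin probabilities, followed by the fitted
#'   copula correlations `rho(k,l)` if any were declared.
#' @export
coef.vpop <- function(object, ...) {
  out <- object$solution$p
  pr <- object$solution$pairs
  if (!is.null(pr))
    out <- c(out, stats::setNames(pr$rho, paste0("rho(", pr$k, ",", pr$l, ")")))
  out
}

#' Prevalence weights of a calibrated virtual population
#'
#' @param object a `vpop` fit.
#' @param ... unused.
#' @return named numeric vector of normalized per-VP weights.
#' @export
weights.vpop <- function(object, ...) object$weights

#' Calibration residuals
#'
#' Differences between the weighted virtual-population statistics and the
#' trial targets, per therapy/timepoint: mean and SD differences (ACR-N %)
#' and per-bin fraction differences (VPop fraction minus trial fraction).
#'
#' @param object a `vpop` fit.
#' @param ... unused.
#' @return data.frame with columns `therapy, months, statistic, residual`.
#' @export
residuals.vpop <- function(object, ...) {
  do.call(rbind, lapply(seq_along(object$targets), function(i) {
    t <- object$targets[[i]]
    s <- object$stats[[i]]
    rbind(
      data.frame(therapy = t$therapy, months = t$months, statistic = "mean",
                 residual = s$mean - t$mean),
      data.frame(therapy = t$therapy, months = t$months, statistic = "sd",
                 residual = s$sd - t$sd),
      data.frame(therapy = t$therapy, months = t$months,
                 statistic = paste0("bin:", t$bins$label),
                 residual = as.numeric(s$fractions) - t$bins$count / t$n_trial))
  }))
}

#' Re-stat scenario responses under the fitted weights
#'
#' Applies the calibrated prevalence weights, unchanged, to a new set of
#' simulated responses (e.g. a pathway-knockout scenario simulated for the
#' same VPs) and recomputes the population statistics. No re-optimization
#' is performed; this is the weight-application half of a sensitivity
#' analysis.
#'
#' @param object a `vpop` fit.
#' @param responses named numeric vector (names = VP ids) or matrix of
#'   scenario responses aligned to the cohort; defaults to the calibration
#'   responses.
#' @param bins bin table used for the fraction summary (defaults to the
#'   first target's bins).
#' @param ... unused.
#' @return a [population_stats()]-style list (single entry per response
#'   column).
#' @export
predict.vpop <- function(object, responses = NULL, bins = NULL, ...) {
  if (is.null(responses)) responses <- object$cohort$responses
  if (is.null(bins)) bins <- object$targets[[1L]]$bins
  restat_scenario(object$weights, responses, bins,
                  clip = object$settings$clip)
}

#' Simulate trial outcomes from a calibrated virtual population
#'
#' Draws replicate trial-arm datasets from the fitted population: for each
#' target, bin counts are sampled from a multinomial with the fitted
#' weighted bin fractions and the target's patient count, and summarized as
#' new [trial_target()] objects.
#'
#' @param object a `vpop` fit.
#' @param nsim number of replicate target sets.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of length `nsim`; each element is a list of
#'   [trial_target()] objects mirroring the calibration targets.
#' @export
simulate.vpop <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, lapply(seq_len(nsim), function(r)
    lapply(seq_along(object$targets), function(i) {
      t <- object$targets[[i]]
      f <- object$stats[[i]]$fractions
      cnt <- as.numeric(stats::rmultinom(1L, t$n_trial, f))
      b <- t$bins
      b$count <- cnt
      trial_target(t$therapy, t$months, t$n_trial, b)
    })))
}

#' Plot calibration fit
#'
#' One panel per target: the trial's binned response distribution (open
#' bars) next to the weighted virtual-population bin fractions (filled
#' bars), annotated with the three per-target p-values.
#'
#' @param x a `vpop` fit.
#' @param ... passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.vpop <- function(x, ...) {
  k <- length(x$targets)
  old <- graphics::par(mfrow = c(1, k), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(old))
  for (i in seq_len(k)) {
    t <- x$targets[[i]]
    s <- x$stats[[i]]
    m <- rbind(trial = t$bins$count / t$n_trial, vpop = as.numeric(s$fractions))
    colnames(m) <- t$bins$label
    p_i <- x$gof$p_value[x$gof$therapy == t$therapy & x$gof$months == t$months]
    graphics::barplot(m, beside = TRUE, col = c("white", "grey40"),
                      ylim = c(0, max(m) * 1.2), ylab = "fraction",
                      main = sprintf("%s @ %g mo", t$therapy, t$months), ...)
    graphics::legend("topright", c("trial", "VPop"),
                     fill = c("white", "grey40"), bty = "n", cex = 0.8)
    graphics::mtext(sprintf("p: %s", paste(signif(p_i, 2), collapse = " / ")),
                    side = 3, line = 0, cex = 0.7)
  }
  invisible(x)
}
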