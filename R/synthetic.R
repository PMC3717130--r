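#' Specification for a synthetic cohort with known ground truth
#'
#' Defines a synthetic virtual-patient cohort that mimics the statistical
#' structure the calibration operates on — axis coefficients with a
#' median-splittable spread, continuous per-therapy responses spanning
#' roughly -21% to 100% ACR-N, and a collinear mediator panel — together
#' with a known ground-truth axes-weight solution from which trial targets
#' can be generated for parameter-recovery experiments. It emulates only
#' this statistical structure, not any mechanistic disease biology.
#'
#' All stochastic ingredients (axis loadings, ground truth) are drawn once
#' here from the master seed, so the spec is a complete, reproducible
#' description of the study conditions.
#'
#' @param n_vp number of virtual patients (default 200).
#' @param n_axes number of mechanistic axes (default 10).
#' @param therapies therapy labels (default three biologic arms).
#' @param months sample time(s) in months (default 6).
#' @param intercepts per-therapy response intercept `a_t` (ACR-N %),
#'   recycled; defaults to `c(20, 5, 35)`.
#' @param loadings optional `n_axes x n_therapies` matrix of axis loadings
#'   `b_tj`; drawn from `U(-10, 15)` under the master seed when omitted.
#' @param noise_sd residual response SD `sigma_t` (default 10).
#' @param clip response clipping range in ACR-N % (default `c(-21, 100)`,
#'   the observed envelope of simulated responses).
#' @param n_analytes number of independent base mediators (default 9).
#' @param n_collinear number of near-duplicate mediator columns appended to
#'   exercise correlation pruning (default 3; duplicates carry Gaussian
#'   noise with SD 0.05 x the column SD).
#' @param mediator_noise_sd additive noise SD on the base mediators
#'   (default 0.3).
#' @param truth_p optional ground-truth upper-bin probabilities; drawn from
#'   `U(0.2, 0.8)` under the master seed when omitted.
#' @param truth_pairs optional data.frame `k, l, rho` of ground-truth
#'   correlated pairs.
#' @param n_trial trial patient count per target (default 300).
#' @param bins target bin table (default [acr_bins()]).
#' @param target_mode `"exact"` (expectation-matched counts) or
#'   `"sampled"` (multinomial-sampled counts).
#' @param seed master seed.
#' @return list of class `synthetic_spec`, including the resolved `truth`
#'   ([axes_solution()]).
#' @export
synthetic_spec <- function(n_vp = 200, n_axes = 10,
                           therapies = c("antitnf", "rituximab",
                                         "tocilizumab"),
                           months = 6, intercepts = c(20, 5, 35),
                           loadings = NULL, noise_sd = 10,
                           clip = c(-21, 100), n_analytes = 9,
                           n_collinear = 3, mediator_noise_sd = 0.3,
                           truth_p = NULL, truth_pairs = NULL,
                           n_trial = 300, bins = acr_bins(),
                           target_mode = c("exact", "sampled"), seed = 1) {
  target_mode <- match.arg(target_mode)
  if (n_vp < 2) stop("need n_vp >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_trial < 10) stop("need n_trial >= 10")
  nt <- length(therapies)
  intercepts <- rep_len(intercepts, nt)
  axis_names <- sprintf("ax%02d", seq_len(n_axes))
  drawn <- with_seed(seed, list(
    loadings = matrix(stats::runif(n_axes * nt, -10, 15), n_axes, nt,
                      dimnames = list(axis_names, therapies)),
    med_loadings = matrix(stats::runif(n_axes * n_analytes, -2, 2),
                          n_axes, n_analytes),
    truth_p = stats::runif(n_axes, 0.2, 0.8)))
  if (is.null(loadings)) loadings <- drawn$loadings
  if (is.null(truth_p)) truth_p <- drawn$truth_p
  truth <- axes_solution(stats::setNames(truth_p, axis_names),
                         pairs = truth_pairs)
  structure(list(n_vp = n_vp, n_axes = n_axes, axis_names = axis_names,
                 therapies = therapies, months = months,
                 intercepts = intercepts, loadings = loadings,
                 noise_sd = noise_sd, clip = clip,
                 n_analytes = n_analytes, n_collinear = n_collinear,
                 mediator_noise_sd = mediator_noise_sd,
                 med_loadings = drawn$med_loadings, truth = truth,
                 n_trial = n_trial, bins = bins, target_mode = target_mode,
                 seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic cohort
#'
#' Axis coefficients are i.i.d. `U(0, 1)`; responses are
#' `clip(a_t + sum_j b_tj C_ij + eps, lo, hi)` with Gaussian noise;
#' mediators are linear maps of the axes plus noise, with `n_collinear`
#' near-duplicate columns (suffix `_dup`) appended to exercise the
#' correlation-pruning path. Fully reproducible from the spec's master
#' seed.
#'
#' @param spec a [synthetic_spec()].
#' @return a [vp_cohort()].
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed + 1L, {
    n <- spec$n_vp
    C <- matrix(stats::runif(n * spec$n_axes), n, spec$n_axes,
                dimnames = list(NULL, spec$axis_names))
    resp <- matrix(NA_real_, n, length(spec$therapies) * length(spec$months))
    cn <- character(ncol(resp))
    col <- 0L
    for (t in seq_along(spec$therapies)) {
      base <- spec$intercepts[t] + drop(C %*% spec$loadings[, t])
      for (s in spec$months) {
        col <- col + 1L
        raw <- base + stats::rnorm(n, 0, spec$noise_sd)
        resp[, col] <- pmin(pmax(raw, spec$clip[1L]), spec$clip[2L])
        cn[col] <- paste0(spec$therapies[t], ":", s)
      }
    }
    colnames(resp) <- cn
    med <- NULL
    if (spec$n_analytes > 0) {
      med <- C %*% spec$med_loadings +
        matrix(stats::rnorm(n * spec$n_analytes, 0, spec$mediator_noise_sd),
               n, spec$n_analytes)
      colnames(med) <- sprintf("an%02d", seq_len(spec$n_analytes))
      if (spec$n_collinear > 0) {
        kdup <- seq_len(min(spec$n_collinear, spec$n_analytes))
        dup <- med[, kdup, drop = FALSE] +
          vapply(kdup, function(j)
            stats::rnorm(n, 0, 0.05 * stats::sd(med[, j])), numeric(n))
        colnames(dup) <- paste0(colnames(med)[kdup], "_dup")
        med <- cbind(med, dup)
      }
    }
    vp_cohort(C, resp, mediators = med)
  })
}

#' Trial targets generated from a known ground-truth solution
#'
#' Computes the ground-truth prevalence weights and converts the weighted
#' response distribution of every therapy/timepoint column into a
#' [trial_target()]. In `"exact"` mode bin counts are the
#' largest-remainder rounding of `N_T x f_b` and the target mean/SD are
#' the weighted population values, so the truth itself scores a
#' near-perfect fit (up to integer rounding of the counts). In
#' `"sampled"` mode counts are multinomial draws and mean/SD are
#' reconstructed from the sampled counts via [trial_stats_from_bins()].
#'
#' @param cohort a [vp_cohort()].
#' @param truth the ground-truth [axes_solution()].
#' @param bins bin table (default [acr_bins()]).
#' @param n_trial trial patient count per target.
#' @param mode `"exact"` or `"sampled"`.
#' @param seed seed for sampled mode.
#' @return list of [trial_target()] objects, one per response column.
#' @export
targets_from_truth <- function(cohort, truth, bins = acr_bins(),
                               n_trial = 300,
                               mode = c("exact", "sampled"), seed = 1) {
  mode <- match.arg(mode)
  w <- prevalence_weights(cohort, truth)
  n <- length(w)
  cols <- colnames(cohort$responses)
  parts <- strsplit(cols, ":", fixed = TRUE)
  with_seed(if (mode == "sampled") seed else NULL,
    lapply(seq_along(cols), function(i) {
      x <- cohort$responses[, i]
      f <- bin_fractions(x, w, bins)
      b <- bins
      if (mode == "exact") {
        b$count <- largest_remainder(f, n_trial)
        trial_target(parts[[i]][1L], as.numeric(parts[[i]][2L]), n_trial, b,
                     mean = weighted_mean_response(x, w),
                     sd = weighted_sd_response(x, w, n = n))
      } else {
        b$count <- as.numeric(stats::rmultinom(1L, n_trial, f))
        trial_target(parts[[i]][1L], as.numeric(parts[[i]][2L]), n_trial, b)
      }
    }))
}

#' Run a parameter-recovery experiment
#'
#' Generates a synthetic cohort, builds targets from the spec's ground
#' truth, calibrates, and reports the achieved composite goodness-of-fit
#' and per-axis recovery error. With `assert = TRUE` (default) a composite
#' at or below the acceptance threshold is an error carrying full
#' diagnostics.
#'
#' @param spec a [synthetic_spec()].
#' @param settings a [calibration_settings()].
#' @param assert stop if the achieved composite does not exceed
#'   `settings$threshold`.
#' @return list with elements `fit` (the `vpop`), `composite`, `p_error`
#'   (per-axis `|p_hat - p_star|`), `truth`, `targets`, `runtime_s`,
#'   `passed`.
#' @export
recovery_experiment <- function(spec, settings = calibration_settings(),
                                assert = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  cohort <- generate_cohort(spec)
  targets <- targets_from_truth(cohort, spec$truth, bins = spec$bins,
                                n_trial = spec$n_trial,
                                mode = spec$target_mode,
                                seed = spec$seed + 2L)
  fit <- calibrate_vpop(cohort, targets,
                        pairs = spec$truth$pairs, settings = settings)
  runtime <- proc.time()[["elapsed"]] - t0
  passed <- fit$composite > settings$threshold
  if (assert && !passed)
    stop(sprintf(paste0("recovery failed: composite %.4g <= threshold %g ",
                        "(seed %d, %d restarts; restart objectives: %s)"),
                 fit$composite, settings$threshold, settings$seed,
                 settings$restarts,
                 paste(signif(fit$restarts$objective, 4), collapse = ", ")))
  list(fit = fit, composite = fit$composite,
       p_error = abs(fit$solution$p - spec$truth$p), truth = spec$truth,
       targets = targets, runtime_s = runtime, passed = passed)
}
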