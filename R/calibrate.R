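#' Calibration settings
#'
#' @param threshold composite Fisher p-value above which a virtual
#'   population is accepted as statistically valid (default 0.05).
#' @param max_iter Nelder-Mead iteration cap per start (default 2000).
#' @param reltol Nelder-Mead relative convergence tolerance on the objective
#'   (default 1e-6).
#' @param restarts number of random starts per calibration (default 5).
#' @param seed master random seed; every stochastic step derives its seed
#'   from it and records it.
#' @param sigma_seed SD of the Gaussian perturbation applied in the
#'   unconstrained space when re-seeding from an accepted solution
#'   (default 0.25).
#' @param include which statistics enter the Fisher composite, subset of
#'   `c("mean", "sd", "bins")`.
#' @param vpop_n how the weighted VPop is represented in the t/F tests:
#'   `"kish"` (effective sample size of the weights) or `"trial"` (the
#'   target's own patient count on both sides).
#' @param attempt_factor ensemble attempt budget, as a multiple of the
#'   requested number of populations (default 20).
#' @param min_distance optional minimal L-infinity distance (on the bin
#'   probabilities) between accepted ensemble members; 0 disables the
#'   filter.
#' @param clip clip out-of-range responses into the edge bins (default
#'   TRUE).
#' @return a list of class `calibration_settings`.
#' @export
calibration_settings <- function(threshold = 0.05, max_iter = 2000,
                                 reltol = 1e-6, restarts = 5, seed = 1,
                                 sigma_seed = 0.25,
                                 include = c("mean", "sd", "bins"),
                                 vpop_n = c("kish", "trial"),
                                 attempt_factor = 20, min_distance = 0,
                                 clip = TRUE) {
  vpop_n <- match.arg(vpop_n)
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  if (sigma_seed < 0) stop("sigma_seed must be >= 0")
  structure(list(threshold = threshold, max_iter = max_iter,
                 reltol = reltol, restarts = restarts, seed = seed,
                 sigma_seed = sigma_seed, include = include,
                 vpop_n = vpop_n, attempt_factor = attempt_factor,
                 min_distance = min_distance, clip = clip),
            class = "calibration_settings")
}

#' Read calibration settings (and correlated axis pairs) from YAML/JSON
#'
#' Recognized top-level fields are the arguments of
#' [calibration_settings()] plus `pairs`, a list of `{k, l, rho}` records.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return list with elements `settings` and `pairs` (data.frame or NULL).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(sub(".*\\.", "", path))
  cfg <- if (ext == "json") jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  else yaml::yaml.load_file(path)
  pairs <- NULL
  if (!is.null(cfg$pairs)) {
    pairs <- do.call(rbind, lapply(cfg$pairs, function(r)
      data.frame(k = r$k, l = r$l,
                 rho = if (is.null(r$rho)) 0 else r$rho,
                 stringsAsFactors = FALSE)))
    cfg$pairs <- NULL
  }
  known <- names(formals(calibration_settings))
  cfg <- cfg[intersect(names(cfg), known)]
  list(settings = do.call(calibration_settings, cfg), pairs = pairs)
}

effective_n_for <- function(w, targets, settings) {
  if (settings$vpop_n == "kish")
    effective_sample_size(w)
  else vapply(targets, function(t) t$n_trial, 0)
}

#' Score one axes-weight solution against trial targets
#'
#' Pure composition of the pipeline: solution to prevalence weights to
#' weighted population statistics to per-statistic p-values to the Fisher
#' composite. Evaluating the same inputs twice returns identical reports.
#'
#' @param cohort a [vp_cohort()].
#' @param targets list of [trial_target()] objects.
#' @param sol an [axes_solution()].
#' @param binning an axis binning; recomputed from the cohort if omitted.
#' @param settings a [calibration_settings()].
#' @return a [gof_report()].
#' @export
evaluate_solution <- function(cohort, targets, sol,
                              binning = compute_axis_binning(cohort),
                              settings = calibration_settings()) {
  if (inherits(targets, "trial_target")) targets <- list(targets)
  w <- prevalence_weights(cohort, sol, binning)
  pop <- population_stats(cohort, w, targets, clip = settings$clip)
  gof_report(pop, targets, n_eff = effective_n_for(w, targets, settings),
             include = settings$include)
}

# objective for the optimizer: sum(log p) at the unconstrained coordinates;
# a solution that annihilates every VP scores the sentinel worst value.
solution_objective <- function(vec, template, cohort, binning, targets,
                               settings) {
  sol <- from_unconstrained(vec, template)
  w <- tryCatch(prevalence_weights(cohort, sol, binning),
                error = function(e) NULL)
  if (is.null(w)) return(-1e12)
  pop <- population_stats(cohort, w, targets, clip = settings$clip)
  rep <- gof_report(pop, targets,
                    n_eff = effective_n_for(w, targets, settings),
                    include = settings$include)
  obj <- attr(rep, "objective")
  if (!is.finite(obj)) -1e12 else obj
}

random_start <- function(template) {
  p <- stats::runif(length(template$p))
  pairs <- template$pairs
  if (!is.null(pairs)) pairs$rho <- stats::runif(nrow(pairs), -0.5, 0.5)
  axes_solution(stats::setNames(p, names(template$p)), pairs,
                mu = template$mu, sigma = template$sigma)
}

#' Calibrate a virtual population to trial targets
#'
#' Fits the axes-weight solution by maximizing the sum of log p-values
#' (equivalently the Fisher composite goodness-of-fit) with Nelder-Mead in
#' the unconstrained hyperspherical space, from `restarts` random starts
#' (bin probabilities initialized uniformly at random) or from a supplied
#' initial solution. The best solution over all starts, its prevalence
#' weights and its goodness-of-fit report are returned as a fitted-model
#' object.
#'
#' @param cohort a [vp_cohort()].
#' @param targets a [trial_target()] or list of them.
#' @param pairs optional data.frame `k, l, rho` declaring correlated axis
#'   pairs (the `rho` column gives initial values; it is optimized).
#' @param init optional [axes_solution()] used as the first start.
#' @param settings a [calibration_settings()].
#' @param binning precomputed axis binning (recomputed if omitted).
#' @return an object of class `vpop`; see [summary.vpop()], [coef.vpop()],
#'   [weights.vpop()], [predict.vpop()].
#' @examples
#' spec <- synthetic_spec(n_vp = 60, n_axes = 2, therapies = "tx",
#'                        seed = 7)
#' cohort <- generate_cohort(spec)
#' targets <- targets_from_truth(cohort, spec$truth)
#' fit <- calibrate_vpop(cohort, targets,
#'                       settings = calibration_settings(restarts = 2,
#'                                                       seed = 7))
#' summary(fit)
#' @export
calibrate_vpop <- function(cohort, targets, pairs = NULL, init = NULL,
                           settings = calibration_settings(),
                           binning = compute_axis_binning(cohort)) {
  validate_cohort(cohort)
  if (inherits(targets, "trial_target")) targets <- list(targets)
  m <- ncol(cohort$axes)
  template <- axes_solution(
    stats::setNames(rep(0.5, m), colnames(cohort$axes)),
    pairs = pairs,
    mu = colMeans(cohort$axes),
    sigma = apply(cohort$axes, 2L, stats::sd))
  if (!is.null(init)) {
    if (length(init$p) != m) stop("init has wrong number of axes")
    template$pairs <- if (!is.null(init$pairs)) init$pairs else template$pairs
  }

  best <- NULL
  restart_log <- list()
  for (r in seq_len(settings$restarts)) {
    seed_r <- settings$seed + r - 1L
    start <- if (r == 1L && !is.null(init)) {
      axes_solution(init$p, template$pairs, template$mu, template$sigma)
    } else with_seed(seed_r, random_start(template))
    v0 <- to_unconstrained(start)
    trace_env <- new.env()
    trace_env$obj <- numeric(0)
    fn <- function(v) {
      o <- solution_objective(v, template, cohort, binning, targets, settings)
      trace_env$obj <- c(trace_env$obj, o)
      -o
    }
    opt <- withCallingHandlers(
      stats::optim(as.numeric(v0), fn, method = "Nelder-Mead",
                   control = list(maxit = settings$max_iter,
                                  reltol = settings$reltol)),
      warning = function(w) {
        # Nelder-Mead in one dimension is fine here (verified against a
        # grid search); silence optim's generic advisory
        if (grepl("Nelder-Mead", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    obj <- -opt$value
    restart_log[[r]] <- data.frame(restart = r, seed = seed_r,
                                   objective = obj,
                                   evaluations = length(trace_env$obj),
                                   converged = opt$convergence == 0L)
    if (is.null(best) || obj > best$objective)
      best <- list(par = opt$par, objective = obj,
                   converged = opt$convergence == 0L,
                   trace = cummax(trace_env$obj), restart = r,
                   seed = seed_r)
  }

  sol <- from_unconstrained(best$par, template)
  w <- prevalence_weights(cohort, sol, binning)
  pop <- population_stats(cohort, w, targets, clip = settings$clip)
  report <- gof_report(pop, targets,
                       n_eff = effective_n_for(w, targets, settings),
                       include = settings$include)
  structure(
    list(solution = sol, weights = w, gof = report, stats = pop,
         composite = attr(report, "composite"),
         objective = attr(report, "objective"),
         converged = best$converged, trace = best$trace,
         restarts = do.call(rbind, restart_log),
         best_restart = best$restart, seed = best$seed,
         binning = binning, targets = targets, settings = settings,
         cohort = cohort, call = match.call()),
    class = "vpop")
}

#' Perturb an axes-weight solution for ensemble re-seeding
#'
#' Adds independent Gaussian noise (SD `sigma`) to every unconstrained
#' coordinate of the solution and maps back; `sigma = 0` is the identity.
#' This is how accepted solutions seed the search for alternate virtual
#' populations.
#'
#' @param sol an [axes_solution()].
#' @param sigma perturbation SD in the unconstrained space.
#' @param seed optional seed for reproducibility.
#' @return a perturbed [axes_solution()].
#' @export
perturb_solution <- function(sol, sigma = 0.25, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(sol)
  v <- to_unconstrained(sol)
  noise <- with_seed(seed, stats::rnorm(length(v), 0, sigma))
  from_unconstrained(as.numeric(v) + noise, template = attr(v, "template"))
}

#' Build an ensemble of alternate virtual populations
#'
#' Repeatedly calibrates the cohort to the same targets: the first start is
#' random, and once any member has been accepted each new attempt starts
#' from a Gaussian perturbation of a uniformly chosen accepted solution.
#' An attempt is accepted when its composite goodness-of-fit exceeds the
#' threshold; generation stops at `n_populations` accepted members or when
#' the attempt budget (`attempt_factor * n_populations`) is exhausted.
#'
#' @inheritParams calibrate_vpop
#' @param n_populations number of accepted virtual populations requested.
#' @return an object of class `vpop_ensemble`: `members` (list of `vpop`
#'   fits), `provenance` (per-member seed and parent), `threshold`,
#'   `attempts`, `acceptance_rate`.
#' @export
build_ensemble <- function(cohort, targets, n_populations,
                           pairs = NULL,
                           settings = calibration_settings(),
                           binning = compute_axis_binning(cohort)) {
  if (n_populations < 1) stop("n_populations must be >= 1")
  if (settings$threshold >= 1)
    stop("calibration-failure: composite p-values cannot exceed ",
         settings$threshold)
  budget <- ceiling(settings$attempt_factor * n_populations)
  members <- list()
  prov <- list()
  attempts <- 0L
  best_seen <- -Inf
  while (length(members) < n_populations && attempts < budget) {
    attempts <- attempts + 1L
    att_seed <- settings$seed + (attempts - 1L) * (settings$restarts + 1L)
    att_settings <- settings
    att_settings$seed <- att_seed
    init <- NULL
    parent <- NA_integer_
    if (length(members)) {
      parent <- with_seed(att_seed,
                          sample.int(length(members), 1L))
      init <- perturb_solution(members[[parent]]$solution,
                               sigma = settings$sigma_seed,
                               seed = att_seed + settings$restarts)
    }
    fit <- calibrate_vpop(cohort, targets, pairs = pairs, init = init,
                          settings = att_settings, binning = binning)
    best_seen <- max(best_seen, fit$composite)
    accept <- fit$composite > settings$threshold
    if (accept && settings$min_distance > 0 && length(members)) {
      d <- vapply(members, function(mbr)
        max(abs(mbr$solution$p - fit$solution$p)), 0)
      if (min(d) < settings$min_distance) accept <- FALSE
    }
    message(sprintf("attempt %d (seed %d): composite %.4g -> %s",
                    attempts, att_seed, fit$composite,
                    if (accept) "accepted" else "rejected"))
    if (accept) {
      members[[length(members) + 1L]] <- fit
      prov[[length(prov) + 1L]] <- data.frame(
        member = length(members), seed = att_seed, parent = parent,
        composite = fit$composite)
    }
  }
  if (!length(members))
    stop("calibration-failure: no acceptable virtual population in ",
         attempts, " attempts (best composite ", signif(best_seen, 4),
         ", threshold ", settings$threshold, ")")
  structure(list(members = members,
                 provenance = do.call(rbind, prov),
                 threshold = settings$threshold, attempts = attempts,
                 acceptance_rate = length(members) / attempts,
                 settings = settings),
            class = "vpop_ensemble")
}

#' @export
print.vpop_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d virtual population(s), threshold %g\n",
              length(x$members), x$threshold))
  cat(sprintf("  %d attempt(s), acceptance rate %.2f\n", x$attempts,
              x$acceptance_rate))
  invisible(x)
}

#' @export
summary.vpop_ensemble <- function(object, ...) {
  df <- do.call(rbind, lapply(seq_along(object$members), function(i) {
    m <- object$members[[i]]
    data.frame(member = i, composite = m$composite,
               objective = m$objective,
               n_eff = effective_sample_size(m$weights))
  }))
  cat(sprintf("Ensemble summary (%d members, threshold %g):\n",
              nrow(df), object$threshold))
  print(df, row.names = FALSE, digits = 4)
  invisible(df)
}
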