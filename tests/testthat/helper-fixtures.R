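# shared fixtures and independent oracles

# cohort whose 4 VPs cover the four bin combinations (LL, LU, UL, UU)
# on two axes; medians are 1.5 / 1.5
cell_cohort <- function(responses = c(0, 25, 50, 75)) {
  vp_cohort(axes = cbind(a = c(1, 1, 2, 2), b = c(1, 2, 1, 2)),
            responses = matrix(responses, 4, 1,
                               dimnames = list(NULL, "tx:6")))
}

# small random cohort with distinct axis values (no median ties)
random_cohort <- function(n, m, seed) {
  with_seed <- function(s, e) { set.seed(s); e }
  with_seed(seed, {
    vp_cohort(axes = matrix(rnorm(n * m), n, m,
                            dimnames = list(NULL, paste0("x", seq_len(m)))),
              responses = matrix(runif(n, -21, 100), n, 1,
                                 dimnames = list(NULL, "tx:6")))
  })
}

# brute-force prevalence weights: loops VP-by-VP and axis-by-axis,
# independent of the vectorized implementation
brute_force_weights <- function(cohort, p) {
  meds <- apply(cohort$axes, 2, median)
  n <- nrow(cohort$axes)
  u <- numeric(n)
  for (i in seq_len(n)) {
    f <- 1
    for (j in seq_along(p)) {
      if (cohort$axes[i, j] > meds[j]) f <- f * p[j]
      else f <- f * (1 - p[j])
    }
    u[i] <- f
  }
  u / sum(u)
}

# construct n x k data whose sample correlation matrix is exactly R,
# via orthonormal mean-zero columns times chol(R)
exact_cor_data <- function(R, n = nrow(R) + 2) {
  stopifnot(n - 1 >= ncol(R))
  H <- stats::contr.helmert(n)
  E <- apply(H, 2, function(v) v / sqrt(sum(v^2)))[, seq_len(ncol(R)),
                                                   drop = FALSE]
  X <- E %*% chol(R)
  colnames(X) <- colnames(R)
  X
}

# independent t / F / chi-squared CDF routes via the incomplete beta /
# gamma functions, used as oracles against the pt/pf/pchisq-based code
t_twosided_beta <- function(tstat, df)
  stats::pbeta(df / (df + tstat^2), df / 2, 1 / 2)
f_cdf_beta <- function(f, d1, d2)
  stats::pbeta(d1 * f / (d1 * f + d2), d1 / 2, d2 / 2)
chisq_sf_gamma <- function(x, df)
  1 - stats::pgamma(x, shape = df / 2, scale = 2)

# default synthetic recovery task (cohort + exact-expectation targets)
default_recovery_task <- function(seed = 1) {
  spec <- synthetic_spec(seed = seed)
  cohort <- generate_cohort(spec)
  targets <- targets_from_truth(cohort, spec$truth, bins = spec$bins,
                                n_trial = spec$n_trial, mode = "exact")
  list(spec = spec, cohort = cohort, targets = targets)
}

# minimal stand-in for a fitted vpop, for ensemble-analysis tests
fake_vpop <- function(cohort, w, p) {
  structure(list(cohort = cohort, weights = w,
                 solution = axes_solution(p)),
            class = "vpop")
}
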