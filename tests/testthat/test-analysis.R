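test_that("ensembles split into strong/weak responders by weighted mean", {
  mk <- function(mean_resp, p) {
    ch <- vp_cohort(axes = cbind(a = c(1, 2)),
                    responses = matrix(mean_resp, 2, 1,
                                       dimnames = list(NULL, "rtx:6")))
    fake_vpop(ch, setNames(c(0.5, 0.5), ch$vp_ids), setNames(p, "a"))
  }
  members <- list(mk(40, 0.1), mk(46, 0.5), mk(50, 0.9))
  sp <- split_ensemble_by_response(members, "rtx", 6,
                                   hi_cut = 48, lo_cut = 44.75)
  expect_equal(sp$means, c(40, 46, 50))
  expect_length(sp$strong, 1L)
  expect_length(sp$weak, 1L)
  expect_equal(sp$excluded, 2L)
  expect_false(sp$empty_strong || sp$empty_weak)

  # hi_cut = lo_cut partitions everything except exact ties
  sp2 <- split_ensemble_by_response(members, "rtx", 6,
                                    hi_cut = 46, lo_cut = 46)
  expect_length(sp2$strong, 1L)
  expect_length(sp2$weak, 1L)
  expect_equal(sp2$excluded, 2L)  # the exact tie at 46

  expect_error(split_ensemble_by_response(members, "rtx", 6,
                                          hi_cut = 40, lo_cut = 45),
               "hi_cut")
  # empty group warns but proceeds with the flag set
  expect_warning(sp3 <- split_ensemble_by_response(members, "rtx", 6,
                                                   hi_cut = 60,
                                                   lo_cut = 44.75),
                 "strong-responder")
  expect_true(sp3$empty_strong)
})

test_that("group contrasts rank axes by median axes-weight difference", {
  mk <- function(p) {
    ch <- vp_cohort(axes = cbind(hot = c(1, 2), cold = c(2, 1)),
                    responses = matrix(c(10, 20), 2, 1,
                                       dimnames = list(NULL, "rtx:6")))
    fake_vpop(ch, setNames(c(0.5, 0.5), ch$vp_ids),
              setNames(p, c("hot", "cold")))
  }
  strong <- list(mk(c(0.9, 0.55)), mk(c(0.9, 0.45)), mk(c(0.9, 0.5)))
  weak <- list(mk(c(0.1, 0.5)), mk(c(0.1, 0.6)), mk(c(0.1, 0.4)))
  gc <- contrast_groups(strong, weak)
  expect_s3_class(gc, "group_contrast")
  expect_equal(gc$axis[1L], "hot")
  expect_equal(gc$median_diff[1L], 0.8)
  # identical groups give all-zero differences
  gc0 <- contrast_groups(strong, strong)
  expect_equal(gc0$median_diff, c(0, 0))
  # medians/IQRs match an independent type-7 quantile computation
  cold_strong <- c(0.55, 0.45, 0.5)
  row <- gc[gc$axis == "cold", ]
  expect_equal(row$median_strong, median(cold_strong), tolerance = 1e-12)
  expect_equal(c(row$q1_strong, row$q3_strong),
               unname(quantile(cold_strong, c(0.25, 0.75), type = 7)),
               tolerance = 1e-12)
  expect_error(contrast_groups(strong, list()), "non-empty")
})

test_that("scenario re-statting applies fixed weights without refitting", {
  bins <- acr_bins()
  w <- setNames(c(0.7, 0.3), c("v1", "v2"))
  st <- restat_scenario(w, setNames(c(10, 20), c("v1", "v2")) |>
                          (\(x) matrix(x, 2, 1,
                                       dimnames = list(names(x), "s1")))(),
                        bins)
  expect_equal(st[[1L]]$mean, 13)
  # uniform weights reduce to the arithmetic mean
  wu <- setNames(rep(0.25, 4), paste0("v", 1:4))
  x <- matrix(c(5, 30, 55, 90), 4, 1,
              dimnames = list(names(wu), "s1"))
  expect_equal(restat_scenario(wu, x, bins)[[1L]]$mean, mean(x))
  # rows are aligned by vp_id, not by position
  xrev <- x[4:1, , drop = FALSE]
  expect_equal(restat_scenario(wu, xrev, bins)[[1L]]$mean, mean(x))
  expect_error(restat_scenario(wu, x[1:3, , drop = FALSE], bins),
               "alignment error.*v4")
})

test_that("baseline re-statting reproduces calibration stats bit-for-bit", {
  spec <- synthetic_spec(n_vp = 60, n_axes = 2, therapies = "tx",
                         n_analytes = 0, seed = 4)
  cohort <- generate_cohort(spec)
  targets <- targets_from_truth(cohort, spec$truth, n_trial = 200,
                                mode = "exact")
  fit <- calibrate_vpop(cohort, targets,
                        settings = calibration_settings(restarts = 1,
                                                        seed = 4))
  base <- predict(fit)
  expect_identical(base[[1L]]$mean, fit$stats[[1L]]$mean)
  expect_identical(base[[1L]]$sd, fit$stats[[1L]]$sd)
  expect_identical(unname(base[[1L]]$fractions),
                   unname(fit$stats[[1L]]$fractions))
})

test_that("correlated mediators collapse to the least-connected analyte", {
  # exact sample correlations: rho(A,B) = 0.9, rho(A,C) = 0.1, rho(B,C) = 0.5
  nm <- c("A", "B", "C")
  R <- matrix(c(1, 0.9, 0.1,
                0.9, 1, 0.5,
                0.1, 0.5, 1), 3, 3, dimnames = list(nm, nm))
  X <- exact_cor_data(R, n = 8)
  expect_equal(abs(cor(X)), abs(R), tolerance = 1e-12)
  kept <- prune_correlated_mediators(X, rho_cut = 0.8)
  # component {A, B}: mean |rho| is 0.5 for A vs 0.7 for B -> retain A
  expect_setequal(as.character(kept), c("A", "C"))
  expect_equal(attr(kept, "components"), list(c("A", "B")))

  # duplicate columns collapse to one
  Y <- cbind(A = X[, "A"], B = X[, "A"], C = X[, "C"])
  expect_length(prune_correlated_mediators(Y, 0.8), 2L)
  # mutually weakly correlated panel is fully retained
  expect_length(prune_correlated_mediators(X, 0.95), 3L)
  # invariant to sign flips and row permutations
  Xf <- X
  Xf[, "B"] <- -Xf[, "B"]
  expect_equal(as.character(prune_correlated_mediators(Xf, 0.8)),
               as.character(kept))
  expect_equal(as.character(prune_correlated_mediators(X[c(3, 1, 4, 2, 5:8), ],
                                                       0.8)),
               as.character(kept))
  # constant column: retained, flagged
  Z <- cbind(X, flat = rep(1, 8))
  kz <- prune_correlated_mediators(Z, 0.8)
  expect_true("flat" %in% kz)
  expect_equal(attr(kz, "flagged"), "flat")
})

test_that("exhaustive best-subset regression recovers exact linear truth", {
  set.seed(21)
  n <- 40
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("an", 1:6)))
  y <- 2 * X[, "an2"] - 3 * X[, "an5"]
  fit <- best_subset_regression(X, y, k = 2)
  expect_setequal(fit$analytes, c("an2", "an5"))
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients[c("an2", "an5")]), c(2, -3),
               tolerance = 1e-8)

  # k = 1 with uniform weights picks the highest squared correlation
  yn <- y + rnorm(n, 0, 3)
  f1 <- best_subset_regression(X, yn, k = 1)
  expect_equal(f1$analytes, names(which.max(cor(X, yn)[, 1]^2)))

  expect_error(best_subset_regression(X, y, k = 2, budget = 10),
               "budget error")
  expect_error(best_subset_regression(X, y, k = 7), "fewer candidate")
})

test_that("weighted subset selection matches an lm() re-enumeration oracle", {
  set.seed(22)
  n <- 30
  X <- matrix(rnorm(n * 8), n, 8,
              dimnames = list(NULL, paste0("an", 1:8)))
  y <- X[, 1] - 0.5 * X[, 4] + rnorm(n, 0, 1.5)
  w <- runif(n)
  w <- w / sum(w)
  for (k in 1:3) {
    fit <- best_subset_regression(X, y, w = w, k = k)
    # independent oracle: enumerate with lm(weights = )
    combos <- utils::combn(8, k)
    rss <- apply(combos, 2, function(cols) {
      d <- data.frame(y = y, X[, cols, drop = FALSE])
      sum(w * residuals(lm(y ~ ., data = d, weights = w))^2)
    })
    best <- colnames(X)[combos[, which.min(rss)]]
    expect_setequal(fit$analytes, best)
    # raw weighted R2 is monotone non-decreasing in k
    if (k > 1)
      expect_gte(fit$r_squared + 1e-12,
                 best_subset_regression(X, y, w = w, k = k - 1)$r_squared)
  }
})

test_that("selection frequencies count analytes across VPop models", {
  m1 <- structure(list(analytes = c("a", "b", "c", "d", "e"), k = 5),
                  class = "biomarker_model")
  m2 <- structure(list(analytes = c("a", "b", "c", "x", "y"), k = 5),
                  class = "biomarker_model")
  fr <- analyte_selection_frequency(list(m1, m2))
  expect_equal(sum(fr$count), 5 * 2)
  expect_equal(fr$fraction[match(c("a", "x"), fr$analyte)], c(1, 0.5))
  # unanimity
  fr1 <- analyte_selection_frequency(list(m1, m1, m1))
  expect_true(all(fr1$fraction == 1))
  expect_error(analyte_selection_frequency(list()), "at least one")
})

test_that("noise-free truth survives pruning and is re-selected end-to-end", {
  spec <- synthetic_spec(n_vp = 100, n_axes = 3, therapies = "tx",
                         n_analytes = 6, n_collinear = 2, seed = 6)
  cohort <- generate_cohort(spec)
  med <- cohort$mediators
  kept <- prune_correlated_mediators(med, 0.8)
  # the injected near-duplicates must have been collapsed
  expect_lt(length(kept), ncol(med))
  y <- 1.5 * med[, kept[1L]] - 2 * med[, kept[2L]]
  fit <- best_subset_regression(med[, kept], y, k = 2)
  expect_setequal(fit$analytes, kept[1:2])
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-6)
})
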