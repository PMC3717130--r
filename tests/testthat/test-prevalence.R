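test_that("hyperspherical transform hits its closed-form anchor points", {
  expect_equal(as.numeric(to_unconstrained(axes_solution(0.5))), pi / 4)
  expect_equal(as.numeric(to_unconstrained(axes_solution(0))), 0)
  expect_equal(as.numeric(to_unconstrained(axes_solution(1))), pi / 2)
  # atanh(0.46211715726...) = 0.5
  sol <- axes_solution(c(0.3, 0.7),
                       pairs = data.frame(k = 1, l = 2,
                                          rho = tanh(0.5)))
  v <- to_unconstrained(sol)
  expect_equal(as.numeric(v)[3L], 0.5, tolerance = 1e-12)
  back <- from_unconstrained(v)
  expect_equal(back$pairs$rho, sol$pairs$rho, tolerance = 1e-12)
})

test_that("transform round-trips and accepts any real vector", {
  set.seed(42)
  for (r in 1:1000) {
    m <- sample(1:6, 1)
    p <- runif(m)
    pairs <- if (m >= 2 && r %% 3 == 0)
      data.frame(k = 1, l = 2, rho = runif(1, -0.99, 0.99))
    sol <- axes_solution(p, pairs)
    back <- from_unconstrained(to_unconstrained(sol))
    expect_lt(max(abs(back$p - p)), 1e-12)
    if (!is.null(pairs)) expect_lt(abs(back$pairs$rho - pairs$rho), 1e-12)
  }
  # far outside [0, pi/2]: periodicity keeps p in range
  tpl <- axes_solution(0.5)
  out <- from_unconstrained(structure(10, template = tpl))
  expect_equal(out$p, sin(10)^2)
  expect_true(out$p >= 0 && out$p <= 1)
})

test_that("independent-axes weights match hand-computed products", {
  ch <- vp_cohort(axes = cbind(a = c(1, 2, 3, 4)),
                  responses = matrix(1:4, 4, 1,
                                     dimnames = list(NULL, "tx:6")))
  expect_equal(unname(weights_independent(ch, axes_solution(0.5))),
               rep(0.25, 4))
  expect_equal(unname(weights_independent(ch, axes_solution(1))),
               c(0, 0, 0.5, 0.5))

  # one VP per bin combination, p = (0.7, 0.2): products sum to 1 by design
  ch2 <- cell_cohort()
  expect_equal(unname(weights_independent(ch2, axes_solution(c(0.7, 0.2)))),
               c(0.3 * 0.8, 0.3 * 0.2, 0.7 * 0.8, 0.7 * 0.2))

  # a p pattern that annihilates every VP: only (U, L) survives, absent here
  ch3 <- vp_cohort(axes = cbind(a = c(1, 2), b = c(1, 2)),
                   responses = matrix(1:2, 2, 1,
                                      dimnames = list(NULL, "tx:6")))
  expect_error(weights_independent(ch3, axes_solution(c(1, 0))),
               "all-mass-lost")
})

test_that("weights are normalized, uniform at p = 1/2, monotone in p_j", {
  for (seed in 1:5) {
    ch <- random_cohort(15, 3, seed)
    set.seed(seed)
    p <- runif(3)
    w <- weights_independent(ch, axes_solution(p))
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
    # all p = 0.5 gives exactly uniform weights
    expect_equal(unname(weights_independent(ch, axes_solution(rep(0.5, 3)))),
                 rep(1 / 15, 15))
    # raising p_1 weakly increases the UPPER-bin mass of axis 1
    bn <- compute_axis_binning(ch)
    p_hi <- p
    p_hi[1L] <- min(1, p[1L] + 0.2)
    mass <- function(pp) sum(weights_independent(ch, axes_solution(pp))[
      bn$upper[, 1L]])
    expect_gte(mass(p_hi) + 1e-12, mass(p))
  }
})

test_that("weights agree with a VP-by-VP brute-force oracle", {
  set.seed(99)
  for (r in 1:10) {
    n <- sample(4:16, 1)
    m <- sample(1:4, 1)
    ch <- random_cohort(n, m, seed = 500 + r)
    p <- runif(m)
    expect_equal(unname(weights_independent(ch, axes_solution(p))),
                 brute_force_weights(ch, p), tolerance = 1e-12)
  }
})

test_that("copula rectangle probability obeys its closed forms", {
  # independence product
  expect_equal(bivariate_rectangle_probability("upper", "upper", 0.5, 0.5, 0),
               0.25)
  expect_equal(bivariate_rectangle_probability("upper", "lower", 0.3, 0.8, 0),
               0.3 * 0.2)
  # orthant closed form 1/4 + asin(rho) / (2 pi)
  expect_equal(bivariate_rectangle_probability("upper", "upper", 0.5, 0.5, 0.5),
               1 / 3, tolerance = 1e-8)
  for (rho in c(-0.8, -0.3, 0.2, 0.9)) {
    expect_equal(
      bivariate_rectangle_probability("upper", "upper", 0.5, 0.5, rho),
      1 / 4 + asin(rho) / (2 * pi), tolerance = 1e-8)
    # central symmetry: P(LL) = P(UU)
    expect_equal(
      bivariate_rectangle_probability("lower", "lower", 0.5, 0.5, rho),
      bivariate_rectangle_probability("upper", "upper", 0.5, 0.5, rho),
      tolerance = 1e-10)
  }
  # marginals are preserved: the four cells sum to 1 and rows sum to p
  p_k <- 0.3; p_l <- 0.75; rho <- 0.6
  cells <- outer(c(FALSE, TRUE), c(FALSE, TRUE),
                 Vectorize(function(bk, bl)
                   bivariate_rectangle_probability(bk, bl, p_k, p_l, rho)))
  expect_equal(sum(cells), 1, tolerance = 1e-8)
  expect_equal(sum(cells[2L, ]), p_k, tolerance = 1e-8)
  expect_equal(sum(cells[, 2L]), p_l, tolerance = 1e-8)
  expect_error(bivariate_rectangle_probability("upper", "upper", .5, .5, 1),
               "rho")
})

test_that("copula rectangles match a Monte-Carlo oracle within 3 SE", {
  set.seed(7)
  rho <- 0.6; p_k <- 0.3; p_l <- 0.75
  n <- 1e6
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  ck <- qnorm(1 - p_k); cl <- qnorm(1 - p_l)
  for (bk in c(FALSE, TRUE)) for (bl in c(FALSE, TRUE)) {
    hit <- (if (bk) z1 > ck else z1 <= ck) & (if (bl) z2 > cl else z2 <= cl)
    phat <- mean(hit)
    se <- sqrt(phat * (1 - phat) / n)
    expect_lt(abs(bivariate_rectangle_probability(bk, bl, p_k, p_l, rho) -
                    phat), 3 * se)
  }
})

test_that("copula weights reduce to the independent form at rho = 0", {
  for (seed in 1:5) {
    ch <- random_cohort(12, 4, seed)
    set.seed(seed)
    p <- runif(4)
    w0 <- weights_with_copula(
      ch, axes_solution(p, pairs = data.frame(k = "x1", l = "x3", rho = 0)))
    wi <- weights_independent(ch, axes_solution(p))
    expect_lt(max(abs(w0 - wi)), 1e-8)
  }
})

test_that("copula weights on the four-cell cohort match the arcsin form", {
  ch <- cell_cohort()
  sol <- axes_solution(c(0.5, 0.5),
                       pairs = data.frame(k = "a", l = "b", rho = 0.5))
  w <- weights_with_copula(ch, sol)
  expect_equal(unname(w), c(1 / 3, 1 / 6, 1 / 6, 1 / 3), tolerance = 1e-8)
})

test_that("Kish effective sample size covers its extreme and middle cases", {
  expect_equal(effective_sample_size(rep(0.01, 100)), 100)
  expect_equal(effective_sample_size(c(1, 0, 0, 0)), 1)
  expect_equal(effective_sample_size(c(0.5, 0.25, 0.25)), 1 / 0.375)
  expect_error(effective_sample_size(c(0.5, -0.1)), "non-negative")
})
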