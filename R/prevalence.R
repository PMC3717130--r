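#' Construct an axes-weight solution
#'
#' The optimizer's variable: one upper-bin probability `p_j` per mechanistic
#' axis, plus an optional set of pairwise correlations coupling two axes
#' through a Gaussian copula. Since the two bin probabilities on an axis sum
#' to one, `p_j` is the only free probability per axis.
#'
#' @param p numeric vector of upper-bin probabilities in `[0, 1]`, ideally
#'   named by axis.
#' @param pairs optional data.frame with columns `k`, `l` (axis names or
#'   indices) and `rho` (latent bivariate-normal correlation, `|rho| < 1`).
#'   An axis may appear in at most one pair.
#' @param mu,sigma optional per-axis cohort mean and SD, recorded for the
#'   copula formulation (the rectangle limits themselves depend only on the
#'   bin probabilities).
#' @return an object of class `axes_solution`.
#' @export
axes_solution <- function(p, pairs = NULL, mu = NULL, sigma = NULL) {
  p <- as.numeric(p) |> stats::setNames(names(p))
  if (any(p < 0 | p > 1)) stop("upper-bin probabilities must lie in [0, 1]")
  if (!is.null(pairs)) {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    if (!all(c("k", "l", "rho") %in% names(pairs)))
      stop("pairs must have columns k, l, rho")
    if (nrow(pairs)) {
      if (any(abs(pairs$rho) >= 1)) stop("|rho| must be < 1")
      ax <- c(pairs$k, pairs$l)
      if (anyDuplicated(ax))
        stop("an axis may appear in at most one correlation pair")
    } else pairs <- NULL
  }
  structure(list(p = p, pairs = pairs, mu = mu, sigma = sigma),
            class = "axes_solution")
}

#' @export
print.axes_solution <- function(x, ...) {
  cat("Axes-weight solution (", length(x$p), " axes",
      if (!is.null(x$pairs)) paste0(", ", nrow(x$pairs), " correlated pair(s)"),
      ")\n", sep = "")
  print(round(x$p, 4))
  if (!is.null(x$pairs)) print(x$pairs)
  invisible(x)
}

# resolve pair axis references (name or index) to column indices
pair_indices <- function(sol, axis_names) {
  if (is.null(sol$pairs)) return(NULL)
  res <- function(a) {
    if (is.numeric(a)) return(as.integer(a))
    i <- match(a, axis_names)
    if (anyNA(i)) stop("unknown axis in correlation pair: ",
                       paste(a[is.na(i)], collapse = ", "))
    i
  }
  data.frame(k = res(sol$pairs$k), l = res(sol$pairs$l), rho = sol$pairs$rho)
}

# ---- hyperspherical transform ---------------------------------------------

#' Map an axes-weight solution to unconstrained optimizer coordinates
#'
#' Bin probabilities are re-parameterized hyperspherically as
#' `p = sin^2(theta)` (the two-bin case), and correlations through the
#' inverse hyperbolic tangent, so the optimizer's independent variables can
#' vary over the whole real line with no edge complications at 0, 1 or
#' +/- 1.
#'
#' @param sol an [axes_solution()].
#' @return numeric vector of length `M + #pairs` (`theta` coordinates first,
#'   then `atanh(rho)`), carrying the solution skeleton as attribute
#'   `"template"` so [from_unconstrained()] can invert it.
#' @export
to_unconstrained <- function(sol) {
  stopifnot(inherits(sol, "axes_solution"))
  theta <- asin(sqrt(sol$p))
  z <- if (!is.null(sol$pairs)) atanh(sol$pairs$rho) else numeric(0)
  structure(c(unname(theta), z), template = sol)
}

#' Map unconstrained optimizer coordinates back to an axes-weight solution
#'
#' Inverse of [to_unconstrained()] on its image; any real vector is valid
#' (`sin^2` is periodic, `tanh` maps into `(-1, 1)`).
#'
#' @param vec numeric vector; `template` defaults to the attribute stamped
#'   by [to_unconstrained()].
#' @param template an `axes_solution` providing names and pair structure.
#' @return an [axes_solution()].
#' @export
from_unconstrained <- function(vec, template = attr(vec, "template")) {
  if (is.null(template)) stop("no solution template available")
  m <- length(template$p)
  k <- if (is.null(template$pairs)) 0L else nrow(template$pairs)
  if (length(vec) != m + k)
    stop("coordinate vector has length ", length(vec), ", expected ", m + k)
  p <- sin(vec[seq_len(m)])^2 |> stats::setNames(names(template$p))
  pairs <- template$pairs
  if (k) pairs$rho <- tanh(vec[m + seq_len(k)])
  axes_solution(p, pairs, mu = template$mu, sigma = template$sigma)
}

# ---- copula rectangle ------------------------------------------------------

# standard bivariate normal CDF P(Z1 <= x, Z2 <= y; rho), deterministic
binorm_cdf <- function(x, y, rho) {
  if (x == -Inf || y == -Inf) return(0)
  if (x == Inf && y == Inf) return(1)
  if (x == Inf) return(stats::pnorm(y))
  if (y == Inf) return(stats::pnorm(x))
  v <- mvtnorm::pmvnorm(lower = c(-Inf, -Inf), upper = c(x, y),
                        corr = matrix(c(1, rho, rho, 1), 2L),
                        algorithm = mvtnorm::TVPACK(abseps = 1e-10))
  as.numeric(v)
}

# P(Z in rect; rho) for standard bivariate normal, limits lo/hi per margin.
# Product of marginals at rho = 0; CDF inclusion-exclusion otherwise.
binorm_rect <- function(lo1, hi1, lo2, hi2, rho) {
  if (hi1 <= lo1 || hi2 <= lo2) return(0)
  m1 <- stats::pnorm(hi1) - stats::pnorm(lo1)
  m2 <- stats::pnorm(hi2) - stats::pnorm(lo2)
  if (rho == 0) return(m1 * m2)
  if (m1 == 0 || m2 == 0) return(0)
  if (m1 == 1) return(m2)   # margin 1 spans the whole line
  if (m2 == 1) return(m1)
  v <- binorm_cdf(hi1, hi2, rho) - binorm_cdf(lo1, hi2, rho) -
    binorm_cdf(hi1, lo2, rho) + binorm_cdf(lo1, lo2, rho)
  min(max(v, 0), 1)
}

# per-axis latent cut: upper bin carries mass p => cut at qnorm(1 - p)
bin_limits <- function(upper, p) {
  z <- stats::qnorm(1 - p)
  if (upper) c(z, Inf) else c(-Inf, z)
}

#' Gaussian-copula bin rectangle probability
#'
#' Probability that a standard bivariate normal with correlation `rho` falls
#' in the rectangle corresponding to one bin on each of two correlated axes.
#' Each axis is cut at the latent value whose upper tail carries its
#' upper-bin probability, so the marginals are preserved exactly and at
#' `rho = 0` the probability reduces to the product of the two marginal bin
#' probabilities.
#'
#' @param bin_k,bin_l `"lower"`/`"upper"` (or logical, TRUE = upper).
#' @param p_k,p_l upper-bin probabilities of the two axes, in `[0, 1]`.
#' @param rho latent correlation, `|rho| < 1`.
#' @return the rectangle probability (absolute accuracy better than 1e-8).
#' @export
bivariate_rectangle_probability <- function(bin_k, bin_l, p_k, p_l, rho) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (p_k < 0 || p_k > 1 || p_l < 0 || p_l > 1)
    stop("bin probabilities must lie in [0, 1]")
  up <- function(b) if (is.logical(b)) b else
    match.arg(tolower(b), c("lower", "upper")) == "upper"
  lk <- bin_limits(up(bin_k), p_k)
  ll <- bin_limits(up(bin_l), p_l)
  binorm_rect(lk[1L], lk[2L], ll[1L], ll[2L], rho)
}

# ---- prevalence weights ----------------------------------------------------

normalize_weights <- function(u, vp_ids) {
  s <- sum(u)
  if (s <= 0)
    stop("all-mass-lost: every VP received zero prevalence weight")
  stats::setNames(u / s, vp_ids)
}

#' Prevalence weights under independent axes
#'
#' Each VP's unnormalized weight is the product over axes of the probability
#' of the bin it occupies (`p_j` if UPPER, `1 - p_j` if LOWER); weights are
#' normalized to sum to one, so each is the fraction of the virtual
#' population that the VP statistically represents.
#'
#' @param cohort a [vp_cohort()].
#' @param sol an [axes_solution()] (correlation pairs, if any, are ignored).
#' @param binning an [compute_axis_binning()] result; recomputed if omitted.
#' @return named numeric vector of N normalized weights.
#' @export
weights_independent <- function(cohort, sol, binning = compute_axis_binning(cohort)) {
  upper <- binning$upper
  p <- sol$p
  if (length(p) != ncol(upper))
    stop("solution has ", length(p), " probabilities for ", ncol(upper), " axes")
  u <- rep(1, nrow(upper))
  for (j in seq_along(p))
    u <- u * ifelse(upper[, j], p[j], 1 - p[j])
  normalize_weights(u, cohort$vp_ids)
}

#' Prevalence weights with Gaussian-copula axis correlations
#'
#' As [weights_independent()], except that for each correlated axis pair the
#' two independent bin factors are replaced by the joint
#' [bivariate_rectangle_probability()] of the VP's bin combination, coupling
#' the two binned marginals through a latent bivariate normal while
#' preserving them. With all `rho = 0` this reduces to the independent form.
#'
#' @inheritParams weights_independent
#' @return named numeric vector of N normalized weights.
#' @export
weights_with_copula <- function(cohort, sol, binning = compute_axis_binning(cohort)) {
  pairs <- pair_indices(sol, colnames(cohort$axes))
  if (is.null(pairs) || !nrow(pairs))
    return(weights_independent(cohort, sol, binning))
  upper <- binning$upper
  p <- sol$p
  in_pair <- c(pairs$k, pairs$l)
  u <- rep(1, nrow(upper))
  for (j in setdiff(seq_along(p), in_pair))
    u <- u * ifelse(upper[, j], p[j], 1 - p[j])
  for (r in seq_len(nrow(pairs))) {
    k <- pairs$k[r]; l <- pairs$l[r]; rho <- pairs$rho[r]
    # the four bin-combination cells, indexed (upper_k, upper_l)
    cell <- matrix(NA_real_, 2L, 2L)
    for (bk in 0:1) for (bl in 0:1)
      cell[bk + 1L, bl + 1L] <- bivariate_rectangle_probability(
        as.logical(bk), as.logical(bl), p[k], p[l], rho)
    u <- u * cell[cbind(upper[, k] + 1L, upper[, l] + 1L)]
  }
  normalize_weights(u, cohort$vp_ids)
}

#' Prevalence weights for an axes-weight solution
#'
#' Dispatches to the copula form when the solution carries correlation
#' pairs, and to the independent-axes product otherwise.
#'
#' @inheritParams weights_independent
#' @return named numeric vector of N normalized weights.
#' @export
prevalence_weights <- function(cohort, sol, binning = compute_axis_binning(cohort)) {
  if (!is.null(sol$pairs) && nrow(sol$pairs))
    weights_with_copula(cohort, sol, binning)
  else weights_independent(cohort, sol, binning)
}

#' Kish effective sample size of a weight vector
#'
#' `(sum w)^2 / sum(w^2)`: the number of equally-weighted observations with
#' the same variance-carrying capacity as the weighted sample. Equals N for
#' uniform weights and 1 when a single VP carries all mass. Used to
#' parameterize the t- and F-tests for a weighted virtual population.
#'
#' @param w numeric weight vector (any positive scale).
#' @return scalar effective sample size.
#' @export
effective_sample_size <- function(w) {
  if (any(w < 0)) stop("weights must be non-negative")
  sum(w)^2 / sum(w^2)
}

#' Write prevalence weights / an axes-weight solution to CSV
#'
#' @param w named weight vector (names are VP ids).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(w, path) {
  utils::write.csv(data.frame(vp_id = names(w), weight = as.numeric(w)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @param sol an [axes_solution()].
#' @export
write_solution <- function(sol, path) {
  nm <- names(sol$p)
  if (is.null(nm)) nm <- paste0("axis", seq_along(sol$p))
  df <- data.frame(axis = nm, p_upper = as.numeric(sol$p),
                   pair_k = NA, pair_l = NA, rho = NA)
  if (!is.null(sol$pairs))
    df <- rbind(df, data.frame(axis = NA, p_upper = NA,
                               pair_k = sol$pairs$k, pair_l = sol$pairs$l,
                               rho = sol$pairs$rho))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
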