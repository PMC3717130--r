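#' Median-split binning of mechanistic axes
#'
#' Splits every mechanistic axis at its empirical median into a LOWER and an
#' UPPER bin, so that each axis carries a single free upper-bin probability.
#' Values equal to the median are assigned to LOWER: the bins are the
#' half-open intervals `(-Inf, med]` and `(med, Inf)`, which makes the
#' assignment deterministic and reproducible from the cutpoints alone.
#'
#' @param cohort a [vp_cohort()].
#' @return An object of class `axis_binning`: `cutpoints` (named vector of
#'   per-axis medians), `upper` (N x M logical matrix, TRUE = UPPER bin) and
#'   `semantics` (a string recording boundary ownership).
#' @export
compute_axis_binning <- function(cohort) {
  validate_cohort(cohort)
  C <- cohort$axes
  cut <- apply(C, 2L, stats::median)
  upper <- sweep(C, 2L, cut, `>`)
  n_up <- colSums(upper)
  bad <- colnames(C)[n_up == 0L | n_up == nrow(C)]
  if (length(bad))
    stop("degenerate axis (one median bin empty): ",
         paste(bad, collapse = ", "))
  structure(
    list(cutpoints = cut, upper = upper,
         semantics = "LOWER = (-Inf, median], UPPER = (median, Inf)"),
    class = "axis_binning")
}

#' @export
print.axis_binning <- function(x, ...) {
  cat("Axis binning (", length(x$cutpoints), " axes, ", nrow(x$upper),
      " VPs); ", x$semantics, "\n", sep = "")
  invisible(x)
}
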