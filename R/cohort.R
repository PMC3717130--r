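#' Construct a virtual-patient cohort
#'
#' A cohort bundles the per-VP mechanistic-axis coefficients, the simulated
#' ACR-N responses (percent improvement; negative values are worsening) for
#' each therapy and sample time, and optionally a panel of baseline synovial
#' mediator concentrations. Prevalence weighting never modifies a cohort;
#' every virtual population derived from it is a reweighting of these rows.
#'
#' @param axes numeric matrix or data.frame, one row per VP, one column per
#'   mechanistic axis (dimensionless coefficients). Column names are the axis
#'   names.
#' @param responses numeric matrix or data.frame of simulated ACR-N responses
#'   (percent scale), one column per therapy/timepoint named
#'   `"<therapy>:<months>"`, e.g. `"rituximab:6"`.
#' @param vp_ids character vector of unique VP identifiers; defaults to
#'   `vp1, vp2, ...`.
#' @param mediators optional numeric matrix or data.frame of baseline
#'   mediator concentrations (arbitrary units), one column per analyte.
#' @return An object of class `vp_cohort` with elements `vp_ids`, `axes`,
#'   `responses`, `mediators`.
#' @export
vp_cohort <- function(axes, responses, vp_ids = NULL, mediators = NULL) {
  axes <- as.matrix(axes)
  responses <- as.matrix(responses)
  storage.mode(axes) <- "double"
  storage.mode(responses) <- "double"
  n <- nrow(axes)
  if (is.null(vp_ids)) vp_ids <- paste0("vp", seq_len(n))
  vp_ids <- as.character(vp_ids)
  if (is.null(colnames(axes)))
    colnames(axes) <- paste0("axis", seq_len(ncol(axes)))
  if (!is.null(mediators)) {
    mediators <- as.matrix(mediators)
    storage.mode(mediators) <- "double"
    if (is.null(colnames(mediators)))
      colnames(mediators) <- paste0("analyte", seq_len(ncol(mediators)))
  }
  obj <- structure(
    list(vp_ids = vp_ids, axes = axes, responses = responses,
         mediators = mediators),
    class = "vp_cohort")
  validate_cohort(obj)
  obj
}

validate_cohort <- function(x) {
  stopifnot(inherits(x, "vp_cohort"))
  n <- nrow(x$axes)
  if (n < 2L)
    stop("cohort must contain at least 2 virtual patients (has ", n, ")")
  if (ncol(x$axes) < 1L)
    stop("cohort must contain at least 1 mechanistic axis")
  if (length(x$vp_ids) != n)
    stop("vp_ids length (", length(x$vp_ids), ") does not match rows (", n, ")")
  dup <- x$vp_ids[duplicated(x$vp_ids)]
  if (length(dup))
    stop("duplicate vp_id: ", paste(unique(dup), collapse = ", "))
  if (anyNA(x$axes))
    stop("missing values in axes_values are not allowed")
  if (nrow(x$responses) != n)
    stop("responses rows (", nrow(x$responses), ") do not match cohort size (", n, ")")
  if (anyNA(x$responses)) {
    bad <- colnames(x$responses)[colSums(is.na(x$responses)) > 0]
    stop("response column(s) not fully populated: ", paste(bad, collapse = ", "))
  }
  if (!is.null(x$mediators) && nrow(x$mediators) != n)
    stop("mediators rows do not match cohort size")
  invisible(x)
}

#' @export
print.vp_cohort <- function(x, ...) {
  cat("Virtual-patient cohort\n")
  cat("  VPs:      ", nrow(x$axes), "\n")
  cat("  axes:     ", ncol(x$axes), " (", paste(utils::head(colnames(x$axes), 4), collapse = ", "),
      if (ncol(x$axes) > 4) ", ..." else "", ")\n", sep = "")
  cat("  responses:", ncol(x$responses), "therapy x time column(s)\n")
  if (!is.null(x$mediators))
    cat("  mediators:", ncol(x$mediators), "analyte(s)\n")
  invisible(x)
}

#' Number of VPs and axes
#' @param x a `vp_cohort`
#' @param ... unused
#' @return `dim.vp_cohort` returns `c(N, M)`.
#' @export
dim.vp_cohort <- function(x) c(nrow(x$axes), ncol(x$axes))

#' Extract one response column from a cohort
#'
#' @param cohort a `vp_cohort`
#' @param therapy therapy label
#' @param months sample time in months
#' @return numeric vector of ACR-N responses aligned to `cohort$vp_ids`.
#' @export
response_column <- function(cohort, therapy, months) {
  key <- paste0(therapy, ":", months)
  idx <- match(key, colnames(cohort$responses))
  if (is.na(idx))
    stop("no response column for therapy '", therapy, "' at ", months,
         " months; available: ", paste(colnames(cohort$responses), collapse = ", "))
  cohort$responses[, idx]
}

# ---- cohort CSV dialect ----------------------------------------------------
# header columns: vp_id, axis:<name> (xM), resp:<therapy>:<months> (xTS),
# med:<analyte> (optional). Roles are resolved case-insensitively on the
# prefix; an explicit schema overrides prefix detection.

#' Read a virtual-patient cohort from CSV/TSV
#'
#' Column roles are resolved from the header: `vp_id`, `axis:<name>`,
#' `resp:<therapy>:<months>`, `med:<analyte>` (prefixes matched
#' case-insensitively). An explicit `schema` can override detection for
#' spreadsheets exported with other headers.
#'
#' @param path CSV or TSV file (delimiter chosen by extension).
#' @param schema optional list with elements `vp_id` (column name), `axes`
#'   (named character vector, `axis name = column name`), `responses`
#'   (data.frame with columns `column`, `therapy`, `months`) and optionally
#'   `mediators` (named character vector).
#' @return a validated [vp_cohort()].
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  nm <- names(raw)
  if (anyDuplicated(nm))
    stop("duplicate column(s) in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (is.null(schema)) {
    lower <- tolower(nm)
    id_col <- nm[lower == "vp_id"]
    if (length(id_col) != 1L)
      stop("schema error: expected exactly one 'vp_id' column")
    ax_cols <- nm[startsWith(lower, "axis:")]
    rs_cols <- nm[startsWith(lower, "resp:")]
    md_cols <- nm[startsWith(lower, "med:")]
    if (!length(ax_cols)) stop("schema error: no 'axis:<name>' columns found")
    if (!length(rs_cols)) stop("schema error: no 'resp:<therapy>:<months>' columns found")
    parts <- strsplit(sub("^[Rr][Ee][Ss][Pp]:", "", rs_cols), ":", fixed = TRUE)
    bad <- rs_cols[lengths(parts) != 2L]
    if (length(bad))
      stop("schema error: response column(s) not of form resp:<therapy>:<months>: ",
           paste(bad, collapse = ", "))
    schema <- list(
      vp_id = id_col,
      axes = stats::setNames(ax_cols, sub("^[Aa][Xx][Ii][Ss]:", "", ax_cols)),
      responses = data.frame(
        column = rs_cols,
        therapy = vapply(parts, `[`, "", 1L),
        months = as.numeric(vapply(parts, `[`, "", 2L)),
        stringsAsFactors = FALSE),
      mediators = if (length(md_cols))
        stats::setNames(md_cols, sub("^[Mm][Ee][Dd]:", "", md_cols)))
  }
  missing_cols <- setdiff(
    c(schema$vp_id, unname(schema$axes), schema$responses$column,
      unname(schema$mediators)), nm)
  if (length(missing_cols))
    stop("schema error: column(s) absent from file: ",
         paste(missing_cols, collapse = ", "))

  num <- function(cols, what) {
    m <- matrix(NA_real_, nrow(raw), length(cols))
    for (j in seq_along(cols)) {
      v <- suppressWarnings(as.numeric(raw[[cols[j]]]))
      bad <- which(is.na(v) & !(trimws(raw[[cols[j]]]) %in% c("NA", "")))
      if (length(bad))
        stop("parse error: non-numeric ", what, " value in column '", cols[j],
             "', row ", bad[1L], " ('", raw[[cols[j]]][bad[1L]], "')")
      m[, j] <- v
    }
    m
  }
  axes <- num(unname(schema$axes), "axis")
  colnames(axes) <- names(schema$axes)
  responses <- num(schema$responses$column, "response")
  colnames(responses) <- paste0(schema$responses$therapy, ":",
                                schema$responses$months)
  mediators <- NULL
  if (length(schema$mediators)) {
    mediators <- num(unname(schema$mediators), "mediator")
    colnames(mediators) <- names(schema$mediators)
  }
  vp_cohort(axes, responses, vp_ids = raw[[schema$vp_id]],
            mediators = mediators)
}

#' Write a cohort to CSV in the canonical dialect
#'
#' @param cohort a `vp_cohort`
#' @param path output CSV path
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  df <- data.frame(vp_id = cohort$vp_ids, stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (j in colnames(cohort$axes))
    df[[paste0("axis:", j)]] <- cohort$axes[, j]
  for (j in colnames(cohort$responses))
    df[[paste0("resp:", j)]] <- cohort$responses[, j]
  if (!is.null(cohort$mediators))
    for (j in colnames(cohort$mediators))
      df[[paste0("med:", j)]] <- cohort$mediators[, j]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---- trial targets ---------------------------------------------------------

#' Default ACR-N response bins
#'
#' The conventional four ACR response bins on the ACR-N percent-improvement
#' scale: below 20, 20-50, 50-70 and 70 or more. Intervals are half-open
#' `[lo, hi)`; the edge bins extend to -Inf/+Inf. The 20-50 midpoint of 35
#' is the standard convention; edge-bin midpoints default to 10 and 85 and
#' are configurable.
#'
#' @param midpoints numeric length-4 vector of bin midpoints (ACR-N %).
#' @return data.frame with columns `label`, `lo`, `hi`, `mid`.
#' @export
acr_bins <- function(midpoints = c(10, 35, 60, 85)) {
  stopifnot(length(midpoints) == 4L)
  data.frame(
    label = c("<20", "20-50", "50-70", ">=70"),
    lo = c(-Inf, 20, 50, 70),
    hi = c(20, 50, 70, Inf),
    mid = as.numeric(midpoints),
    stringsAsFactors = FALSE)
}

#' Construct a trial target
#'
#' One calibration target: the reported response distribution of a clinical
#' trial arm for one therapy at one sample time, as bin counts plus the
#' trial mean and standard deviation. When `mean`/`sd` are not reported they
#' are reconstructed from the binned distribution via
#' [trial_stats_from_bins()].
#'
#' @param therapy therapy label.
#' @param months sample time (months).
#' @param n_trial trial patient count `N_T`.
#' @param bins data.frame with columns `label`, `lo`, `hi`, `mid`, `count`;
#'   bins must be ordered, non-overlapping, with midpoints inside their bin
#'   and counts summing to `n_trial`.
#' @param mean,sd optional reported trial mean and SD (ACR-N %).
#' @return an object of class `trial_target`.
#' @export
trial_target <- function(therapy, months, n_trial, bins,
                         mean = NULL, sd = NULL) {
  bins <- as.data.frame(bins, stringsAsFactors = FALSE)
  need <- c("label", "lo", "hi", "mid", "count")
  if (!all(need %in% names(bins)))
    stop("bins must have columns ", paste(need, collapse = ", "))
  bins <- bins[need]
  for (v in c("lo", "hi", "mid", "count")) bins[[v]] <- as.numeric(bins[[v]])
  if (nrow(bins) < 1L) stop("at least one bin required")
  if (any(bins$count < 0)) stop("bin counts must be non-negative")
  if (any(bins$hi <= bins$lo)) stop("each bin needs lo < hi")
  if (is.unsorted(bins$lo, strictly = TRUE) ||
      any(utils::head(bins$hi, -1) > utils::tail(bins$lo, -1) + 1e-9))
    stop("bins must be ordered and non-overlapping")
  if (any(bins$mid < bins$lo | bins$mid > bins$hi))
    stop("bin midpoints must lie inside their bins")
  if (abs(sum(bins$count) - n_trial) > 1e-9)
    stop("consistency error: bin counts sum to ", sum(bins$count),
         " but n_trial is ", n_trial)
  obj <- structure(
    list(therapy = as.character(therapy), months = as.numeric(months),
         n_trial = as.numeric(n_trial), bins = bins,
         mean = if (!is.null(mean)) as.numeric(mean),
         sd = if (!is.null(sd)) as.numeric(sd)),
    class = "trial_target")
  if (is.null(obj$mean) || is.null(obj$sd)) {
    ms <- trial_stats_from_bins(obj)
    if (is.null(obj$mean)) obj$mean <- ms[["mean"]]
    if (is.null(obj$sd)) obj$sd <- ms[["sd"]]
  }
  obj
}

#' @export
print.trial_target <- function(x, ...) {
  cat(sprintf("Trial target: %s at %g months (N_T = %g)\n",
              x$therapy, x$months, x$n_trial))
  cat(sprintf("  mean %.2f, sd %.2f; bins: %s\n", x$mean, x$sd,
              paste(sprintf("%s=%g", x$bins$label, x$bins$count),
                    collapse = ", ")))
  invisible(x)
}

#' Read trial targets
#'
#' CSV dialect: one row per bin with columns `therapy, months, n_trial,
#' bin_label, bin_lo, bin_hi, bin_mid, count` and optional `mean, sd`
#' (constant within a therapy/months group). JSON/YAML dialect: a list of
#' records each carrying `therapy, months, n_trial, bins` (list of objects
#' with `label, lo, hi, mid, count`) and optional `mean, sd`.
#'
#' @param path `.csv`/`.tsv`, `.json`, `.yaml`/`.yml` file.
#' @return list of [trial_target()] objects.
#' @export
read_targets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("json", "yaml", "yml")) {
    recs <- if (ext == "json")
      jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    else yaml::yaml.load_file(path)
    return(lapply(recs, function(r) {
      bins <- do.call(rbind, lapply(r$bins, function(b)
        data.frame(label = b$label, lo = null_inf(b$lo, -Inf),
                   hi = null_inf(b$hi, Inf), mid = b$mid, count = b$count,
                   stringsAsFactors = FALSE)))
      trial_target(r$therapy, r$months, r$n_trial, bins,
                   mean = r$mean, sd = r$sd)
    }))
  }
  sep <- if (ext == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("therapy", "months", "n_trial", "bin_label", "bin_lo", "bin_hi",
            "bin_mid", "count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("targets file lacks column(s): ", paste(miss, collapse = ", "))
  key <- paste(df$therapy, df$months, sep = "\r")
  lapply(split(df, factor(key, levels = unique(key))), function(g) {
    trial_target(
      g$therapy[1L], g$months[1L], g$n_trial[1L],
      data.frame(label = g$bin_label, lo = g$bin_lo, hi = g$bin_hi,
                 mid = g$bin_mid, count = g$count, stringsAsFactors = FALSE),
      mean = if ("mean" %in% names(g) && !anyNA(g$mean)) g$mean[1L],
      sd = if ("sd" %in% names(g) && !anyNA(g$sd)) g$sd[1L])
  }) |> unname()
}

null_inf <- function(x, default) {
  if (is.null(x)) return(default)
  if (is.character(x)) return(as.numeric(x))
  x
}

#' Write trial targets to CSV
#' @param targets list of `trial_target` objects
#' @param path output CSV path
#' @return `path`, invisibly.
#' @export
write_targets <- function(targets, path) {
  rows <- do.call(rbind, lapply(targets, function(t)
    data.frame(therapy = t$therapy, months = t$months, n_trial = t$n_trial,
               bin_label = t$bins$label, bin_lo = t$bins$lo,
               bin_hi = t$bins$hi, bin_mid = t$bins$mid, count = t$bins$count,
               mean = t$mean, sd = t$sd, stringsAsFactors = FALSE)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
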