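# Order-statistic normative ranges from a control cohort and the
# divergence-count classification of lateralization normality.

#' Order-statistic normal range of a control sample
#'
#' Control values are sorted in ascending order; the normal range spans
#' the 2nd up to the (n-1)th value (for the canonical 12-member control
#' cohort: the 2nd to the 11th value), with inclusive bounds.  By
#' construction exactly the minimum and maximum holders - 2/n of the
#' cohort when values are distinct - fall outside their own range.
#' Non-finite control values are dropped first and the positional rule is
#' applied to the remaining n valid values.
#'
#' @param control_values Numeric vector of control measurements.
#' @return Named numeric `c(lo = ..., hi = ...)`.
#' @export
normal_range <- function(control_values) {
  v <- sort(control_values[is.finite(control_values)])
  n <- length(v)
  if (n < 4L)
    stop("need at least 4 finite control values, got ", n)
  c(lo = v[2L], hi = v[n - 1L])
}

#' Classify a value against a normal range
#'
#' @param x Value to classify (may be `NA`).
#' @param lo,hi Inclusive normal-range bounds.
#' @return `"normal"` if `lo <= x <= hi`; `"divergent"` outside;
#'   `"na_divergent"` for undefined (`NA`) values, which count toward the
#'   divergence total: a metric that is undefinable for a patient while
#'   defined for every control is itself a deviation.
#' @export
classify_value <- function(x, lo, hi) {
  if (is.na(x)) return("na_divergent")
  if (x >= lo && x <= hi) "normal" else "divergent"
}

#' Build a per-metric normative table from control metric vectors
#'
#' @param control_metrics Data frame of control sessions in the
#'   [metrics_table()] schema (31 metric columns).
#' @return Data frame with one row per metric: `metric`, `lo`, `hi`,
#'   `mean`, `sd`, `iqr`, `n_controls` (number of finite control values
#'   the range was built from).
#' @export
build_normative_table <- function(control_metrics) {
  nm <- metric_names()
  missing_cols <- setdiff(nm, names(control_metrics))
  if (length(missing_cols) > 0L)
    stop("control metrics lack column(s): ",
         paste(missing_cols, collapse = ", "))
  rows <- lapply(nm, function(m) {
    v <- control_metrics[[m]]
    fin <- v[is.finite(v)]
    r <- normal_range(v)
    data.frame(metric = m, lo = r[["lo"]], hi = r[["hi"]],
               mean = mean(fin), sd = stats::sd(fin),
               iqr = stats::IQR(fin), n_controls = length(fin),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Divergence profile of one metric vector against a normative table
#'
#' Flags each of the 31 metrics as normal, divergent or NA-divergent,
#' counts the divergences and classifies overall lateralization as normal
#' when the count does not exceed 5 (the expected number of
#' by-construction false divergences for 31 metrics and 12 controls, see
#' [expected_false_divergences()]).
#'
#' @param metrics Named numeric vector of the 31 metrics, or a one-row
#'   data frame in the [metrics_table()] schema.
#' @param table Normative table from [build_normative_table()].
#' @return List with `flags` (named character vector over metrics),
#'   `count` (divergent + NA-divergent) and `is_normal_lateralization`.
#' @export
divergence_profile <- function(metrics, table) {
  nm <- metric_names()
  if (is.data.frame(metrics)) {
    stopifnot(nrow(metrics) == 1L)
    metrics <- stats::setNames(as.numeric(metrics[1L, nm]), nm)
  }
  missing_m <- setdiff(nm, names(metrics))
  if (length(missing_m) > 0L)
    stop("metric vector lacks: ", paste(missing_m, collapse = ", "))
  missing_t <- setdiff(nm, table$metric)
  if (length(missing_t) > 0L)
    stop("normative table lacks metric(s): ",
         paste(missing_t, collapse = ", "))
  tab <- table[match(nm, table$metric), ]
  flags <- vapply(seq_along(nm), function(i) {
    classify_value(metrics[[nm[i]]], tab$lo[i], tab$hi[i])
  }, character(1))
  names(flags) <- nm
  count <- sum(flags != "normal")
  list(flags = flags, count = count,
       is_normal_lateralization = count <= NORMAL_DIVERGENCE_MAX)
}

#' Divergence table for a cohort of metric vectors
#'
#' Applies [divergence_profile()] to every row of a metrics table.
#'
#' @param metrics_df Data frame in the [metrics_table()] schema.
#' @param table Normative table.
#' @return Data frame with `participant_id`, `phase`, one flag column per
#'   metric, `n_divergent` and `is_normal`.
#' @export
divergence_table <- function(metrics_df, table) {
  nm <- metric_names()
  rows <- lapply(seq_len(nrow(metrics_df)), function(i) {
    p <- divergence_profile(metrics_df[i, ], table)
    cbind(data.frame(participant_id = metrics_df$participant_id[i],
                     phase = metrics_df$phase[i],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(p$flags), stringsAsFactors = FALSE),
          data.frame(n_divergent = p$count,
                     is_normal = p$is_normal_lateralization))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expected number of by-construction false divergences
#'
#' With the 2nd-to-(n-1)th positional rule, 2/n of the control values per
#' metric lie outside the normal range by definition, so a normally
#' performing participant is expected to diverge in
#' `n_metrics * 2 / n_controls` metrics (31 metrics, 12 controls: 5.17,
#' reported as 5).
#'
#' @param n_metrics Number of metrics (>= 1).
#' @param n_controls Number of controls (>= 4).
#' @return List with `expected` (exact) and `reported` (nearest integer).
#' @export
expected_false_divergences <- function(n_metrics = 31L, n_controls = 12L) {
  stopifnot(n_metrics >= 1L, n_controls >= 4L)
  e <- n_metrics * 2 / n_controls
  list(expected = e, reported = round(e))
}
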