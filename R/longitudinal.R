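# Longitudinal change quantification: per-metric change between
# measurement phases expressed in control-dispersion units with a
# toward/away-from-control sign convention, and trajectory classification
# by divergence counts.

#' Signed change score in control-dispersion units
#'
#' `(|x_earlier - control_mean| - |x_later - control_mean|) /
#' control_dispersion`: positive when the later measurement lies closer
#' to the control-group mean (change toward normal), negative when it
#' diverges further.  The default dispersion unit is the control-group
#' standard deviation; the interquartile range is available as an
#' alternative.
#'
#' @param x_earlier,x_later Metric values in the earlier/later phase.
#' @param control_mean,control_dispersion Control-group center and
#'   dispersion of the metric; dispersion must be positive.
#' @return Signed dimensionless change; `NA` if either phase value is
#'   `NA`.
#' @export
change_score <- function(x_earlier, x_later, control_mean,
                         control_dispersion) {
  if (any(!is.finite(control_dispersion)) || any(control_dispersion <= 0))
    stop("control dispersion must be positive")
  (abs(x_earlier - control_mean) - abs(x_later - control_mean)) /
    control_dispersion
}

# phase pairs reported: adjacent pairs plus first-vs-last
phase_pairs <- function(phases) {
  k <- length(phases)
  if (k < 2L) return(list())
  pairs <- lapply(seq_len(k - 1L), function(i) c(phases[i], phases[i + 1L]))
  if (k > 2L) pairs <- append(pairs, list(c(phases[1L], phases[k])), 1L)
  unique(pairs)
}

#' Compare divergence profiles and metrics across measurement phases
#'
#' For every patient and every available phase pair (adjacent phases plus
#' first-vs-last), classifies the trajectory from the divergence counts
#' (improved if the later count is smaller, stable if equal, deteriorated
#' if larger) and, when a metrics table and normative table are supplied,
#' computes per-metric [change_score()]s.  Patients with a single phase
#' are skipped with a message.
#'
#' @param divergence_df Cohort divergence table from [divergence_table()]
#'   (patient rows; columns `participant_id`, `phase`, `n_divergent`).
#' @param metrics_df Optional metrics table ([metrics_table()] schema) for
#'   per-metric change scores; `NULL` for count-level comparison only.
#' @param normative Normative table ([build_normative_table()]); required
#'   when `metrics_df` is given.
#' @param phases Phase order (default acute, subacute, chronic).
#' @param dispersion `"sd"` (default) or `"iqr"`: the control-dispersion
#'   unit of the change scores.
#' @return List with `records` (one row per patient and phase pair:
#'   counts, `delta`, `trajectory`), `changes` (long data frame:
#'   `participant_id`, `phase_earlier`, `phase_later`, `metric`,
#'   `cluster`, `change`; `NULL` without metrics) and `summary` (per
#'   phase pair: trajectory counts, mean and SD of count deltas).
#' @export
phase_comparison <- function(divergence_df, metrics_df = NULL,
                             normative = NULL, phases = default_phases(),
                             dispersion = c("sd", "iqr")) {
  dispersion <- match.arg(dispersion)
  if (!is.null(metrics_df) && is.null(normative))
    stop("normative table required for per-metric change scores")
  nm <- metric_names()
  pairs <- phase_pairs(phases)
  records <- list()
  changes <- list()
  for (pid in unique(divergence_df$participant_id)) {
    sub <- divergence_df[divergence_df$participant_id == pid, ]
    have <- intersect(phases, sub$phase)
    if (length(have) < 2L) {
      message("participant ", pid, " has fewer than 2 phases; skipped")
      next
    }
    for (pr in pairs) {
      if (!all(pr %in% have)) next
      ce <- sub$n_divergent[sub$phase == pr[1L]]
      cl <- sub$n_divergent[sub$phase == pr[2L]]
      delta <- cl - ce
      records[[length(records) + 1L]] <- data.frame(
        participant_id = pid, phase_earlier = pr[1L], phase_later = pr[2L],
        count_earlier = ce, count_later = cl, delta = delta,
        trajectory = if (delta < 0) "improved"
                     else if (delta == 0) "stable" else "deteriorated",
        stringsAsFactors = FALSE)
      if (!is.null(metrics_df)) {
        me <- metrics_df[metrics_df$participant_id == pid &
                           metrics_df$phase == pr[1L], ]
        ml <- metrics_df[metrics_df$participant_id == pid &
                           metrics_df$phase == pr[2L], ]
        if (nrow(me) != 1L || nrow(ml) != 1L)
          stop("metrics rows missing for participant ", pid,
               " pair ", pr[1L], "/", pr[2L])
        tab <- normative[match(nm, normative$metric), ]
        disp <- if (dispersion == "sd") tab$sd else tab$iqr
        sc <- change_score(as.numeric(me[1L, nm]), as.numeric(ml[1L, nm]),
                           tab$mean, disp)
        changes[[length(changes) + 1L]] <- data.frame(
          participant_id = pid, phase_earlier = pr[1L],
          phase_later = pr[2L], metric = nm,
          cluster = unname(metric_clusters()[nm]), change = sc,
          stringsAsFactors = FALSE)
      }
    }
  }
  records <- if (length(records)) do.call(rbind, records) else NULL
  changes <- if (length(changes)) do.call(rbind, changes) else NULL
  summary <- NULL
  if (!is.null(records)) {
    key <- paste(records$phase_earlier, records$phase_later, sep = " vs ")
    summary <- lapply(split(records, key), function(r) {
      list(n = nrow(r),
           improved = sum(r$trajectory == "improved"),
           stable = sum(r$trajectory == "stable"),
           deteriorated = sum(r$trajectory == "deteriorated"),
           mean_delta = mean(r$delta),
           sd_delta = stats::sd(r$delta))
    })
  }
  list(records = records, changes = changes, summary = summary)
}

#' Per-patient by per-metric signed-change matrix
#'
#' Reshapes the long change table of one phase pair into a matrix (rows =
#' patients, columns = the 31 metrics in cluster order A-F).  Positive
#' entries mark change toward the control mean, negative entries change
#' away from it; `NA` entries (a metric undefined in either phase) are
#' excluded from cluster summaries.
#'
#' @param changes Long change table from [phase_comparison()].
#' @param phase_earlier,phase_later Phase pair to extract; defaults to the
#'   only pair present.
#' @return Numeric matrix with a `clusters` attribute (named character
#'   vector over columns).
#' @export
metric_change_matrix <- function(changes, phase_earlier = NULL,
                                 phase_later = NULL) {
  if (is.null(phase_earlier)) {
    pr <- unique(changes[, c("phase_earlier", "phase_later")])
    if (nrow(pr) != 1L)
      stop("multiple phase pairs present; specify phase_earlier/phase_later")
    phase_earlier <- pr$phase_earlier
    phase_later <- pr$phase_later
  }
  sub <- changes[changes$phase_earlier == phase_earlier &
                   changes$phase_later == phase_later, ]
  cl <- metric_clusters()
  cols <- names(cl)[order(cl, match(names(cl), metric_names()))]
  pids <- unique(sub$participant_id)
  m <- matrix(NA_real_, nrow = length(pids), ncol = length(cols),
              dimnames = list(pids, cols))
  for (i in seq_len(nrow(sub)))
    m[sub$participant_id[i], sub$metric[i]] <- sub$change[i]
  attr(m, "clusters") <- cl[cols]
  m
}
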