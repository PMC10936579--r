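# File formats and the in-memory data model.  All files are UTF-8,
# comma-delimited with a "." decimal separator and one header row; the
# undefined-value sentinel is the literal token "NA".

SENTINEL <- "NA"

#' Construct a lateralization session
#'
#' A session holds all trials of one participant in one measurement phase.
#'
#' @param participant_id Participant identifier string.
#' @param group `"control"` or `"patient"`.
#' @param phase Phase label (free string; `"control"`, `"acute"`, ...).
#' @param trials Data frame with columns `cue_type`, `cue_value`,
#'   `presentation_index`, `response_key`.
#' @param check If `TRUE` (default), validate trial fields and report
#'   completeness against [stimulus_design()].
#' @return An object of class `lat_session` with fields `participant_id`,
#'   `group`, `phase`, `trials` and logical `complete`.
#' @export
lat_session <- function(participant_id, group, phase, trials, check = TRUE) {
  stopifnot(is.character(participant_id), length(participant_id) == 1L)
  group <- match.arg(group, c("control", "patient"))
  required <- c("cue_type", "cue_value", "presentation_index", "response_key")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols) > 0L)
    stop("trials lack column(s): ", paste(missing_cols, collapse = ", "))
  if (check) validate_trials(trials)
  obj <- list(
    participant_id = participant_id,
    group = group,
    phase = phase,
    trials = trials[, required],
    complete = if (check) session_is_complete(trials) else NA
  )
  class(obj) <- "lat_session"
  obj
}

#' @export
print.lat_session <- function(x, ...) {
  cat(sprintf("<lat_session> %s [%s, %s]: %d trials%s\n",
              x$participant_id, x$group, x$phase, nrow(x$trials),
              if (isFALSE(x$complete)) " (incomplete)" else ""))
  invisible(x)
}

validate_trials <- function(trials, rows = seq_len(nrow(trials))) {
  known <- c("itd", "ild", "mono_left", "mono_right", "diotic")
  bad <- !(trials$cue_type %in% known)
  if (any(bad))
    stop("unknown cue_type ", sQuote(trials$cue_type[which(bad)[1L]]),
         " in row ", rows[which(bad)[1L]])
  rk <- trials$response_key
  bad <- !(is.finite(rk) & rk == round(rk) & rk >= 1 & rk <= 9)
  if (any(bad))
    stop("response_key outside 1..9 in row ", rows[which(bad)[1L]])
  itd_rows <- trials$cue_type == "itd"
  bad <- itd_rows & !(trials$cue_value %in% c(ITD_PHYS, ITD_EXTREME))
  if (any(bad))
    stop("invalid ITD cue_value ", trials$cue_value[which(bad)[1L]],
         " in row ", rows[which(bad)[1L]])
  ild_rows <- trials$cue_type == "ild"
  bad <- ild_rows & !(trials$cue_value %in% ILD_PHYS)
  if (any(bad))
    stop("invalid ILD cue_value ", trials$cue_value[which(bad)[1L]],
         " in row ", rows[which(bad)[1L]])
  invisible(TRUE)
}

# stable per-trial stimulus label used for grouping
stimulus_key <- function(trials) {
  ifelse(trials$cue_type %in% c("itd", "ild"),
         paste(trials$cue_type, trials$cue_value),
         trials$cue_type)
}

session_is_complete <- function(trials) {
  design <- stimulus_design()
  want <- stats::setNames(design$n_presentations, stimulus_key(design))
  have <- table(stimulus_key(trials))
  all(names(want) %in% names(have)) &&
    all(as.integer(have[names(want)]) == want)
}

#' Read lateralization sessions from a trials file
#'
#' Parses a comma-delimited trials table (columns `participant_id`,
#' `group`, `phase`, `cue_type`, `cue_value`, `presentation_index`,
#' `response_key`) and groups rows into one [lat_session()] per
#' participant-phase combination.  Malformed rows raise errors naming the
#' offending file row; sessions that do not contain the complete stimulus
#' design are still returned but flagged `complete = FALSE` with a warning.
#'
#' @param path Path to the CSV file.
#' @return List of `lat_session` objects.
#' @export
read_sessions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = SENTINEL, colClasses = NA)
  required <- c("participant_id", "group", "phase", "cue_type", "cue_value",
                "presentation_index", "response_key")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("trials file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) return(list())
  # +1 header row: report file line numbers in diagnostics
  validate_trials(df, rows = seq_len(nrow(df)) + 1L)
  keys <- paste(df$participant_id, df$phase, sep = "\r")
  sessions <- lapply(split(seq_len(nrow(df)), keys), function(idx) {
    sub <- df[idx, ]
    grp <- unique(sub$group)
    if (length(grp) != 1L)
      stop("participant ", sub$participant_id[1L], " phase ", sub$phase[1L],
           " has inconsistent group labels")
    lat_session(sub$participant_id[1L], grp, sub$phase[1L],
                sub[, c("cue_type", "cue_value", "presentation_index",
                        "response_key")])
  })
  incomplete <- vapply(sessions, function(s) isFALSE(s$complete), logical(1))
  if (any(incomplete))
    warning(sum(incomplete), " session(s) incomplete: ",
            paste(vapply(sessions[incomplete], function(s)
              paste0(s$participant_id, "/", s$phase), character(1)),
              collapse = ", "))
  unname(sessions[order(names(sessions))])
}

#' Write lateralization sessions to a trials file
#'
#' Inverse of [read_sessions()]; `read_sessions(write_sessions(x, p))`
#' reproduces `x`.
#'
#' @param sessions List of `lat_session` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  rows <- lapply(sessions, function(s) {
    cbind(data.frame(participant_id = s$participant_id, group = s$group,
                     phase = s$phase, stringsAsFactors = FALSE),
          s$trials)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, na = SENTINEL, quote = FALSE)
  invisible(path)
}

# serialize doubles at full precision so files round-trip exactly
format_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) SENTINEL else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a metrics table
#'
#' Writes one row per participant-phase with the 31 metric columns in the
#' canonical [metric_names()] order.  Undefined metrics are written as the
#' sentinel token `NA`.  Values round-trip through [read_metrics()] at full
#' double precision; every column keeps its native unit (ITD slopes in
#' keys per microsecond - multiply by 100 for the more readable keys per
#' 100 us when eyeballing tables).
#'
#' @param table Data frame with columns `participant_id`, `phase` and the
#'   31 metrics.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(table, path) {
  nm <- metric_names()
  missing_cols <- setdiff(c("participant_id", "phase", nm), names(table))
  if (length(missing_cols) > 0L)
    stop("metrics table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- table[, c("participant_id", "phase", nm)]
  chr <- data.frame(participant_id = out$participant_id, phase = out$phase,
                    stringsAsFactors = FALSE)
  for (col in nm) chr[[col]] <- format_full(out[[col]])
  utils::write.csv(chr, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a metrics table written by [write_metrics()]
#'
#' @param path CSV path.
#' @return Data frame with `participant_id`, `phase` and the 31 metric
#'   columns.
#' @export
read_metrics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = SENTINEL)
  nm <- metric_names()
  missing_cols <- setdiff(c("participant_id", "phase", nm), names(df))
  if (length(missing_cols) > 0L)
    stop("metrics file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in nm) df[[col]] <- as.numeric(df[[col]])
  df[, c("participant_id", "phase", nm)]
}

#' Write / read a normative table as JSON
#'
#' One JSON object per metric with fields `lo`, `hi`, `mean`, `sd`, `iqr`
#' and `n_controls`.
#'
#' @param table Normative table from [build_normative_table()].
#' @param path JSON path.
#' @return `write_normative`: `path` invisibly; `read_normative`: the table.
#' @export
write_normative <- function(table, path) {
  recs <- lapply(seq_len(nrow(table)), function(i) {
    as.list(table[i, c("lo", "hi", "mean", "sd", "iqr", "n_controls")])
  })
  names(recs) <- table$metric
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_normative
#' @export
read_normative <- function(path) {
  recs <- jsonlite::read_json(path)
  as_num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  df <- do.call(rbind, lapply(names(recs), function(m) {
    r <- recs[[m]]
    data.frame(metric = m, lo = as_num(r$lo), hi = as_num(r$hi),
               mean = as_num(r$mean), sd = as_num(r$sd),
               iqr = as_num(r$iqr), n_controls = as.integer(r$n_controls),
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}

#' Write / read adaptive-track logs
#'
#' Long-format tracks table: one row per trial with columns
#' `participant_id`, `phase`, `condition`, `run_index`, `trial_index`,
#' `level_db`, `correct`, `reversal`, `valid`.
#'
#' @param tracks Data frame in the tracks schema.
#' @param path CSV path.
#' @return `write_tracks`: `path` invisibly; `read_tracks`: the data frame.
#' @export
write_tracks <- function(tracks, path) {
  required <- c("participant_id", "phase", "condition", "run_index",
                "trial_index", "level_db", "correct", "reversal", "valid")
  missing_cols <- setdiff(required, names(tracks))
  if (length(missing_cols) > 0L)
    stop("tracks table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  utils::write.csv(tracks[, required], path, row.names = FALSE,
                   na = SENTINEL, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = SENTINEL)
  for (col in c("correct", "reversal", "valid"))
    df[[col]] <- as.logical(df[[col]])
  df
}

#' Read an audiometry table
#'
#' Long-format per-ear pure-tone thresholds: `participant_id`, `phase`,
#' `ear` (`"left"`/`"right"`), `frequency` (Hz), `threshold` (dB HL).
#'
#' @param path CSV path.
#' @return Data frame in the audiometry schema.
#' @export
read_audiograms <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = SENTINEL)
  required <- c("participant_id", "phase", "ear", "frequency", "threshold")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("audiometry file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- !(df$ear %in% c("left", "right"))
  if (any(bad))
    stop("invalid ear label in row ", which(bad)[1L] + 1L)
  bad <- !(df$frequency >= 125 & df$frequency <= 8000)
  if (any(bad))
    stop("frequency outside 125..8000 Hz in row ", which(bad)[1L] + 1L)
  df
}

#' @rdname read_audiograms
#' @param audiograms Data frame in the audiometry schema.
#' @export
write_audiograms <- function(audiograms, path) {
  utils::write.csv(audiograms, path, row.names = FALSE, na = SENTINEL,
                   quote = FALSE)
  invisible(path)
}
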