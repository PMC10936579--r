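# Experimental design constants shared by every module: the stimulus
# ensemble of the lateralization task, the fixed 31-metric schema and its
# cluster assignment, and the phase ordering.

#' Stimulus ensemble of the lateralization task
#'
#' Returns the full stimulus set of the headphone lateralization experiment
#' as a data frame: interaural time differences (ITD) of +/-200, +/-400,
#' +/-600 microseconds within the physiological range plus +/-1500
#' microseconds outside it, interaural level differences (ILD) of +/-4,
#' +/-8, +/-12 dB, monaural left/right presentation, and the shared diotic
#' stimulus (zero ITD and zero ILD).  Negative cue values favor the left
#' ear, positive the right.
#'
#' @return A data frame with columns `cue_type` (one of `"itd"`, `"ild"`,
#'   `"mono_left"`, `"mono_right"`, `"diotic"`), `cue_value` (microseconds
#'   for ITD, dB for ILD, `NA` for monaural/diotic) and `n_presentations`
#'   (6 for every stimulus except the diotic, which is presented 8 times).
#' @examples
#' stimulus_design()
#' sum(stimulus_design()$n_presentations)  # 104 trials in a complete session
#' @export
stimulus_design <- function() {
  itd <- c(-1500, -600, -400, -200, 200, 400, 600, 1500)
  ild <- c(-12, -8, -4, 4, 8, 12)
  out <- rbind(
    data.frame(cue_type = "itd", cue_value = itd),
    data.frame(cue_type = "ild", cue_value = ild),
    data.frame(cue_type = c("mono_left", "mono_right", "diotic"),
               cue_value = NA_real_)
  )
  out$n_presentations <- ifelse(out$cue_type == "diotic", 8L, 6L)
  rownames(out) <- NULL
  out
}

# cue spans of the physiological range, used for saturation and simulation
ITD_SPAN_US <- 600
ILD_SPAN_DB <- 12

# physiological (non-extreme) cue sets per family, excluding the diotic zero
ITD_PHYS <- c(-600, -400, -200, 200, 400, 600)
ILD_PHYS <- c(-12, -8, -4, 4, 8, 12)
ITD_EXTREME <- c(-1500, 1500)

# floors applied before logarithmic ratios so that degenerate (constant or
# near-constant) response patterns stay finite and comparable
STD_FLOOR_KEYS <- 0.1
RANGE_FLOOR_KEYS <- 0.5

# divergence count at or below which lateralization is classified normal
NORMAL_DIVERGENCE_MAX <- 5L

#' Names of the 31 lateralization metrics, in canonical order
#'
#' The fixed schema of the quantitative lateralization profile: 6 slope
#' metrics (side-wise linear-fit slopes and their log ratios), 9 bias
#' metrics (family means, side-fit means, perceived-center cue values, the
#' diotic percept), 9 variability metrics (per-stimulus standard deviations
#' aggregated per family and side, and their log ratios), 3 range metrics,
#' 2 monaural percepts and 2 extreme-ITD percepts.
#'
#' @return Character vector of length 31.
#' @seealso [metric_clusters()] for the A-F grouping used in longitudinal
#'   reports, [compute_metric_vector()] for the computation.
#' @export
metric_names <- function() {
  c(
    # slopes (6)
    "ild_l_slope", "ild_r_slope", "itd_l_slope", "itd_r_slope",
    "ild_slope_ratio", "itd_slope_ratio",
    # side biases / shifts (9)
    "itd_mean", "ild_mean", "itd_l_fit", "itd_r_fit", "ild_l_fit",
    "ild_r_fit", "itd_center", "ild_center", "diotic_percept",
    # variability (9)
    "diotic_std", "ild_std", "itd_std", "itd_l_std", "itd_r_std",
    "ild_l_std", "ild_r_std", "itd_std_ratio", "ild_std_ratio",
    # ranges (3)
    "itd_range", "ild_range", "range_ratio",
    # monaural (2)
    "mon_left", "mon_right",
    # extreme ITDs (2)
    "neg_1500", "pos_1500"
  )
}

#' Metric-to-cluster assignment for longitudinal change reports
#'
#' Groups the 31 metrics into the six interpretive clusters used when
#' summarizing per-metric change: A = shift of the auditory space (means,
#' side-fit means, perceived centers, diotic percept), B = variability,
#' C = slopes of the side fits, D = perceived ranges, E = monaural
#' percepts, F = ITDs outside the physiological range.
#'
#' @return Named character vector mapping each metric name to `"A"`..`"F"`.
#' @export
metric_clusters <- function() {
  nm <- metric_names()
  cl <- character(length(nm))
  names(cl) <- nm
  cl[c("itd_mean", "ild_mean", "itd_l_fit", "itd_r_fit", "ild_l_fit",
       "ild_r_fit", "itd_center", "ild_center", "diotic_percept")] <- "A"
  cl[c("diotic_std", "ild_std", "itd_std", "itd_l_std", "itd_r_std",
       "ild_l_std", "ild_r_std", "itd_std_ratio", "ild_std_ratio")] <- "B"
  cl[c("ild_l_slope", "ild_r_slope", "itd_l_slope", "itd_r_slope",
       "ild_slope_ratio", "itd_slope_ratio")] <- "C"
  cl[c("itd_range", "ild_range", "range_ratio")] <- "D"
  cl[c("mon_left", "mon_right")] <- "E"
  cl[c("neg_1500", "pos_1500")] <- "F"
  cl
}

#' Default ordering of measurement phases
#'
#' Phases are free strings; this is the default chronological order used
#' when forming phase pairs for longitudinal comparisons.
#'
#' @return Character vector `c("acute", "subacute", "chronic")`.
#' @export
default_phases <- function() c("acute", "subacute", "chronic")
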