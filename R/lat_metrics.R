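# The 31-metric quantitative description of one session's lateralization
# pattern.  All key-scale metrics are in response-key units (keys 1..9,
# key 5 = intracranial midline; one key = 1/8 of the inter-ear distance);
# slopes are keys per native cue unit (dB for ILD, microseconds for ITD);
# perceived-center metrics are in native cue units; "logarithmic ratio"
# metrics use the natural log.

#' Discard the first presentation of every stimulus
#'
#' The response to the first trial of each stimulus is not used in the
#' analysis: for every stimulus the trial with the smallest
#' `presentation_index` is removed and all remaining trials are kept in
#' their original order.
#'
#' @param session A [lat_session()].
#' @return The session with trimmed trials (a complete session retains 5
#'   trials per non-diotic stimulus and 7 diotic trials).
#' @export
retain_trials <- function(session) {
  trials <- session$trials
  keys <- stimulus_key(trials)
  drop <- unlist(lapply(split(seq_len(nrow(trials)), keys), function(idx) {
    if (length(idx) < 2L)
      stop("stimulus ", sQuote(keys[idx[1L]]),
           " has a single presentation; cannot discard the first trial ",
           "and retain any")
    idx[which.min(trials$presentation_index[idx])]
  }))
  session$trials <- trials[-drop, , drop = FALSE]
  session
}

# retained trials of one cue family mapped to a (cue, response) table;
# diotic trials enter both families at cue 0 (the stimulus has zero ITD
# and zero ILD), extreme ITDs and monaural stimuli are excluded
family_trials <- function(trials, family) {
  phys <- if (family == "itd") ITD_PHYS else ILD_PHYS
  own <- trials$cue_type == family & trials$cue_value %in% phys
  dio <- trials$cue_type == "diotic"
  data.frame(cue = c(trials$cue_value[own], rep(0, sum(dio))),
             response = c(trials$response_key[own], trials$response_key[dio]))
}

#' Ordinary-least-squares fit to one side's stimuli of one cue family
#'
#' Fits `response_key ~ cue_value` by OLS over the individual retained
#' trials of exactly the three left-favoring (or right-favoring)
#' physiological stimuli of a family: ILD -12/-8/-4 dB (left) or
#' 4/8/12 dB (right); ITD -600/-400/-200 us (left) or 200/400/600 us
#' (right).  With balanced trial counts the slope equals a fit through the
#' per-stimulus means; trial-level fitting additionally defines behavior
#' for incomplete sessions.
#'
#' @param session A retained [lat_session()] (see [retain_trials()]).
#' @param family `"itd"` or `"ild"`.
#' @param side `"left"` or `"right"`.
#' @return List with `side`, `cue_family`, `slope` (keys per cue unit),
#'   `intercept` (keys at zero cue) and `fitted_mean` (mean of the fitted
#'   values at the three stimuli, i.e. the prediction at the middle one).
#' @export
fit_side_line <- function(session, family = c("itd", "ild"),
                          side = c("left", "right")) {
  family <- match.arg(family)
  side <- match.arg(side)
  phys <- if (family == "itd") ITD_PHYS else ILD_PHYS
  cues <- if (side == "left") phys[phys < 0] else phys[phys > 0]
  trials <- session$trials
  sel <- trials$cue_type == family & trials$cue_value %in% cues
  present <- unique(trials$cue_value[sel])
  absent <- setdiff(cues, present)
  if (length(absent) > 0L)
    stop("missing ", family, " stimulus ", absent[1L],
         " for the ", side, "-side fit")
  x <- trials$cue_value[sel]
  y <- trials$response_key[sel]
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  list(side = side, cue_family = family, slope = slope,
       intercept = intercept,
       fitted_mean = intercept + slope * mean(cues))
}

#' Log ratio of left and right side slopes
#'
#' `log(slope_left / slope_right)` (natural log); 0 indicates symmetric
#' steepness.  Undefined (`NA`) when the quotient is not positive, e.g.
#' when one side's fit has a reversed or zero slope.
#'
#' @param slope_left,slope_right Side-fit slopes in the same units.
#' @return Dimensionless log ratio, or `NA`.
#' @export
slope_ratio <- function(slope_left, slope_right) {
  q <- slope_left / slope_right
  if (!is.finite(q) || q <= 0) return(NA_real_)
  log(q)
}

log_ratio_floored <- function(num, den, floor) {
  log(max(num, floor) / max(den, floor))
}

#' Side-bias (shift) metrics of a retained session
#'
#' Family means are mean responses over all physiological stimuli of the
#' family including the diotic trials; perceived centers are the mean cue
#' value (native units, diotic counted at cue 0) of trials answered with
#' key 5, `NA` when key 5 never occurs; the diotic percept is the mean
#' response to the diotic stimulus.
#'
#' @param session A retained [lat_session()].
#' @return Named list: `itd_mean`, `ild_mean`, `itd_center`, `ild_center`,
#'   `diotic_percept`.
#' @export
location_metrics <- function(session) {
  trials <- session$trials
  fam <- lapply(c(itd = "itd", ild = "ild"),
                function(f) family_trials(trials, f))
  center <- function(ft) {
    hit <- ft$response == 5
    if (!any(hit)) NA_real_ else mean(ft$cue[hit])
  }
  dio <- trials$response_key[trials$cue_type == "diotic"]
  list(itd_mean = mean(fam$itd$response),
       ild_mean = mean(fam$ild$response),
       itd_center = center(fam$itd),
       ild_center = center(fam$ild),
       diotic_percept = mean(dio))
}

# per-stimulus summary (mean, sd, n) over a family's physiological set,
# diotic included at cue 0; rows ordered by cue
per_stimulus_stats <- function(trials, family) {
  ft <- family_trials(trials, family)
  by_cue <- split(ft$response, ft$cue)
  n <- vapply(by_cue, length, integer(1))
  data.frame(cue = as.numeric(names(by_cue)),
             mean = vapply(by_cue, mean, numeric(1)),
             sd = vapply(by_cue, stats::sd, numeric(1)),
             n = n)
}

#' Variability metrics of a retained session
#'
#' Per-stimulus sample standard deviations (n-1 denominator) aggregated
#' per family (mean over the seven physiological stimuli, diotic
#' included) and per side (mean over the three side stimuli); log ratios
#' of left over right side standard deviations with both sides floored at
#' 0.1 keys so that deterministic response patterns stay finite (a
#' symmetric deterministic listener scores ratio 0).
#'
#' @param session A retained [lat_session()]; every physiological stimulus
#'   needs at least 2 retained trials.
#' @return Named list of the nine variability metrics.
#' @export
variability_metrics <- function(session) {
  trials <- session$trials
  out <- list()
  for (family in c("itd", "ild")) {
    st <- per_stimulus_stats(trials, family)
    if (any(st$n < 2L))
      stop("stimulus ", family, " ", st$cue[which(st$n < 2L)[1L]],
           " has fewer than 2 retained trials; standard deviation undefined")
    side_sd <- function(cues) mean(st$sd[st$cue %in% cues])
    phys <- if (family == "itd") ITD_PHYS else ILD_PHYS
    out[[paste0(family, "_std")]] <- mean(st$sd)
    out[[paste0(family, "_l_std")]] <- side_sd(phys[phys < 0])
    out[[paste0(family, "_r_std")]] <- side_sd(phys[phys > 0])
    out[[paste0(family, "_std_ratio")]] <- log_ratio_floored(
      out[[paste0(family, "_l_std")]], out[[paste0(family, "_r_std")]],
      STD_FLOOR_KEYS)
  }
  dio <- trials$response_key[trials$cue_type == "diotic"]
  if (length(dio) < 2L)
    stop("fewer than 2 retained diotic trials; diotic std undefined")
  c(list(diotic_std = stats::sd(dio)), out)
}

#' Perceived-range metrics of a retained session
#'
#' The range of a family is the difference between the largest and
#' smallest per-stimulus mean response over its physiological stimuli
#' (diotic included; extreme ITDs and monaural stimuli excluded).  The
#' range ratio is `log(ILD range / ITD range)` with both ranges floored
#' at 0.5 keys before the ratio.
#'
#' @param session A retained [lat_session()].
#' @return Named list: `itd_range`, `ild_range`, `range_ratio`.
#' @export
range_metrics <- function(session) {
  trials <- session$trials
  rng <- vapply(c(itd = "itd", ild = "ild"), function(family) {
    st <- per_stimulus_stats(trials, family)
    max(st$mean) - min(st$mean)
  }, numeric(1))
  list(itd_range = rng[["itd"]], ild_range = rng[["ild"]],
       range_ratio = log_ratio_floored(rng[["ild"]], rng[["itd"]],
                                       RANGE_FLOOR_KEYS))
}

#' Monaural and extreme-ITD percepts
#'
#' The monaural stimuli and the +/-1500 us ITDs (outside the
#' physiological range) are evaluated only as mean responses; they enter
#' no other metric.
#'
#' @param session A retained [lat_session()].
#' @return Named list: `neg_1500`, `pos_1500`, `mon_left`, `mon_right`.
#' @export
extreme_and_monaural <- function(session) {
  trials <- session$trials
  m <- function(sel) mean(trials$response_key[sel])
  list(neg_1500 = m(trials$cue_type == "itd" & trials$cue_value == -1500),
       pos_1500 = m(trials$cue_type == "itd" & trials$cue_value == 1500),
       mon_left = m(trials$cue_type == "mono_left"),
       mon_right = m(trials$cue_type == "mono_right"))
}

#' Compute the 31-metric lateralization profile of a session
#'
#' Applies [retain_trials()] and assembles the full metric vector from the
#' side fits, the bias, variability, range and extreme/monaural metrics.
#'
#' @param session A [lat_session()] (untrimmed; first presentations are
#'   discarded internally).
#' @return Named numeric vector of length 31 in [metric_names()] order.
#' @examples
#' m <- ideal_listener()
#' v <- compute_metric_vector(simulate_session(m, phase = "control"))
#' v[["ild_r_slope"]]  # 1/3 keys per dB for the ideal listener
#' @export
compute_metric_vector <- function(session) {
  s <- retain_trials(session)
  fits <- list(
    itd_l = fit_side_line(s, "itd", "left"),
    itd_r = fit_side_line(s, "itd", "right"),
    ild_l = fit_side_line(s, "ild", "left"),
    ild_r = fit_side_line(s, "ild", "right")
  )
  loc <- location_metrics(s)
  var <- variability_metrics(s)
  rng <- range_metrics(s)
  ext <- extreme_and_monaural(s)
  v <- c(
    ild_l_slope = fits$ild_l$slope,
    ild_r_slope = fits$ild_r$slope,
    itd_l_slope = fits$itd_l$slope,
    itd_r_slope = fits$itd_r$slope,
    ild_slope_ratio = slope_ratio(fits$ild_l$slope, fits$ild_r$slope),
    itd_slope_ratio = slope_ratio(fits$itd_l$slope, fits$itd_r$slope),
    itd_mean = loc$itd_mean,
    ild_mean = loc$ild_mean,
    itd_l_fit = fits$itd_l$fitted_mean,
    itd_r_fit = fits$itd_r$fitted_mean,
    ild_l_fit = fits$ild_l$fitted_mean,
    ild_r_fit = fits$ild_r$fitted_mean,
    itd_center = loc$itd_center,
    ild_center = loc$ild_center,
    diotic_percept = loc$diotic_percept,
    diotic_std = var$diotic_std,
    ild_std = var$ild_std,
    itd_std = var$itd_std,
    itd_l_std = var$itd_l_std,
    itd_r_std = var$itd_r_std,
    ild_l_std = var$ild_l_std,
    ild_r_std = var$ild_r_std,
    itd_std_ratio = var$itd_std_ratio,
    ild_std_ratio = var$ild_std_ratio,
    itd_range = rng$itd_range,
    ild_range = rng$ild_range,
    range_ratio = rng$range_ratio,
    mon_left = ext$mon_left,
    mon_right = ext$mon_right,
    neg_1500 = ext$neg_1500,
    pos_1500 = ext$pos_1500
  )
  stopifnot(identical(names(v), metric_names()))
  v
}

#' Compute a metrics table for a list of sessions
#'
#' @param sessions List of [lat_session()] objects.
#' @return Data frame with `participant_id`, `phase` and the 31 metric
#'   columns, one row per session.
#' @export
metrics_table <- function(sessions) {
  rows <- lapply(sessions, function(s) {
    v <- compute_metric_vector(s)
    cbind(data.frame(participant_id = s$participant_id, phase = s$phase,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(v)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
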