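# Synthetic cohorts: seeded generation of lateralization sessions,
# tone-in-noise observers and audiograms for control-like listeners and
# impaired-listener archetypes (laterally shifted, side-oriented,
# high-variability, left-right confusing), with per-phase severity
# trajectories so recovery and deterioration can be emulated end to end.

#' Construct a generative listener model
#'
#' The model maps an interaural cue to a latent intracranial percept on
#' the 9-key scale: `p = 5 + 4 * gain * sat(cue) + bias` with
#' `sat(cue) = clamp(cue / span, -1, 1)` (span 600 us for ITD - the
#' `itd_saturation` parameter - and 12 dB for ILD; the +/-1500 us
#' extremes saturate fully).  Side-oriented listeners override the graded
#' mapping with `p = 5 + sign(cue) * 4 * gain + bias` for any nonzero
#' cue.  Monaural stimuli map to fixed target keys.  With probability
#' `confusion_prob` a lateralized percept is mirrored about key 5
#' (left-right confusion); `extreme_confusion_prob` does the same for the
#' +/-1500 us stimuli only.  The button press is
#' `clamp(round(p + noise), 1, 9)` with Gaussian response noise, rounding
#' half away from zero after noise addition and clamping after rounding.
#'
#' @param gain_itd,gain_ild Mapping gains (1 = the physiological cue span
#'   covers the full 8-key range); >= 0.
#' @param bias Constant rightward shift in keys (negative = leftward).
#' @param itd_saturation ITD (us) at which the percept saturates.
#' @param response_noise_sd Gaussian response noise SD in keys; >= 0.
#' @param confusion_prob Probability of mirroring a lateralized percept.
#' @param extreme_confusion_prob Additional mirror probability applied to
#'   the +/-1500 us stimuli only.
#' @param side_oriented If `TRUE`, percepts are pushed to the extremes for
#'   any nonzero cue.
#' @param mono_left_target,mono_right_target Latent percepts for monaural
#'   stimulation (keys).
#' @return Object of class `listener_model`.
#' @export
listener_model <- function(gain_itd = 1, gain_ild = 1, bias = 0,
                           itd_saturation = ITD_SPAN_US,
                           response_noise_sd = 0, confusion_prob = 0,
                           extreme_confusion_prob = 0,
                           side_oriented = FALSE,
                           mono_left_target = 1, mono_right_target = 9) {
  stopifnot(gain_itd >= 0, gain_ild >= 0, itd_saturation > 0,
            response_noise_sd >= 0,
            confusion_prob >= 0, confusion_prob <= 1,
            extreme_confusion_prob >= 0, extreme_confusion_prob <= 1)
  structure(list(gain_itd = gain_itd, gain_ild = gain_ild, bias = bias,
                 itd_saturation = itd_saturation,
                 response_noise_sd = response_noise_sd,
                 confusion_prob = confusion_prob,
                 extreme_confusion_prob = extreme_confusion_prob,
                 side_oriented = side_oriented,
                 mono_left_target = mono_left_target,
                 mono_right_target = mono_right_target),
            class = "listener_model")
}

#' @rdname listener_model
#' @details `ideal_listener()` is the noiseless, unbiased reference
#'   listener (gains 1, no confusion): every metric of its sessions is
#'   fully determined by the design.
#' @export
ideal_listener <- function() listener_model()

#' Mirror a listener model left-right
#'
#' Negates the bias and swaps the monaural targets; sessions generated
#' from the mirrored model are statistically the left-right mirror image
#' of the original's.
#'
#' @param model A [listener_model()].
#' @return The mirrored model.
#' @export
mirror_model <- function(model) {
  model$bias <- -model$bias
  tmp <- model$mono_left_target
  model$mono_left_target <- 10 - model$mono_right_target
  model$mono_right_target <- 10 - tmp
  model
}

# latent percept for one stimulus (before confusion and noise)
latent_percept <- function(model, cue_type, cue_value) {
  if (cue_type == "diotic") return(5 + model$bias)
  if (cue_type == "mono_left") return(model$mono_left_target)
  if (cue_type == "mono_right") return(model$mono_right_target)
  gain <- if (cue_type == "itd") model$gain_itd else model$gain_ild
  span <- if (cue_type == "itd") model$itd_saturation else ILD_SPAN_DB
  if (model$side_oriented)
    5 + sign(cue_value) * 4 * gain + model$bias
  else
    5 + 4 * gain * max(-1, min(1, cue_value / span)) + model$bias
}

round_half_up <- function(x) floor(x + 0.5)

#' Simulate one lateralization session from a listener model
#'
#' Emits the full stimulus design (6 presentations per stimulus, 8 for
#' the diotic one) in randomized order, drawing each button press from
#' the model's percept plus response noise.  Uses the current RNG state;
#' seed beforehand for reproducibility.
#'
#' @param model A [listener_model()].
#' @param participant_id,group,phase Session identity fields.
#' @return A [lat_session()].
#' @export
simulate_session <- function(model, participant_id = "SYN1",
                             group = "control", phase = "control") {
  design <- stimulus_design()
  idx <- rep(seq_len(nrow(design)), design$n_presentations)
  order <- sample(length(idx))
  idx <- idx[order]
  trials <- data.frame(
    cue_type = design$cue_type[idx],
    cue_value = design$cue_value[idx],
    presentation_index = stats::ave(seq_along(idx), idx, FUN = seq_along),
    response_key = NA_integer_,
    stringsAsFactors = FALSE)
  n <- nrow(trials)
  percept <- vapply(seq_len(n), function(i)
    latent_percept(model, trials$cue_type[i], trials$cue_value[i]),
    numeric(1))
  lateralized <- trials$cue_type != "diotic"
  flip <- stats::runif(n) < model$confusion_prob & lateralized
  extreme <- trials$cue_type == "itd" & abs(trials$cue_value) == 1500
  flip <- flip | (stats::runif(n) < model$extreme_confusion_prob & extreme)
  percept[flip] <- 10 - percept[flip]
  noise <- if (model$response_noise_sd > 0)
    stats::rnorm(n, 0, model$response_noise_sd) else numeric(n)
  trials$response_key <- pmin(9, pmax(1, round_half_up(percept + noise)))
  lat_session(participant_id, group, phase, trials)
}

# ---- cohort specification ---------------------------------------------

#' Default impaired-listener archetypes
#'
#' Declarative archetype definitions: each entry gives the model
#' parameters at full severity (severity 1); at severity `s` numeric
#' parameters are linearly blended between a control-like base draw and
#' the archetype value, and `side_oriented` is set when `s > 0.5`.
#'
#' * `shifted` - constant lateral shift of the auditory space
#'   (bias 2 keys at full severity).
#' * `side_oriented` - percepts pushed to the ears for any nonzero cue,
#'   with the extreme +/-1500 us stimuli becoming confusable.
#' * `high_variability` - response noise SD 1.5 keys.
#' * `confuser` - left-right confusion probability 0.3.
#'
#' @return Named list of parameter lists.
#' @export
default_archetypes <- function() {
  list(
    shifted = list(bias = 2),
    side_oriented = list(side_oriented = TRUE,
                         extreme_confusion_prob = 0.5),
    high_variability = list(response_noise_sd = 1.5),
    confuser = list(confusion_prob = 0.3)
  )
}

# severity of each phase (first..last) under a trajectory label
trajectory_severity <- function(trajectory, n_phases) {
  anchors <- switch(trajectory,
    recovering = c(1, 0.5, 0.15),
    deteriorating = c(0.3, 0.65, 1),
    stable = c(0.8, 0.8, 0.8),
    stop("unknown trajectory ", sQuote(trajectory)))
  if (n_phases == 1L) return(anchors[1L])
  stats::approx(seq(0, 1, length.out = 3L), anchors,
                xout = seq(0, 1, length.out = n_phases))$y
}

#' Default patient roster of the synthetic cohort
#'
#' One recovering and one deteriorating patient per archetype.
#'
#' @return Data frame with columns `archetype` and `trajectory`.
#' @export
default_patients <- function() {
  expand.grid(archetype = names(default_archetypes()),
              trajectory = c("recovering", "deteriorating"),
              stringsAsFactors = FALSE)[, c("archetype", "trajectory")]
}

# blend a control-like base model toward an archetype at severity s
apply_archetype <- function(base, arche, s) {
  for (field in names(arche)) {
    target <- arche[[field]]
    if (is.logical(target)) {
      base[[field]] <- target && s > 0.5
    } else {
      base[[field]] <- base[[field]] + s * (target - base[[field]])
    }
  }
  base
}

# deterministic 31-bit substream seed per participant x phase, so adding
# participants never perturbs existing ones
derive_seed <- function(master_seed, participant_id, phase) {
  p <- 2147483647
  h <- 0
  for (code in utf8ToInt(paste(participant_id, phase, sep = "/")))
    h <- (h * 131 + code) %% p
  as.integer((master_seed %% p + h * 7919) %% p)
}

# control-like base model draw (documented default jitter)
draw_control_model <- function() {
  listener_model(
    gain_itd = stats::runif(1, 0.9, 1.1),
    gain_ild = stats::runif(1, 0.9, 1.1),
    bias = stats::runif(1, -0.3, 0.3),
    response_noise_sd = stats::runif(1, 0.4, 0.8),
    mono_left_target = 1 + stats::runif(1, 0, 0.5),
    mono_right_target = 9 - stats::runif(1, 0, 0.5))
}

# tone-in-noise observer draw; stroke leaves binaural unmasking largely
# intact, so patients share the control distribution (BMLD ~ 10-16 dB)
draw_observer <- function() {
  mu0 <- stats::runif(1, 53, 57)
  tone_observer(mu_n0s0 = mu0,
                mu_n0spi = mu0 - stats::runif(1, 10, 16),
                sigma = stats::runif(1, 3, 5))
}

draw_audiogram <- function(participant_id, phase, group) {
  base <- if (group == "control") stats::rnorm(1, 14, 4)
          else stats::rnorm(1, 17, 5)
  asym <- stats::rnorm(1, 0, if (group == "control") 2 else 4)
  rows <- expand.grid(ear = c("left", "right"), frequency = c(500, 1000, 3000),
                      stringsAsFactors = FALSE)
  thr <- base + ifelse(rows$ear == "left", asym / 2, -asym / 2) +
    stats::rnorm(nrow(rows), 0, 2)
  data.frame(participant_id = participant_id, phase = phase, ear = rows$ear,
             frequency = rows$frequency,
             threshold = round(pmax(-10, thr)),
             stringsAsFactors = FALSE)
}

#' Simulate a full synthetic cohort
#'
#' Generates, fully seeded, a control cohort (one `"control"` phase each)
#' and a patient cohort measured at every phase: lateralization sessions,
#' tone-in-noise adaptive tracks (two N0Spi runs followed by one N0S0
#' run, as in the measurement protocol) with BMLD extraction, and PTA3
#' audiograms.  Every participant-phase combination consumes its own RNG
#' substream derived from the master seed, so extending the cohort never
#' changes existing participants' data.
#'
#' @param n_controls Number of control listeners (>= 4, default 12).
#' @param patients Data frame with columns `archetype` and `trajectory`
#'   (one row per patient), default [default_patients()].
#' @param phases Patient phase order, default acute/subacute/chronic.
#' @param seed Master seed (integer).
#' @param archetypes Archetype definitions, default [default_archetypes()].
#' @return List of class `synthetic_cohort`: `sessions` (list of
#'   [lat_session()]), `tracks` (long tracks data frame), `bmld` (one row
#'   per participant-phase), `audiograms`, `models` (generative
#'   parameters per participant-phase) and `seed`.
#' @export
simulate_cohort <- function(n_controls = 12L, patients = default_patients(),
                            phases = default_phases(), seed = 1L,
                            archetypes = default_archetypes()) {
  stopifnot(n_controls >= 4L)
  if (nrow(patients) > 0L) {
    unknown <- setdiff(unique(patients$archetype), names(archetypes))
    if (length(unknown) > 0L)
      stop("unknown archetype ", sQuote(unknown[1L]))
  }
  roster <- rbind(
    data.frame(participant_id = sprintf("C%02d", seq_len(n_controls)),
               group = "control", archetype = NA_character_,
               trajectory = NA_character_, stringsAsFactors = FALSE),
    if (nrow(patients) > 0L)
      data.frame(participant_id = sprintf("P%02d", seq_len(nrow(patients))),
                 group = "patient", archetype = patients$archetype,
                 trajectory = patients$trajectory, stringsAsFactors = FALSE)
  )
  sessions <- list()
  tracks <- list()
  bmld <- list()
  audiograms <- list()
  models <- list()
  for (i in seq_len(nrow(roster))) {
    who <- roster[i, ]
    p_phases <- if (who$group == "control") "control" else phases
    sev <- if (who$group == "control") rep(0, length(p_phases))
           else trajectory_severity(who$trajectory, length(p_phases))
    # participant-level base draw from a dedicated substream
    set.seed(derive_seed(seed, who$participant_id, "@base"))
    base_model <- draw_control_model()
    for (j in seq_along(p_phases)) {
      phase <- p_phases[j]
      set.seed(derive_seed(seed, who$participant_id, phase))
      model <- if (who$group == "control") base_model
               else apply_archetype(base_model,
                                    archetypes[[who$archetype]], sev[j])
      sessions[[length(sessions) + 1L]] <-
        simulate_session(model, who$participant_id, who$group, phase)
      obs <- draw_observer()
      runs <- list(run_staircase(obs, "N0Spi", run_index = 1L),
                   run_staircase(obs, "N0Spi", run_index = 2L),
                   run_staircase(obs, "N0S0", run_index = 1L))
      for (tr in runs) {
        td <- tr$trials
        tracks[[length(tracks) + 1L]] <- data.frame(
          participant_id = who$participant_id, phase = phase,
          condition = tr$condition, run_index = tr$run_index,
          trial_index = seq_len(nrow(td)), level_db = td$tone_level,
          correct = td$correct, reversal = td$is_reversal,
          valid = tr$valid, stringsAsFactors = FALSE)
      }
      b <- compute_bmld(runs[[3L]]$threshold, runs[[1L]]$threshold,
                        runs[[2L]]$threshold)
      bmld[[length(bmld) + 1L]] <- data.frame(
        participant_id = who$participant_id, phase = phase,
        thr_n0s0 = b$threshold_n0s0, thr_pi_1 = b$threshold_n0spi_run1,
        thr_pi_2 = b$threshold_n0spi_run2, bmld = b$bmld,
        stringsAsFactors = FALSE)
      audiograms[[length(audiograms) + 1L]] <-
        draw_audiogram(who$participant_id, phase, who$group)
      models[[length(models) + 1L]] <- cbind(
        data.frame(participant_id = who$participant_id, phase = phase,
                   group = who$group, archetype = who$archetype,
                   trajectory = who$trajectory, severity = sev[j],
                   stringsAsFactors = FALSE),
        as.data.frame(model[vapply(model, function(f)
          is.numeric(f) || is.logical(f), logical(1))]))
    }
  }
  structure(list(sessions = sessions,
                 tracks = do.call(rbind, tracks),
                 bmld = do.call(rbind, bmld),
                 audiograms = do.call(rbind, audiograms),
                 models = do.call(rbind, models),
                 seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d sessions, seed %d\n",
              length(x$sessions), x$seed))
  invisible(x)
}

#' Compare injected listener parameters with metric-level readouts
#'
#' Validation harness for the generator: given the model a session was
#' generated from and the session's computed metric vector, reports the
#' injected parameter next to its metric-level estimate - bias from
#' `diotic percept - 5`, `gain_ild` from 3x the mean ILD slope (the
#' full-range slope is `4 * gain / 12` keys/dB), `gain_itd` from 150x the
#' mean ITD slope (`4 * gain / 600` keys/us), and the response noise SD
#' from the mean per-stimulus standard deviation with a quantization
#' correction `sqrt(max(s^2 - 1/12, 0))` for the variance added by
#' rounding percepts to integer keys.
#'
#' @param model The injected [listener_model()].
#' @param metrics The session's metric vector ([compute_metric_vector()]).
#' @return Data frame with columns `parameter`, `injected`, `recovered`,
#'   `error`.
#' @export
parameter_recovery_check <- function(model, metrics) {
  mean_std <- mean(c(metrics[["itd_std"]], metrics[["ild_std"]]))
  rec <- data.frame(
    parameter = c("bias", "gain_ild", "gain_itd", "response_noise_sd"),
    injected = c(model$bias, model$gain_ild, model$gain_itd,
                 model$response_noise_sd),
    recovered = c(
      metrics[["diotic_percept"]] - 5,
      mean(c(metrics[["ild_l_slope"]], metrics[["ild_r_slope"]])) * 3,
      mean(c(metrics[["itd_l_slope"]], metrics[["itd_r_slope"]])) * 150,
      sqrt(max(mean_std^2 - 1 / 12, 0))),
    stringsAsFactors = FALSE)
  rec$error <- rec$recovered - rec$injected
  rec
}
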