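# Shared fixtures: hand-built and randomly generated sessions, the
# left-right mirror transform, and small constructors.

# trials data frame from per-stimulus response vectors; names are
# "itd_-600", "ild_4", "mono_left", "mono_right", "diotic"
make_trials <- function(responses) {
  rows <- lapply(names(responses), function(nm) {
    r <- responses[[nm]]
    if (nm %in% c("mono_left", "mono_right", "diotic")) {
      cue_type <- nm
      cue_value <- NA_real_
    } else {
      parts <- strsplit(nm, "_")[[1]]
      cue_type <- parts[1]
      cue_value <- as.numeric(parts[2])
    }
    data.frame(cue_type = cue_type, cue_value = cue_value,
               presentation_index = seq_along(r), response_key = r,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

make_session <- function(responses, participant_id = "T1",
                         group = "control", phase = "control") {
  lat_session(participant_id, group, phase, make_trials(responses))
}

# complete session where retained responses per stimulus are given and an
# extra (discarded) first presentation is prepended
full_design_responses <- function(fill = 5L) {
  design <- stimulus_design()
  resp <- lapply(seq_len(nrow(design)), function(i)
    rep(fill, design$n_presentations[i]))
  names(resp) <- ifelse(design$cue_type %in% c("itd", "ild"),
                        paste(design$cue_type, design$cue_value, sep = "_"),
                        design$cue_type)
  resp
}

# left-right mirror of a session: cues negated, monaural sides swapped,
# responses reflected about key 5
mirror_session <- function(session) {
  tr <- session$trials
  tr$cue_value <- -tr$cue_value
  tr$cue_type <- c(itd = "itd", ild = "ild", diotic = "diotic",
                   mono_left = "mono_right",
                   mono_right = "mono_left")[tr$cue_type]
  tr$response_key <- 10L - tr$response_key
  lat_session(session$participant_id, session$group, session$phase, tr)
}

# random listener drawn wide enough to hit saturation, confusion and
# side-oriented branches
random_model <- function() {
  listener_model(
    gain_itd = runif(1, 0.3, 1.3),
    gain_ild = runif(1, 0.3, 1.3),
    bias = runif(1, -2, 2),
    response_noise_sd = runif(1, 0, 1.5),
    confusion_prob = sample(c(0, runif(1, 0, 0.4)), 1),
    extreme_confusion_prob = sample(c(0, 0.5), 1),
    side_oriented = runif(1) < 0.25,
    mono_left_target = runif(1, 1, 3),
    mono_right_target = runif(1, 7, 9))
}

random_session <- function() {
  simulate_session(random_model(), participant_id = "RND",
                   group = "patient", phase = "acute")
}

# control metrics table with distinct continuous values, for order-rule
# properties where ties must not occur
random_control_metrics <- function(n = 12L) {
  nm <- metric_names()
  df <- data.frame(participant_id = sprintf("C%02d", seq_len(n)),
                   phase = "control", stringsAsFactors = FALSE)
  for (m in nm) df[[m]] <- rnorm(n)
  df
}
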