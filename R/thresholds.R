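# Adaptive tone-in-noise task: one-up/three-down transformed staircase
# simulation, threshold extraction, binaural masking level difference
# (BMLD) and audiometric pure-tone-average (PTA3) summaries.

#' Asymptotic percent-correct target of a one-up/n-down staircase
#'
#' A transformed up-down staircase that lowers the level after `n_down`
#' consecutive correct responses and raises it after any error converges
#' to the level where `p^n_down = 1/2`, i.e. `p = (1/2)^(1/n_down)`.
#' For the one-up/three-down rule this is 0.7937 (79.4% correct).
#'
#' @param n_down Number of consecutive correct responses required before
#'   a level decrease (>= 1).
#' @return Probability correct at convergence.
#' @examples
#' convergence_target(3)  # 0.7937...
#' @export
convergence_target <- function(n_down) {
  if (!is.numeric(n_down) || n_down < 1)
    stop("n_down must be >= 1")
  0.5^(1 / n_down)
}

#' Construct a tone-in-noise observer
#'
#' A three-interval forced-choice observer with a cumulative-normal
#' psychometric function: probability correct at tone level `L` is
#' `guess + (1 - guess - lapse) * pnorm((L - mu) / sigma)` with guess
#' rate 1/3.  Binaural unmasking enters only through the condition
#' midpoints: `mu_n0spi <= mu_n0s0`, and their difference is the
#' observer's underlying BMLD.
#'
#' @param mu_n0s0,mu_n0spi Psychometric midpoints (dB SPL) in the
#'   tone-in-phase (N0S0) and tone-phase-inverted (N0Spi) condition.
#' @param sigma Psychometric spread (dB), > 0.
#' @param lapse Lapse rate (default 0).
#' @return Object of class `tin_observer`.
#' @export
tone_observer <- function(mu_n0s0 = 55, mu_n0spi = 42, sigma = 4,
                          lapse = 0) {
  stopifnot(sigma > 0, lapse >= 0, lapse < 2 / 3)
  if (mu_n0spi > mu_n0s0)
    stop("mu_n0spi must not exceed mu_n0s0 (binaural unmasking)")
  structure(list(mu_n0s0 = mu_n0s0, mu_n0spi = mu_n0spi, sigma = sigma,
                 guess = 1 / 3, lapse = lapse), class = "tin_observer")
}

#' Probability correct of an observer at a tone level
#'
#' @param observer A [tone_observer()].
#' @param level Tone level(s) in dB SPL.
#' @param condition `"N0S0"` or `"N0Spi"`.
#' @return Probability correct (vectorized over `level`).
#' @export
prob_correct <- function(observer, level, condition = c("N0S0", "N0Spi")) {
  condition <- match.arg(condition)
  mu <- if (condition == "N0S0") observer$mu_n0s0 else observer$mu_n0spi
  observer$guess + (1 - observer$guess - observer$lapse) *
    stats::pnorm((level - mu) / observer$sigma)
}

#' Simulate one adaptive tone-in-noise track
#'
#' One-up/three-down transformed staircase: the tone level drops by the
#' current step after three consecutive correct responses (the counter
#' resets after every level change) and rises after any error.  The step
#' is 4 dB up to the second reversal and 2 dB for the remaining eight;
#' the track ends at the tenth reversal.  Requested levels above the
#' 80 dB SPL cap are clamped; a track that requests a level above the cap
#' `cap_invalid_after` times (default 3) is stopped and marked invalid
#' with threshold `NA`.  The threshold of a valid track is the mean of
#' the last eight reversal levels (the level presented on the trial at
#' which the direction change occurred).
#'
#' @param observer A [tone_observer()].
#' @param condition `"N0S0"` (start 65 dB SPL) or `"N0Spi"` (start 50).
#' @param start_level Override of the condition's default start level.
#' @param run_index Run label stored in the record.
#' @param n_down Consecutive-correct rule (default 3).
#' @param n_reversals Total reversals per track (default 10).
#' @param step_sizes `c(initial, final)` step in dB (default 4, 2).
#' @param step_switch_after Reversal count after which the final step is
#'   used (default 2).
#' @param max_level Level cap in dB SPL (default 80).
#' @param cap_invalid_after Number of above-cap requests that invalidate
#'   the track (default 3).
#' @return Object of class `track_record`: `condition`, `run_index`,
#'   `trials` (data frame `tone_level`, `correct`, `is_reversal`),
#'   `reversal_levels`, `valid`, `threshold`.
#' @export
run_staircase <- function(observer, condition = c("N0S0", "N0Spi"),
                          start_level = NULL, run_index = 1L, n_down = 3L,
                          n_reversals = 10L, step_sizes = c(4, 2),
                          step_switch_after = 2L, max_level = 80,
                          cap_invalid_after = 3L) {
  condition <- match.arg(condition)
  if (is.null(start_level))
    start_level <- if (condition == "N0S0") 65 else 50
  if (start_level > max_level)
    stop("start_level exceeds the ", max_level, " dB SPL cap")
  level <- start_level
  n_correct <- 0L
  last_dir <- 0L
  cap_hits <- 0L
  reversal_levels <- numeric(0)
  levels <- numeric(0); corrects <- logical(0); revflags <- logical(0)
  valid <- TRUE
  max_trials <- 10000L   # safety net; never reached in practice
  for (trial in seq_len(max_trials)) {
    p <- prob_correct(observer, level, condition)
    correct <- stats::runif(1) < p
    levels[trial] <- level
    corrects[trial] <- correct
    revflags[trial] <- FALSE
    step <- if (length(reversal_levels) < step_switch_after)
      step_sizes[1] else step_sizes[2]
    change <- 0
    if (correct) {
      n_correct <- n_correct + 1L
      if (n_correct >= n_down) {
        change <- -step
        n_correct <- 0L
      }
    } else {
      change <- step
      n_correct <- 0L
    }
    if (change != 0) {
      dir <- sign(change)
      if (last_dir != 0L && dir != last_dir) {
        reversal_levels <- c(reversal_levels, level)
        revflags[trial] <- TRUE
      }
      last_dir <- dir
      if (length(reversal_levels) >= n_reversals) break
      new_level <- level + change
      if (new_level > max_level) {
        cap_hits <- cap_hits + 1L
        new_level <- max_level
        if (cap_hits >= cap_invalid_after) {
          valid <- FALSE
          break
        }
      }
      level <- new_level
    }
  }
  rec <- structure(list(
    condition = condition, run_index = run_index,
    trials = data.frame(tone_level = levels, correct = corrects,
                        is_reversal = revflags),
    reversal_levels = reversal_levels, valid = valid,
    n_reversals_expected = n_reversals, threshold = NA_real_),
    class = "track_record")
  rec$threshold <- extract_threshold(rec)
  rec
}

#' @export
print.track_record <- function(x, ...) {
  cat(sprintf("<track_record> %s run %d: %d trials, %d reversals, %s\n",
              x$condition, x$run_index, nrow(x$trials),
              length(x$reversal_levels),
              if (x$valid) sprintf("threshold %.1f dB SPL", x$threshold)
              else "invalid"))
  invisible(x)
}

#' Threshold of a recorded track
#'
#' Mean of the last eight reversal levels; `NA` for invalid tracks.
#'
#' @param track A `track_record` from [run_staircase()].
#' @return Threshold in dB SPL, or `NA`.
#' @export
extract_threshold <- function(track) {
  if (!track$valid) return(NA_real_)
  k <- length(track$reversal_levels)
  if (k < track$n_reversals_expected)
    stop("valid track has only ", k, " reversals; expected ",
         track$n_reversals_expected)
  mean(utils::tail(track$reversal_levels, 8L))
}

#' Binaural masking level difference from three thresholds
#'
#' `BMLD = threshold(N0S0) - better (lower) of the two N0Spi run
#' thresholds`.  Invalid runs enter as `NA`; the BMLD is `NA` when the
#' N0S0 threshold or both N0Spi thresholds are missing.
#'
#' @param thr_n0s0 N0S0 threshold (dB SPL).
#' @param thr_pi_run1,thr_pi_run2 Thresholds of the two N0Spi runs.
#' @return List: `threshold_n0s0`, `threshold_n0spi_run1`,
#'   `threshold_n0spi_run2`, `bmld` (dB).
#' @export
compute_bmld <- function(thr_n0s0, thr_pi_run1, thr_pi_run2 = NA_real_) {
  pi_thr <- c(thr_pi_run1, thr_pi_run2)
  bmld <- if (!is.finite(thr_n0s0) || !any(is.finite(pi_thr)))
    NA_real_
  else
    thr_n0s0 - min(pi_thr[is.finite(pi_thr)])
  list(threshold_n0s0 = thr_n0s0, threshold_n0spi_run1 = thr_pi_run1,
       threshold_n0spi_run2 = thr_pi_run2, bmld = bmld)
}

#' Normative range of control BMLDs
#'
#' Applies the order-statistic [normal_range()] to the valid (finite)
#' control BMLDs, mirroring the handling of invalid control tracks: with
#' 11 of 12 controls valid the range spans the 2nd to the 10th value.
#'
#' @param bmlds Numeric vector of control BMLDs (invalid as `NA`).
#' @return Named numeric `c(lo, hi)` in dB.
#' @export
bmld_normal_range <- function(bmlds) {
  normal_range(bmlds)
}

#' Score adaptive-track logs into thresholds and BMLDs
#'
#' `score_tracks()` recomputes the threshold of every run in a long
#' tracks table (schema of [write_tracks()]) from its logged reversal
#' trials: mean of the last eight reversal levels for valid runs, `NA`
#' for invalid ones.  `bmld_from_tracks()` additionally combines, per
#' participant and phase, the N0S0 run with the better of the two N0Spi
#' runs into a BMLD row.
#'
#' @param tracks Long tracks data frame.
#' @return `score_tracks`: data frame `participant_id`, `phase`,
#'   `condition`, `run_index`, `valid`, `threshold`; `bmld_from_tracks`:
#'   data frame `participant_id`, `phase`, `thr_n0s0`, `thr_pi_1`,
#'   `thr_pi_2`, `bmld`.
#' @export
score_tracks <- function(tracks) {
  key <- paste(tracks$participant_id, tracks$phase, tracks$condition,
               tracks$run_index, sep = "\r")
  rows <- lapply(split(tracks, key), function(run) {
    run <- run[order(run$trial_index), ]
    valid <- all(run$valid)
    revs <- run$level_db[run$reversal]
    thr <- if (!valid) NA_real_ else mean(utils::tail(revs, 8L))
    data.frame(participant_id = run$participant_id[1L],
               phase = run$phase[1L], condition = run$condition[1L],
               run_index = run$run_index[1L], valid = valid,
               threshold = thr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname score_tracks
#' @export
bmld_from_tracks <- function(tracks) {
  thr <- score_tracks(tracks)
  key <- paste(thr$participant_id, thr$phase, sep = "\r")
  rows <- lapply(split(thr, key), function(sub) {
    pick <- function(cond, run) {
      v <- sub$threshold[sub$condition == cond & sub$run_index == run]
      if (length(v) == 0L) NA_real_ else v[1L]
    }
    b <- compute_bmld(pick("N0S0", 1L), pick("N0Spi", 1L),
                      pick("N0Spi", 2L))
    data.frame(participant_id = sub$participant_id[1L],
               phase = sub$phase[1L], thr_n0s0 = b$threshold_n0s0,
               thr_pi_1 = b$threshold_n0spi_run1,
               thr_pi_2 = b$threshold_n0spi_run2, bmld = b$bmld,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pure-tone average over 500, 1000 and 3000 Hz
#'
#' Per-ear mean threshold over the three PTA3 frequencies, their average,
#' and the left-minus-right asymmetry (positive = left ear worse).
#'
#' @param audiogram Audiometry data frame (schema of [read_audiograms()])
#'   for one participant and phase.
#' @return List: `pta3_l`, `pta3_r`, `pta3`, `asymmetry` (all dB HL).
#' @export
pta3 <- function(audiogram) {
  freqs <- c(500, 1000, 3000)
  ear_mean <- function(ear) {
    sub <- audiogram[audiogram$ear == ear & audiogram$frequency %in% freqs, ]
    missing_f <- setdiff(freqs, sub$frequency)
    if (length(missing_f) > 0L)
      stop("missing ", ear, "-ear threshold at ", missing_f[1L], " Hz")
    mean(vapply(freqs, function(f)
      mean(sub$threshold[sub$frequency == f]), numeric(1)))
  }
  l <- ear_mean("left")
  r <- ear_mean("right")
  list(pta3_l = l, pta3_r = r, pta3 = (l + r) / 2, asymmetry = l - r)
}
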