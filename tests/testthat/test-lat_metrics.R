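# Unit and property tests of the 31-metric computation.

test_that("retain_trials drops exactly the first presentation of each stimulus", {
  s <- make_session(full_design_responses())
  r <- retain_trials(s)
  counts <- table(ifelse(r$trials$cue_type %in% c("itd", "ild"),
                         paste(r$trials$cue_type, r$trials$cue_value),
                         r$trials$cue_type))
  expect_equal(sum(r$trials$cue_type == "diotic"), 7L)
  expect_true(all(counts[names(counts) != "diotic"] == 5L))
  expect_equal(nrow(r$trials), 104L - 17L)
  # the dropped trial is the one with the smallest presentation index
  keys <- paste(r$trials$cue_type, r$trials$cue_value)
  expect_true(all(tapply(r$trials$presentation_index, keys, min) >= 2L))
})

test_that("retain_trials is invariant to trial order and errors on single presentations", {
  set.seed(41)
  s <- random_session()
  shuffled <- s
  shuffled$trials <- s$trials[sample(nrow(s$trials)), ]
  a <- retain_trials(s)$trials
  b <- retain_trials(shuffled)$trials
  ord <- function(d) d[order(d$cue_type, d$cue_value,
                             d$presentation_index), ]
  expect_equal(ord(a), ord(b), ignore_attr = TRUE)

  single <- make_session(list(`ild_-4` = c(3L, 3L), diotic = 5L))
  expect_error(retain_trials(single), "single presentation")
})

test_that("fit_side_line reproduces forced and oracle OLS solutions", {
  # collinear per-stimulus means 2,3,4 at ILD -12,-8,-4 force r = 5 + ILD/4
  resp <- full_design_responses()
  resp[["ild_-12"]] <- rep(2L, 6); resp[["ild_-8"]] <- rep(3L, 6)
  resp[["ild_-4"]] <- rep(4L, 6)
  s <- retain_trials(make_session(resp))
  fit <- fit_side_line(s, "ild", "left")
  expect_equal(fit$slope, 0.25)
  expect_equal(fit$fitted_mean, 3.0)
  expect_equal(fit$intercept, 5.0)

  # all-equal responses give slope 0
  flat <- retain_trials(make_session(full_design_responses(5L)))
  f0 <- fit_side_line(flat, "itd", "right")
  expect_equal(f0$slope, 0)
  expect_equal(f0$fitted_mean, 5)

  # noisy trials against closed-form OLS via lm()
  set.seed(7)
  for (i in 1:5) {
    s <- retain_trials(random_session())
    for (family in c("itd", "ild")) for (side in c("left", "right")) {
      fit <- fit_side_line(s, family, side)
      phys <- if (family == "itd") c(-600, -400, -200, 200, 400, 600)
              else c(-12, -8, -4, 4, 8, 12)
      cues <- if (side == "left") phys[1:3] else phys[4:6]
      sel <- s$trials$cue_type == family & s$trials$cue_value %in% cues
      m <- lm(response_key ~ cue_value, data = s$trials[sel, ])
      expect_equal(fit$slope, unname(coef(m)[2]))
      expect_equal(fit$intercept, unname(coef(m)[1]))
    }
  }

  # a missing side stimulus is reported by name
  gap <- resp
  gap[["ild_-8"]] <- NULL
  s_gap <- retain_trials(lat_session("T1", "control", "control",
                                     make_trials(gap)))
  expect_error(fit_side_line(s_gap, "ild", "left"), "-8")
})

test_that("slope_ratio follows the natural-log / NA contract", {
  expect_equal(slope_ratio(0.25, 0.25), 0)
  expect_equal(slope_ratio(0.5, 0.25), log(2))
  expect_true(is.na(slope_ratio(-0.1, 0.25)))
  expect_true(is.na(slope_ratio(0.1, 0)))
})

test_that("location metrics: symmetry, weighted centers, diotic percept", {
  # mirror-symmetric listener: response 10-k for mirrored stimuli
  resp <- full_design_responses()
  steps <- list(`itd_-600` = 1L, `itd_-400` = 2L, `itd_-200` = 4L,
                itd_200 = 6L, itd_400 = 8L, itd_600 = 9L,
                `ild_-12` = 1L, `ild_-8` = 2L, `ild_-4` = 4L,
                ild_4 = 6L, ild_8 = 8L, ild_12 = 9L)
  for (nm in names(steps)) resp[[nm]] <- rep(steps[[nm]], 6)
  loc <- location_metrics(retain_trials(make_session(resp)))
  expect_equal(loc$itd_mean, 5)
  expect_equal(loc$ild_mean, 5)
  expect_equal(loc$itd_center, 0)
  expect_equal(loc$ild_center, 0)
  expect_equal(loc$diotic_percept, 5)

  # key 5 at ITD {-200 x2, 0 x7, +200 x3} -> weighted mean 200/12
  resp2 <- full_design_responses(9L)  # no other key-5 responses
  resp2[["itd_-200"]] <- c(9L, 5L, 5L, 9L, 9L, 9L)   # first discarded
  resp2[["itd_200"]] <- c(9L, 5L, 5L, 5L, 9L, 9L)
  resp2[["diotic"]] <- c(9L, rep(5L, 7))
  loc2 <- location_metrics(retain_trials(make_session(resp2)))
  expect_equal(loc2$itd_center, 200 / 12)
  # diotic key-5 trials enter the ILD family at cue 0 too
  expect_equal(loc2$ild_center, 0)
  expect_equal(loc2$diotic_percept, 5)

  # no key-5 press anywhere in a family: center undefined
  loc3 <- location_metrics(retain_trials(make_session(
    full_design_responses(9L))))
  expect_true(is.na(loc3$itd_center))
  expect_true(is.na(loc3$ild_center))

  # all diotic responses 7 -> diotic percept 7
  resp3 <- full_design_responses()
  resp3$diotic <- rep(7L, 8)
  expect_equal(location_metrics(retain_trials(make_session(resp3)))$diotic_percept, 7)
})

test_that("variability metrics: sample sd, side aggregation, floored ratios", {
  # deterministic listener: all stds 0, ratios ln(0.1/0.1) = 0
  v <- variability_metrics(retain_trials(make_session(full_design_responses())))
  expect_equal(unname(unlist(v)), rep(0, 9))

  # retained responses {4,4,6,6,5} have sample sd 1
  resp <- full_design_responses()
  resp[["ild_4"]] <- c(1L, 4L, 4L, 6L, 6L, 5L)  # first discarded
  v2 <- variability_metrics(retain_trials(make_session(resp)))
  # ild_r_std = mean over three right stimuli = (1 + 0 + 0)/3
  expect_equal(v2$ild_r_std, 1 / 3)
  expect_equal(v2$ild_std, 1 / 7)  # 7 stimuli incl. diotic
  expect_equal(v2$ild_std_ratio, log(0.1 / (1 / 3)))

  # single retained trial -> error
  bad <- make_session(full_design_responses())
  bad$trials <- bad$trials[!(bad$trials$cue_type == "diotic" &
                               bad$trials$presentation_index > 2), ]
  expect_error(variability_metrics(retain_trials(bad)),
               "fewer than 2 retained trials")
})

test_that("range metrics: max-min of per-stimulus means with floors", {
  resp <- full_design_responses()
  means <- c(2, 2.6, 3.4, 5, 6.2, 7, 7.8)
  stim <- c("itd_-600", "itd_-400", "itd_-200", "diotic",
            "itd_200", "itd_400", "itd_600")
  # integer responses whose retained means equal the target values
  sets <- list(c(2, 2, 2, 2, 2), c(3, 3, 3, 2, 2), c(4, 4, 3, 3, 3),
               c(5, 5, 5, 5, 5, 5, 5), c(7, 7, 6, 6, 5), c(7, 7, 7, 7, 7),
               c(8, 8, 8, 8, 7))
  for (i in seq_along(stim))
    resp[[stim[i]]] <- as.integer(c(1, sets[[i]]))  # prepend discarded trial
  r <- range_metrics(retain_trials(make_session(resp)))
  expect_equal(r$itd_range, 5.8)
  expect_equal(r$ild_range, 0)
  expect_equal(r$range_ratio, log(0.5 / 5.8))

  flat <- range_metrics(retain_trials(make_session(full_design_responses())))
  expect_equal(flat$itd_range, 0)
  expect_equal(flat$range_ratio, 0)
})

test_that("extreme and monaural percepts are plain means", {
  resp <- full_design_responses()
  resp$mono_left <- rep(1L, 6)
  resp$mono_right <- rep(9L, 6)
  resp$itd_1500 <- c(5L, 2L, 2L, 2L, 8L, 8L)  # first discarded
  e <- extreme_and_monaural(retain_trials(make_session(resp)))
  expect_equal(e$mon_left, 1)
  expect_equal(e$mon_right, 9)
  expect_equal(e$pos_1500, 4.4)
})

test_that("compute_metric_vector on the noiseless reference listener is fully determined", {
  set.seed(11)
  v <- compute_metric_vector(simulate_session(ideal_listener()))
  expect_identical(names(v), metric_names())
  # integer-key quantization of the linear percept forces responses
  # 1,2,4 | 6,8,9 per side, hence OLS slope 0.375 keys/dB (ILD) and
  # 0.0075 keys/us (ITD), not the continuous-response 4/12 and 4/600
  expect_equal(unname(v[c("ild_l_slope", "ild_r_slope")]), c(0.375, 0.375))
  expect_equal(unname(v[c("itd_l_slope", "itd_r_slope")]), c(0.0075, 0.0075))
  expect_equal(unname(v[c("ild_slope_ratio", "itd_slope_ratio",
                          "itd_std_ratio", "ild_std_ratio",
                          "range_ratio")]), rep(0, 5))
  expect_equal(unname(v[c("itd_mean", "ild_mean", "diotic_percept")]),
               rep(5, 3))
  expect_equal(unname(v[c("itd_center", "ild_center")]), c(0, 0))
  expect_equal(unname(v[grep("_std$", names(v))]), rep(0, 7))
  expect_equal(unname(v[c("itd_range", "ild_range")]), c(8, 8))
  expect_equal(unname(v[c("mon_left", "mon_right", "neg_1500", "pos_1500")]),
               c(1, 9, 1, 9))
})

test_that("metric vector is permutation-invariant and within bounds", {
  set.seed(23)
  for (i in 1:10) {
    s <- random_session()
    v <- compute_metric_vector(s)
    shuffled <- s
    shuffled$trials <- s$trials[sample(nrow(s$trials)), ]
    expect_equal(compute_metric_vector(shuffled), v)
    key_scale <- c("itd_mean", "ild_mean", "itd_l_fit", "itd_r_fit",
                   "ild_l_fit", "ild_r_fit", "diotic_percept",
                   "mon_left", "mon_right", "neg_1500", "pos_1500")
    expect_true(all(v[key_scale] >= 1 - 1e-9 & v[key_scale] <= 9 + 1e-9))
    expect_true(all(v[grep("_std$", names(v))] >= 0))
    expect_true(all(v[c("itd_range", "ild_range")] >= 0 &
                      v[c("itd_range", "ild_range")] <= 8))
    if (!is.na(v[["itd_center"]]))
      expect_true(abs(v[["itd_center"]]) <= 600)
    if (!is.na(v[["ild_center"]]))
      expect_true(abs(v[["ild_center"]]) <= 12)
  }
})
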