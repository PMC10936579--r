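# File formats, round trips and the command-line entry point.

test_that("session write/read round trip preserves trials and identity", {
  set.seed(31)
  cohort <- simulate_cohort(n_controls = 4L,
                            patients = data.frame(archetype = "shifted",
                                                  trajectory = "recovering"),
                            seed = 31L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sessions(cohort$sessions, path)
  back <- read_sessions(path)
  expect_equal(length(back), length(cohort$sessions))
  key <- function(s) paste(s$participant_id, s$phase)
  back <- back[match(vapply(cohort$sessions, key, character(1)),
                     vapply(back, key, character(1)))]
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$group, cohort$sessions[[i]]$group)
    expect_equal(back[[i]]$trials, cohort$sessions[[i]]$trials,
                 ignore_attr = TRUE)
    expect_true(back[[i]]$complete)
  }
})

test_that("loader rejects malformed rows and flags incomplete sessions", {
  set.seed(33)
  s <- simulate_session(ideal_listener(), "A1", "control", "control")
  path <- withr::local_tempfile(fileext = ".csv")
  write_sessions(list(s), path)

  # response_key outside 1..9 names the file row
  df <- utils::read.csv(path)
  df$response_key[5] <- 0L
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_sessions(path), "response_key outside 1..9 in row 6")

  # unknown cue type
  df <- utils::read.csv(path)
  df$response_key[5] <- 5L
  df$cue_type[10] <- "binaural"
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_sessions(path), "unknown cue_type")

  # missing column is a format error
  df <- utils::read.csv(path)
  df$cue_type[10] <- "diotic"
  df$cue_value[10] <- NA
  utils::write.csv(df[, setdiff(names(df), "response_key")], path,
                   row.names = FALSE)
  expect_error(read_sessions(path), "lacks column")

  # deleting the diotic rows loads with an incomplete flag and warning
  write_sessions(list(s), path)
  df <- utils::read.csv(path)
  utils::write.csv(df[df$cue_type != "diotic", ], path, row.names = FALSE)
  expect_warning(back <- read_sessions(path), "incomplete")
  expect_false(back[[1]]$complete)
})

test_that("metrics table round-trips at full precision including NA", {
  set.seed(35)
  sessions <- replicate(3, random_session(), simplify = FALSE)
  for (i in seq_along(sessions)) {
    sessions[[i]]$participant_id <- paste0("P", i)
    sessions[[i]]$phase <- "acute"
  }
  tab <- metrics_table(sessions)
  # force an undefined metric into the table
  tab$ild_slope_ratio[2] <- NA_real_
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics(tab, path)
  # the sentinel token is written, not an empty field
  raw <- readLines(path)
  expect_true(any(grepl(",NA", raw[3])))
  back <- read_metrics(path)
  expect_identical(back$participant_id, tab$participant_id)
  for (m in metric_names()) expect_identical(back[[m]], tab[[m]])
  expect_error(write_metrics(tab[, -5], path), "lacks column")
})

test_that("normative table and track logs round-trip through their files", {
  set.seed(37)
  ctrl <- random_control_metrics(12L)
  tab <- build_normative_table(ctrl)
  path <- withr::local_tempfile(fileext = ".json")
  write_normative(tab, path)
  expect_equal(read_normative(path), tab)

  obs <- tone_observer()
  tr <- run_staircase(obs, "N0S0")
  log <- data.frame(participant_id = "X", phase = "acute",
                    condition = tr$condition, run_index = 1L,
                    trial_index = seq_len(nrow(tr$trials)),
                    level_db = tr$trials$tone_level,
                    correct = tr$trials$correct,
                    reversal = tr$trials$is_reversal, valid = tr$valid)
  tpath <- withr::local_tempfile(fileext = ".csv")
  write_tracks(log, tpath)
  expect_equal(read_tracks(tpath), log)
})

test_that("audiometry loader validates ear labels and frequency range", {
  aud <- data.frame(participant_id = "X", phase = "acute",
                    ear = c("left", "right"), frequency = c(500, 500),
                    threshold = c(10, 15))
  path <- withr::local_tempfile(fileext = ".csv")
  write_audiograms(aud, path)
  expect_equal(read_audiograms(path), aud)
  aud$ear[2] <- "middle"
  write_audiograms(aud, path)
  expect_error(read_audiograms(path), "invalid ear")
})

test_that("cli: seeded simulate runs are byte-identical and pipe into metrics", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  args <- function(out) c("simulate", "--controls", "4", "--patients", "2",
                          "--seed", "7", "--log-level", "quiet",
                          "--out", out)
  expect_equal(cli_main(args(out1)), 0L)
  expect_equal(cli_main(args(out2)), 0L)
  for (f in c("trials.csv", "tracks.csv", "audiometry.csv", "bmld.csv"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))

  mfile <- file.path(out1, "metrics.csv")
  expect_equal(cli_main(c("metrics", "--trials", file.path(out1, "trials.csv"),
                          "--log-level", "quiet", "--out", mfile)), 0L)
  m <- read_metrics(mfile)
  # one row per session: 4 controls + 2 patients x 3 phases
  expect_equal(nrow(m), 4L + 2L * 3L)

  nfile <- file.path(out1, "normative.json")
  expect_equal(cli_main(c("normative", "--metrics", mfile,
                          "--log-level", "quiet", "--out", nfile)), 0L)
  dfile <- file.path(out1, "divergence.csv")
  expect_equal(cli_main(c("diverge", "--metrics", mfile,
                          "--normative", nfile,
                          "--log-level", "quiet", "--out", dfile)), 0L)
  div <- utils::read.csv(dfile)
  expect_equal(nrow(div), 6L)
  expect_true(all(div$n_divergent >= 0 & div$n_divergent <= 31))

  ldir <- file.path(out1, "long")
  expect_equal(cli_main(c("longitudinal", "--divergence", dfile,
                          "--metrics", mfile, "--normative", nfile,
                          "--log-level", "quiet", "--out", ldir)), 0L)
  expect_true(file.exists(file.path(ldir, "summary.json")))

  rfile <- file.path(out1, "report.md")
  expect_equal(cli_main(c("report", "--normative", nfile,
                          "--divergence", dfile,
                          "--log-level", "quiet", "--out", rfile)), 0L)
  expect_true(any(grepl("Normal lateralization", readLines(rfile))))
})

test_that("cli: unknown subcommand and bad input exit nonzero", {
  expect_equal(suppressMessages(cli_main("frobnicate")), 1L)
  expect_equal(suppressWarnings(suppressMessages(
    cli_main(c("metrics", "--trials", "/nonexistent/x.csv",
               "--out", "y.csv")))), 1L)
  expect_equal(cli_main(character(0)), 2L)
})
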