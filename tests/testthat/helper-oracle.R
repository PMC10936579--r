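# Independent straightforward re-implementation of the 31-metric profile,
# used as a brute-force oracle.  Deliberately written with different
# machinery (lm(), tapply(), explicit loops) than the package code.

oracle_metrics <- function(session) {
  tr <- session$trials
  key <- ifelse(tr$cue_type %in% c("itd", "ild"),
                paste0(tr$cue_type, "@", tr$cue_value), tr$cue_type)
  keep <- logical(nrow(tr))
  for (k in unique(key)) {
    idx <- which(key == k)
    first <- idx[order(tr$presentation_index[idx])][1]
    keep[setdiff(idx, first)] <- TRUE
  }
  tr <- tr[keep, ]

  resp_of <- function(type, value = NULL) {
    if (is.null(value)) tr$response_key[tr$cue_type == type]
    else tr$response_key[tr$cue_type == type & tr$cue_value == value]
  }
  # (cue, response) pairs of a family's physiological set, diotic at 0
  fam <- function(family) {
    phys <- if (family == "itd") c(-600, -400, -200, 200, 400, 600)
            else c(-12, -8, -4, 4, 8, 12)
    cues <- c(); resps <- c()
    for (v in phys) {
      r <- resp_of(family, v)
      cues <- c(cues, rep(v, length(r))); resps <- c(resps, r)
    }
    r <- resp_of("diotic")
    list(cue = c(cues, rep(0, length(r))), resp = c(resps, r),
         phys = phys)
  }
  side_fit <- function(family, side) {
    f <- fam(family)
    cues <- if (side == "l") f$phys[1:3] else f$phys[4:6]
    sel <- f$cue %in% cues
    m <- stats::lm(resp ~ cue, data = data.frame(cue = f$cue[sel],
                                                 resp = f$resp[sel]))
    slope <- unname(coef(m)[2])
    # lm() returns ~1e-18 noise where the exact slope is 0 (constant
    # responses); zap it so the log-ratio NA contract is comparable
    if (abs(slope) < 1e-10) slope <- 0
    list(slope = slope,
         fitted_mean = mean(unname(predict(m, data.frame(cue = cues)))))
  }
  lr <- function(l, r) { q <- l / r; if (!is.finite(q) || q <= 0) NA_real_ else log(q) }
  per_stim <- function(family, fun) {
    f <- fam(family)
    vapply(sort(unique(f$cue)), function(v) fun(f$resp[f$cue == v]),
           numeric(1))
  }
  per_stim_cues <- function(family) sort(unique(fam(family)$cue))
  center <- function(family) {
    f <- fam(family)
    hit <- f$resp == 5
    if (sum(hit) == 0) NA_real_ else mean(f$cue[hit])
  }
  side_mean_sd <- function(family, side) {
    f <- fam(family)
    cues <- if (side == "l") f$phys[1:3] else f$phys[4:6]
    mean(vapply(cues, function(v) stats::sd(f$resp[f$cue == v]),
                numeric(1)))
  }
  fits <- list(itd_l = side_fit("itd", "l"), itd_r = side_fit("itd", "r"),
               ild_l = side_fit("ild", "l"), ild_r = side_fit("ild", "r"))
  sds_itd <- per_stim("itd", stats::sd)
  sds_ild <- per_stim("ild", stats::sd)
  means_itd <- per_stim("itd", mean)
  means_ild <- per_stim("ild", mean)
  itd_l_std <- side_mean_sd("itd", "l"); itd_r_std <- side_mean_sd("itd", "r")
  ild_l_std <- side_mean_sd("ild", "l"); ild_r_std <- side_mean_sd("ild", "r")
  itd_range <- max(means_itd) - min(means_itd)
  ild_range <- max(means_ild) - min(means_ild)
  c(ild_l_slope = fits$ild_l$slope, ild_r_slope = fits$ild_r$slope,
    itd_l_slope = fits$itd_l$slope, itd_r_slope = fits$itd_r$slope,
    ild_slope_ratio = lr(fits$ild_l$slope, fits$ild_r$slope),
    itd_slope_ratio = lr(fits$itd_l$slope, fits$itd_r$slope),
    itd_mean = mean(fam("itd")$resp), ild_mean = mean(fam("ild")$resp),
    itd_l_fit = fits$itd_l$fitted_mean, itd_r_fit = fits$itd_r$fitted_mean,
    ild_l_fit = fits$ild_l$fitted_mean, ild_r_fit = fits$ild_r$fitted_mean,
    itd_center = center("itd"), ild_center = center("ild"),
    diotic_percept = mean(resp_of("diotic")),
    diotic_std = stats::sd(resp_of("diotic")),
    ild_std = mean(sds_ild), itd_std = mean(sds_itd),
    itd_l_std = itd_l_std, itd_r_std = itd_r_std,
    ild_l_std = ild_l_std, ild_r_std = ild_r_std,
    itd_std_ratio = log(max(itd_l_std, 0.1) / max(itd_r_std, 0.1)),
    ild_std_ratio = log(max(ild_l_std, 0.1) / max(ild_r_std, 0.1)),
    itd_range = itd_range, ild_range = ild_range,
    range_ratio = log(max(ild_range, 0.5) / max(itd_range, 0.5)),
    mon_left = mean(resp_of("mono_left")),
    mon_right = mean(resp_of("mono_right")),
    neg_1500 = mean(resp_of("itd", -1500)),
    pos_1500 = mean(resp_of("itd", 1500)))
}

# documented swap/reflection of the metric vector under session mirroring
mirror_expected <- function(v) {
  m <- v
  swap <- function(a, b) { m[[a]] <<- v[[b]]; m[[b]] <<- v[[a]] }
  reflect <- function(a, b) { m[[a]] <<- 10 - v[[b]]; m[[b]] <<- 10 - v[[a]] }
  swap("ild_l_slope", "ild_r_slope")
  swap("itd_l_slope", "itd_r_slope")
  swap("itd_l_std", "itd_r_std")
  swap("ild_l_std", "ild_r_std")
  for (nm in c("ild_slope_ratio", "itd_slope_ratio",
               "itd_std_ratio", "ild_std_ratio"))
    m[[nm]] <- -v[[nm]]
  for (nm in c("itd_mean", "ild_mean", "diotic_percept"))
    m[[nm]] <- 10 - v[[nm]]
  reflect("itd_l_fit", "itd_r_fit")
  reflect("ild_l_fit", "ild_r_fit")
  reflect("mon_left", "mon_right")
  reflect("neg_1500", "pos_1500")
  m[["itd_center"]] <- -v[["itd_center"]]
  m[["ild_center"]] <- -v[["ild_center"]]
  # ranges and range_ratio (ILD over ITD) are mirror-invariant
  m
}
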