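# Minimal base-graphics views of a session's lateralization pattern.

#' Plot a session's lateralization pattern
#'
#' Per-stimulus response scatter with per-stimulus means and the two
#' side-wise linear fits for one cue family, optionally with the control
#' band (normative mean +/- 1.5 SD of per-stimulus control responses)
#' behind it.
#'
#' @param session A [lat_session()] (untrimmed).
#' @param family `"itd"` or `"ild"`.
#' @param control_band Optional data frame `cue`, `mean`, `sd` of control
#'   per-stimulus response summaries.
#' @param ... Passed to [plot()].
#' @return Invisibly, the per-stimulus summary used for plotting.
#' @export
plot_lateralization <- function(session, family = c("itd", "ild"),
                                control_band = NULL, ...) {
  family <- match.arg(family)
  s <- retain_trials(session)
  ft <- family_trials(s$trials, family)
  st <- per_stimulus_stats(s$trials, family)
  unit <- if (family == "itd") "ITD [us]" else "ILD [dB]"
  plot(ft$cue, ft$response, pch = 1, col = "grey40",
       xlab = unit, ylab = "response key", ylim = c(1, 9),
       main = sprintf("%s (%s) - %s", s$participant_id, s$phase,
                      toupper(family)), ...)
  if (!is.null(control_band)) {
    graphics::polygon(c(control_band$cue, rev(control_band$cue)),
                      c(control_band$mean + 1.5 * control_band$sd,
                        rev(control_band$mean - 1.5 * control_band$sd)),
                      col = grDevices::adjustcolor("grey", 0.4),
                      border = NA)
  }
  graphics::points(st$cue, st$mean, pch = 4, cex = 1.4)
  for (side in c("left", "right")) {
    fit <- fit_side_line(s, family, side)
    phys <- if (family == "itd") ITD_PHYS else ILD_PHYS
    cues <- if (side == "left") phys[phys < 0] else phys[phys > 0]
    graphics::lines(cues, fit$intercept + fit$slope * cues,
                    col = if (side == "left") "blue" else "red", lwd = 2)
  }
  invisible(st)
}
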