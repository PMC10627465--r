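# Quiet-eye scoring: the final ball-directed fixation beginning before swing
# onset, its offset under the sustained-deviation rule, and the
# early/online/dwell phase decomposition.

qe_zero <- function(present = FALSE, status = "ok") {
  structure(list(present = present, status = status,
                 onset_s = NA_real_, offset_s = NA_real_,
                 total_ms = 0, early_ms = 0, online_ms = 0, dwell_ms = 0),
            class = "quiet_eye")
}

#' Score the quiet-eye fixation
#'
#' The quiet eye is the final fixation directed at the ball (mean visual
#' angle to the ball at most `on_target_deg`) whose onset precedes swing
#' onset. Its offset is the first time gaze leaves the target window for
#' longer than `offset_tol_ms`: consecutive on-target fixations separated by
#' shorter excursions are merged into a single quiet-eye period. If gaze is
#' still on target when the trial ends (or leaves it for no longer than the
#' tolerance), the offset is the end of the trial window. The absence of a
#' qualifying fixation is scored as a zero.
#'
#' @param fixations A `fixation_set` from [idt_fixations()].
#' @param events A `trial_events` from [detect_swing_events()]; trials with
#'   `status = "missing"` yield an unusable result (excluded downstream).
#' @param on_target_deg On-target criterion in degrees of visual angle.
#' @param offset_tol_ms Maximum off-target excursion that does not terminate
#'   the quiet eye (ms).
#' @param trial_end_s End of the trial window (s); defaults to the last
#'   fixation end when not supplied.
#' @return A `quiet_eye` object: `present`, `status`, `onset_s`, `offset_s`,
#'   `total_ms` and (after [split_phases()]) `early_ms`, `online_ms`,
#'   `dwell_ms`.
#' @export
extract_quiet_eye <- function(fixations, events, on_target_deg = 3.0,
                              offset_tol_ms = 100,
                              trial_end_s = NULL) {
  if (events$status != "ok") return(qe_zero(present = NA, status = "missing"))
  if (is.null(trial_end_s)) {
    trial_end_s <- if (nrow(fixations)) max(fixations$end_s) else events$contact_s
  }
  if (!nrow(fixations)) return(qe_zero())
  tol_s <- offset_tol_ms / 1000
  # group on-target fixations into chains separated by sub-tolerance
  # excursions; any intervening off-target fixation occupies the gap and
  # pushes it over the tolerance, breaking the chain
  ot <- which(fixations$mean_angle_to_ball <= on_target_deg)
  if (!length(ot)) return(qe_zero())
  gaps <- fixations$start_s[ot[-1]] - fixations$end_s[ot[-length(ot)]]
  chain_id <- cumsum(c(1, as.integer(gaps > tol_s)))
  chain_start <- tapply(fixations$start_s[ot], chain_id, min)
  chain_end <- tapply(fixations$end_s[ot], chain_id, max)
  # the quiet eye is the final chain beginning before movement initiation
  cand <- which(chain_start < events$swing_onset_s)
  if (!length(cand)) return(qe_zero())
  k <- max(cand)
  onset_s <- chain_start[[k]]
  offset_s <- chain_end[[k]]
  # if the remaining off-target tail is shorter than the tolerance, the
  # deviation never qualifies and the quiet eye runs to the trial end
  if (trial_end_s - offset_s <= tol_s) offset_s <- trial_end_s
  structure(list(present = TRUE, status = "ok",
                 onset_s = onset_s, offset_s = offset_s,
                 total_ms = (offset_s - onset_s) * 1000,
                 early_ms = NA_real_, online_ms = NA_real_, dwell_ms = NA_real_),
            class = "quiet_eye")
}

#' Decompose a quiet-eye period into early, online and dwell phases
#'
#' Early quiet eye is the portion before movement initiation, online quiet
#' eye the portion between swing onset and ball contact, and dwell the
#' portion after contact. The three phases are computed by telescoping
#' interval arithmetic so they sum to the total exactly.
#'
#' @param qe A `quiet_eye` from [extract_quiet_eye()].
#' @param events A `trial_events` with `swing_onset_s` and `contact_s`.
#' @param trial_start_s,trial_end_s Trial window bounds (s); the dwell phase
#'   is capped at `trial_end_s`.
#' @return The `quiet_eye` object with `early_ms`, `online_ms`, `dwell_ms`
#'   filled in.
#' @export
split_phases <- function(qe, events, trial_start_s = 0, trial_end_s = NULL) {
  if (!isTRUE(qe$present)) {
    qe$early_ms <- qe$online_ms <- qe$dwell_ms <- 0
    return(qe)
  }
  on <- max(qe$onset_s, trial_start_s)
  off <- qe$offset_s
  if (!is.null(trial_end_s)) off <- min(off, trial_end_s)
  m1 <- min(max(events$swing_onset_s, on), off)
  m2 <- min(max(events$contact_s, on), off)
  qe$early_ms <- (m1 - on) * 1000
  qe$online_ms <- (m2 - m1) * 1000
  qe$dwell_ms <- (off - m2) * 1000
  # the total is defined as the sum of the phases so additivity is exact in
  # floating point as well as on paper
  qe$total_ms <- (qe$early_ms + qe$online_ms) + qe$dwell_ms
  qe$onset_s <- on
  qe$offset_s <- off
  qe
}

#' @export
print.quiet_eye <- function(x, ...) {
  if (x$status != "ok") {
    cat("<quiet_eye> unusable (missing swing events)\n")
  } else if (!isTRUE(x$present)) {
    cat("<quiet_eye> absent (scored as zero)\n")
  } else {
    cat(sprintf("<quiet_eye> %.0f ms [%.3f, %.3f] s; early %.0f / online %.0f / dwell %.0f ms\n",
                x$total_ms, x$onset_s, x$offset_s,
                x$early_ms, x$online_ms, x$dwell_ms))
  }
  invisible(x)
}
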