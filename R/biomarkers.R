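# Twitch and calcium-transient biomarker extraction.

# Threshold crossing after the peak, linearly interpolated. Tie-break: the
# search starts at the last sample still >= peak - 1e-3 * amplitude, so a
# noisy plateau around the peak does not trigger an early crossing.
.cross_after_peak <- function(t, x, i_peak, target, eps) {
  i0 <- i_peak
  near <- which(x >= x[i_peak] - eps)
  near <- near[near >= i_peak]
  if (length(near)) i0 <- max(near[cumsum(diff(c(i_peak, near)) > 1) == 0])
  if (i0 >= length(x)) return(NA_real_)
  for (i in i0:(length(x) - 1)) {
    if (x[i] >= target && x[i + 1] < target) {
      frac <- (x[i] - target) / (x[i] - x[i + 1])
      return(t[i] + frac * (t[i + 1] - t[i]))
    }
  }
  NA_real_
}

.channel_biomarkers <- function(t, x, amp_floor) {
  base <- x[1] # pre-stimulus value of the analysed beat
  i_peak <- which.max(x)
  peak <- x[i_peak]
  amp <- peak - base
  if (!is.finite(amp) || amp < amp_floor) {
    return(c(amp = 0, ttp = NA, rt50 = NA, rt90 = NA,
             td50 = NA, td95 = NA, dia = base))
  }
  eps <- 1e-3 * amp
  ttp <- t[i_peak] - t[1]
  cr <- function(frac) .cross_after_peak(t, x, i_peak, peak - frac * amp, eps)
  t50 <- cr(0.5); t90 <- cr(0.9); t95 <- cr(0.95)
  c(amp = amp,
    ttp = ttp,
    rt50 = if (is.na(t50)) NA else t50 - t[i_peak],
    rt90 = if (is.na(t90)) NA else t90 - t[i_peak],
    td50 = if (is.na(t50)) NA else t50 - t[1],
    td95 = if (is.na(t95)) NA else t95 - t[1],
    dia = base)
}

#' Extract twitch and calcium-transient biomarkers
#'
#' Computes, per channel, the amplitude (peak minus pre-stimulus baseline),
#' time to peak (from the stimulus), relaxation times RT50/RT90 (from the
#' peak to 50%/90% decay of the amplitude, linearly interpolated between
#' samples) and, for calcium, the transient decay times TD50/TD95 measured
#' from the stimulus. The analysed beat is assumed to start at its stimulus
#' (as traces returned by [simulate_beats()] do); pass `beat_window` to
#' select a sub-interval of a longer trace.
#'
#' A flat channel (amplitude below `amp_floor`) yields amplitude 0 with the
#' time metrics `NA`; a truncated decay (no crossing inside the window)
#' yields `NA` for the affected metric with a warning, since very strong
#' interventions can suppress relaxation below the measurable range.
#'
#' @param trace A trace tibble with `time_ms`, `cai_uM`, `tension_kPa`
#'   (e.g. from [simulate_beats()] or [synth_twitch()]).
#' @param beat_window Optional `c(start, end)` time window, ms.
#' @param amp_floor Amplitude below which a channel counts as flat.
#' @return A one-row tibble: `tension_amp` (kPa), `tension_ttp`,
#'   `tension_rt50`, `tension_rt90` (ms), `tension_dia` (kPa), `ca_amp`
#'   (uM), `ca_ttp`, `ca_rt50`, `ca_rt90`, `ca_td50`, `ca_td95` (ms),
#'   `ca_dia` (uM).
#' @examples
#' tr <- synth_twitch(amp = 10, tau_rise = 30, tau_decay = 150)
#' extract_biomarkers(tr)
#' @export
extract_biomarkers <- function(trace, beat_window = NULL, amp_floor = 1e-9) {
  t <- trace$time_ms
  if (any(!is.finite(t)) || any(diff(t) <= 0)) {
    stop("trace time must be finite and strictly increasing", call. = FALSE)
  }
  if (!is.null(beat_window)) {
    keep <- t >= beat_window[1] & t <= beat_window[2]
    trace <- trace[keep, ]
    t <- trace$time_ms
  }
  if (nrow(trace) < 3) stop("trace too short for biomarkers", call. = FALSE)
  ten <- .channel_biomarkers(t, trace$tension_kPa, amp_floor)
  ca <- .channel_biomarkers(t, trace$cai_uM, amp_floor)
  if (ten[["amp"]] > 0 && is.na(ten[["rt90"]])) {
    warning("tension decay truncated: RT90 undefined within the window",
            call. = FALSE)
  }
  if (ca[["amp"]] > 0 && is.na(ca[["rt90"]])) {
    warning("calcium decay truncated: RT90 undefined within the window",
            call. = FALSE)
  }
  tibble::tibble(
    tension_amp = ten[["amp"]], tension_ttp = ten[["ttp"]],
    tension_rt50 = ten[["rt50"]], tension_rt90 = ten[["rt90"]],
    tension_dia = ten[["dia"]],
    ca_amp = ca[["amp"]], ca_ttp = ca[["ttp"]],
    ca_rt50 = ca[["rt50"]], ca_rt90 = ca[["rt90"]],
    ca_td50 = ca[["td50"]], ca_td95 = ca[["td95"]],
    ca_dia = ca[["dia"]])
}
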