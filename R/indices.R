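#' Elevated plus maze anxiety index
#'
#' The fraction of the session spent out of the open arms, expressed as a
#' percentage: `100 * (time_closed + time_center) / time_total`. Higher
#' values indicate more anxiety-like behavior.
#'
#' @param time_closed Seconds spent in the closed arms.
#' @param time_center Seconds spent in the center zone.
#' @param time_total Total session time in seconds (> 0).
#' @return Index in \[0, 100\]. Vectorized.
#' @examples
#' anxiety_index(150, 30, 300)  # 60
#' @export
anxiety_index <- function(time_closed, time_center, time_total) {
  if (any(time_total <= 0)) stop("time_total must be positive")
  if (any(time_closed < 0) || any(time_center < 0))
    stop("times must be non-negative")
  if (any(time_closed + time_center > time_total + 1e-9))
    stop("closed-arm plus center time exceeds total session time")
  100 * (time_closed + time_center) / time_total
}

#' Social recognition preference index
#'
#' Relative preference for exploring an unfamiliar over a familiar
#' conspecific: `100 * (t_unfamiliar - t_familiar) / (t_unfamiliar +
#' t_familiar)`. Positive values indicate intact social recognition memory;
#' 0 is indifference.
#'
#' @param time_unfamiliar Seconds exploring the unfamiliar animal.
#' @param time_familiar Seconds exploring the familiar animal.
#' @return Index in \[-100, 100\]. Vectorized.
#' @examples
#' preference_index(60, 40)  # 20
#' @export
preference_index <- function(time_unfamiliar, time_familiar) {
  if (any(time_unfamiliar < 0) || any(time_familiar < 0))
    stop("exploration times must be non-negative")
  tot <- time_unfamiliar + time_familiar
  if (any(tot <= 0)) stop("no exploration recorded (both times zero)")
  100 * (time_unfamiliar - time_familiar) / tot
}

#' Western blot densitometry normalization
#'
#' Background-subtracted band signal, divided by the background-subtracted
#' loading-control (GAPDH) signal of the same lane, then scaled to the mean
#' of the control group so that control expression averages 1 by
#' construction. Background correction is subtractive; under that reading
#' the loading-control step is the usual ratio.
#'
#' @param band_od Band optical density (a.u.).
#' @param background_od Local background optical density.
#' @param gapdh_od Loading-control band optical density.
#' @param gapdh_background_od Loading-control background optical density.
#' @param control_group_mean Mean background/GAPDH-normalized density of the
#'   control group (> 0); pass 1 to skip the group scaling.
#' @return Relative expression (dimensionless). Vectorized.
#' @export
normalize_densitometry <- function(band_od, background_od,
                                   gapdh_od, gapdh_background_od,
                                   control_group_mean = 1) {
  if (any(c(band_od, background_od, gapdh_od, gapdh_background_od) < 0))
    stop("optical densities must be non-negative")
  net_gapdh <- gapdh_od - gapdh_background_od
  if (any(net_gapdh <= 0))
    stop("non-positive net GAPDH signal; cannot normalize")
  if (any(control_group_mean <= 0))
    stop("control_group_mean must be positive")
  ((band_od - background_od) / net_gapdh) / control_group_mean
}

#' Summarize evoked responses as percent of baseline
#'
#' `100 * mean(responses) / mean(baseline)`. Used for frequency-dependent
#' inhibition (average of the 1 Hz pulse-train responses vs the 0.1 Hz
#' baseline pulses) and paired-pulse protocols (average second-pulse
#' response vs baseline pulses). Values below 100 indicate inhibition,
#' above 100 facilitation.
#'
#' @param responses Numeric vector of protocol responses (EPSP slope or
#'   population spike amplitude), non-empty.
#' @param baseline Numeric vector of baseline responses, non-empty with
#'   nonzero mean.
#' @return Percent of baseline (scalar).
#' @export
percent_of_baseline <- function(responses, baseline) {
  if (!length(responses) || !length(baseline))
    stop("responses and baseline must be non-empty")
  mb <- mean(baseline)
  if (abs(mb) < .Machine$double.eps)
    stop("baseline mean is zero; percent of baseline undefined")
  100 * mean(responses) / mb
}
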