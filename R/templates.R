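#' Evoked-waveform template
#'
#' Builds a zero-baseline response template of one of three shapes:
#' * `"fast"`: multiphasic (positive, larger negative, small positive
#'   Gaussian lobes) emulating short-latency striated-muscle EMG responses;
#'   integrates to approximately zero (AC-coupled EMG).
#' * `"slow"`: biphasic positive-then-negative raised-cosine lobes spanning
#'   the whole duration, emulating slow smooth-muscle waves of 200-250 ms;
#'   integrates to approximately zero.
#' * `"pressure"`: a single positive raised-cosine lobe (a pressure wave does
#'   not integrate to zero).
#'
#' The returned template is scaled so that its peak-to-peak amplitude equals
#' `amplitude` exactly (up to floating-point rounding).
#'
#' @param kind `"fast"`, `"slow"` or `"pressure"`.
#' @param duration_ms Template duration in ms; must be positive.
#' @param amplitude Peak-to-peak amplitude in signal units; must be >= 0.
#' @param sampling_rate Sampling rate in Hz; must be positive.
#' @return Numeric vector of `round(duration_ms / 1000 * sampling_rate)`
#'   samples (at least 3).
#' @examples
#' tpl <- waveform_template("slow", 225, 10, 20000)
#' max(tpl) - min(tpl) # 10
#' @export
waveform_template <- function(kind = c("fast", "slow", "pressure"),
                              duration_ms, amplitude, sampling_rate) {
  kind <- match.arg(kind)
  if (duration_ms <= 0) stop_invalid("`duration_ms` must be > 0")
  if (sampling_rate <= 0) stop_invalid("`sampling_rate` must be > 0")
  if (amplitude < 0) stop_invalid("`amplitude` must be >= 0")
  n <- max(3L, as.integer(round(duration_ms / 1000 * sampling_rate)))
  t <- seq(0, 1, length.out = n)
  shape <- switch(kind,
    fast = {
      # two opposite-sign Gaussian lobes plus a smaller third lobe; lobe
      # amplitudes (1, -1.35, 0.35) sum to zero so the equal-width lobes
      # cancel in area
      g <- function(center, w) exp(-0.5 * ((t - center) / w)^2)
      w <- 1 / 14
      g(0.22, w) - 1.35 * g(0.50, w) + 0.35 * g(0.78, w)
    },
    slow = {
      # positive then negative raised-cosine lobes of equal area; the
      # positive lobe occupies the first quarter so the wave rises quickly
      # after its onset (keeping the response causal when the first peak is
      # aligned at the configured latency) and then swings slowly negative
      lobe <- function(a, b) ifelse(t >= a & t <= b,
                                    sin(pi * (t - a) / (b - a))^2, 0)
      rise <- 0.25
      lobe(0, rise) - rise / (1 - rise) * lobe(rise, 1)
    },
    pressure = {
      # fast rise, slow decay: peak at 15% of the duration
      p <- 0.15
      ifelse(t <= p,
             sin(pi / 2 * t / p)^2,
             cos(pi / 2 * (t - p) / (1 - p))^2)
    }
  )
  p2p <- max(shape) - min(shape)
  if (amplitude == 0 || p2p == 0) return(rep(0, n))
  shape * (amplitude / p2p)
}

# Sample index of the template's first prominent local extremum (> 20% of
# the template's absolute maximum); the generator aligns this sample with
# the configured latency so that measured first-peak latency equals the
# configured one.
template_first_peak <- function(tpl) {
  ext <- local_extrema(tpl)
  ext <- ext[abs(tpl[ext]) > 0.2 * max(abs(tpl))]
  if (length(ext) == 0L) which.max(abs(tpl)) else ext[1L]
}

#' Piecewise-linear recruitment function
#'
#' Response amplitude as a function of stimulation current: zero at or below
#' the recruitment threshold, rising linearly with slope `gain` above it, and
#' constant above the saturation current.
#'
#' @param current Stimulation current(s) in uA; must be >= 0.
#' @param threshold Recruitment threshold in uA.
#' @param gain Slope in amplitude units per uA.
#' @param saturation Saturation current in uA; must be >= `threshold`.
#' @return Response amplitude(s), same length as `current`.
#' @examples
#' recruitment_gain(c(10, 40, 200), threshold = 20, gain = 0.5, saturation = 100)
#' @export
recruitment_gain <- function(current, threshold, gain, saturation) {
  if (saturation < threshold)
    stop_invalid("`saturation` must be >= `threshold`")
  if (any(current < 0)) stop_invalid("`current` must be >= 0")
  amp <- gain * (pmin(current, saturation) - threshold)
  amp[current <= threshold] <- 0
  pmax(amp, 0)
}
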