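#' Stimulation protocol
#'
#' Describes a pulse-train protocol: a stepped current ladder delivered at a
#' fixed pulse rate (recruitment mapping), or a constant-current train (burst
#' mode). The default values reproduce the mapping protocol used throughout
#' this package: 1 Hz pulses, 10 to 800 uA in 10 uA increments, 10 pulses per
#' amplitude, 0.3 ms pulse width.
#'
#' @param frequency Pulse rate in Hz.
#' @param current_start,current_stop,current_step Current ladder in uA.
#' @param pulses_per_current Number of pulses delivered at each current step.
#' @param pulse_width_ms Pulse width in ms (metadata only; the simulated
#'   stimulus artifact is a single-sample deflection).
#' @param train_duration_s Duration of the constant-current train in seconds,
#'   used only by [generate_burst_session()].
#' @return An object of class `stim_protocol`.
#' @examples
#' stim_protocol(frequency = 1, current_start = 10, current_stop = 100)
#' @export
stim_protocol <- function(frequency = 1,
                          current_start = 10,
                          current_stop = 800,
                          current_step = 10,
                          pulses_per_current = 10,
                          pulse_width_ms = 0.3,
                          train_duration_s = 10) {
  if (frequency <= 0) stop_invalid("`frequency` must be > 0")
  if (current_step <= 0) stop_invalid("`current_step` must be > 0")
  if (current_start > current_stop)
    stop_invalid("`current_start` must be <= `current_stop`")
  if (pulses_per_current < 1) stop_invalid("`pulses_per_current` must be >= 1")
  if (pulse_width_ms <= 0) stop_invalid("`pulse_width_ms` must be > 0")
  if (train_duration_s <= 0) stop_invalid("`train_duration_s` must be > 0")
  structure(
    list(frequency = frequency,
         current_start = current_start,
         current_stop = current_stop,
         current_step = current_step,
         pulses_per_current = pulses_per_current,
         pulse_width_ms = pulse_width_ms,
         train_duration_s = train_duration_s),
    class = "stim_protocol")
}

protocol_currents <- function(protocol) {
  seq(protocol$current_start, protocol$current_stop, by = protocol$current_step)
}

#' Channel response model
#'
#' Phenomenological model of one recorded channel: an evoked waveform
#' template (fast multiphasic EMG, slow biphasic EMG, or monophasic pressure
#' wave), an onset latency, a piecewise-linear recruitment function
#' (threshold, linear gain, saturation) and additive white background noise.
#'
#' @param name Channel label, e.g. `"Detr"`, `"EUS"`, `"TA"`, `"CYST"`.
#' @param kind Template shape: `"fast"`, `"slow"` or `"pressure"`.
#' @param latency_ms First-peak latency in ms (site profiles may override it).
#' @param latency_jitter_sd_ms SD of the per-pulse latency jitter in ms;
#'   jitter is drawn from a normal distribution truncated (clamped) at 3 SD.
#' @param template_duration_ms Template duration in ms. Defaults to 20 ms for
#'   fast templates and 225 ms for slow/pressure templates.
#' @param threshold_uA Recruitment threshold in uA (no response below it).
#' @param gain Recruitment gain in amplitude units per uA above threshold.
#' @param saturation_uA Current at which the response amplitude saturates.
#' @param noise_sd SD of the additive white background noise, amplitude units.
#' @param unit Physical unit label of the channel.
#' @return An object of class `channel_model`.
#' @export
channel_model <- function(name,
                          kind = c("fast", "slow", "pressure"),
                          latency_ms,
                          latency_jitter_sd_ms = 0.5,
                          template_duration_ms = NULL,
                          threshold_uA = 20,
                          gain = 0.05,
                          saturation_uA = 600,
                          noise_sd = 0.2,
                          unit = "mV") {
  kind <- match.arg(kind)
  if (is.null(template_duration_ms))
    template_duration_ms <- if (kind == "fast") 20 else 225
  if (latency_ms <= 0) stop_invalid("`latency_ms` must be > 0")
  if (template_duration_ms <= 0) stop_invalid("`template_duration_ms` must be > 0")
  if (gain < 0) stop_invalid("`gain` must be >= 0")
  if (latency_jitter_sd_ms < 0) stop_invalid("`latency_jitter_sd_ms` must be >= 0")
  if (noise_sd < 0) stop_invalid("`noise_sd` must be >= 0")
  if (saturation_uA < threshold_uA)
    stop_invalid("`saturation_uA` must be >= `threshold_uA`")
  structure(
    list(name = name, kind = kind, latency_ms = latency_ms,
         latency_jitter_sd_ms = latency_jitter_sd_ms,
         template_duration_ms = template_duration_ms,
         threshold_uA = threshold_uA, gain = gain,
         saturation_uA = saturation_uA, noise_sd = noise_sd, unit = unit),
    class = "channel_model")
}

#' Stimulation site profile
#'
#' A stimulation site (spinal segment) with its rostral/caudal group label,
#' per-channel gain multipliers, and optional per-channel latency overrides
#' (latencies of some channels differ between rostral and caudal sites).
#'
#' @param site_id Site label, e.g. `"T13"`, `"L1"`, `"L7"`, `"S1"`.
#' @param group `"rostral"` (lower thoracic / upper lumbar) or `"caudal"`
#'   (lower lumbar / sacral / coccygeal).
#' @param multipliers Named non-negative numeric vector, one entry per
#'   channel, scaling that channel's recruitment gain at this site.
#' @param latency_ms Optional named numeric vector overriding channel
#'   latencies (ms) at this site.
#' @return An object of class `site_profile`.
#' @export
site_profile <- function(site_id, group = c("rostral", "caudal"),
                         multipliers, latency_ms = NULL) {
  group <- match.arg(group)
  if (is.null(names(multipliers)) || any(!nzchar(names(multipliers))))
    stop_invalid("`multipliers` must be a named vector (one entry per channel)")
  if (any(multipliers < 0)) stop_invalid("gain multipliers must be >= 0")
  if (!is.null(latency_ms)) {
    if (is.null(names(latency_ms)))
      stop_invalid("`latency_ms` overrides must be named by channel")
    if (any(latency_ms <= 0)) stop_invalid("latency overrides must be > 0")
  }
  structure(
    list(site_id = site_id, group = group,
         multipliers = multipliers, latency_ms = latency_ms),
    class = "site_profile")
}

#' Default feline lower-urinary-tract mapping preset
#'
#' Preset protocol, channel models and site profiles emulating epidural
#' mapping of the feline lower urinary tract and hindlimb: four channels
#' (detrusor EMG, bladder pressure, external urethral sphincter EMG,
#' tibialis anterior EMG), rostral sites (T13, L1) with dominant
#' detrusor/pressure recruitment, and caudal sites (L6, L7, S1) with
#' dominant sphincter recruitment. Channel latencies follow the reported
#' group means: Detr 38.01/38.07 ms (rostral/caudal), EUS 13.72/7.41 ms,
#' TA 14.61/8.96 ms. Bladder-pressure latency is set to 40 ms (a slow wave
#' comparable to the detrusor; it is conventionally excluded from latency
#' statistics). Noise SDs are not reported for the original recordings and
#' are package choices (see the methods vignette).
#'
#' @return A list with elements `protocol` ([stim_protocol()]), `channels`
#'   (named list of [channel_model()]) and `sites` (list of
#'   [site_profile()]).
#' @examples
#' p <- preset_feline_lut()
#' names(p$channels)
#' @export
preset_feline_lut <- function() {
  channels <- list(
    Detr = channel_model("Detr", "slow", latency_ms = 38.01,
                         gain = 0.05, noise_sd = 0.2, unit = "mV"),
    CYST = channel_model("CYST", "pressure", latency_ms = 40,
                         gain = 0.02, noise_sd = 0.05, unit = "cmH2O"),
    EUS  = channel_model("EUS", "fast", latency_ms = 13.72,
                         gain = 0.10, noise_sd = 0.2, unit = "mV"),
    TA   = channel_model("TA", "fast", latency_ms = 14.61,
                         gain = 0.10, noise_sd = 0.2, unit = "mV")
  )
  caudal_lat <- c(Detr = 38.07, EUS = 7.41, TA = 8.96)
  sites <- list(
    site_profile("T13", "rostral",
                 c(Detr = 1.00, CYST = 1.00, EUS = 0.30, TA = 0.70)),
    site_profile("L1", "rostral",
                 c(Detr = 0.85, CYST = 0.85, EUS = 0.25, TA = 0.60)),
    site_profile("L6", "caudal",
                 c(Detr = 0.20, CYST = 0.20, EUS = 0.90, TA = 1.00),
                 latency_ms = caudal_lat),
    site_profile("L7", "caudal",
                 c(Detr = 0.25, CYST = 0.25, EUS = 1.00, TA = 1.00),
                 latency_ms = caudal_lat),
    site_profile("S1", "caudal",
                 c(Detr = 0.15, CYST = 0.15, EUS = 0.95, TA = 0.90),
                 latency_ms = caudal_lat)
  )
  list(protocol = stim_protocol(), channels = channels, sites = sites)
}
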