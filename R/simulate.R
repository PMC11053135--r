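#' Generate a stimulation-locked recording session
#'
#' Synthesizes a multichannel recording containing, for each stimulation
#' site, a contiguous block in which the full current ladder of `protocol` is
#' delivered at the protocol pulse rate. Each pulse inserts, in every
#' channel, the channel's waveform template scaled by the piecewise-linear
#' recruitment function times the site's gain multiplier, aligned so that the
#' template's first peak falls `latency + jitter` ms after the pulse. A
#' single-sample stimulus artifact of `artifact_amplitude` is added at each
#' pulse time, and white noise of the channel's `noise_sd` is added
#' throughout. Identical arguments and seed yield bit-identical sessions;
#' each site uses an independent substream seeded as `seed + site_index`, so
#' adding a site does not perturb the others.
#'
#' @param protocol A [stim_protocol()].
#' @param sites List of [site_profile()]; every channel must have a
#'   multiplier at every site.
#' @param channels Named list of [channel_model()].
#' @param seed Integer master seed (required).
#' @param sampling_rate Sampling rate in Hz; default 20 kHz.
#' @param gap_s Quiet lead-in/tail around each site block, seconds.
#' @param artifact_amplitude Stimulus-artifact deflection, signal units.
#' @param animal_id Identifier stored in the session metadata.
#' @return An object of class `ees_session`: a list with the channel traces
#'   (`$channels`, named numeric vectors), the event table (`$events`, with
#'   columns `time_s`, `current_uA`, `site_id`), `$sampling_rate`, `$units`,
#'   `$protocol`, `$sites`, `$metadata`, and the generator ground truth
#'   (`$ground_truth`, one row per site x channel with the true latency,
#'   threshold, effective gain, saturation and noise SD; `$pulse_truth`, one
#'   row per pulse x channel with the true inserted amplitude).
#' @seealso [generate_burst_session()], [extract_evoked()], [write_session()]
#' @examples
#' p <- preset_feline_lut()
#' proto <- stim_protocol(current_start = 30, current_stop = 60,
#'                        pulses_per_current = 2)
#' s <- generate_session(proto, p$sites[1], p$channels["EUS"], seed = 1,
#'                       sampling_rate = 2000)
#' s
#' @export
generate_session <- function(protocol, sites, channels, seed,
                             sampling_rate = 20000, gap_s = 1,
                             artifact_amplitude = 100,
                             animal_id = "animal_1") {
  stopifnot(inherits(protocol, "stim_protocol"))
  if (length(sites) < 1L) stop_invalid("at least one site is required")
  if (length(channels) < 1L) stop_invalid("at least one channel is required")
  if (missing(seed) || !is.numeric(seed))
    stop_invalid("`seed` must be an explicit integer")
  if (sampling_rate <= 0) stop_invalid("`sampling_rate` must be > 0")
  channels <- name_channels(channels)
  check_site_multipliers(sites, names(channels))

  currents <- protocol_currents(protocol)
  n_events_site <- length(currents) * protocol$pulses_per_current
  block_s <- gap_s + n_events_site / protocol$frequency + gap_s
  plan <- lapply(seq_along(sites), function(si) {
    t0 <- (si - 1L) * block_s
    list(site = sites[[si]],
         event_t = t0 + gap_s + (seq_len(n_events_site) - 1L) / protocol$frequency,
         event_current = rep(currents, each = protocol$pulses_per_current),
         block_start_s = t0, block_s = block_s)
  })
  synthesize_session(plan, channels, protocol, seed, sampling_rate,
                     artifact_amplitude, animal_id, intervals = NULL)
}

#' Generate a 5 Hz burst session with a pre-stimulation background segment
#'
#' Like [generate_session()] but each site block consists of a noise-only
#' background segment of `bg_duration_s` seconds followed by a
#' constant-current pulse train of `protocol$train_duration_s` seconds at
#' `protocol$frequency` (5 Hz in the emulated condition). At 5 Hz the slow
#' templates outlast the inter-pulse interval, producing the sustained
#' amplitude increase that the percent-of-background analysis quantifies.
#'
#' @inheritParams generate_session
#' @param current Train current in uA; defaults to `protocol$current_stop`.
#' @param bg_duration_s Length of the pre-stimulation background segment, s.
#' @return An `ees_session` whose `$intervals` element gives, per site, the
#'   background and stimulation windows (`bg_start_s`, `bg_end_s`,
#'   `stim_start_s`, `stim_end_s`) used by [burst_percent()].
#' @export
generate_burst_session <- function(protocol, sites, channels, seed,
                                   current = protocol$current_stop,
                                   bg_duration_s = 5,
                                   sampling_rate = 20000, gap_s = 1,
                                   artifact_amplitude = 100,
                                   animal_id = "animal_1") {
  stopifnot(inherits(protocol, "stim_protocol"))
  if (bg_duration_s <= 0) stop_invalid("`bg_duration_s` must be > 0")
  if (current < 0) stop_invalid("`current` must be >= 0")
  if (missing(seed) || !is.numeric(seed))
    stop_invalid("`seed` must be an explicit integer")
  channels <- name_channels(channels)
  check_site_multipliers(sites, names(channels))

  n_pulses <- max(1L, floor(protocol$train_duration_s * protocol$frequency))
  block_s <- bg_duration_s + protocol$train_duration_s + gap_s
  plan <- lapply(seq_along(sites), function(si) {
    t0 <- (si - 1L) * block_s
    list(site = sites[[si]],
         event_t = t0 + bg_duration_s + (seq_len(n_pulses) - 1L) / protocol$frequency,
         event_current = rep(current, n_pulses),
         block_start_s = t0, block_s = block_s)
  })
  intervals <- do.call(rbind, lapply(plan, function(b) data.frame(
    site_id = b$site$site_id, group = b$site$group,
    bg_start_s = b$block_start_s,
    bg_end_s = b$block_start_s + bg_duration_s,
    stim_start_s = b$block_start_s + bg_duration_s,
    stim_end_s = b$block_start_s + bg_duration_s + protocol$train_duration_s,
    stringsAsFactors = FALSE)))
  synthesize_session(plan, channels, protocol, seed, sampling_rate,
                     artifact_amplitude, animal_id, intervals = intervals)
}

# Shared renderer: lays the planned blocks into per-channel traces.
# Per-site RNG substream: set.seed(seed + site_index); within it, per channel
# (in channel order) the latency jitters are drawn first, then the block
# noise, so noise_sd = 0 leaves all other draws unchanged.
synthesize_session <- function(plan, channels, protocol, seed, sampling_rate,
                               artifact_amplitude, animal_id, intervals) {
  n_total <- as.integer(round(sum(vapply(plan, `[[`, numeric(1), "block_s")) *
                                sampling_rate))
  ch_names <- names(channels)
  traces <- stats::setNames(lapply(ch_names, function(ch) numeric(n_total)),
                            ch_names)
  templates <- lapply(channels, function(cm)
    waveform_template(cm$kind, cm$template_duration_ms, 1, sampling_rate))
  peak_idx <- vapply(templates, template_first_peak, integer(1))
  # causality: the response onset (first peak latency minus the template's
  # internal first-peak offset, worst-case jitter) must not precede the pulse
  for (si in seq_along(plan)) for (ci in seq_along(ch_names)) {
    cm <- channels[[ci]]
    lat <- site_latency(plan[[si]]$site, cm)
    offset_ms <- (peak_idx[[ci]] - 1L) / sampling_rate * 1000
    if (lat - 3 * cm$latency_jitter_sd_ms < offset_ms)
      stop_invalid(paste0(
        "channel '%s' at site '%s': latency %g ms (minus 3 SD jitter) is ",
        "smaller than the template's first-peak offset %.3g ms; the ",
        "response would begin before the pulse"),
        ch_names[ci], plan[[si]]$site$site_id, lat, offset_ms)
  }

  events <- vector("list", length(plan))
  truth <- vector("list", length(plan))
  pulse_truth <- vector("list", length(plan))

  for (si in seq_along(plan)) {
    b <- plan[[si]]
    site <- b$site
    set.seed(seed + si)
    block_i0 <- as.integer(round(b$block_start_s * sampling_rate)) + 1L
    block_n <- as.integer(round(b$block_s * sampling_rate))
    block_n <- min(block_n, n_total - block_i0 + 1L)
    site_truth <- vector("list", length(ch_names))
    site_pulse <- vector("list", length(ch_names))
    for (ci in seq_along(ch_names)) {
      ch <- ch_names[ci]
      cm <- channels[[ch]]
      lat <- site_latency(site, cm)
      mult <- unname(site$multipliers[[ch]])
      tpl <- templates[[ch]]
      pk <- peak_idx[[ch]]
      m <- length(b$event_t)
      jit <- pmin(pmax(stats::rnorm(m), -3), 3) * cm$latency_jitter_sd_ms
      amps <- recruitment_gain(b$event_current, cm$threshold_uA, cm$gain,
                               cm$saturation_uA) * mult
      x <- traces[[ch]]
      for (k in seq_len(m)) {
        i0 <- as.integer(round(b$event_t[k] * sampling_rate)) + 1L
        x[i0] <- x[i0] + artifact_amplitude
        if (amps[k] > 0) {
          s <- i0 + as.integer(round((lat + jit[k]) * sampling_rate / 1000)) -
            (pk - 1L)
          e <- s + length(tpl) - 1L
          lo <- max(s, 1L); hi <- min(e, n_total)
          if (hi >= lo)
            x[lo:hi] <- x[lo:hi] + amps[k] * tpl[(lo - s + 1L):(hi - s + 1L)]
        }
      }
      idx <- block_i0:(block_i0 + block_n - 1L)
      x[idx] <- x[idx] + stats::rnorm(block_n, 0, cm$noise_sd)
      traces[[ch]] <- x
      site_truth[[ci]] <- data.frame(
        site_id = site$site_id, group = site$group, channel = ch,
        latency_ms = lat, threshold_uA = cm$threshold_uA,
        gain = cm$gain * mult, saturation_uA = cm$saturation_uA,
        noise_sd = cm$noise_sd, stringsAsFactors = FALSE)
      site_pulse[[ci]] <- data.frame(
        site_id = site$site_id, channel = ch, time_s = b$event_t,
        current_uA = b$event_current, amplitude = amps,
        stringsAsFactors = FALSE)
    }
    events[[si]] <- data.frame(time_s = b$event_t,
                               current_uA = b$event_current,
                               site_id = site$site_id,
                               stringsAsFactors = FALSE)
    truth[[si]] <- do.call(rbind, site_truth)
    pulse_truth[[si]] <- do.call(rbind, site_pulse)
  }

  structure(
    list(sampling_rate = sampling_rate,
         channels = traces,
         units = vapply(channels, `[[`, character(1), "unit"),
         kinds = vapply(channels, `[[`, character(1), "kind"),
         events = do.call(rbind, events),
         protocol = protocol,
         sites = plan_sites(plan),
         intervals = intervals,
         metadata = list(animal_id = animal_id, seed = seed),
         ground_truth = do.call(rbind, truth),
         pulse_truth = do.call(rbind, pulse_truth),
         duration_s = n_total / sampling_rate),
    class = "ees_session")
}

site_latency <- function(site, cm) {
  ov <- site$latency_ms
  if (!is.null(ov) && cm$name %in% names(ov)) unname(ov[[cm$name]])
  else cm$latency_ms
}

plan_sites <- function(plan) lapply(plan, `[[`, "site")

name_channels <- function(channels) {
  nm <- names(channels)
  if (is.null(nm) || any(!nzchar(nm)))
    names(channels) <- vapply(channels, `[[`, character(1), "name")
  channels
}

check_site_multipliers <- function(sites, ch_names) {
  for (s in sites) {
    missing <- setdiff(ch_names, names(s$multipliers))
    if (length(missing))
      stop_invalid("site '%s' lacks a gain multiplier for channel(s): %s",
                   s$site_id, paste(missing, collapse = ", "))
  }
}

#' @export
print.ees_session <- function(x, ...) {
  cat(sprintf("<ees_session> %s, %.4g s at %g Hz\n",
              x$metadata$animal_id, x$duration_s, x$sampling_rate))
  cat(sprintf("  channels: %s\n",
              paste(sprintf("%s [%s]", names(x$channels), x$units),
                    collapse = ", ")))
  sites <- vapply(x$sites, `[[`, character(1), "site_id")
  groups <- vapply(x$sites, `[[`, character(1), "group")
  cat(sprintf("  sites: %s\n",
              paste(sprintf("%s (%s)", sites, substr(groups, 1, 1)),
                    collapse = ", ")))
  cat(sprintf("  events: %d pulses, %g-%g uA, seed %s\n",
              nrow(x$events), min(x$events$current_uA),
              max(x$events$current_uA), format(x$metadata$seed)))
  invisible(x)
}
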