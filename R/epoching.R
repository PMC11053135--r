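#' Epoching and measurement configuration
#'
#' Parameters of the stimulus-triggered averaging and measurement chain.
#'
#' @param pre_ms Pre-stimulus window length, ms.
#' @param post_ms Post-stimulus window length, ms.
#' @param blank_ms Post-pulse blanking window, ms: samples in `[0, blank_ms]`
#'   are excluded from all measurements (stimulus-artifact exclusion).
#' @param rectify If `TRUE`, sweeps are full-wave rectified before averaging.
#'   Off by default: rectification destroys the polarity of the first peak
#'   and is applied only where a rectified metric is wanted (burst analysis).
#' @param baseline_ms Baseline window length, ms; baseline statistics are
#'   computed on `[-baseline_ms, 0)`.
#' @param presence_k Detection threshold in units of the sweep-level
#'   background SD: a response is "present" when some post-blanking local
#'   extremum of the averaged epoch deviates from the baseline mean by more
#'   than `presence_k` background SDs. When the background SD is exactly
#'   zero (noise-free data) any nonzero extremum qualifies.
#' @param smooth_ms Optional centered moving-average smoothing applied before
#'   peak detection, ms; 0 disables it.
#' @param peak_window_ms Sustained-peak window, ms: a candidate extremum
#'   counts as a peak only if it is also the most extreme value over the
#'   following `peak_window_ms`. This rejects the small noise wiggles that
#'   appear on the rising edge of slow waves, which would otherwise be taken
#'   for the first peak; it limits latency resolution for responses whose
#'   true peaks are closer together than the window.
#' @param p2p_mode Peak-to-peak definition: `"first_biphasic"` (value at the
#'   first qualifying peak minus the value at the next opposite-polarity
#'   extremum; absolute deviation from the baseline mean if the response is
#'   monophasic) or `"window_range"` (max minus min over the post-blanking
#'   window).
#' @return An object of class `epoching_config`.
#' @export
epoching_config <- function(pre_ms = 50, post_ms = 400, blank_ms = 2,
                            rectify = FALSE, baseline_ms = 20,
                            presence_k = 3, smooth_ms = 0,
                            peak_window_ms = 50,
                            p2p_mode = c("first_biphasic", "window_range")) {
  p2p_mode <- match.arg(p2p_mode)
  if (peak_window_ms < 0) stop_invalid("`peak_window_ms` must be >= 0")
  if (blank_ms < 0 || post_ms <= blank_ms)
    stop_invalid("`post_ms` must exceed `blank_ms` (>= 0)")
  if (baseline_ms <= 0 || pre_ms < baseline_ms)
    stop_invalid("`pre_ms` must be >= `baseline_ms` > 0")
  if (presence_k <= 0) stop_invalid("`presence_k` must be > 0")
  if (smooth_ms < 0) stop_invalid("`smooth_ms` must be >= 0")
  structure(
    list(pre_ms = pre_ms, post_ms = post_ms, blank_ms = blank_ms,
         rectify = rectify, baseline_ms = baseline_ms,
         presence_k = presence_k, smooth_ms = smooth_ms,
         peak_window_ms = peak_window_ms, p2p_mode = p2p_mode),
    class = "epoching_config")
}

#' Stimulus-triggered averaging
#'
#' Cuts one window `[-pre_ms, +post_ms]` around each event and averages them
#' pointwise (optionally after full-wave rectification). Baseline statistics
#' are computed on `[-baseline_ms, 0)`: `baseline_mean`/`baseline_sd` on the
#' averaged epoch, and `baseline_sd_sweep` as the pooled SD of the
#' single-sweep baseline segments (the background-noise scale used by the
#' presence criterion; averaging n sweeps shrinks the averaged-epoch noise by
#' 1/sqrt(n) relative to it, which is what makes small responses detectable).
#'
#' @param trace Numeric vector, one channel.
#' @param event_times_s Event times in seconds from trace start; at least one.
#' @param sampling_rate Sampling rate, Hz.
#' @param config An [epoching_config()].
#' @return An object of class `evoked_potential` with elements `epoch`,
#'   `time_ms` (stimulus-relative), `n_sweeps`, `baseline_mean`,
#'   `baseline_sd`, `baseline_sd_sweep`.
#' @seealso [measure_latency()], [measure_p2p()], [extract_evoked()]
#' @export
epoch_and_average <- function(trace, event_times_s, sampling_rate,
                              config = epoching_config()) {
  if (length(event_times_s) < 1L)
    stop_invalid("empty selection: no matching events")
  pre_n <- as.integer(round(config$pre_ms / 1000 * sampling_rate))
  post_n <- as.integer(round(config$post_ms / 1000 * sampling_rate))
  idx0 <- as.integer(round(event_times_s * sampling_rate)) + 1L
  if (any(idx0 - pre_n < 1L) || any(idx0 + post_n > length(trace)))
    stop_invalid("truncation: an epoch window extends beyond the trace")
  sweeps <- vapply(idx0, function(i) trace[(i - pre_n):(i + post_n)],
                   numeric(pre_n + post_n + 1L))
  if (isTRUE(config$rectify)) sweeps <- abs(sweeps)
  avg <- rowMeans(sweeps)
  time_ms <- ((-pre_n):post_n) / sampling_rate * 1000
  bl <- which(time_ms >= -config$baseline_ms & time_ms < 0)
  structure(
    list(epoch = avg, time_ms = time_ms, n_sweeps = length(idx0),
         baseline_mean = mean(avg[bl]),
         baseline_sd = sd0(avg[bl]),
         baseline_sd_sweep = sd0(as.vector(sweeps[bl, , drop = FALSE])),
         sampling_rate = sampling_rate, config = config),
    class = "evoked_potential")
}

# Candidate extremum i of x is "sustained" if it is also the most extreme
# value over the following w samples; this rejects noise wiggles riding on
# the rising/falling flanks of slow waves.
is_sustained <- function(x, i, w, is_max) {
  hi <- min(i + w, length(x))
  if (hi <= i) return(TRUE)
  seg <- x[(i + 1L):hi]
  if (is_max) x[i] >= max(seg) else x[i] <= min(seg)
}

measurement_signal <- function(ep, config) {
  x <- ep$epoch
  if (config$smooth_ms > 0)
    x <- moving_average(x, max(1L, round(config$smooth_ms / 1000 *
                                           ep$sampling_rate)))
  x
}

peak_window_samples <- function(ep, config) {
  max(0L, as.integer(round(config$peak_window_ms / 1000 * ep$sampling_rate)))
}

# Index (into ep$epoch) of the first qualifying peak, or NA if the response
# is absent. Qualifying = sustained local extremum (either polarity, ties
# toward the earlier sample) in (blank_ms, post_ms] whose polarity-consistent
# deviation from the baseline mean exceeds presence_k x sweep-level
# background SD (any nonzero deviation when that SD is 0): a maximum must
# deviate above the baseline, a minimum below it.
find_first_peak <- function(ep, config = ep$config) {
  x <- measurement_signal(ep, config)
  w <- peak_window_samples(ep, config)
  maxima <- local_maxima(x)
  cand <- sort(c(maxima, local_minima(x)))
  cand <- cand[ep$time_ms[cand] > config$blank_ms &
                 ep$time_ms[cand] <= config$post_ms]
  if (length(cand) == 0L) return(NA_integer_)
  is_max <- cand %in% maxima
  dev <- ifelse(is_max, x[cand] - ep$baseline_mean,
                ep$baseline_mean - x[cand])
  thr <- config$presence_k * ep$baseline_sd_sweep
  ok <- if (thr > 0) dev > thr else dev > 0
  for (j in which(ok))
    if (is_sustained(x, cand[j], w, is_max[j])) return(cand[j])
  NA_integer_
}

#' First-peak latency
#'
#' Time from pulse onset to the first local extremum (either polarity) after
#' the blanking window whose deviation from the baseline mean exceeds the
#' presence threshold. Returns `NA` when no sample qualifies within the
#' post-stimulus window (absent response).
#'
#' @param ep An [epoch_and_average()] result.
#' @param config An [epoching_config()]; defaults to the one stored in `ep`.
#' @return Latency in ms, or `NA_real_` if absent.
#' @export
measure_latency <- function(ep, config = ep$config) {
  i <- find_first_peak(ep, config)
  if (is.na(i)) NA_real_ else ep$time_ms[i]
}

#' Peak-to-peak amplitude of the first response peak
#'
#' Under the default `"first_biphasic"` definition: the value at the first
#' qualifying peak minus the value at the immediately following
#' opposite-polarity extremum within the post-stimulus window; for a
#' monophasic response (no following opposite extremum), the absolute
#' deviation of the peak from the baseline mean. Returns 0 for an absent
#' response. Under `"window_range"`: max minus min over the post-blanking
#' window (0 if absent).
#'
#' @inheritParams measure_latency
#' @return Non-negative amplitude in signal units.
#' @export
measure_p2p <- function(ep, config = ep$config) {
  i <- find_first_peak(ep, config)
  if (is.na(i)) return(0)
  x <- measurement_signal(ep, config)
  w <- peak_window_samples(ep, config)
  in_window <- ep$time_ms > config$blank_ms & ep$time_ms <= config$post_ms
  if (config$p2p_mode == "window_range")
    return(diff(range(x[in_window])))
  peak_is_max <- x[i] >= ep$baseline_mean
  opp <- if (peak_is_max) local_minima(x) else local_maxima(x)
  opp <- opp[opp > i & in_window[opp]]
  opp <- opp[vapply(opp, function(j) is_sustained(x, j, w, !peak_is_max),
                    logical(1))]
  if (length(opp) == 0L) abs(x[i] - ep$baseline_mean)
  else abs(x[i] - x[opp[1L]])
}

#' Extract evoked-potential measurements from a session
#'
#' Runs stimulus-triggered averaging for every (site, channel, current)
#' combination in the session and measures first-peak latency and
#' peak-to-peak amplitude of the averaged response.
#'
#' @param session An `ees_session` (from [generate_session()] or
#'   [read_session()]).
#' @param config An [epoching_config()].
#' @param channels Channel names to analyze; default all.
#' @param sweeps Optional cap on the number of sweeps averaged per condition
#'   (the first `sweeps` pulses); default all available.
#' @return A data frame with one row per (site, channel, current):
#'   `site_id`, `group`, `channel`, `current_uA`, `n_sweeps`, `latency_ms`
#'   (`NA` if absent), `p2p`, `present`.
#' @export
extract_evoked <- function(session, config = epoching_config(),
                           channels = NULL, sweeps = NULL) {
  stopifnot(inherits(session, "ees_session"))
  if (is.null(channels)) channels <- names(session$channels)
  groups <- stats::setNames(
    vapply(session$sites, `[[`, character(1), "group"),
    vapply(session$sites, `[[`, character(1), "site_id"))
  ev <- session$events
  out <- list()
  for (sid in unique(ev$site_id)) {
    ev_site <- ev[ev$site_id == sid, ]
    for (cur in unique(ev_site$current_uA)) {
      t <- ev_site$time_s[ev_site$current_uA == cur]
      if (!is.null(sweeps)) t <- utils::head(t, sweeps)
      for (ch in channels) {
        ep <- epoch_and_average(session$channels[[ch]], t,
                                session$sampling_rate, config)
        lat <- measure_latency(ep, config)
        out[[length(out) + 1L]] <- data.frame(
          site_id = sid, group = unname(groups[[sid]]), channel = ch,
          current_uA = cur, n_sweeps = ep$n_sweeps,
          latency_ms = lat, p2p = measure_p2p(ep, config),
          present = !is.na(lat), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' @export
print.evoked_potential <- function(x, ...) {
  lat <- measure_latency(x)
  cat(sprintf(
    "<evoked_potential> %d sweeps, window [%g, %g] ms\n",
    x$n_sweeps, min(x$time_ms), max(x$time_ms)))
  cat(sprintf("  baseline: mean %.4g, SD %.4g (sweep-level SD %.4g)\n",
              x$baseline_mean, x$baseline_sd, x$baseline_sd_sweep))
  if (is.na(lat)) cat("  response: absent\n")
  else cat(sprintf("  response: latency %.4g ms, p2p %.4g\n",
                   lat, measure_p2p(x)))
  invisible(x)
}

#' @export
plot.evoked_potential <- function(x, ...) {
  graphics::plot(x$time_ms, x$epoch, type = "l", xlab = "time (ms)",
                 ylab = "amplitude", ...)
  graphics::abline(v = 0, lty = 3)
  lat <- measure_latency(x)
  if (!is.na(lat)) graphics::abline(v = lat, col = 2, lty = 2)
  invisible(x)
}
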