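#' Percent-of-background response metric
#'
#' Quantifies the signal during a stimulation train relative to the
#' pre-stimulation background: the same metric (RMS by default) is computed
#' on both intervals after identical conditioning (full-wave rectification
#' followed by a moving-average smoother by default), and the result is
#' expressed as `100 * stim / background` percent.
#'
#' @param trace Numeric vector, one channel.
#' @param sampling_rate Sampling rate, Hz.
#' @param bg_interval,stim_interval Two-element numeric vectors `c(start,
#'   end)` in seconds; the background interval must precede the stimulation
#'   interval and the two must not overlap.
#' @param metric `"rms"` or `"mean_rectified"`.
#' @param rectify Full-wave rectify before smoothing (default `TRUE`).
#' @param smooth_ms Moving-average window, ms (default 50; 0 disables).
#' @param event_times_s Optional pulse times (seconds): samples within
#'   `[t, t + blank_ms]` of each pulse are zeroed before conditioning, so the
#'   stimulus artifact does not inflate the stimulation-interval metric.
#' @param blank_ms Post-pulse blanking window for artifact removal, ms.
#' @return An object of class `burst_result` with `bg_metric`, `stim_metric`,
#'   `percent`, and the conditioning parameters used.
#' @examples
#' x <- c(rep(c(1, -1), 500), rep(c(30.77, -30.77), 500))
#' percent_of_background(x, 1000, c(0, 1), c(1, 2))$percent # 3077
#' @export
percent_of_background <- function(trace, sampling_rate, bg_interval,
                                  stim_interval,
                                  metric = c("rms", "mean_rectified"),
                                  rectify = TRUE, smooth_ms = 50,
                                  event_times_s = NULL, blank_ms = 2) {
  metric <- match.arg(metric)
  if (!is.null(event_times_s) && blank_ms > 0) {
    blank_n <- as.integer(round(blank_ms / 1000 * sampling_rate))
    for (t in event_times_s) {
      i0 <- as.integer(round(t * sampling_rate)) + 1L
      idx <- i0:min(i0 + blank_n, length(trace))
      trace[idx[idx >= 1L]] <- 0
    }
  }
  check_interval <- function(iv, what) {
    if (length(iv) != 2L || iv[2L] <= iv[1L])
      stop_invalid("invalid %s interval: must be c(start, end) with end > start",
                   what)
    if (iv[1L] < 0 || iv[2L] > length(trace) / sampling_rate)
      stop_invalid("invalid %s interval: outside the trace", what)
  }
  check_interval(bg_interval, "background")
  check_interval(stim_interval, "stimulation")
  if (bg_interval[2L] > stim_interval[1L])
    stop_invalid("background interval must precede the stimulation interval")

  segment <- function(iv) {
    i0 <- as.integer(floor(iv[1L] * sampling_rate)) + 1L
    i1 <- as.integer(ceiling(iv[2L] * sampling_rate))
    trace[i0:min(i1, length(trace))]
  }
  condition <- function(x) {
    if (isTRUE(rectify)) x <- abs(x)
    if (smooth_ms > 0)
      x <- moving_average(x, max(1L, round(smooth_ms / 1000 * sampling_rate)))
    x
  }
  score <- function(x) switch(metric,
                              rms = sqrt(mean(x^2)),
                              mean_rectified = mean(abs(x)))
  bg <- score(condition(segment(bg_interval)))
  st <- score(condition(segment(stim_interval)))
  if (bg == 0)
    stop_invalid("degenerate background: background metric is zero")
  structure(
    list(bg_metric = bg, stim_metric = st, percent = 100 * st / bg,
         metric = metric, rectify = rectify, smooth_ms = smooth_ms),
    class = "burst_result")
}

#' @export
print.burst_result <- function(x, ...) {
  cat(sprintf("<burst_result> %.4g%% of background (bg %.4g, stim %.4g; %s%s)\n",
              x$percent, x$bg_metric, x$stim_metric, x$metric,
              if (x$smooth_ms > 0)
                sprintf(", rectified + %g ms smoothing", x$smooth_ms)
              else ""))
  invisible(x)
}

#' Percent-of-background table for a burst session
#'
#' Applies [percent_of_background()] to every (site, channel) of a session
#' generated by [generate_burst_session()], using the background and
#' stimulation windows recorded in the session.
#'
#' @param session An `ees_session` with an `$intervals` element.
#' @param metric,rectify,smooth_ms,blank_ms Passed to
#'   [percent_of_background()]; the session's pulse times are used for
#'   artifact blanking.
#' @return Data frame with `animal`, `site_id`, `group`, `channel`,
#'   `bg_metric`, `stim_metric`, `percent`.
#' @export
burst_percent <- function(session, metric = "rms", rectify = TRUE,
                          smooth_ms = 50, blank_ms = 2) {
  stopifnot(inherits(session, "ees_session"))
  if (is.null(session$intervals))
    stop_invalid("session has no background/stimulation intervals (not a burst session?)")
  iv <- session$intervals
  out <- list()
  for (i in seq_len(nrow(iv))) {
    for (ch in names(session$channels)) {
      r <- percent_of_background(
        session$channels[[ch]], session$sampling_rate,
        c(iv$bg_start_s[i], iv$bg_end_s[i]),
        c(iv$stim_start_s[i], iv$stim_end_s[i]),
        metric = metric, rectify = rectify, smooth_ms = smooth_ms,
        event_times_s = session$events$time_s, blank_ms = blank_ms)
      out[[length(out) + 1L]] <- data.frame(
        animal = session$metadata$animal_id, site_id = iv$site_id[i],
        group = iv$group[i], channel = ch, bg_metric = r$bg_metric,
        stim_metric = r$stim_metric, percent = r$percent,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Bundled per-animal percent-of-background reference values
#'
#' Loads the packaged table of percent-of-background responses (CYST bladder
#' pressure, detrusor EMG and external urethral sphincter EMG) measured in
#' five cats under 5 Hz rostral and caudal epidural stimulation, as reported
#' in the published mapping experiment this pipeline operationalizes. These
#' are the paired samples used by the exact Wilcoxon signed-rank
#' site-specificity tests.
#'
#' @return Data frame with columns `cat`, `channel`, `rostral_pct`,
#'   `caudal_pct`.
#' @examples
#' bp <- load_burst_percent()
#' cyst <- bp[bp$channel == "CYST", ]
#' wilcoxon_exact(cyst$rostral_pct, cyst$caudal_pct, "greater")
#' @export
load_burst_percent <- function() {
  path <- system.file("extdata", "burst_percent_by_cat.csv",
                      package = "eesmap", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
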