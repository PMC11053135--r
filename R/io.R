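#' Write a session to a plain-text container directory
#'
#' The container is a directory holding `metadata.json` (sampling rate,
#' protocol, channel names/units/kinds, site blocks, seed, sample count), one
#' text file per channel (`channel_<name>.txt`, one sample per line, full
#' double precision), `events.csv` with header `time_s,current_uA,site_id`
#' (absolute seconds from recording start), and, when present,
#' `ground_truth.json` with the generator ground truth.
#'
#' @param session An `ees_session`.
#' @param dir Target directory (created if needed).
#' @param ground_truth Write `ground_truth.json` when the session has one.
#' @return `dir`, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(session, dir, ground_truth = TRUE) {
  stopifnot(inherits(session, "ees_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_samples <- length(session$channels[[1L]])
  meta <- list(
    sampling_rate = session$sampling_rate,
    n_samples = n_samples,
    duration_s = session$duration_s,
    channels = lapply(names(session$channels), function(ch) list(
      name = ch, unit = unname(session$units[[ch]]),
      kind = unname(session$kinds[[ch]]))),
    sites = lapply(session$sites, function(s) list(
      site_id = s$site_id, group = s$group,
      multipliers = as.list(s$multipliers),
      latency_ms = if (is.null(s$latency_ms)) NULL else as.list(s$latency_ms))),
    protocol = unclass(session$protocol),
    intervals = session$intervals,
    metadata = session$metadata)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  for (ch in names(session$channels))
    writeLines(sprintf("%.17g", session$channels[[ch]]),
               file.path(dir, paste0("channel_", ch, ".txt")))
  utils::write.csv(session$events, file.path(dir, "events.csv"),
                   row.names = FALSE, quote = FALSE)
  if (ground_truth && !is.null(session$ground_truth))
    jsonlite::write_json(
      list(ground_truth = session$ground_truth,
           pulse_truth = session$pulse_truth),
      file.path(dir, "ground_truth.json"), digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a session container directory
#'
#' Loads and validates a directory written by [write_session()] (or any
#' conforming directory): all channel traces must have the declared sample
#' count, and event times must be strictly increasing and lie within the
#' trace. Errors name the offending file.
#'
#' @param dir Container directory.
#' @return An `ees_session`.
#' @export
read_session <- function(dir) {
  meta_path <- file.path(dir, "metadata.json")
  if (!file.exists(meta_path))
    stop_invalid("missing required file '%s'", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  fs <- meta$sampling_rate
  n_samples <- meta$n_samples
  ch_info <- meta$channels
  traces <- list(); units <- character(0); kinds <- character(0)
  for (ci in ch_info) {
    path <- file.path(dir, paste0("channel_", ci$name, ".txt"))
    if (!file.exists(path))
      stop_invalid("missing channel file '%s'", path)
    x <- scan(path, what = numeric(), quiet = TRUE)
    if (length(x) != n_samples)
      stop_invalid("channel file '%s' is truncated or malformed: expected %d samples, found %d",
                   path, n_samples, length(x))
    traces[[ci$name]] <- x
    units[ci$name] <- ci$unit
    kinds[ci$name] <- ci$kind
  }
  ev_path <- file.path(dir, "events.csv")
  if (!file.exists(ev_path)) stop_invalid("missing required file '%s'", ev_path)
  events <- utils::read.csv(ev_path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "current_uA", "site_id") %in% names(events)))
    stop_invalid("'%s' must have header time_s,current_uA,site_id", ev_path)
  if (nrow(events) > 1L && any(diff(events$time_s) <= 0))
    stop_invalid("validation error in '%s': event times must be strictly increasing",
                 ev_path)
  duration <- n_samples / fs
  if (any(events$time_s < 0) || any(events$time_s >= duration))
    stop_invalid("validation error in '%s': event outside the trace (duration %g s)",
                 ev_path, duration)

  sites <- lapply(meta$sites, function(s) site_profile(
    s$site_id, s$group,
    multipliers = unlist(s$multipliers),
    latency_ms = if (is.null(s$latency_ms)) NULL else unlist(s$latency_ms)))
  protocol <- do.call(stim_protocol, meta$protocol)
  intervals <- if (!is.null(meta$intervals))
    as.data.frame(meta$intervals, stringsAsFactors = FALSE) else NULL

  gt <- NULL; pt <- NULL
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    g <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    gt <- as.data.frame(g$ground_truth, stringsAsFactors = FALSE)
    pt <- as.data.frame(g$pulse_truth, stringsAsFactors = FALSE)
  }

  structure(
    list(sampling_rate = fs, channels = traces, units = units, kinds = kinds,
         events = events, protocol = protocol, sites = sites,
         intervals = intervals, metadata = meta$metadata,
         ground_truth = gt, pulse_truth = pt, duration_s = duration),
    class = "ees_session")
}
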