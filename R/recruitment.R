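#' Build a recruitment curve
#'
#' Assembles the current-to-amplitude recruitment curve for one
#' (site, channel) from evoked-potential measurements. Absent responses
#' contribute amplitude 0 (they are kept as points); repeated measurements at
#' one current are averaged; points are sorted by increasing current.
#'
#' @param measurements Data frame with columns `current_uA` and `p2p` (rows
#'   of an [extract_evoked()] table for a single site and channel), plus
#'   optional `site_id`/`channel` columns carried into the result.
#' @return An object of class `recruitment_curve` with `$points`
#'   (`current_uA`, `p2p`); fit fields are filled in by [fit_slope()].
#' @export
build_recruitment_curve <- function(measurements) {
  if (is.null(measurements) || nrow(measurements) == 0L)
    stop_invalid("empty selection: no measurements to build a curve from")
  amp <- tapply(measurements$p2p, measurements$current_uA, mean)
  cur <- as.numeric(names(amp))
  o <- order(cur)
  structure(
    list(site_id = if ("site_id" %in% names(measurements))
           measurements$site_id[1L] else NA_character_,
         channel = if ("channel" %in% names(measurements))
           measurements$channel[1L] else NA_character_,
         points = data.frame(current_uA = cur[o], p2p = unname(amp)[o]),
         slope = NA_real_, intercept = NA_real_, regression_range = NULL,
         degenerate = FALSE),
    class = "recruitment_curve")
}

#' Fit the recruitment-curve slope
#'
#' Ordinary least-squares regression of amplitude on current over the rising
#' part of the curve: from the lowest current through the first current at
#' which the maximum amplitude is attained. Points after the maximum
#' (saturation or decline) are excluded. If all amplitudes are equal the
#' slope is 0 over the full range; if the maximum is attained at the first
#' point (fewer than 2 points in range) the slope is undefined (`NA`,
#' flagged), and such curves are excluded from normalization.
#'
#' @param curve A [build_recruitment_curve()] result.
#' @return The curve with `$slope` (units/uA), `$intercept`,
#'   `$regression_range` (index pair into `$points`) and `$degenerate`
#'   filled in.
#' @examples
#' cv <- build_recruitment_curve(
#'   data.frame(current_uA = c(10, 20, 30, 40, 50),
#'              p2p = c(0, 5, 10, 10, 9)))
#' coef(fit_slope(cv)) # slope 0.5 over the first three points
#' @export
fit_slope <- function(curve) {
  stopifnot(inherits(curve, "recruitment_curve"))
  pts <- curve$points
  if (nrow(pts) < 2L)
    stop_invalid("at least two points are required to fit a slope")
  if (all(pts$p2p == pts$p2p[1L])) {
    curve$slope <- 0
    curve$intercept <- pts$p2p[1L]
    curve$regression_range <- c(1L, nrow(pts))
    return(curve)
  }
  imax <- which.max(pts$p2p) # first attainment of the maximum
  if (imax < 2L) {
    curve$slope <- NA_real_
    curve$intercept <- NA_real_
    curve$regression_range <- c(1L, imax)
    curve$degenerate <- TRUE
    return(curve)
  }
  fit <- stats::lm(p2p ~ current_uA, data = pts[seq_len(imax), ])
  curve$slope <- unname(stats::coef(fit)[2L])
  curve$intercept <- unname(stats::coef(fit)[1L])
  curve$regression_range <- c(1L, imax)
  curve
}

#' @export
coef.recruitment_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
print.recruitment_curve <- function(x, ...) {
  cat(sprintf("<recruitment_curve> %s / %s: %d points, %g-%g uA\n",
              x$site_id, x$channel, nrow(x$points),
              min(x$points$current_uA), max(x$points$current_uA)))
  if (!is.null(x$regression_range))
    cat(sprintf("  slope %.6g units/uA over points %d..%d%s\n",
                x$slope, x$regression_range[1L], x$regression_range[2L],
                if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' @export
plot.recruitment_curve <- function(x, ...) {
  graphics::plot(x$points$current_uA, x$points$p2p, xlab = "current (uA)",
                 ylab = "peak-to-peak amplitude", ...)
  if (!is.null(x$regression_range) && !is.na(x$slope)) {
    rng <- seq(x$regression_range[1L], x$regression_range[2L])
    graphics::abline(x$intercept, x$slope, col = 2)
    graphics::points(x$points$current_uA[rng], x$points$p2p[rng], pch = 16)
  }
  invisible(x)
}

#' Normalize slopes to the per-animal per-channel maximum
#'
#' Divides each slope by the maximum over stimulation sites (for one animal
#' and one channel) and expresses the result in percent, so the best site
#' scores 100. Negative slopes are clamped to 0 before normalization. An
#' all-zero vector maps to all zeros with attribute `degenerate = TRUE`.
#'
#' @param slopes Numeric vector of fitted slopes across sites; `NA`s are
#'   propagated and ignored when locating the maximum.
#' @return Numeric vector of percentages in `[0, 100]`, with a logical
#'   `degenerate` attribute.
#' @examples
#' normalize_slopes(c(2, 4, 1)) # 50 100 25
#' @export
normalize_slopes <- function(slopes) {
  if (all(is.na(slopes)))
    stop_invalid("at least one finite slope is required")
  x <- pmax(slopes, 0)
  m <- max(x, na.rm = TRUE)
  if (m == 0) {
    out <- ifelse(is.na(x), NA_real_, 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- 100 * x / m
  attr(out, "degenerate") <- FALSE
  out
}

#' Fitted slopes for every (site, channel) of one session
#'
#' Convenience wrapper running [build_recruitment_curve()] and [fit_slope()]
#' over an [extract_evoked()] table.
#'
#' @param evoked An [extract_evoked()] data frame (single animal).
#' @return Data frame with `site_id`, `group`, `channel`, `slope`,
#'   `intercept`, `degenerate`.
#' @export
recruitment_slopes <- function(evoked) {
  combos <- unique(evoked[, c("site_id", "group", "channel")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- evoked[evoked$site_id == combos$site_id[i] &
                    evoked$channel == combos$channel[i], ]
    fit <- fit_slope(build_recruitment_curve(sub))
    data.frame(site_id = combos$site_id[i], group = combos$group[i],
               channel = combos$channel[i], slope = fit$slope,
               intercept = fit$intercept, degenerate = fit$degenerate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble the cross-animal segment map
#'
#' Normalizes slopes per animal and channel across sites
#' ([normalize_slopes()]), averages the normalized percentages across animals
#' into a sites x channels map (mean and SE per cell; sites missing in an
#' animal are treated as absent), and aggregates sites into rostral/caudal
#' group scores per animal (by default the maximum over the animal's sites in
#' the group — the region's best recruitment; `"mean"` is available), with a
#' cross-animal mean +/- SE summary per (group, channel) for both normalized
#' and absolute slopes.
#'
#' @param slopes Data frame with columns `animal`, `site_id`, `group`,
#'   `channel`, `slope` (rows from [recruitment_slopes()], one set per
#'   animal).
#' @param group_rule `"max"` (default) or `"mean"`: per-animal aggregation of
#'   site scores into a group score.
#' @return An object of class `segment_map`: `$mean` and `$se` (sites x
#'   channels matrices of normalized percentages), `$slopes` (the input with
#'   a `norm_pct` column added), `$group_scores` (per animal x group x
#'   channel), `$group_stats` (mean/SE/n per group x channel).
#' @export
build_segment_map <- function(slopes, group_rule = c("max", "mean")) {
  group_rule <- match.arg(group_rule)
  if (is.null(slopes) || nrow(slopes) == 0L)
    stop_invalid("empty selection: no animals/slopes provided")
  if (!all(c("animal", "site_id", "group", "channel", "slope") %in%
             names(slopes)))
    stop_invalid("`slopes` must have animal, site_id, group, channel, slope")

  slopes$norm_pct <- NA_real_
  for (an in unique(slopes$animal)) {
    for (ch in unique(slopes$channel)) {
      sel <- slopes$animal == an & slopes$channel == ch
      if (!any(sel)) next
      slopes$norm_pct[sel] <- as.numeric(normalize_slopes(slopes$slope[sel]))
    }
  }

  site_levels <- unique(slopes$site_id)
  ch_levels <- unique(slopes$channel)
  cell <- function(fun) {
    m <- matrix(NA_real_, length(site_levels), length(ch_levels),
                dimnames = list(site_levels, ch_levels))
    for (s in site_levels) for (ch in ch_levels) {
      v <- slopes$norm_pct[slopes$site_id == s & slopes$channel == ch]
      v <- v[!is.na(v)]
      if (length(v)) m[s, ch] <- fun(v)
    }
    m
  }
  mean_mat <- cell(mean)
  se_mat <- cell(function(v) mean_se(v)$se)

  agg <- if (group_rule == "max") {
    function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  } else {
    function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  combos <- unique(slopes[, c("animal", "group", "channel")])
  group_scores <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sel <- slopes$animal == combos$animal[i] &
      slopes$group == combos$group[i] & slopes$channel == combos$channel[i]
    data.frame(animal = combos$animal[i], group = combos$group[i],
               channel = combos$channel[i],
               norm_score = agg(slopes$norm_pct[sel]),
               abs_score = agg(pmax(slopes$slope[sel], 0)),
               stringsAsFactors = FALSE)
  }))

  gc_combos <- unique(group_scores[, c("group", "channel")])
  group_stats <- do.call(rbind, lapply(seq_len(nrow(gc_combos)), function(i) {
    sel <- group_scores$group == gc_combos$group[i] &
      group_scores$channel == gc_combos$channel[i]
    v <- group_scores$norm_score[sel]
    v <- v[!is.na(v)]
    ms <- mean_se(v)
    data.frame(group = gc_combos$group[i], channel = gc_combos$channel[i],
               mean_norm_pct = ms$mean, se_norm_pct = ms$se, n = ms$n,
               stringsAsFactors = FALSE)
  }))

  structure(
    list(mean = mean_mat, se = se_mat, slopes = slopes,
         group_scores = group_scores, group_stats = group_stats,
         group_rule = group_rule),
    class = "segment_map")
}

#' @export
print.segment_map <- function(x, digits = 4, ...) {
  cat(sprintf("<segment_map> %d sites x %d channels, %d animal(s), group rule '%s'\n",
              nrow(x$mean), ncol(x$mean),
              length(unique(x$slopes$animal)), x$group_rule))
  cat("mean normalized slope (%):\n")
  print(round(x$mean, digits))
  invisible(x)
}

#' @export
plot.segment_map <- function(x, ...) {
  m <- x$mean
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "",
                  zlim = c(0, 100), ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m))
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)), las = 1)
  graphics::box()
  invisible(x)
}
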