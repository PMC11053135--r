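# Internal numeric helpers shared across modules.

# Indices of strict local extrema of x, ties broken toward the earlier
# sample: a plateau counts only at its first sample (rising on the left,
# not rising on the right).
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  is_max <- x[i - 1L] < x[i] & x[i] >= x[i + 1L]
  is_min <- x[i - 1L] > x[i] & x[i] <= x[i + 1L]
  i[is_max | is_min]
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[x[i - 1L] < x[i] & x[i] >= x[i + 1L]]
}

local_minima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[x[i - 1L] > x[i] & x[i] <= x[i + 1L]]
}

# Centered moving average with shrinking windows at the edges, so the
# output has the same length and no NA padding.
moving_average <- function(x, width) {
  width <- as.integer(width)
  if (width <= 1L) return(x)
  n <- length(x)
  half <- width %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# sd() that returns 0 instead of NA for fewer than two samples.
sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

stop_invalid <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
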