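# Independent brute-force oracles for the exact tests: they literally
# enumerate every sign assignment / labeling, so they share no code with the
# distribution-counting implementations they check.

brute_wilcoxon <- function(x, y = NULL, alternative = "two.sided") {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))
  Ws <- as.vector(signs %*% r)
  pg <- mean(Ws >= W - 1e-9)
  pl <- mean(Ws <= W + 1e-9)
  switch(alternative,
         greater = pg, less = pl,
         two.sided = min(1, 2 * min(pg, pl)))
}

brute_mannwhitney <- function(x, y, alternative = "two.sided") {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  R1 <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  Rs <- colSums(matrix(r[combos], nrow = n1))
  pg <- mean(Rs >= R1 - 1e-9)
  pl <- mean(Rs <= R1 + 1e-9)
  switch(alternative,
         greater = pg, less = pl,
         two.sided = min(1, 2 * min(pg, pl)))
}

# Small fixture builders used across test files -------------------------------

test_protocol <- function(...) {
  defaults <- list(frequency = 1, current_start = 30, current_stop = 60,
                   current_step = 10, pulses_per_current = 2)
  do.call(stim_protocol, utils::modifyList(defaults, list(...)))
}

# Noise- and jitter-free copies of the preset channels, for exactness checks.
quiet_channels <- function(channels = preset_feline_lut()$channels) {
  lapply(channels, function(cm) {
    cm$noise_sd <- 0
    cm$latency_jitter_sd_ms <- 0
    cm
  })
}

# Round half away from zero (the convention used for printed p-values;
# base round() rounds half to even, turning 0.03125 into 0.0312).
round_half_up <- function(x, digits) {
  floor(x * 10^digits + 0.5) / 10^digits
}

# Bundled reference table of per-cat percent-of-background values.
burst_pairs <- function(channel) {
  bp <- load_burst_percent()
  bp[bp$channel == channel, ]
}
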