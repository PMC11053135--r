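preset <- preset_feline_lut()

# A short configuration for hand-built epochs sampled at 1 kHz.
short_cfg <- epoching_config(pre_ms = 10, post_ms = 40, blank_ms = 2,
                             baseline_ms = 10, peak_window_ms = 5)

# Builds a single-sweep trace with a hand-chosen epoch shape: 20 ms of
# baseline, the pulse at sample 21, then `response` (sampled at 1 kHz).
hand_epoch <- function(response, cfg = short_cfg) {
  trace <- c(rep(0, 20), response, rep(0, 60))
  epoch_and_average(trace, 20 / 1000, 1000, cfg)
}

test_that("averaging identical sweeps reproduces a single sweep", {
  tpl <- waveform_template("fast", 20, 4, 1000)
  sweep <- c(rep(0, 30), tpl, rep(0, 50))
  trace <- rep(sweep, 10)
  events <- (seq_len(10) - 1) * length(sweep) / 1000 + 0.030
  cfg <- epoching_config(pre_ms = 20, post_ms = 40, baseline_ms = 10)
  ep <- epoch_and_average(trace, events, 1000, cfg)
  single <- epoch_and_average(trace, events[1], 1000, cfg)
  expect_equal(ep$epoch, single$epoch)
  expect_equal(ep$n_sweeps, 10)
})

test_that("a pure zero trace gives a zero epoch with zero baseline SD", {
  ep <- epoch_and_average(rep(0, 2000), c(0.5, 1.0), 1000,
                          epoching_config(pre_ms = 50, post_ms = 100))
  expect_true(all(ep$epoch == 0))
  expect_equal(ep$baseline_sd, 0)
  expect_equal(ep$baseline_sd_sweep, 0)
  expect_true(is.na(measure_latency(ep)))
  expect_equal(measure_p2p(ep), 0)
})

test_that("epoching errors on empty selections and truncated windows", {
  expect_error(epoch_and_average(rep(0, 100), numeric(0), 1000,
                                 short_cfg), "empty selection")
  expect_error(epoch_and_average(rep(0, 30), 0.025, 1000, short_cfg),
               "truncation")
})

test_that("averaged-epoch baseline SD scales as sigma/sqrt(n)", {
  sigma <- 0.7
  n_sweeps <- 10
  sds <- vapply(seq_len(100), function(i) {
    set.seed(4000 + i)
    trace <- rnorm(n_sweeps * 1000, 0, sigma) # 1 s per sweep at 1 kHz
    events <- (seq_len(n_sweeps) - 1) + 0.5
    epoch_and_average(trace, events, 1000,
                      epoching_config(pre_ms = 50, post_ms = 100))$baseline_sd
  }, numeric(1))
  expect_equal(mean(sds), sigma / sqrt(n_sweeps), tolerance = 0.2)
})

test_that("latency and p2p on a biphasic epoch follow the first-peak rules", {
  # +6 peak at 10 ms, -4 trough at 20 ms
  resp <- c(0, 2, 4, 5, 5.8, 6, 5.8, 5, 3, 0, -2, -3.5, -4, -3.5, -2, 0)
  ep <- hand_epoch(resp)
  expect_equal(measure_latency(ep), 5) # peak is the 6th response sample
  expect_equal(measure_p2p(ep), 10) # 6 - (-4)
})

test_that("a monophasic lobe measures its deviation from baseline", {
  resp <- c(0, 1, 2.5, 4, 5, 4, 2.5, 1, 0)
  ep <- hand_epoch(resp)
  expect_equal(measure_p2p(ep), 5)
})

test_that("window-range p2p is the max-minus-min alternative", {
  resp <- c(0, 2, 4, 5, 5.8, 6, 5.8, 5, 3, 0, -2, -3.5, -4, -3.5, -2, 0)
  cfg <- epoching_config(pre_ms = 10, post_ms = 40, blank_ms = 2,
                         baseline_ms = 10, peak_window_ms = 5,
                         p2p_mode = "window_range")
  expect_equal(measure_p2p(hand_epoch(resp, cfg), cfg), 10)
})

test_that("latency is scale-invariant and p2p is 1-homogeneous", {
  ch <- quiet_channels(preset$channels["EUS"])
  s <- generate_session(test_protocol(current_start = 50, current_stop = 50,
                                      pulses_per_current = 3),
                        preset$sites[1], ch, seed = 6, sampling_rate = 2000)
  cfg <- epoching_config()
  t <- s$events$time_s
  ep1 <- epoch_and_average(s$channels$EUS, t, 2000, cfg)
  for (k in c(0.5, 3, 17)) {
    ep2 <- epoch_and_average(k * s$channels$EUS, t, 2000, cfg)
    expect_equal(measure_latency(ep2, cfg), measure_latency(ep1, cfg))
    expect_equal(measure_p2p(ep2, cfg), k * measure_p2p(ep1, cfg),
                 tolerance = 1e-12)
  }
})

test_that("noise-free sessions reproduce configured latencies and amplitudes", {
  ch <- quiet_channels(preset$channels)
  s <- generate_session(test_protocol(), preset$sites, ch, seed = 42,
                        sampling_rate = 20000)
  ev <- extract_evoked(s)
  expect_true(all(ev$present))
  m <- merge(ev, s$ground_truth, by = c("site_id", "channel"))
  expect_lt(max(abs(m$latency_ms.x - m$latency_ms.y)), 1000 / 20000 + 1e-9)
  truth <- aggregate(amplitude ~ site_id + channel + current_uA,
                     s$pulse_truth, mean)
  mm <- merge(ev, truth, by = c("site_id", "channel", "current_uA"))
  expect_equal(mm$p2p, mm$amplitude, tolerance = 1e-6)
})

test_that("a strong fast response is timed within half a millisecond in noise", {
  ch <- preset$channels["EUS"]
  ch$EUS$latency_jitter_sd_ms <- 0
  ch$EUS$noise_sd <- 1
  # peak height is amplitude / 2.35 for the fast shape: set the template peak
  # to 10 noise SDs
  ch$EUS$gain <- 10 * 2.35 / (50 - ch$EUS$threshold_uA)
  ch$EUS$latency_ms <- 7.4
  site <- list(site_profile("X1", "caudal", c(EUS = 1)))
  hits <- vapply(seq_len(100), function(i) {
    s <- generate_session(test_protocol(current_start = 50, current_stop = 50,
                                        pulses_per_current = 10),
                          site, ch, seed = 7000 + i,
                          sampling_rate = 10000)
    lat <- measure_latency(epoch_and_average(s$channels$EUS, s$events$time_s,
                                             10000, epoching_config()))
    !is.na(lat) && abs(lat - 7.4) <= 0.5
  }, logical(1))
  expect_gte(sum(hits), 95)
})

test_that("pure-noise channels are rarely flagged as responses (k = 3)", {
  present <- vapply(seq_len(100), function(i) {
    set.seed(9000 + i)
    trace <- rnorm(11 * 1000, 0, 0.3)
    events <- (seq_len(10) - 1) + 0.5
    ep <- epoch_and_average(trace, events, 1000, epoching_config())
    !is.na(measure_latency(ep))
  }, logical(1))
  expect_lte(sum(present), 5)
})

test_that("recovered group-mean latencies match the configured means", {
  proto <- test_protocol(current_start = 60, current_stop = 80,
                         current_step = 10, pulses_per_current = 10)
  lat <- list()
  for (a in 1:5) {
    s <- generate_session(proto, preset$sites, preset$channels,
                          seed = 300 + a, sampling_rate = 10000,
                          animal_id = paste0("a", a))
    ev <- extract_evoked(s)
    ev <- ev[ev$present & ev$current_uA == 80, ]
    lat[[a]] <- aggregate(latency_ms ~ group + channel, ev, mean)
  }
  lat <- do.call(rbind, lat)
  # the configured mean must lie inside the 95% CI of the recovered
  # cross-animal mean, up to one sample period of quantization slack
  check <- function(group, channel, expected) {
    v <- lat$latency_ms[lat$group == group & lat$channel == channel]
    se <- sd(v) / sqrt(length(v))
    slack <- qt(0.975, length(v) - 1) * se + 0.1
    expect_lt(abs(mean(v) - expected), slack + 1e-9,
              label = sprintf("%s %s latency |bias|", group, channel))
  }
  check("rostral", "Detr", 38.01)
  check("caudal", "EUS", 7.41)
  check("rostral", "EUS", 13.72)
})
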