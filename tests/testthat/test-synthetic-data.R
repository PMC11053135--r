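preset <- preset_feline_lut()

test_that("identical seeds yield bit-identical sessions", {
  s1 <- generate_session(test_protocol(), preset$sites[1:2],
                         preset$channels[c("Detr", "EUS")], seed = 11,
                         sampling_rate = 1000)
  s2 <- generate_session(test_protocol(), preset$sites[1:2],
                         preset$channels[c("Detr", "EUS")], seed = 11,
                         sampling_rate = 1000)
  expect_identical(s1$channels, s2$channels)
  expect_identical(s1$events, s2$events)
  s3 <- generate_session(test_protocol(), preset$sites[1:2],
                         preset$channels[c("Detr", "EUS")], seed = 12,
                         sampling_rate = 1000)
  expect_false(identical(s1$channels, s3$channels))
})

test_that("per-site substreams make earlier site blocks independent of later ones", {
  s12 <- generate_session(test_protocol(), preset$sites[1:2],
                          preset$channels["EUS"], seed = 5,
                          sampling_rate = 1000)
  s1 <- generate_session(test_protocol(), preset$sites[1],
                         preset$channels["EUS"], seed = 5,
                         sampling_rate = 1000)
  n <- length(s1$channels$EUS)
  expect_identical(s12$channels$EUS[seq_len(n)], s1$channels$EUS)
})

test_that("noise-free zero-gain traces are zero outside stimulus artifacts", {
  ch <- quiet_channels(preset$channels["EUS"])
  ch$EUS$gain <- 0
  s <- generate_session(test_protocol(), preset$sites[1], ch, seed = 2,
                        sampling_rate = 1000)
  x <- s$channels$EUS
  artifact_idx <- round(s$events$time_s * s$sampling_rate) + 1
  expect_true(all(x[artifact_idx] == 100))
  expect_true(all(x[-artifact_idx] == 0))
})

test_that("noise-free templates place the first peak at the configured latency", {
  ch <- quiet_channels(preset$channels["Detr"])
  s <- generate_session(test_protocol(current_start = 50, current_stop = 50,
                                      pulses_per_current = 1),
                        preset$sites[1], ch, seed = 1, sampling_rate = 20000)
  x <- s$channels$Detr
  i0 <- round(s$events$time_s[1] * 20000) + 1
  seg <- x[(i0 + 41):(i0 + 20000)] # skip the single-sample artifact region
  peak_offset_ms <- (which.max(seg) + 41 - 1) / 20000 * 1000
  expect_equal(peak_offset_ms, 38.01, tolerance = 0.05)
})

test_that("a latency below the template first-peak offset is rejected as acausal", {
  ch <- quiet_channels(preset$channels["Detr"])
  ch$Detr$latency_ms <- 5 # slow template rises for ~28 ms
  expect_error(
    generate_session(test_protocol(), preset$sites[1], ch, seed = 1,
                     sampling_rate = 1000),
    "before the pulse")
})

test_that("event tables follow the protocol ladder and are strictly increasing", {
  proto <- test_protocol(current_start = 10, current_stop = 30,
                         current_step = 10, pulses_per_current = 3)
  s <- generate_session(proto, preset$sites[1:2], preset$channels["EUS"],
                        seed = 7, sampling_rate = 1000)
  expect_equal(nrow(s$events), 2 * 3 * 3)
  expect_true(all(diff(s$events$time_s) > 0))
  per_site <- s$events[s$events$site_id == "T13", ]
  expect_equal(per_site$current_uA, rep(c(10, 20, 30), each = 3))
  expect_equal(diff(per_site$time_s), rep(1, 8)) # 1 Hz
})

test_that("ground truth records one row per site x channel with effective gains", {
  s <- generate_session(test_protocol(), preset$sites, preset$channels,
                        seed = 3, sampling_rate = 1000)
  gt <- s$ground_truth
  expect_equal(nrow(gt), length(preset$sites) * length(preset$channels))
  t13_detr <- gt[gt$site_id == "T13" & gt$channel == "Detr", ]
  expect_equal(t13_detr$gain, 0.05 * 1.0)
  l7_eus <- gt[gt$site_id == "L7" & gt$channel == "EUS", ]
  expect_equal(l7_eus$latency_ms, 7.41)
})

test_that("burst sessions are deterministic and have a noise-only background", {
  bproto <- stim_protocol(frequency = 5, current_start = 100,
                          current_stop = 100, pulses_per_current = 1,
                          train_duration_s = 2)
  ch <- quiet_channels(preset$channels[c("Detr", "CYST")])
  b1 <- generate_burst_session(bproto, preset$sites[1], ch, seed = 9,
                               bg_duration_s = 2, sampling_rate = 1000)
  b2 <- generate_burst_session(bproto, preset$sites[1], ch, seed = 9,
                               bg_duration_s = 2, sampling_rate = 1000)
  expect_identical(b1$channels, b2$channels)
  iv <- b1$intervals
  bg_idx <- seq(round(iv$bg_start_s * 1000) + 1, round(iv$bg_end_s * 1000))
  expect_true(all(b1$channels$Detr[bg_idx] == 0)) # noise-free background
  expect_equal(nrow(b1$events), 10) # 5 Hz x 2 s
  expect_true(all(b1$events$time_s >= iv$stim_start_s))
})

test_that("sessions validate their inputs", {
  expect_error(generate_session(test_protocol(), list(), preset$channels,
                                seed = 1), "site")
  expect_error(generate_session(test_protocol(), preset$sites[1],
                                preset$channels["Detr"]), "seed")
  bad_site <- site_profile("X1", "rostral", c(Detr = 1))
  expect_error(generate_session(test_protocol(), list(bad_site),
                                preset$channels[c("Detr", "EUS")], seed = 1),
               "multiplier")
  expect_error(stim_protocol(current_step = 0), "current_step")
  expect_error(stim_protocol(current_start = 100, current_stop = 50), "current_start")
  expect_error(channel_model("X", "fast", latency_ms = 10, saturation_uA = 5,
                             threshold_uA = 20), "saturation")
})
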