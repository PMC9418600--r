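test_that("segmentation divides exactly, truncates, and round-trips", {
  w <- waveform(seq_len(100000) * 1e-6, 1000)
  segs <- segment(w, 10)
  expect_length(segs, 10L)
  expect_true(all(vapply(segs, function(s) length(s$samples), 0L) == 10000L))

  w25 <- waveform(seq_len(25000) * 1e-6, 1000)
  segs25 <- segment(w25, 10)
  expect_length(segs25, 2L)
  expect_equal(unlist(lapply(segs25, `[[`, "samples")),
               w25$samples[1:20000])
  expect_error(segment(waveform(1:100, 1000), 10), "insufficient")
})

test_that("moving average is exact on constants and follows the Dirichlet gain", {
  wc <- waveform(rep(2.5, 5000), 1000)
  expect_equal(moving_average(wc)$samples, rep(2.5, 5000))

  t <- (0:59999) / 1000
  for (f in c(2, 5)) {
    x <- waveform(sin(2 * pi * f * t), 1000)
    y <- moving_average(x, 200)
    mid <- 5001:55000
    gain <- fitted_amplitude(y$samples[mid], f, 1000)
    expect_equal(gain, dirichlet_gain(f, 200, 1000), tolerance = 1e-3)
  }
  # frozen closed-form anchors: 0.757 at 2 Hz, null at 5 Hz
  expect_equal(dirichlet_gain(2, 200, 1000), 0.7568, tolerance = 1e-4)
  expect_lt(dirichlet_gain(5, 200, 1000), 1e-12)
  expect_error(moving_average(waveform(1:10, 1000), 11), "insufficient")
})

test_that("amplitude spectrum is calibrated, linear, and zero on silence", {
  wz <- waveform(rep(0, 8192), 1000)
  expect_true(all(amplitude_spectrum(wz)$amplitude == 0))

  t <- (0:8191) / 1000
  f0 <- 10 * 1000 / 4096          # bin-aligned tone
  w <- waveform(sin(2 * pi * f0 * t), 1000)
  s <- amplitude_spectrum(w)
  expect_equal(max(s$amplitude), 1, tolerance = 0.02)
  expect_equal(s$frequency[which.max(s$amplitude)], f0)
  expect_equal(s$frequency[2] - s$frequency[1], 1000 / 4096)

  # off-bin 2 Hz tone reads near 1 within Hamming scalloping loss
  w2 <- waveform(sin(2 * pi * 2 * t), 1000)
  s2 <- amplitude_spectrum(w2)
  expect_gt(max(s2$amplitude), 0.75)
  expect_lt(max(s2$amplitude), 1.05)

  # linearity
  s3 <- amplitude_spectrum(scale_waveform(w, 2))
  expect_equal(s3$amplitude, 2 * s$amplitude, tolerance = 1e-12)
  expect_error(amplitude_spectrum(waveform(1:100, 1000)), "insufficient")
})

test_that("band filtering keeps exactly the bins inside [low, high]", {
  w <- waveform(stats::rnorm(4096, sd = 1e-5), 1000)
  s <- amplitude_spectrum(w)
  b <- band_filter(s, 0.2, 4)
  k <- which(s$frequency >= 0.2 & s$frequency <= 4)
  expect_equal(b$frequency, s$frequency[k])
  expect_equal(b$amplitude, s$amplitude[k])
  # resolution 0.244 Hz puts bins 1..16 in band
  expect_length(b$frequency, 16L)
  expect_equal(b$frequency[1], 1000 / 4096)
  expect_equal(b$frequency[16], 16 * 1000 / 4096)
  # full-band filter is the identity
  full <- band_filter(s, 0, 500)
  expect_equal(full$amplitude, s$amplitude)
  expect_error(band_filter(s, 4, 0.2), "below")
  expect_error(band_filter(s, 0.05, 0.1), "empty band")
})

test_that("activity equals the brute-force trapezoid sum and scales linearly", {
  t <- (0:9999) / 1000
  w <- waveform(2e-4 * sin(2 * pi * 2 * t), 1000)
  b <- band_filter(amplitude_spectrum(w), 0.2, 4)
  a <- activity(b)
  # independent summation oracle over the printed bin values
  manual <- sum(diff(b$frequency) *
                (utils::head(b$amplitude, -1) + utils::tail(b$amplitude, -1)) / 2)
  expect_equal(as.numeric(a), manual)
  expect_gt(as.numeric(a), 0)
  # homogeneity of degree 1
  b2 <- b; b2$amplitude <- 3 * b$amplitude
  expect_equal(as.numeric(activity(b2)), 3 * as.numeric(a))
  # zero spectrum
  bz <- b; bz$amplitude <- 0 * b$amplitude
  expect_equal(as.numeric(activity(bz)), 0)
})

test_that("dominant peak takes the global argmax with low-frequency ties", {
  t <- (0:8191) / 1000
  w <- waveform(sin(2 * pi * 2 * t), 1000)
  b <- band_filter(amplitude_spectrum(w), 0.2, 4)
  expect_within_bin(dominant_peak(b), 2)
  # two tones: larger line wins
  w2 <- waveform(sin(2 * pi * 1 * t) + 2 * sin(2 * pi * 3 * t), 1000)
  b2 <- band_filter(amplitude_spectrum(w2), 0.2, 4)
  expect_within_bin(dominant_peak(b2), 3)
  # exact tie breaks toward the lower frequency
  b3 <- b2; b3$amplitude <- rep(1, length(b3$amplitude))
  expect_equal(dominant_peak(b3), b3$frequency[1])
})

test_that("end-to-end activity is linear in the input amplitude", {
  w <- generate_recording(quick_config(seed = 9), larva_motion_spec(),
                          quiet_noise())
  a1 <- as.numeric(analyze_recording(w)$activity)
  a3 <- as.numeric(analyze_recording(scale_waveform(w, 3))$activity)
  expect_equal(a3, 3 * a1, tolerance = 1e-10)
})

test_that("active recordings separate from controls by more than 5x activity", {
  for (sd in 1:2) {
    cfg <- recording_config(1000, 60, sd)
    act <- analyze_recording(generate_recording(cfg, larva_motion_spec(),
                                                noise_model()))
    ctl <- analyze_recording(generate_recording(
      cfg, larva_motion_spec(active_fraction = 0), noise_model()))
    expect_gt(as.numeric(act$activity), 5 * as.numeric(ctl$activity))
  }
})

test_that("activity grows with the number of active larvae (seed-averaged)", {
  afs <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
  act <- rowMeans(vapply(1:6, function(sd) {
    vapply(afs, function(af) {
      w <- generate_recording(recording_config(1000, 60, sd),
                              larva_motion_spec(active_fraction = af),
                              noise_model())
      as.numeric(analyze_recording(w)$activity)
    }, 0)
  }, numeric(length(afs))))
  expect_true(all(diff(act) > 0))
})

test_that("driven-frequency recovery succeeds in at least 95% of 100 seeds", {
  hits <- vapply(1:100, function(sd) {
    w <- generate_driven_recording(recording_config(1000, 20, sd), 3,
                                   amplitude = 1e-4, noise = noise_model())
    abs(analyze_recording(w)$peak_frequency - 3) <= default_bin
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
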