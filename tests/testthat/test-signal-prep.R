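test_that("min-max normalisation maps examples and degenerate input correctly", {
  expect_equal(minmax_normalize(c(0, 5, 10)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(-1, 0, 3)), c(0, 0.25, 1))
  expect_equal(minmax_normalize(rep(3.7, 8)), rep(0, 8))
  expect_error(minmax_normalize(numeric(0)), "empty")
})

test_that("min-max normalisation is invariant to positive affine transforms", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(50)
    a <- runif(1, 0.1, 10); b <- rnorm(1, 0, 5)
    expect_equal(minmax_normalize(a * x + b), minmax_normalize(x),
                 tolerance = 1e-9)
  }
})

test_that("filters preserve length and rate, and are linear on zero input", {
  fs <- 496
  z <- channel_signal("z", rep(0, 1000), fs)
  for (fam in list(filter_spec("notch", c(59, 61)),
                   filter_spec("fir-bandpass", c(1.5, 150)),
                   filter_spec("butterworth-lowpass", 4),
                   filter_spec("gaussian"))) {
    out <- apply_filter(z, fam)
    expect_equal(length(out$samples), 1000)
    expect_equal(out$fs, fs)
    expect_equal(out$samples, rep(0, 1000))
  }
})

test_that("notch and band-pass meet their pass/stop contracts (FFT oracle)", {
  fs <- 496
  t <- seq(0, 4, by = 1 / fs)
  hum <- channel_signal("x", sin(2 * pi * 60 * t), fs)
  notched <- apply_filter(hum, filter_spec("notch", c(59, 61)))
  expect_lt(rms(notched$samples) / rms(hum$samples), 0.05)
  expect_lt(band_power(notched$samples, fs, 60) / band_power(hum$samples, fs, 60),
            0.01)

  tone <- channel_signal("x", sin(2 * pi * 10 * t), fs)
  passed <- apply_filter(tone, filter_spec("fir-bandpass", c(1.5, 150)))
  expect_lt(abs(rms(passed$samples) / rms(tone$samples) - 1), 0.10)
})

test_that("re-filtering a passband tone with the same spec changes RMS < 1%", {
  fs <- 496
  t <- seq(0, 4, by = 1 / fs)
  tone <- channel_signal("x", sin(2 * pi * 20 * t), fs)
  spec <- filter_spec("fir-bandpass", c(1.5, 150))
  once <- apply_filter(tone, spec)
  twice <- apply_filter(once, spec)
  expect_lt(abs(rms(twice$samples) / rms(once$samples) - 1), 0.01)
})

test_that("invalid filter specs are rejected", {
  expect_error(apply_filter(channel_signal("x", numeric(0), 100),
                            filter_spec("notch", c(59, 61))), "empty")
  # both notch edges above 0.45*fs: the band degenerates
  lowfs <- channel_signal("x", rnorm(500), 50)
  expect_error(suppressWarnings(
    apply_filter(lowfs, filter_spec("notch", c(59, 61)))), "degenerates")
  expect_error(filter_spec("notch", c(61, 59)), "increasing")
  expect_error(filter_spec("butterworth-lowpass", 4, order = 0), "order")
})

test_that("ECG cleaning removes drift and mains hum but keeps the pulse", {
  fs <- 496
  t <- seq(0, 20, by = 1 / fs)
  pulse <- rep(0, length(t)); pulse[seq(1, length(t), by = fs / 2)] <- 1
  raw <- pulse + 0.5 * sin(2 * pi * 0.2 * t) + 0.3 * sin(2 * pi * 60 * t)
  cleaned <- clean_channel(channel_signal("ecg", raw, fs), "ecg")
  expect_equal(length(cleaned$samples), length(raw))
  expect_true(all(cleaned$samples >= 0 & cleaned$samples <= 1))
  # band power relative to the 2 Hz pulse fundamental, before vs after
  expect_lt(rel_band_change_db(raw, cleaned$samples, fs, f = 0.2, f_ref = 2), -20)
  expect_lt(rel_band_change_db(raw, cleaned$samples, fs, f = 60, f_ref = 2), -20)
})

test_that("RESP cleaning attenuates out-of-band noise >= 20 dB", {
  fs <- 31
  t <- seq(0, 60, by = 1 / fs)
  raw <- sin(2 * pi * 0.25 * t) + 0.5 * sin(2 * pi * 5 * t)
  cleaned <- clean_channel(channel_signal("resp", raw, fs), "resp")
  expect_lt(rel_band_change_db(raw, cleaned$samples, fs, f = 5, f_ref = 0.25), -20)
})

test_that("constant GSR scales to all ones; EMG high edge clips with a warning", {
  g <- clean_channel(channel_signal("gsr", rep(2.5, 300), 31), "gsr")
  expect_equal(g$samples, rep(1, 300), tolerance = 1e-9)
  expect_warning(clean_channel(channel_signal("emg", rnorm(2000), 495), "emg"),
                 "clipped")
})

test_that("cleaning errors name the failing stage and reject unknown kinds", {
  expect_error(suppressWarnings(
    clean_channel(channel_signal("x", rnorm(100), 31), "ecg")),
    "stage 'notch'")
  expect_error(clean_channel(channel_signal("x", rnorm(100), 31), "sweat"))
})

test_that("QRS-band output emphasises 5-15 Hz", {
  fs <- 496
  t <- seq(0, 4, by = 1 / fs)
  raw <- sin(2 * pi * 10 * t) + sin(2 * pi * 40 * t)
  out <- ecg_qrs_band(channel_signal("ecg", raw, fs))
  expect_lt(rel_band_change_db(raw, out$samples, fs, f = 40, f_ref = 10), -20)
})

test_that("segmentation window counts match the sliding-window arithmetic", {
  ann <- phase_annotation(0, 100, "rest", "three")
  rec <- multi_channel_recording(
    list(hr = channel_signal("hr", rnorm(800, 70), 8)), ann)
  s0 <- segment_record(rec, window_s = 10, overlap = 0, common_fs = 8)
  expect_equal(n_windows(s0), 10)
  expect_true(all(s0$labels == "low"))
  s5 <- segment_record(rec, window_s = 10, overlap = 0.5, common_fs = 8)
  expect_equal(n_windows(s5), 19)
})

test_that("window count equals floor((N-W)/S)+1 against brute-force enumeration", {
  set.seed(5)
  for (i in 1:12) {
    n_s <- sample(40:200, 1)            # seconds of recording at 4 Hz
    w_s <- sample(5:20, 1)
    ov <- sample(c(0, 0.25, 0.5, 0.75), 1)
    ann <- phase_annotation(0, n_s, "city", "three")
    rec <- multi_channel_recording(
      list(x = channel_signal("x", rnorm(n_s * 4), 4)), ann)
    got <- n_windows(segment_record(rec, w_s, ov, common_fs = 4))
    N <- n_s * 4; W <- round(w_s * 4); S <- max(1, round(W * (1 - ov)))
    # brute-force enumeration of valid start positions
    starts <- 0L; k <- 0L
    repeat {
      if (k * S + W > N) break
      k <- k + 1L
    }
    expect_equal(got, k)
  }
})

test_that("windows straddling a phase boundary take the majority label", {
  ann <- phase_annotation(c(0, 30), c(30, 60), c("rest", "city"), "three")
  rec <- multi_channel_recording(
    list(hr = channel_signal("hr", rnorm(480, 70), 8),
         gsr = channel_signal("gsr", rnorm(480, 2), 8)), ann)
  s <- segment_record(rec, window_s = 10, overlap = 0, common_fs = 8)
  expect_equal(as.character(s$labels), c(rep("low", 3), rep("high", 3)))
  # permuting channel order never changes labels
  rec2 <- multi_channel_recording(rev(rec$channels), ann)
  s2 <- segment_record(rec2, window_s = 10, overlap = 0, common_fs = 8)
  expect_equal(s2$labels, s$labels)
})

test_that("two-level scheme maps rest to relaxed and driving to stressed", {
  ann <- phase_annotation(c(0, 30, 60), c(30, 60, 90),
                          c("rest", "highway", "city"), "two")
  rec <- multi_channel_recording(
    list(hr = channel_signal("hr", rnorm(720, 70), 8)), ann)
  s <- segment_record(rec, window_s = 10, overlap = 0, common_fs = 8)
  expect_equal(as.character(s$labels),
               c(rep("relaxed", 3), rep("stressed", 6)))
})

test_that("degenerate segmentations are rejected", {
  ann <- phase_annotation(0, 20, "rest", "three")
  rec <- multi_channel_recording(
    list(x = channel_signal("x", rnorm(160), 8)), ann)
  expect_error(segment_record(rec, window_s = 30, overlap = 0, common_fs = 8),
               "longer than recording")
  expect_error(phase_annotation(numeric(0), numeric(0), character(0)), "empty")
  expect_error(segment_record(rec, window_s = 10, overlap = 1), "overlap")
})

test_that("channels at different rates are resampled onto a common grid", {
  ann <- phase_annotation(0, 50, "rest", "three")
  rec <- multi_channel_recording(
    list(slow = channel_signal("slow", rnorm(200, 1), 4),
         fast = channel_signal("fast", rnorm(24800, 0), 496)), ann)
  s <- segment_record(rec, window_s = 10, overlap = 0, common_fs = 8)
  expect_equal(dim(s$x)[2:3], c(80L, 2L))
  expect_equal(s$channels, c("slow", "fast"))
})
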