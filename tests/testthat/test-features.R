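# Kinematic feature definitions and invariances.

test_that("sinusoid features match closed form", {
  # 3 Hz, 36 deg peak-to-valley, 30 FPS: amplitude 36, cycle 1/3 s, rate 3,
  # mean speed 36 * 3 = 108 deg/s, opening speed 216 deg/s
  sig <- lowpass(make_sinusoid(freq = 3, half_amp = 18, duration = 10))
  fv <- extract_features(sig, segment_cycles(sig))
  expect_equal(fv$mean_amplitude, 36, tolerance = 0.05)
  expect_equal(fv$mean_cycle_duration, 1 / 3, tolerance = 0.05)
  expect_equal(fv$rate, 3, tolerance = 0.05)
  expect_equal(fv$mean_speed, 108, tolerance = 0.05)
  expect_equal(fv$mean_opening_speed, 216, tolerance = 0.05)
  expect_equal(fv$mean_closing_speed, 216, tolerance = 0.05)
  for (f in grep("^cv_", names(fv), value = TRUE)) {
    expect_lt(fv[[f]], 0.05)
  }
  expect_equal(fv$amplitude_decay, 1, tolerance = 0.02)
})

test_that("amplitude decay and zero-variance cases follow the definitions", {
  # taps with amplitudes (40, 40, 32, 32) -> decay = 1.25
  fx <- make_manual_segmentation(peaks = c(45, 45, 37, 37),
                                 valleys = rep(5, 5))
  fv <- extract_features(fx$signal, fx$seg)
  expect_equal(fv$amplitude_decay, 1.25)
  # identical taps -> all CVs 0, range 0
  fx2 <- make_manual_segmentation(peaks = rep(41, 6), valleys = rep(5, 7))
  fv2 <- extract_features(fx2$signal, fx2$seg)
  for (f in grep("^cv_", names(fv2), value = TRUE)) expect_equal(fv2[[f]], 0)
  expect_equal(fv2$range_cycle_duration, 0)
})

test_that("error contracts: too few taps, non-positive amplitude", {
  fx <- make_manual_segmentation(peaks = c(45, 45, 37), valleys = rep(5, 4))
  expect_error(extract_features(fx$signal, fx$seg),
               class = "tk_insufficient_taps_error")
  bad <- make_manual_segmentation(peaks = c(45, 4, 37, 37), valleys = rep(5, 5))
  expect_error(extract_features(bad$signal, bad$seg),
               class = "tk_segmentation_integrity_error")
})

test_that("features are scale-equivariant in amplitude", {
  p <- tap_signal_params(n_taps = 20L, noise_sd = 0, seed = 9L)
  raw <- simulate_signal(p)
  base_sig <- lowpass(raw)
  base <- extract_features(base_sig, segment_cycles(base_sig))
  c0 <- 1.7
  scaled_raw <- displacement_signal(
    min(raw$values) + c0 * (raw$values - min(raw$values)), raw$frame_rate)
  ss <- lowpass(scaled_raw)
  sc <- extract_features(ss, segment_cycles(ss))
  for (f in c("mean_amplitude", "mean_speed", "mean_opening_speed",
              "mean_closing_speed")) {
    expect_equal(sc[[f]], c0 * base[[f]], tolerance = 1e-6, label = f)
  }
  for (f in c("cv_amplitude", "cv_speed", "mean_cycle_duration",
              "cv_cycle_duration", "rate", "amplitude_decay")) {
    expect_equal(sc[[f]], base[[f]], tolerance = 1e-6, label = f)
  }
})

test_that("features are stable under 30 vs 60 FPS sampling", {
  # seed-averaged: single-trial sub-movement durations are quantized to the
  # frame, so the invariant is about expectation, not one realization.
  # range_cycle_duration has a one-frame (0.033 s) resolution floor at
  # 30 FPS and is held to that absolute scale.
  diffs <- vapply(1:10, function(s) {
    p30 <- tap_signal_params(n_taps = 25L, noise_sd = 0, seed = s)
    p60 <- p30
    p60$frame_rate <- 60
    f30 <- {
      x <- lowpass(simulate_signal(p30))
      unlist(extract_features(x, segment_cycles(x)))
    }
    f60 <- {
      x <- lowpass(simulate_signal(p60))
      unlist(extract_features(x, segment_cycles(x)))
    }
    c(rel = abs(f60 / f30 - 1), abs = abs(f60 - f30))
  }, numeric(26))
  m <- rowMeans(diffs)
  for (f in FEATURE_NAMES) {
    if (f == "range_cycle_duration") {
      expect_lt(m[[paste0("abs.", f)]], 0.05, label = f)
    } else if (grepl("^cv_", f)) {
      expect_lt(m[[paste0("abs.", f)]], 0.02, label = f)
    } else {
      expect_lt(m[[paste0("rel.", f)]], 0.02, label = f)
    }
  }
})

test_that("generator targets are recovered (light sweep; full in acceptance)", {
  p <- severity_presets()[["0"]]$params
  p$n_taps <- 200L
  res <- vapply(1:10, function(s) {
    p$seed <- s
    sig <- lowpass(simulate_signal(p))
    unlist(extract_features(sig, segment_cycles(sig)))
  }, numeric(13))
  m <- rowMeans(res)
  expect_lt(abs(m["mean_amplitude"] / p$mean_peak_to_valley - 1), 0.05)
  expect_lt(abs(m["mean_cycle_duration"] / p$mean_cycle_duration - 1), 0.05)
  expect_lt(abs(m["cv_amplitude"] - p$amplitude_cv), 0.05)
  expect_lt(abs(m["cv_cycle_duration"] - p$cycle_duration_cv), 0.05)
  expect_lt(abs(m["amplitude_decay"] / p$decay_ratio - 1), 0.05)
})

test_that("batch_extract contains per-file failures", {
  sigs <- lapply(1:3, function(s)
    simulate_signal(tap_signal_params(n_taps = 8L, seed = s)))
  files <- vapply(sigs, function(s) {
    f <- tmp_path(".csv")
    write_landmarks(signal_to_landmarks(s), f)
    f
  }, character(1))
  tab <- batch_extract(files, frame_rate = 30)
  expect_equal(nrow(tab), 3L)
  expect_equal(nrow(attr(tab, "failures")), 0L)
  # add a monotone-ramp displacement CSV: 3 rows + 1 logged failure
  ramp <- tmp_path(".csv")
  write_signal_csv(displacement_signal(seq(5, 60, length.out = 200), 30), ramp)
  tab2 <- batch_extract(c(files, ramp), frame_rate = 30)
  expect_equal(nrow(tab2), 3L)
  fails <- attr(tab2, "failures")
  expect_equal(nrow(fails), 1L)
  expect_equal(fails$file, ramp)
  expect_error(batch_extract(character(0)), class = "tk_usage_error")
  unlink(c(files, ramp))
})

test_that("file route and in-memory route agree (pipeline self-consistency)", {
  sig <- simulate_signal(tap_signal_params(n_taps = 12L, seed = 31L))
  f <- tmp_path(".csv")
  write_landmarks(signal_to_landmarks(sig), f)
  via_file <- batch_extract(f, frame_rate = 30)
  fs <- lowpass(sig)
  direct <- extract_features(fs, segment_cycles(fs))
  for (nm in FEATURE_NAMES) {
    expect_equal(via_file[[nm]], direct[[nm]], tolerance = 1e-6, label = nm)
  }
  unlink(f)
})
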