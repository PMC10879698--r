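test_that("extract_trace averages each frame", {
  f1 <- micrograph(matrix(10, 8, 8), 1); f2 <- micrograph(matrix(20, 8, 8), 1)
  f3 <- micrograph(matrix(30, 8, 8), 1)
  tr <- extract_trace(list(f1, f2, f3), fps = 70)
  expect_equal(tr$values, c(10, 20, 30))

  half <- matrix(0, 8, 8); half[, 1:4] <- 100
  tr2 <- extract_trace(list(micrograph(half, 1), micrograph(half, 1)), 70)
  expect_equal(tr2$values, c(50, 50))

  expect_error(extract_trace(list(f1, micrograph(matrix(1, 4, 4), 1)), 70),
               "dimensions differ")
})

test_that("baseline load is the minimum frame value", {
  expect_equal(baseline_load(cm_trace(c(5, 9, 4, 8), 10)), 4)
  expect_equal(baseline_load(cm_trace(rep(7, 30), 10)), 7)
})

test_that("transient segmentation matches the closed-form pulse oracle", {
  # triangular pulse: rise 0 -> 100 over 10 frames, fall over 20
  v <- c(rep(0, 5), seq(0, 100, by = 10), seq(95, 0, by = -5), rep(0, 5))
  tr <- cm_trace(v, 70)
  ev <- detect_transients(tr)
  expect_equal(nrow(ev), 1)
  oracle <- single_pulse_oracle(v)
  expect_equal(ev$onset_idx, unname(oracle["onset"]))
  expect_equal(ev$peak_idx, unname(oracle["peak"]))
  expect_equal(ev$end_idx, unname(oracle["end"]))
  expect_equal(ev$amplitude, 100)

  # explicit closed-form indices: onset at the 10% sample, end at the
  # first sample at or below the 10% level on the descent
  expect_equal(v[ev$onset_idx], 10)
  expect_lte(v[ev$end_idx], 10 + 1e-9)
  expect_gte(v[ev$end_idx - 1], 10)
})

test_that("constant traces and flat segments yield no events", {
  expect_equal(nrow(detect_transients(cm_trace(rep(3, 200), 70))), 0)
})

test_that("two identical pulses give two events with identical shape", {
  pulse <- c(seq(0, 100, by = 10), seq(95, 0, by = -5))
  v <- c(rep(0, 10), pulse, rep(0, 30), pulse, rep(0, 10))
  ev <- detect_transients(cm_trace(v, 70))
  expect_equal(nrow(ev), 2)
  expect_equal(diff(ev$peak_idx), ev$peak_idx[2] - ev$peak_idx[1])
  expect_equal(ev$peak_idx - ev$onset_idx,
               rep(ev$peak_idx[1] - ev$onset_idx[1], 2))
  expect_equal(ev$end_idx - ev$peak_idx,
               rep(ev$end_idx[1] - ev$peak_idx[1], 2))
  expect_equal(ev$amplitude, rep(100, 2))
})

test_that("kinetics recover synthetic truth within a frame (noise-free)", {
  tt <- make_trace(noise_sigma = 0, seed = 1)
  k <- kinetics(tt$trace)
  expect_equal(k$n_events, tt$truth$n_events)
  expect_equal(k$frequency_hz, 1.0, tolerance = 1e-8)
  expect_lte(abs(k$time_to_peak_s - tt$truth$time_to_peak_s), 1 / 70)
  expect_lte(abs(k$time_to_decay_s - tt$truth$time_to_decay_s), 1.5 / 70)
  expect_equal(k$baseline_load_au, tt$truth$baseline_load_au,
               tolerance = 1e-6)
})

test_that("amplitude scaling scales amplitudes and velocities, not times", {
  tt <- make_trace(noise_sigma = 0, seed = 2)
  k1 <- kinetics(tt$trace)
  k2 <- kinetics(cm_trace(3 * tt$trace$values, 70))
  expect_equal(k2$amplitude_au, 3 * k1$amplitude_au)
  expect_equal(k2$baseline_load_au, 3 * k1$baseline_load_au)
  expect_equal(k2$contraction_velocity, 3 * k1$contraction_velocity)
  expect_equal(k2$relaxation_velocity, 3 * k1$relaxation_velocity)
  expect_equal(k2$frequency_hz, k1$frequency_hz)
  expect_equal(k2$time_to_peak_s, k1$time_to_peak_s)
  expect_equal(k2$time_to_decay_s, k1$time_to_decay_s)
})

test_that("halving fps halves frequency and velocities exactly", {
  tt <- make_trace(noise_sigma = 0, seed = 3)
  k1 <- kinetics(tt$trace)
  k2 <- kinetics(cm_trace(tt$trace$values, 35))
  expect_equal(k2$frequency_hz, k1$frequency_hz / 2)
  expect_equal(k2$contraction_velocity, k1$contraction_velocity / 2)
  expect_equal(k2$relaxation_velocity, k1$relaxation_velocity / 2)
  expect_equal(k2$time_to_peak_s, 2 * k1$time_to_peak_s)
})

test_that("kinetics handle event-poor traces gracefully", {
  pulse <- c(rep(0, 50), seq(0, 100, by = 10), seq(95, 0, by = -5), rep(0, 50))
  k <- kinetics(cm_trace(pulse, 70))
  expect_equal(k$n_events, 1L)
  expect_true(is.na(k$frequency_hz))
  expect_false(is.na(k$time_to_peak_s))

  k0 <- kinetics(cm_trace(rep(5, 200), 70))
  expect_equal(k0$n_events, 0L)
  expect_true(is.na(k0$amplitude_au))
})

test_that("kinetics normalization is a ratio of ratios", {
  m <- kinetics(make_trace(noise_sigma = 0, seed = 4)$trace)
  out <- normalize_kinetics(m, m)
  expect_true(all(abs(unlist(out) - 100) < 1e-9))

  m_half <- m; m_half$amplitude_au <- m$amplitude_au / 2
  out2 <- normalize_kinetics(m_half, m)
  expect_equal(out2$amplitude_au, 50)

  # drug at 80% of t0, control at 80% of t0 -> control-normalized 100%
  m80 <- m
  for (cl in names(m)[1:7]) m80[[cl]] <- m[[cl]] * 0.8
  out3 <- normalize_kinetics(m80, m, m80, m)
  expect_true(all(abs(unlist(out3) - 100) < 1e-9))
})

test_that("parameter recovery holds across seeds with frame-mean noise", {
  # noise level equivalent to a 64x64-pixel video with per-pixel sigma of
  # 2% of the beat amplitude, averaged per frame
  for (s in 1:5) {
    tt <- make_trace(noise_sigma = 2 / 64, seed = s)
    k <- kinetics(tt$trace)
    expect_equal(k$frequency_hz, 1.0, tolerance = 0.1)
    expect_lte(abs(k$time_to_peak_s - tt$truth$time_to_peak_s), 2 / 70)
    expect_lte(abs(k$time_to_decay_s - tt$truth$time_to_decay_s), 2 / 70)
  }
})
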