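test_that("quantizer rounds to the DAC grid with LSB/sqrt(12) error", {
  lsb <- 3.1e-12
  expect_identical(quantize(0, lsb), 0)
  expect_equal(quantize(1.55 * lsb, lsb), 2 * lsb)
  expect_equal(quantize(-1.55 * lsb, lsb), -2 * lsb) # half away from zero
  expect_equal(quantize(1.4 * lsb, lsb), lsb)
  # 16-bit range clip
  expect_equal(quantize(1e-6, lsb), 2^15 * lsb)
  expect_equal(quantize(-1e-6, lsb), -(2^15) * lsb)
  # RMS error over many steps approaches the uniform-quantizer closed form
  set.seed(1)
  v <- stats::runif(1e6, -1e-9, 1e-9)
  rms <- sqrt(mean((quantize(v, lsb) - v)^2))
  expect_equal(rms, lsb / sqrt(12), tolerance = 0.02)
})

test_that("OPM forward model applies gain, noise-free projection and clipping", {
  m <- opm_channel_model(white_noise_asd = 0)
  expect_identical(opm_forward(m, c(0, 0, 0), c(1, 0, 0))$y, 0)
  out <- opm_forward(m, c(2e-9, 0, 0), c(1, 0, 0))
  expect_equal(out$y, 1.5e-9)
  expect_true(out$saturated)
  m9 <- opm_channel_model(gain = 0.9, white_noise_asd = 0)
  expect_equal(opm_forward(m9, c(1e-9, 0, 0), c(1, 0, 0))$y, 0.9e-9)
  expect_error(opm_forward(m, c(0, 0, 0), c(1, 1, 0)), "unit norm")
})

test_that("controller converges to the quantization floor on a static field", {
  arr <- random_array(5, seed = 2)
  proj <- hfc_projector(arr, 1)
  opm <- opm_channel_model(white_noise_asd = 0)
  timing0 <- timing_model(
    base_latency_ms = 0, jitter_max_ms = 0,
    overrun_extra_ms = 0, overrun_prob = 0
  )
  # zero input, zero state -> zero-valued commands
  st <- list(prev_feedback = rep(0, 10), filter = NULL)
  tick <- controller_tick(st, proj, timing0, rep(0, 10), now_s = 0.01, opm = opm)
  expect_true(all(vapply(tick$commands, function(cmd) all(cmd$values == 0), TRUE)))

  # static homogeneous field, filter bypassed, zero latency: two ticks in
  B <- c(0.8e-9, -0.3e-9, 0.4e-9)
  y_true <- drop(proj$N %*% B)
  fb <- rep(0, 10)
  for (k in 1:2) {
    chunk_mean <- y_true - fb # noiseless, gain 1
    st <- list(prev_feedback = fb, filter = NULL)
    tick <- controller_tick(st, proj, timing0, chunk_mean,
      now_s = k * 0.01, opm = opm
    )
    for (cmd in tick$commands) fb[cmd$idx] <- cmd$values
  }
  expect_lt(max(abs(y_true - fb)), opm$lsb_z)
})

test_that("forced overruns delay every command by exactly base + extra", {
  arr <- random_array(4, seed = 3)
  proj <- hfc_projector(arr, 1)
  timing <- timing_model(
    base_latency_ms = 31, jitter_max_ms = 0,
    overrun_extra_ms = 15, overrun_prob = 1
  )
  st <- list(prev_feedback = rep(0, 8), filter = NULL)
  tick <- controller_tick(st, proj, timing, rep(1e-10, 8), now_s = 0.5)
  times <- vapply(tick$commands, function(cmd) cmd$time_s, 0)
  expect_equal(sort(times), 0.5 + (31 + 15) / 1000 + c(0, 5 / 1000))
})

test_that("without feedback a strong static field saturates the expected channels", {
  setup <- drift_test_setup(n_opms = 6, fs = 600, dur = 1)
  spec <- room_field_spec(
    homogeneous_offset = c(1.6e-9, 0.9e-9, 0.4e-9),
    gradient = matrix(0, 3, 3), drift = list(type = "none")
  )
  fld <- make_field(spec, duration = 1)
  cfg <- loop_config(
    sample_rate = 600, chunk_size = 6, feedback_on = FALSE,
    null_at_start = FALSE, opm = opm_channel_model(white_noise_asd = 0)
  )
  sim <- simulate_closed_loop(setup$array, fld, 1, config = cfg, seed = 1)
  proj_true <- drop(build_basis(setup$array, 1) %*% spec$homogeneous_offset)
  should_sat <- abs(proj_true) > 1.5e-9
  expect_true(any(should_sat) && !all(should_sat)) # the layout splits
  expect_equal(unname(rowMeans(sim$saturation_truth)), as.numeric(should_sat))
  expect_equal(
    unname(sim$recorded$data[should_sat, 1]),
    unname(1.5e-9 * sign(proj_true[should_sat]))
  )
})

test_that("simulation is bit-identical under a fixed seed", {
  setup <- drift_test_setup(
    n_opms = 4, fs = 600, dur = 3,
    drift = list(type = "random_walk", sd = 2e-10, cutoff_hz = 0.5, seed = 5)
  )
  s1 <- simulate_closed_loop(setup$array, setup$field, 3, config = setup$config(), seed = 7)
  s2 <- simulate_closed_loop(setup$array, setup$field, 3, config = setup$config(), seed = 7)
  expect_identical(s1$recorded$data, s2$recorded$data)
  expect_identical(s1$applied_feedback, s2$applied_feedback)
  expect_identical(s1$saturation_truth, s2$saturation_truth)
})

test_that("the loop is linear when noise, quantization and clipping are off", {
  opm_lin <- opm_channel_model(
    white_noise_asd = 0, quantize = FALSE,
    saturation_limit = Inf
  )
  arr <- example_scanner_cast_array(n_opms = 5)
  dur <- 4
  fs <- 600
  cfg <- loop_config(sample_rate = fs, chunk_size = 6, opm = opm_lin)
  spec <- room_field_spec(drift = list(
    type = "random_walk", sd = 2e-10, cutoff_hz = 0.5, seed = 3
  ))
  fld <- make_field(spec, duration = dur)
  zspec <- room_field_spec(
    homogeneous_offset = c(0, 0, 0), gradient = matrix(0, 3, 3),
    drift = list(type = "none")
  )
  zfld <- make_field(zspec, duration = dur)
  set.seed(11)
  neural <- matrix(stats::rnorm(10 * dur * fs, sd = 2e-13), 10, dur * fs)

  s_bg <- simulate_closed_loop(arr, fld, dur, config = cfg, seed = 1)
  s_ne <- simulate_closed_loop(arr, zfld, dur, neural = neural, config = cfg, seed = 1)
  s_both <- simulate_closed_loop(arr, fld, dur, neural = neural, config = cfg, seed = 1)
  expect_equal(s_both$recorded$data, s_bg$recorded$data + s_ne$recorded$data,
    tolerance = 1e-10
  )

  # feedback accounting: recorded + G * applied feedback reconstructs the
  # projected true field plus neural wherever nothing clips
  cfg2 <- loop_config(
    sample_rate = fs, chunk_size = 6, opm = opm_lin,
    null_at_start = FALSE
  )
  s3 <- simulate_closed_loop(arr, fld, dur, neural = neural, config = cfg2, seed = 2)
  lhs <- s3$recorded$data + s3$applied_feedback # gain = 1
  rhs <- s3$true_background + neural
  expect_equal(lhs, rhs, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("slow homogeneous drift is strongly rejected at the drift frequency", {
  arr <- example_scanner_cast_array(n_opms = 12, feedback_opms = 1:6)
  dur <- 200
  fs <- 600
  spec <- room_field_spec(
    homogeneous_offset = c(0, 0, 0), gradient = matrix(0, 3, 3),
    drift = list(
      type = "sine", freq_hz = 0.01, amplitude = 500e-12,
      direction = c(1, 1, 1) / sqrt(3)
    )
  )
  fld <- make_field(spec, duration = dur)
  cfg <- loop_config(sample_rate = fs, chunk_size = 6)
  sim <- simulate_closed_loop(arr, fld, dur, config = cfg, seed = 13)
  fbi <- feedback_channels(arr)
  off <- setdiff(seq_len(n_channels(arr)), fbi)
  p_on <- welch_psd(recording(sim$recorded$data[fbi, ], fs), segment_s = 100)
  p_off <- welch_psd(recording(sim$recorded$data[off, ], fs), segment_s = 100)
  msf <- median_shielding_factor(p_off, p_on)
  at_drift <- msf$msf_db[which.min(abs(msf$frequency - 0.01))]
  expect_gt(at_drift, 15)
})

test_that("feedback raises the white-noise floor of the corrected channels above 2 Hz", {
  # background drift below 0.5 Hz plus sensor white noise: above the drift
  # band the corrected channels carry the extra quantized-command noise, so
  # their spectrum sits strictly above the uncorrected channels'
  arr <- example_scanner_cast_array(n_opms = 12, feedback_opms = 1:6)
  dur <- 80
  fs <- 600
  spec <- room_field_spec(
    homogeneous_offset = c(0, 0, 0), gradient = matrix(0, 3, 3),
    drift = list(type = "random_walk", sd = 200e-12, cutoff_hz = 0.5, seed = 17)
  )
  fld <- make_field(spec, duration = dur)
  cfg <- loop_config(sample_rate = fs, chunk_size = 6)
  sim <- simulate_closed_loop(arr, fld, dur, config = cfg, seed = 19)
  fbi <- feedback_channels(arr)
  off <- setdiff(seq_len(n_channels(arr)), fbi)
  p_on <- welch_psd(recording(sim$recorded$data[fbi, ], fs), segment_s = 20)
  p_off <- welch_psd(recording(sim$recorded$data[off, ], fs), segment_s = 20)
  band <- p_on$frequencies >= 2 & p_on$frequencies <= 10
  med_on <- apply(p_on$asd[, band], 2, stats::median)
  med_off <- apply(p_off$asd[, band], 2, stats::median)
  expect_true(all(med_on > med_off))
})

test_that("trajectory gaps are rejected by the simulator", {
  setup <- drift_test_setup(n_opms = 3, fs = 600, dur = 2)
  traj <- make_walk(2, seed = 1) # may contain dropouts -> NA rows
  traj$x_m[5] <- NA
  expect_error(
    simulate_closed_loop(setup$array, setup$field, 2,
      trajectory = traj, config = setup$config()
    ),
    "gaps"
  )
})
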