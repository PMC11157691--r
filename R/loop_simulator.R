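#' OPM channel model for the loop simulator
#'
#' A simplified per-channel signal model: the sensor reports
#' `y = G * (residual_field . orientation + neural) + white noise`, hard
#' clipped at the saturation limit. The on-board coil DACs are 16-bit with
#' axis-specific least-significant-bit step sizes, and a fraction of the
#' field applied by a coil is picked up by the nearest neighbouring sensor
#' (cross-talk).
#'
#' @param gain unitless OPM gain (default 1). `gain_fn`, if supplied, is a
#'   function of the residual field magnitude returning a gain, for
#'   field-dependent gain studies.
#' @param saturation_limit hard clipping level in T (default 1.5e-9);
#'   scalar or per-channel vector.
#' @param white_noise_asd sensor noise amplitude spectral density,
#'   T/sqrt(Hz) (default 15e-15, typical of zero-field OPMs); the
#'   per-sample sd used in simulation is `asd * sqrt(fs / 2)`.
#' @param lsb_y,lsb_z DAC least-significant-bit field step for the radial
#'   (Y) and tangential (Z) coils, T (defaults 1.8e-12 and 3.1e-12).
#' @param crosstalk_coeff fraction of a coil's field seen by the nearest
#'   neighbouring OPM's same-axis channel (default 0.03).
#' @param gain_fn optional function(|field| in T) -> gain.
#' @param quantize logical; apply DAC quantization to commands (default
#'   TRUE; FALSE gives an ideal continuous coil driver, useful for
#'   linearity studies).
#' @return An object of class `opm_channel_model`.
#' @export
opm_channel_model <- function(gain = 1.0, saturation_limit = 1.5e-9,
                              white_noise_asd = 15e-15,
                              lsb_y = 1.8e-12, lsb_z = 3.1e-12,
                              crosstalk_coeff = 0.03, gain_fn = NULL,
                              quantize = TRUE) {
  stopifnot(all(saturation_limit > 0), lsb_y > 0, lsb_z > 0,
    crosstalk_coeff >= 0, crosstalk_coeff < 1)
  structure(
    list(
      gain = gain, saturation_limit = saturation_limit,
      white_noise_asd = white_noise_asd,
      lsb_y = lsb_y, lsb_z = lsb_z,
      crosstalk_coeff = crosstalk_coeff, gain_fn = gain_fn,
      quantize = quantize
    ),
    class = "opm_channel_model"
  )
}

#' Command timing model for the loop simulator
#'
#' Commands are computed once per 10 ms chunk; the radial (Y) coils are
#' updated first and the tangential (Z) coils after a 5 ms stagger, since
#' the serial link can address each axis only every 5 ms. The total lag
#' between field change and correction is about 41 ms: the 10 ms chunk
#' accumulation plus `base_latency_ms` of acquisition/processing/serial
#' delay, plus up to `jitter_max_ms` of uniform jitter, plus an extra
#' `overrun_extra_ms` with probability `overrun_prob` (a command arriving
#' before the previous one has been processed).
#'
#' @param update_interval_ms model update interval (chunk duration), ms.
#' @param axis_stagger_ms Y-to-Z command stagger, ms.
#' @param base_latency_ms deterministic lag from chunk end to command
#'   effect, ms (default 31, so chunk accumulation + base = 41 ms total).
#' @param jitter_max_ms uniform timing jitter upper bound, ms.
#' @param overrun_extra_ms extra delay when the serial link overruns, ms.
#' @param overrun_prob probability of an overrun per command.
#' @return An object of class `timing_model`.
#' @export
timing_model <- function(update_interval_ms = 10, axis_stagger_ms = 5,
                         base_latency_ms = 31, jitter_max_ms = 3,
                         overrun_extra_ms = 15, overrun_prob = 0.19) {
  stopifnot(
    update_interval_ms >= 0, axis_stagger_ms >= 0, base_latency_ms >= 0,
    jitter_max_ms >= 0, overrun_extra_ms >= 0,
    overrun_prob >= 0, overrun_prob <= 1
  )
  structure(
    list(
      update_interval_ms = update_interval_ms,
      axis_stagger_ms = axis_stagger_ms,
      base_latency_ms = base_latency_ms,
      jitter_max_ms = jitter_max_ms,
      overrun_extra_ms = overrun_extra_ms,
      overrun_prob = overrun_prob
    ),
    class = "timing_model"
  )
}

#' Full closed-loop configuration
#'
#' @param sample_rate OPM sampling rate, Hz (default 6000).
#' @param chunk_size samples per model update (default 60; chunk duration
#'   `chunk_size / sample_rate` should equal the timing model's update
#'   interval).
#' @param filter_cutoff_hz cutoff of the low-pass applied to the model
#'   output before quantization, Hz; `NULL` disables the filter. The
#'   filter runs at the chunk rate, where the output signal exists.
#' @param filter_input logical; additionally low-pass the chunk-mean input
#'   with the same cutoff (default FALSE; output filtering is the
#'   configuration used for the reported recordings).
#' @param opm an [opm_channel_model()].
#' @param timing a [timing_model()].
#' @param feedback_on master switch for the loop (default TRUE).
#' @param null_at_start logical; model the initial on-sensor field zeroing
#'   by subtracting each channel's t = 0 field (default TRUE).
#' @return An object of class `loop_config`.
#' @export
loop_config <- function(sample_rate = 6000, chunk_size = 60L,
                        filter_cutoff_hz = 1, filter_input = FALSE,
                        opm = opm_channel_model(), timing = timing_model(),
                        feedback_on = TRUE, null_at_start = TRUE) {
  stopifnot(sample_rate > 0, chunk_size >= 1)
  if (abs(chunk_size / sample_rate * 1000 - timing$update_interval_ms) > 1e-9) {
    warning("chunk duration does not equal the timing model's update interval")
  }
  structure(
    list(
      sample_rate = sample_rate, chunk_size = as.integer(chunk_size),
      filter_cutoff_hz = filter_cutoff_hz, filter_input = filter_input,
      opm = opm, timing = timing,
      feedback_on = feedback_on, null_at_start = null_at_start
    ),
    class = "loop_config"
  )
}

#' Quantize a field value to the coil DAC grid
#'
#' Rounds to the nearest integer multiple of the least-significant bit
#' (half-way cases away from zero) and clips to the 16-bit range
#' `±2^15 * lsb`. The quantization error is at most `lsb / 2` per value,
#' with RMS `lsb / sqrt(12)` for amplitudes exercising many steps.
#'
#' @param value numeric vector, T.
#' @param lsb least-significant-bit step, T (scalar or per-value).
#' @return Quantized values, T.
#' @examples
#' quantize(1.55 * 3.1e-12, 3.1e-12) / 3.1e-12 # 2
#' @export
quantize <- function(value, lsb) {
  stopifnot(all(lsb > 0))
  q <- sign(value) * floor(abs(value) / lsb + 0.5) * lsb
  pmin(pmax(q, -2^15 * lsb), 2^15 * lsb)
}

#' Forward model of a single OPM channel
#'
#' Reference implementation of the per-sample signal path:
#' `y = G * (residual_field . orientation + neural) + noise`, hard-clipped
#' at the saturation limit.
#'
#' @param model an [opm_channel_model()].
#' @param residual_field 3-vector, T (background minus feedback minus the
#'   initial nulling field at the sensor).
#' @param orientation unit 3-vector.
#' @param neural additive signal of interest, T (default 0).
#' @param noise_sd per-sample white noise sd, T (default 0 = noiseless).
#' @return List with `y` (recorded value, T) and `saturated` (logical).
#' @export
opm_forward <- function(model, residual_field, orientation, neural = 0,
                        noise_sd = 0) {
  stopifnot(inherits(model, "opm_channel_model"))
  if (abs(sum(orientation^2) - 1) > 1e-9) stop("orientation must be unit norm")
  proj <- sum(residual_field * orientation)
  g <- if (!is.null(model$gain_fn)) {
    model$gain_fn(sqrt(sum(residual_field^2)))
  } else {
    model$gain
  }
  y <- g * (proj + neural)
  if (noise_sd > 0) y <- y + stats::rnorm(1, 0, noise_sd)
  lim <- model$saturation_limit[1]
  sat <- abs(y) > lim
  list(y = pmin(pmax(y, -lim), lim), saturated = sat)
}

#' One controller update of the feedback loop
#'
#' Implements the per-chunk control law: the latest chunk-mean reading is
#' added to the previously applied feedback to estimate `u`, the field
#' each channel would see with no feedback; the model projection
#' `M pinv(N) u` gives the desired coil fields; these are low-pass
#' filtered (at the chunk rate), quantized to the DAC grid per axis, and
#' scheduled — Y-axis commands at `now + latency`, Z-axis commands a
#' stagger later. The latency is drawn as
#' `base + U(0, jitter) + overrun_extra * Bernoulli(overrun_prob)`.
#' `prev_feedback` is **not** updated here: the simulator updates it when
#' a command takes effect, since the controller tracks intended (not
#' cross-talk-corrupted) feedback.
#'
#' @param state list with `prev_feedback` (full-length per-channel intended
#'   coil field, T) and `filter` (a [design_lowpass()] cascade over the
#'   feedback channels, or `NULL`).
#' @param proj an [hfc_projector()].
#' @param timing a [timing_model()].
#' @param chunk_mean per-channel chunk average, T.
#' @param now_s time of the chunk end, s.
#' @param opm an [opm_channel_model()] (for the DAC step sizes).
#' @return List with `state` (updated filter state) and `commands`, a list
#'   of scheduled commands `list(time_s, idx, values)` with `idx` indexing
#'   the full channel order.
#' @export
controller_tick <- function(state, proj, timing, chunk_mean, now_s = 0,
                            opm = opm_channel_model()) {
  stopifnot(inherits(proj, "hfc_projector"))
  if (length(chunk_mean) != nrow(proj$N)) {
    stop("chunk_mean must have one value per channel")
  }
  u <- chunk_mean + state$prev_feedback
  desired <- drop(proj$feedback_matrix %*% u)
  if (!is.null(state$filter)) {
    st <- biquad_step(state$filter, desired)
    desired <- st$y
    state$filter <- st$filter
  }
  fb_axes <- proj$axes[proj$feedback_idx]
  lsb <- ifelse(fb_axes == "Y", opm$lsb_y, opm$lsb_z)
  qdes <- if (isTRUE(opm$quantize)) quantize(desired, lsb) else desired
  latency <- timing$base_latency_ms / 1000
  if (timing$jitter_max_ms > 0) {
    latency <- latency + stats::runif(1, 0, timing$jitter_max_ms / 1000)
  }
  if (timing$overrun_prob > 0 &&
    stats::runif(1) < timing$overrun_prob) {
    latency <- latency + timing$overrun_extra_ms / 1000
  }
  commands <- list()
  iy <- which(fb_axes == "Y")
  iz <- which(fb_axes == "Z")
  if (length(iy) > 0) {
    commands[[length(commands) + 1L]] <- list(
      time_s = now_s + latency,
      idx = proj$feedback_idx[iy], values = qdes[iy]
    )
  }
  if (length(iz) > 0) {
    commands[[length(commands) + 1L]] <- list(
      time_s = now_s + latency + timing$axis_stagger_ms / 1000,
      idx = proj$feedback_idx[iz], values = qdes[iz]
    )
  }
  list(state = state, commands = commands)
}

# Internal: cross-talk matrix. Feedback applied to channel j is also seen
# by the same-axis channel of the geometrically nearest other OPM.
crosstalk_matrix <- function(array, coeff) {
  n <- n_channels(array)
  C <- diag(n)
  if (coeff <= 0) return(C)
  ch <- array$channels
  pos <- channel_positions(array)
  for (j in seq_len(n)) {
    if (!ch$feedback[j]) next
    same_axis <- which(ch$axis == ch$axis[j] & seq_len(n) != j)
    # exclude the other channel of the same sensor (identical position)
    d <- sqrt(rowSums(sweep(pos[same_axis, , drop = FALSE], 2, pos[j, ])^2))
    same_axis <- same_axis[d > 1e-9]
    d <- d[d > 1e-9]
    if (length(same_axis) == 0L) next
    C[same_axis[which.min(d)], j] <- coeff
  }
  C
}

#' Simulate the closed feedback loop
#'
#' Full-rate simulation of the control loop: at each sample the true
#' background field at every (possibly moving) sensor is computed by
#' rigid-body transformation of the array along the trajectory and
#' evaluation of the room field; the sensors record the residual after the
#' initial nulling and the currently applied (zero-order-hold,
#' cross-talk-corrupted) coil fields, with gain, additive neural signal,
#' white noise and hard clipping. Once per chunk the controller updates
#' the field model and schedules quantized coil commands with realistic
#' latency, jitter and axis stagger.
#'
#' @param array a [sensor_array()].
#' @param field_fn a room field function from [make_field()] (or any
#'   `function(position, time)` with the same contract).
#' @param duration simulated time, s (truncated to whole chunks).
#' @param trajectory optional gap-free trajectory (see [make_walk()] and
#'   [fill_gaps()]); `NULL` simulates a stationary array at the frame
#'   origin. Positions/quaternions are interpolated to sample times;
#'   any `NA` in the trajectory is an error — fill gaps first.
#' @param neural optional channels x samples matrix (T) at the loop sample
#'   rate (e.g. from [make_neural()]), added to every channel's input.
#' @param config a [loop_config()].
#' @param seed integer; seeds all randomness (noise, timing jitter).
#' @return An object of class `sim_result`: list with `recorded` (a
#'   [recording()] whose mask flags clipped samples), `applied_feedback`
#'   and `true_background` (channels x samples, T), `saturation_truth`,
#'   `true_field_center` (3 x n_chunks diagnostic of the full field vector
#'   at the array origin, including the unmeasured axis), `config`,
#'   `seed`, `trajectory`.
#' @export
simulate_closed_loop <- function(array, field_fn, duration, trajectory = NULL,
                                 neural = NULL, config = loop_config(),
                                 seed = 1L) {
  stopifnot(inherits(array, "sensor_array"), inherits(config, "loop_config"))
  fs <- config$sample_rate
  chunk <- config$chunk_size
  nchunks <- floor(duration * fs / chunk)
  if (nchunks < 1L) stop("duration shorter than one chunk")
  nsamp <- nchunks * chunk
  nch <- n_channels(array)
  P <- channel_positions(array)
  O <- channel_orientations(array)
  Pt <- t(P)
  Ot <- t(O)
  opm <- config$opm
  timing <- config$timing
  lim <- rep(opm$saturation_limit, length.out = nch)

  moving <- !is.null(trajectory)
  if (moving) {
    if (anyNA(trajectory[, c("x_m", "y_m", "z_m", "qw", "qx", "qy", "qz")])) {
      stop("trajectory contains gaps; fill them with fill_gaps() first")
    }
    if (max(trajectory$time_s) < (nsamp - 1) / fs) {
      stop("trajectory does not cover the simulation duration")
    }
    tfun <- lapply(c("x_m", "y_m", "z_m", "qw", "qx", "qy", "qz"), function(cc) {
      stats::approxfun(trajectory$time_s, trajectory[[cc]], rule = 2)
    })
    names(tfun) <- c("x", "y", "z", "qw", "qx", "qy", "qz")
  }

  proj <- hfc_projector(array, order = 1)
  noise_sd <- opm$white_noise_asd * sqrt(fs / 2)
  Cx <- crosstalk_matrix(array, opm$crosstalk_coeff)
  gain <- rep(opm$gain, length.out = nch)

  sample_true <- function(ts) {
    # true projected background per channel for a vector of times
    k <- length(ts)
    if (!moving) {
      B <- field_fn(Pt, ts[1]) # static part at fixed positions
      if (k > 1L) {
        d <- attr(field_fn, "drift_fn")
        if (!is.null(d)) {
          dd <- d(ts) - as.numeric(d(ts[1]))
          # homogeneous drift adds O %*% dd to every channel
          return(rowSums(O * t(B)) + O %*% dd)
        }
        B <- field_fn(Pt[, rep(seq_len(nch), k), drop = FALSE], rep(ts, each = nch))
        return(matrix(colSums(matrix(Ot, 3) * B), nch, k))
      }
      return(matrix(rowSums(O * t(B)), nch, 1))
    }
    out <- matrix(0, nch, k)
    for (s in seq_len(k)) {
      t1 <- ts[s]
      q <- c(tfun$qw(t1), tfun$qx(t1), tfun$qy(t1), tfun$qz(t1))
      q <- q / sqrt(sum(q^2))
      R <- quat_to_rot(q)
      trans <- c(tfun$x(t1), tfun$y(t1), tfun$z(t1))
      Pw <- R %*% Pt + trans
      Ow <- R %*% Ot
      B <- field_fn(Pw, t1)
      out[, s] <- colSums(Ow * B)
    }
    out
  }

  with_seed(seed, {
    zero <- if (config$null_at_start) drop(sample_true(0)) else rep(0, nch)

    filt <- NULL
    if (!is.null(config$filter_cutoff_hz) && config$feedback_on) {
      chunk_rate <- fs / chunk
      filt <- design_lowpass(config$filter_cutoff_hz, chunk_rate,
        channels = length(proj$feedback_idx)
      )
    }
    infilt <- NULL
    if (isTRUE(config$filter_input) && config$feedback_on) {
      infilt <- design_lowpass(config$filter_cutoff_hz, fs / chunk,
        channels = nch
      )
    }
    state <- list(prev_feedback = rep(0, nch), filter = filt)

    recorded <- matrix(0, nch, nsamp)
    fb_out <- matrix(0, nch, nsamp)
    true_out <- matrix(0, nch, nsamp)
    satmask <- matrix(FALSE, nch, nsamp)
    center_field <- matrix(0, 3, nchunks)
    pending <- list()
    fb_now <- rep(0, nch) # intended coil field currently applied

    for (c0 in seq_len(nchunks)) {
      s0 <- (c0 - 1L) * chunk
      ts <- (s0 + seq_len(chunk) - 1L) / fs
      cols <- s0 + seq_len(chunk)

      # apply due commands as zero-order holds within this chunk
      fb_chunk <- matrix(fb_now, nch, chunk)
      if (length(pending) > 0L) {
        due <- vapply(pending, function(cmd) cmd$time_s, 0) <= ts[chunk] + 1e-12
        if (any(due)) {
          ord <- order(vapply(pending[due], function(cmd) cmd$time_s, 0))
          for (cmd in pending[due][ord]) {
            k0 <- ceiling((cmd$time_s - ts[1]) * fs - 1e-9) + 1L
            k0 <- min(chunk, max(1L, k0))
            fb_chunk[cmd$idx, k0:chunk] <- cmd$values
            fb_now[cmd$idx] <- cmd$values
          }
          pending <- pending[!due]
        }
      }

      y_true <- sample_true(ts)
      fb_actual <- Cx %*% fb_chunk
      residual <- y_true - zero - fb_actual
      sig <- residual
      if (!is.null(neural)) sig <- sig + neural[, cols, drop = FALSE]
      y <- gain * sig
      if (noise_sd > 0) y <- y + matrix(stats::rnorm(nch * chunk, 0, noise_sd), nch, chunk)
      sat <- abs(y) > lim
      y <- pmin(pmax(y, -lim), lim)

      recorded[, cols] <- y
      fb_out[, cols] <- fb_actual
      true_out[, cols] <- y_true
      satmask[, cols] <- sat
      center_field[, c0] <- as.numeric(field_fn(c(0, 0, 0), ts[chunk]))

      if (config$feedback_on) {
        cm <- rowMeans(y)
        if (!is.null(infilt)) {
          stin <- biquad_step(infilt, cm)
          cm <- stin$y
          infilt <- stin$filter
        }
        state$prev_feedback <- fb_now
        tick <- controller_tick(state, proj, timing, cm,
          now_s = ts[chunk] + 1 / fs, opm = opm
        )
        state <- tick$state
        pending <- c(pending, tick$commands)
      }
    }

    labels <- channel_labels(array)
    rownames(recorded) <- labels
    res <- list(
      recorded = recording(recorded, fs = fs, labels = labels, mask = satmask),
      applied_feedback = fb_out,
      true_background = true_out,
      saturation_truth = satmask,
      true_field_center = center_field,
      config = config, seed = seed,
      trajectory = trajectory, array = array
    )
    class(res) <- "sim_result"
    res
  })
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "<sim_result> %d channels x %d samples @ %g Hz; feedback %s\n",
    nrow(x$recorded$data), ncol(x$recorded$data), x$recorded$fs,
    if (x$config$feedback_on) "ON" else "OFF"
  ))
  cat(sprintf("  saturated samples: %.2f%%\n", 100 * mean(x$saturation_truth)))
  invisible(x)
}

#' Write a simulation result as a directory of TSVs
#'
#' Writes `recording.tsv`, `feedback.tsv`, `truth.tsv`, `mask.tsv`, a JSON
#' `config.json` snapshot (including the seed), and `trajectory.csv` when
#' a trajectory was used.
#'
#' @param sim a [simulate_closed_loop()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_result <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_recording(sim$recorded, file.path(dir, "recording.tsv"))
  tt <- sample_times(sim$recorded)
  wmat <- function(m, path) {
    df <- data.frame(time_s = tt, t(m), check.names = FALSE)
    names(df)[-1] <- rownames(sim$recorded$data)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  wmat(sim$applied_feedback, file.path(dir, "feedback.tsv"))
  wmat(sim$true_background, file.path(dir, "truth.tsv"))
  wmat(sim$saturation_truth * 1L, file.path(dir, "mask.tsv"))
  cfg <- sim$config
  snapshot <- list(
    sample_rate = cfg$sample_rate, chunk_size = cfg$chunk_size,
    filter_cutoff_hz = cfg$filter_cutoff_hz, filter_input = cfg$filter_input,
    feedback_on = cfg$feedback_on, null_at_start = cfg$null_at_start,
    opm = cfg$opm[setdiff(names(cfg$opm), "gain_fn")],
    timing = unclass(cfg$timing), seed = sim$seed
  )
  jsonlite::write_json(snapshot, file.path(dir, "config.json"),
    auto_unbox = TRUE, digits = NA
  )
  if (!is.null(sim$trajectory)) {
    write_trajectory(sim$trajectory, file.path(dir, "trajectory.csv"))
  }
  invisible(dir)
}
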