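# Internal: run code under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Internal quaternion helpers (w, x, y, z convention).
quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

quat_nlerp <- function(q0, q1, a) {
  if (sum(q0 * q1) < 0) q1 <- -q1
  q <- (1 - a) * q0 + a * q1
  q / sqrt(sum(q^2))
}

#' Specification of the synthetic room field
#'
#' Describes the background field inside the shielded room as a static
#' homogeneous offset plus a linear spatial gradient plus a homogeneous
#' temporal drift process: `B(r, t) = offset + gradient %*% r + drift(t)`.
#' The defaults emulate a degaussed multilayer shielded room with a 3 x 4 m
#' footprint (room centre at the origin, "front" at y = +2 m): about 1 nT
#' at the centre, below ~1.7 nT within 0.5 m of the centre, and ~3.5 nT at
#' the front wall, with slow drift of a couple of hundred pT concentrated
#' below 0.5 Hz.
#'
#' @param homogeneous_offset 3-vector, tesla.
#' @param gradient 3 x 3 field-gradient tensor, T/m (defaults to a
#'   traceless-symmetric gradient dominated by the room's long axis).
#' @param drift list describing the per-component drift process: `type`
#'   one of `"none"`, `"random_walk"`, `"one_over_f"`, `"white"`,
#'   `"sine"`; `sd`
#'   target RMS per component (T) for the stochastic types; `cutoff_hz`
#'   band limit for `random_walk` (default 0.5); `freq_hz` and `amplitude`
#'   (T) for `"sine"`; `seed` integer.
#' @return An object of class `room_field_spec`.
#' @export
room_field_spec <- function(
    homogeneous_offset = c(0.5, 0.8, 0.3) * 1e-9,
    gradient = matrix(c(
      -0.7, 0, 0,
      0, 1.4, 0,
      0, 0, -0.7
    ), 3, 3, byrow = TRUE) * 1e-9,
    drift = list(type = "random_walk", sd = 200e-12, cutoff_hz = 0.5, seed = 1L)) {
  stopifnot(length(homogeneous_offset) == 3, all(dim(gradient) == c(3, 3)))
  structure(
    list(
      homogeneous_offset = as.numeric(homogeneous_offset),
      gradient = gradient, drift = drift
    ),
    class = "room_field_spec"
  )
}

# Internal: generate the 3 x n drift table for a spec on a time grid.
make_drift_table <- function(drift, tgrid, fs) {
  n <- length(tgrid)
  if (is.null(drift) || drift$type == "none") {
    return(matrix(0, 3, n))
  }
  if (drift$type == "sine") {
    amp <- if (!is.null(drift$amplitude)) drift$amplitude else drift$sd * sqrt(2)
    dirn <- if (!is.null(drift$direction)) drift$direction else c(1, 1, 1) / sqrt(3)
    return(outer(dirn, amp * sin(2 * pi * drift$freq_hz * tgrid)))
  }
  seed <- if (!is.null(drift$seed)) drift$seed else 1L
  with_seed(seed, {
    d <- matrix(stats::rnorm(3L * n), 3, n)
    if (drift$type == "white") {
      # band-limited white background noise (flat up to the grid Nyquist)
      return(d * drift$sd)
    }
    if (drift$type == "random_walk") {
      d <- t(apply(d, 1, cumsum))
      cutoff <- if (!is.null(drift$cutoff_hz)) drift$cutoff_hz else 0.5
      if (cutoff < fs / 2) {
        bf <- signal::butter(4, cutoff / (fs / 2), "low")
        d <- t(apply(d, 1, function(x) signal::filtfilt(bf, x - mean(x))))
      } else {
        d <- d - rowMeans(d)
      }
    } else if (drift$type == "one_over_f") {
      # shape white noise to 1/f amplitude in the frequency domain
      d <- t(apply(d, 1, function(x) {
        X <- stats::fft(x)
        f <- c(1, seq_len(n - 1))
        f <- pmin(f, n - f + 1) # two-sided frequency index
        Re(stats::fft(X / sqrt(f), inverse = TRUE)) / n
      }))
      d <- d - rowMeans(d)
    } else {
      stop("unknown drift type: ", drift$type)
    }
    sdn <- apply(d, 1, stats::sd)
    sdn[sdn == 0] <- 1
    d * (drift$sd / sdn)
  })
}

#' Build a room-field function from a spec
#'
#' Returns `B(r, t)`, deterministic given the spec's drift seed. The drift
#' is realised once on a uniform grid covering `[0, duration]` and linearly
#' interpolated between grid points (the drift is band-limited well below
#' the grid rate, so interpolation error is negligible).
#'
#' @param spec a [room_field_spec()].
#' @param duration time span the field must cover, in seconds.
#' @param drift_fs grid rate for the drift realisation, Hz (default 50).
#' @return A function `field_fn(position, time)`: `position` a 3-vector or
#'   3 x k matrix (m), `time` a scalar or length-k vector (s); returns a
#'   3-vector or 3 x k matrix (T). The drift-only part is available as
#'   `attr(field_fn, "drift_fn")(time)` and the static part parameters as
#'   attributes `offset` and `gradient`.
#' @examples
#' f <- make_field(room_field_spec(drift = list(type = "none")), duration = 1)
#' f(c(0, 2, 0), 0) # field at the room front
#' @export
make_field <- function(spec, duration = 300, drift_fs = 50) {
  stopifnot(inherits(spec, "room_field_spec"))
  tgrid <- seq(0, duration + 2 / drift_fs, by = 1 / drift_fs)
  dtab <- make_drift_table(spec$drift, tgrid, drift_fs)
  dfun <- list(
    stats::approxfun(tgrid, dtab[1, ], rule = 2),
    stats::approxfun(tgrid, dtab[2, ], rule = 2),
    stats::approxfun(tgrid, dtab[3, ], rule = 2)
  )
  drift_fn <- function(time) {
    rbind(dfun[[1]](time), dfun[[2]](time), dfun[[3]](time))
  }
  offset <- spec$homogeneous_offset
  G <- spec$gradient
  field_fn <- function(position, time) {
    pos <- if (is.matrix(position)) position else matrix(position, 3, 1)
    k <- max(ncol(pos), length(time))
    if (ncol(pos) == 1L && k > 1L) pos <- pos[, rep(1L, k), drop = FALSE]
    d <- drift_fn(time)
    if (ncol(d) == 1L && k > 1L) d <- d[, rep(1L, k), drop = FALSE]
    out <- offset + G %*% pos + d
    if (!is.matrix(position) && length(time) == 1L) drop(out) else out
  }
  attr(field_fn, "offset") <- offset
  attr(field_fn, "gradient") <- G
  attr(field_fn, "drift_fn") <- drift_fn
  attr(field_fn, "spec") <- spec
  class(field_fn) <- c("room_field", "function")
  field_fn
}

#' Generate a walking trajectory through the room
#'
#' A smooth, looping path through waypoints (default: a rounded rectangle
#' through the front half of the room, where the cables allow walking),
#' sampled at the motion-capture rate with heading-aligned yaw rotation.
#' Optionally injects tracking dropouts near the room edges, where marker
#' occlusion and camera coverage loss occur in practice; dropped samples
#' have `tracked = 0` and `NA` position/quaternion. The complete,
#' ungapped trajectory is attached as `attr(traj, "truth")` for
#' validation.
#'
#' @param duration seconds.
#' @param pattern waypoints as an n x 2 matrix of (x, y) in metres, looped
#'   in order; the head height is fixed at `height`.
#' @param speed walking speed in m/s (0 gives a stationary trajectory at
#'   the first waypoint).
#' @param seed integer seed for dropout placement.
#' @param fs motion-capture sampling rate, Hz (default 120).
#' @param height head height above the room centre plane, m (default 0.7).
#' @param dropout logical; inject tracking gaps (default TRUE).
#' @param heading_smooth_s window (s) of the centred moving average applied
#'   to the unwrapped path-tangent heading before building the yaw
#'   quaternion (default 1.5). Walkers do not snap their heads along the
#'   instantaneous path tangent: they cut corners, so the head yaw is a
#'   smoothed, slightly anticipating version of the path direction. Set 0
#'   for raw tangent heading.
#' @return A `trajectory`: data frame with columns `time_s, x_m, y_m, z_m,
#'   qw, qx, qy, qz, tracked`.
#' @export
make_walk <- function(duration, pattern = NULL, speed = 0.6, seed = 1L,
                      fs = 120, height = 0.7, dropout = TRUE,
                      heading_smooth_s = 1.5) {
  if (is.null(pattern)) {
    pattern <- cbind(
      x = c(0, 0.7, 1.0, 0.7, 0, -0.7, -1.0, -0.7),
      y = c(-0.4, -0.25, 0.7, 1.65, 1.8, 1.65, 0.7, -0.25)
    )
  }
  stopifnot(ncol(pattern) == 2, nrow(pattern) >= 3)
  if (any(abs(pattern[, 1]) > 1.5) || any(abs(pattern[, 2]) > 2)) {
    stop("waypoints must lie within the 3 x 4 m room footprint")
  }
  tt <- seq(0, duration, by = 1 / fs)
  n <- length(tt)
  if (speed <= 0) {
    pos <- cbind(rep(pattern[1, 1], n), rep(pattern[1, 2], n), rep(height, n))
    quat <- matrix(rep(c(1, 0, 0, 0), each = n), n, 4)
  } else {
    # periodic spline through the waypoint loop, parameterised by arclength
    wp <- rbind(pattern, pattern[1, , drop = FALSE])
    seg <- sqrt(rowSums(diff(wp)^2))
    s_wp <- c(0, cumsum(seg))
    L <- s_wp[length(s_wp)]
    sfx <- stats::splinefun(s_wp, wp[, 1], method = "periodic")
    sfy <- stats::splinefun(s_wp, wp[, 2], method = "periodic")
    s <- (speed * tt) %% L
    pos <- cbind(sfx(s), sfy(s), height)
    heading <- atan2(sfy(s, deriv = 1), sfx(s, deriv = 1))
    # unwrap, then smooth: the head yaw follows the walking direction but
    # turns gradually through corners
    dh <- diff(heading)
    dh <- dh - 2 * pi * round(dh / (2 * pi))
    heading <- cumsum(c(heading[1], dh))
    if (heading_smooth_s > 0 && n > 2L) {
      w <- max(1L, round(heading_smooth_s * fs))
      if (w %% 2L == 0L) w <- w + 1L
      if (w > 1L && n > w) {
        k <- (w - 1L) %/% 2L
        sl0 <- heading[2] - heading[1]
        sl1 <- heading[n] - heading[n - 1]
        pad <- c(heading[1] - sl0 * (k:1), heading, heading[n] + sl1 * (1:k))
        heading <- as.numeric(stats::filter(pad, rep(1 / w, w), sides = 2))[
          (k + 1L):(k + n)
        ]
      }
    }
    quat <- cbind(cos(heading / 2), 0, 0, sin(heading / 2)) # yaw about z
  }
  tracked <- rep(TRUE, n)
  if (dropout && speed > 0) {
    tracked <- with_seed(seed, {
      tr <- rep(TRUE, n)
      edge <- abs(pos[, 1]) > 0.8 | pos[, 2] > 1.4
      i <- 2L
      while (i < n) {
        if (edge[i] && stats::runif(1) < 0.004) {
          len <- round(stats::runif(1, 0.05, 0.8) * fs)
          j <- min(i + len, n - 1L)
          tr[i:j] <- FALSE
          i <- j + round(0.5 * fs) # refractory period between gaps
        }
        i <- i + 1L
      }
      tr
    })
  }
  truth <- data.frame(
    time_s = tt, x_m = pos[, 1], y_m = pos[, 2], z_m = pos[, 3],
    qw = quat[, 1], qx = quat[, 2], qy = quat[, 3], qz = quat[, 4],
    tracked = 1L
  )
  traj <- truth
  traj$tracked <- as.integer(tracked)
  traj[!tracked, c("x_m", "y_m", "z_m", "qw", "qx", "qy", "qz")] <- NA_real_
  attr(traj, "fs") <- fs
  attr(traj, "truth") <- truth
  class(traj) <- c("trajectory", "data.frame")
  traj
}

#' Fraction of trajectory samples outside a radius
#'
#' Horizontal (x, y) distance from the room centre, matching the 0.5 m
#' radius cylinder used to classify trials.
#'
#' @param traj a trajectory from [make_walk()].
#' @param radius metres (default 0.5).
#' @return Fraction of tracked samples outside the radius.
#' @export
fraction_outside <- function(traj, radius = 0.5) {
  ok <- traj$tracked == 1L | !is.na(traj$x_m)
  r <- sqrt(traj$x_m[ok]^2 + traj$y_m[ok]^2)
  mean(r > radius, na.rm = TRUE)
}

#' Fill motion-capture gaps
#'
#' Gaps shorter than `linear_max_s` are filled by linear interpolation;
#' longer gaps by shape-preserving piecewise-cubic interpolation through
#' the tracked samples (no overshoot beyond neighbouring values).
#' Quaternions are interpolated by normalised linear interpolation between
#' the bounding tracked samples and renormalised. Filled samples are
#' flagged in a new `interpolated` column (and `gap_s` records the length
#' of the gap each filled sample belonged to). Gaps touching the sequence
#' boundary are left unfilled with a warning.
#'
#' @param traj a trajectory with `tracked` and `NA` gaps.
#' @param linear_max_s threshold between linear and cubic filling,
#'   seconds (default 0.2).
#' @return The trajectory with gaps filled and flags added.
#' @export
fill_gaps <- function(traj, linear_max_s = 0.2) {
  fs <- attr(traj, "fs")
  if (is.null(fs)) fs <- 1 / stats::median(diff(traj$time_s))
  n <- nrow(traj)
  tracked <- traj$tracked == 1L
  traj$interpolated <- 0L
  traj$gap_s <- 0
  if (all(tracked)) return(traj)
  r <- rle(tracked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tt <- traj$time_s
  poscols <- c("x_m", "y_m", "z_m")
  qcols <- c("qw", "qx", "qy", "qz")
  for (g in which(!r$values)) {
    i0 <- starts[g]
    i1 <- ends[g]
    if (i0 == 1L || i1 == n) {
      warning("gap at sequence boundary left unfilled")
      next
    }
    gap_s <- (i1 - i0 + 1L) / fs
    idx <- i0:i1
    a <- i0 - 1L
    b <- i1 + 1L
    if (gap_s < linear_max_s) {
      for (cc in poscols) {
        traj[[cc]][idx] <- traj[[cc]][a] +
          (traj[[cc]][b] - traj[[cc]][a]) * (tt[idx] - tt[a]) / (tt[b] - tt[a])
      }
    } else {
      valid <- which(tracked)
      for (cc in poscols) {
        traj[[cc]][idx] <- pracma::pchip(tt[valid], traj[[cc]][valid], tt[idx])
      }
    }
    q0 <- as.numeric(traj[a, qcols])
    q1 <- as.numeric(traj[b, qcols])
    al <- (tt[idx] - tt[a]) / (tt[b] - tt[a])
    for (k in seq_along(idx)) {
      traj[idx[k], qcols] <- quat_nlerp(q0, q1, al[k])
    }
    traj$interpolated[idx] <- 1L
    traj$gap_s[idx] <- gap_s
  }
  traj
}

#' Generate a roving-oddball stimulus schedule
#'
#' A stream of consecutive-tone sets: each set repeats one frequency
#' (drawn uniformly from 500-800 Hz in 50 Hz steps, always different from
#' the previous set); the first tone of each set is the "deviant". Set
#' lengths are drawn from the weighted distribution over 1-11 tones
#' (2.5% each for 1 and 2; 2.75% each for 3 and 4; 12.5% each for 5-11;
#' the printed weights total 98% and are renormalised). The inter-stimulus
#' interval is exactly 0.5 s with no jitter. With 80 deviants (sets), the
#' expected tone count is about 570-595 per block.
#'
#' @param n_deviants number of sets (= deviant tones).
#' @param seed integer seed.
#' @param isi inter-stimulus interval, s (default 0.5).
#' @param t0 onset of the first tone, s (default 0.5).
#' @return A `stimulus_schedule` data frame with columns `onset_s`,
#'   `freq_hz`, `deviant` (0/1).
#' @export
make_stimuli <- function(n_deviants, seed = 1L, isi = 0.5, t0 = 0.5) {
  stopifnot(n_deviants >= 1)
  lengths_support <- 1:11
  w <- c(2.5, 2.5, 2.75, 2.75, rep(12.5, 7))
  w <- w / sum(w)
  freqs <- seq(500, 800, by = 50)
  with_seed(seed, {
    set_len <- sample(lengths_support, n_deviants, replace = TRUE, prob = w)
    freq <- numeric(n_deviants)
    freq[1] <- sample(freqs, 1)
    for (k in seq_len(n_deviants - 1L) + 1L) {
      freq[k] <- sample(setdiff(freqs, freq[k - 1L]), 1)
    }
    tone_freq <- rep(freq, set_len)
    deviant <- unlist(lapply(set_len, function(l) c(1L, rep(0L, l - 1L))))
    n <- length(tone_freq)
    sched <- data.frame(
      onset_s = t0 + isi * (seq_len(n) - 1L),
      freq_hz = tone_freq,
      deviant = deviant
    )
    class(sched) <- c("stimulus_schedule", "data.frame")
    sched
  })
}

#' Synthetic auditory evoked signal at the sensors
#'
#' Adds a fixed bilateral dipolar-like spatial pattern times an evoked
#' template (a Gaussian bump peaking ~100 ms after each tone, ~100 fT at
#' the best channel) at every stimulus onset. This is deliberately simple
#' plumbing: it gives the evoked pipeline a known ground truth, it does
#' not model auditory physiology.
#'
#' @param schedule a [make_stimuli()] schedule.
#' @param array a [sensor_array()].
#' @param template list with `peak_s` (default 0.1), `width_s` (0.03)
#'   and `amplitude` (T, default 1e-13).
#' @param fs sampling rate of the output, Hz.
#' @param duration total length in seconds (default: last onset + 1 s).
#' @return channels x samples matrix (T); the spatial weights are attached
#'   as `attr(, "weights")` and the template time course as
#'   `attr(, "template")`.
#' @export
make_neural <- function(schedule, array,
                        template = list(peak_s = 0.1, width_s = 0.03,
                                        amplitude = 1e-13),
                        fs = 1000, duration = NULL) {
  stopifnot(inherits(array, "sensor_array"))
  if (is.null(duration)) {
    duration <- if (nrow(schedule) > 0) max(schedule$onset_s) + 1 else 1
  }
  n <- round(duration * fs)
  P <- channel_positions(array)
  O <- channel_orientations(array)
  # bilateral sources near the temporal lobes, opposite-signed moments
  lpos <- c(-0.07, 0, 0.02)
  rpos <- c(0.07, 0, 0.02)
  gl <- exp(-rowSums(sweep(P, 2, lpos)^2) / (2 * 0.06^2))
  gr <- exp(-rowSums(sweep(P, 2, rpos)^2) / (2 * 0.06^2))
  w <- gl * O[, 2] - gr * O[, 2]
  if (max(abs(w)) > 0) w <- w / max(abs(w))
  tt_tpl <- seq(0, template$peak_s + 4 * template$width_s, by = 1 / fs)
  tpl <- template$amplitude *
    exp(-(tt_tpl - template$peak_s)^2 / (2 * template$width_s^2))
  sig <- matrix(0, nrow(P), n)
  for (on in schedule$onset_s) {
    i0 <- round(on * fs) + 1L
    i1 <- min(i0 + length(tpl) - 1L, n)
    if (i0 > n) next
    k <- seq_len(i1 - i0 + 1L)
    sig[, i0:i1] <- sig[, i0:i1] + outer(w, tpl[k])
  }
  rownames(sig) <- channel_labels(array)
  attr(sig, "weights") <- w
  attr(sig, "template") <- tpl
  sig
}

#' Write / read a trajectory CSV
#'
#' Columns: `time_s, x_m, y_m, z_m, qw, qx, qy, qz, tracked`.
#' @param traj a trajectory.
#' @param path file path.
#' @return `path` (write) or the trajectory (read).
#' @export
write_trajectory <- function(traj, path) {
  cols <- c("time_s", "x_m", "y_m", "z_m", "qw", "qx", "qy", "qz", "tracked")
  utils::write.csv(as.data.frame(traj)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  traj <- utils::read.csv(path)
  attr(traj, "fs") <- 1 / stats::median(diff(traj$time_s))
  class(traj) <- c("trajectory", "data.frame")
  traj
}

#' Write / read a stimulus schedule TSV
#'
#' Columns: `onset_s, freq_hz, deviant`.
#' @param schedule a [make_stimuli()] schedule.
#' @param path file path.
#' @return `path` (write) or the schedule (read).
#' @export
write_stimuli <- function(schedule, path) {
  utils::write.table(as.data.frame(schedule), path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_stimuli
#' @export
read_stimuli <- function(path) {
  sched <- utils::read.delim(path)
  class(sched) <- c("stimulus_schedule", "data.frame")
  sched
}
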