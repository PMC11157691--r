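# Independent reference implementations and fixture builders used across the
# test files. Everything here is deliberately naive (loops, closed forms) so
# it cannot share a code path with the package.

# random rigid dual-axis array: n_opms sensors at random positions on a
# sphere-ish shell, radial + tangential channels
random_array <- function(n_opms, seed = 1, feedback_opms = seq_len(n_opms)) {
  set.seed(seed)
  rows <- list()
  for (k in seq_len(n_opms)) {
    v <- stats::rnorm(3)
    v <- v / sqrt(sum(v^2))
    pos <- 0.1 * v
    ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    tang <- ref - sum(ref * v) * v
    tang <- tang / sqrt(sum(tang^2))
    fb <- k %in% feedback_opms
    rows[[length(rows) + 1L]] <- data.frame(
      label = sprintf("S%02d-Y", k), x = pos[1], y = pos[2], z = pos[3],
      ox = v[1], oy = v[2], oz = v[3], axis = "Y", feedback = fb
    )
    rows[[length(rows) + 1L]] <- data.frame(
      label = sprintf("S%02d-Z", k), x = pos[1], y = pos[2], z = pos[3],
      ox = tang[1], oy = tang[2], oz = tang[3], axis = "Z", feedback = fb
    )
  }
  sensor_array(do.call(rbind, rows))
}

# a vector orthogonal to the column space of N (via the QR complement)
orthogonal_vector <- function(N, seed = 1) {
  set.seed(seed)
  Q <- qr.Q(qr(N), complete = TRUE)
  Qperp <- Q[, (ncol(N) + 1L):nrow(N), drop = FALSE]
  drop(Qperp %*% stats::rnorm(ncol(Qperp)))
}

# naive direct-form-I IIR filter, one section: y[n] = sum b x - sum a y
filter_df1 <- function(b, a, x) {
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in seq_along(b)) {
      if (i - k + 1L >= 1L) acc <- acc + b[k] * x[i - k + 1L]
    }
    for (k in seq_along(a)[-1L]) {
      if (i - k + 1L >= 1L) acc <- acc - a[k] * y[i - k + 1L]
    }
    y[i] <- acc
  }
  y
}

# run a biquad cascade's sections through the naive filter sequentially
cascade_df1 <- function(cascade, x) {
  for (s in cascade$sections) {
    x <- filter_df1(c(s$b0, s$b1, s$b2), c(1, s$a1, s$a2), x)
  }
  x
}

# MATLAB-style shape-preserving piecewise cubic (pchip): Fritsch-Carlson /
# Moler slopes + Hermite evaluation
pchip_oracle <- function(x, y, xq) {
  n <- length(x)
  h <- diff(x)
  delta <- diff(y) / h
  d <- numeric(n)
  for (k in 2:(n - 1)) {
    if (delta[k - 1] * delta[k] <= 0) {
      d[k] <- 0
    } else {
      w1 <- 2 * h[k] + h[k - 1]
      w2 <- h[k] + 2 * h[k - 1]
      d[k] <- (w1 + w2) / (w1 / delta[k - 1] + w2 / delta[k])
    }
  }
  end_slope <- function(h1, h2, d1, d2) {
    s <- ((2 * h1 + h2) * d1 - h1 * d2) / (h1 + h2)
    if (sign(s) != sign(d1)) s <- 0
    else if (sign(d1) != sign(d2) && abs(s) > 3 * abs(d1)) s <- 3 * d1
    s
  }
  d[1] <- end_slope(h[1], h[2], delta[1], delta[2])
  d[n] <- end_slope(h[n - 1], h[n - 2], delta[n - 1], delta[n - 2])
  out <- numeric(length(xq))
  for (j in seq_along(xq)) {
    k <- findInterval(xq[j], x, rightmost.closed = TRUE)
    k <- min(max(k, 1L), n - 1L)
    t <- (xq[j] - x[k]) / h[k]
    h00 <- 2 * t^3 - 3 * t^2 + 1
    h10 <- t^3 - 2 * t^2 + t
    h01 <- -2 * t^3 + 3 * t^2
    h11 <- t^3 - t^2
    out[j] <- h00 * y[k] + h10 * h[k] * d[k] +
      h01 * y[k + 1] + h11 * h[k] * d[k + 1]
  }
  out
}

# clipped-Gaussian block with known clip indices. Unclipped samples falling
# within the detector's tail band (tail_bins bins below the rail) are pushed
# out of it so that "mask == clip indices" is well-posed at 1 pT granularity.
clipped_block <- function(n = 3e5, sd = 6e-10, lim = 1.5e-9, seed = 1,
                          fs = 1000, guard = 6e-12) {
  set.seed(seed)
  x <- stats::rnorm(n, sd = sd)
  clipped <- abs(x) > lim
  x[clipped] <- lim * sign(x[clipped])
  near <- !clipped & abs(x) > lim - guard
  x[near] <- sign(x[near]) * (lim - guard - 1e-12)
  list(rec = recording(matrix(x, 1), fs = fs), clipped = clipped)
}

# least-squares sinusoid amplitude at a known frequency
fit_amplitude <- function(t, x, f) {
  X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  cf <- stats::coef(stats::lm(x ~ X - 1))
  sqrt(sum(cf^2))
}

# tiny stationary drift scenario used by several loop tests
drift_test_setup <- function(n_opms = 6, fs = 600, dur = 30, drift = list(type = "none"),
                             feedback_opms = NULL) {
  if (is.null(feedback_opms)) feedback_opms <- seq_len(n_opms)
  arr <- example_scanner_cast_array(n_opms = n_opms, feedback_opms = feedback_opms)
  spec <- room_field_spec(
    homogeneous_offset = c(0, 0, 0), gradient = matrix(0, 3, 3),
    drift = drift
  )
  fld <- make_field(spec, duration = dur)
  list(
    array = arr, field = fld,
    config = function(...) {
      loop_config(sample_rate = fs, chunk_size = round(fs / 100), ...)
    }
  )
}
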