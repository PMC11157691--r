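#' Design the real-time low-pass filter as a biquad cascade
#'
#' Fourth-order Butterworth low-pass, factored into two second-order
#' sections ("biquads") and run in the transposed direct form II, the form
#' used for point-by-point multichannel filtering inside the feedback loop.
#' Each analog pole pair is mapped through the bilinear transform with
#' frequency pre-warping; the two sections are ordered lowest-Q first.
#' Each section has unit DC gain by construction.
#'
#' @param cutoff -3 dB corner frequency in Hz.
#' @param sample_rate sampling rate of the stream the filter runs at, in
#'   Hz. Inside the loop this is the chunk rate (100 Hz for 60-sample
#'   chunks at 6 kHz), since the model output only exists once per chunk.
#' @param channels number of parallel channels the filter will process
#'   (state is per channel).
#' @return An object of class `biquad_cascade`.
#' @examples
#' f <- design_lowpass(1, 100, channels = 2)
#' out <- biquad_step(f, c(1, -1))
#' @export
design_lowpass <- function(cutoff, sample_rate, channels = 1L) {
  if (cutoff <= 0 || cutoff >= sample_rate / 2) {
    stop("cutoff must lie strictly between 0 and the Nyquist frequency")
  }
  # order-4 Butterworth pole-pair quality factors, low Q first
  Qs <- 1 / (2 * cos(c(3, 1) * pi / 8))
  K <- tan(pi * cutoff / sample_rate)
  sections <- lapply(Qs, function(Q) {
    norm <- 1 / (1 + K / Q + K^2)
    list(
      b0 = K^2 * norm, b1 = 2 * K^2 * norm, b2 = K^2 * norm,
      a1 = 2 * (K^2 - 1) * norm, a2 = (1 - K / Q + K^2) * norm
    )
  })
  structure(
    list(
      sections = sections,
      state = lapply(sections, function(s) matrix(0, 2, channels)),
      channels = as.integer(channels),
      cutoff = cutoff, sample_rate = sample_rate
    ),
    class = "biquad_cascade"
  )
}

#' @export
print.biquad_cascade <- function(x, ...) {
  cat(sprintf(
    "<biquad_cascade> %d sections, cutoff %g Hz @ %g Hz, %d channel(s)\n",
    length(x$sections), x$cutoff, x$sample_rate, x$channels
  ))
  invisible(x)
}

#' Advance a biquad cascade by one sample (all channels)
#'
#' Transposed direct form II update, one multichannel sample per call:
#' for each section, `y = b0*x + s1; s1 = b1*x - a1*y + s2;
#' s2 = b2*x - a2*y`. Feeding a sequence one sample at a time is
#' bit-identical to batch filtering with the same coefficients.
#'
#' @param filter a [design_lowpass()] cascade.
#' @param x numeric vector, one value per channel.
#' @return List with `y` (filtered sample per channel) and `filter` (the
#'   cascade with updated state).
#' @export
biquad_step <- function(filter, x) {
  stopifnot(inherits(filter, "biquad_cascade"))
  if (length(x) != filter$channels) {
    stop("x must have one value per filter channel")
  }
  if (anyNA(x)) stop("NaN/NA input would poison the filter state")
  for (k in seq_along(filter$sections)) {
    s <- filter$sections[[k]]
    st <- filter$state[[k]]
    y <- s$b0 * x + st[1, ]
    st[1, ] <- s$b1 * x - s$a1 * y + st[2, ]
    st[2, ] <- s$b2 * x - s$a2 * y
    filter$state[[k]] <- st
    x <- y
  }
  list(y = x, filter = filter)
}

#' Reset the delay registers of a biquad cascade
#' @param filter a [design_lowpass()] cascade.
#' @return The cascade with zeroed state.
#' @export
biquad_reset <- function(filter) {
  stopifnot(inherits(filter, "biquad_cascade"))
  filter$state <- lapply(filter$state, function(st) st * 0)
  filter
}

#' Frequency response of a biquad cascade
#'
#' Evaluates the cascade transfer function on the unit circle,
#' `H(e^{j w}) = prod (b0 + b1 z^-1 + b2 z^-2) / (1 + a1 z^-1 + a2 z^-2)`.
#'
#' @param filter a [design_lowpass()] cascade.
#' @param f frequencies in Hz.
#' @return Complex response at each frequency.
#' @export
biquad_response <- function(filter, f) {
  stopifnot(inherits(filter, "biquad_cascade"))
  z1 <- exp(-2i * pi * f / filter$sample_rate)
  z2 <- z1^2
  H <- rep(1 + 0i, length(f))
  for (s in filter$sections) {
    H <- H * (s$b0 + s$b1 * z1 + s$b2 * z2) / (1 + s$a1 * z1 + s$a2 * z2)
  }
  H
}

#' Group delay of a biquad cascade at a frequency
#'
#' Numerical derivative of the unwrapped phase, `-dphi/dw`, in seconds.
#' Used to budget the latency the 1 Hz output filter contributes at the
#' slow drift frequencies the loop is meant to null.
#'
#' @param filter a [design_lowpass()] cascade.
#' @param f frequency in Hz.
#' @return Group delay in seconds.
#' @export
biquad_group_delay <- function(filter, f) {
  df <- max(f * 1e-4, 1e-6)
  ph <- Arg(biquad_response(filter, c(f - df, f + df)))
  dphi <- ph[2] - ph[1]
  # unwrap across the evaluation pair
  if (dphi > pi) dphi <- dphi - 2 * pi
  if (dphi < -pi) dphi <- dphi + 2 * pi
  -dphi / (2 * pi * 2 * df)
}

#' Average one chunk of samples per channel
#'
#' The loop reads the 6 kHz stream in 60-sample (10 ms) chunks and fits the
#' field model to the time-average of each chunk, so one model update is
#' produced per chunk. Averaging over `n` samples acts as a moving-average
#' low-pass (see [moving_average_response()]).
#'
#' @param buffer channels x chunk_size numeric matrix (a full chunk).
#' @return Numeric vector of per-channel means.
#' @export
chunk_average <- function(buffer) {
  buffer <- as.matrix(buffer)
  rowMeans(buffer)
}

#' Chunk means of a whole recording
#'
#' Splits a recording into consecutive `chunk_size`-sample chunks and
#' averages each. A partial final chunk is dropped with a warning.
#'
#' @param rec a [recording()].
#' @param chunk_size samples per chunk (default 60).
#' @return channels x n_chunks matrix of chunk means.
#' @export
chunk_means <- function(rec, chunk_size = 60L) {
  stopifnot(inherits(rec, "recording"))
  n <- ncol(rec$data)
  nchunks <- n %/% chunk_size
  if (n %% chunk_size != 0L) {
    warning(sprintf("dropping partial final chunk of %d samples", n %% chunk_size))
  }
  if (nchunks == 0L) stop("recording shorter than one chunk")
  dim3 <- array(rec$data[, seq_len(nchunks * chunk_size), drop = FALSE],
    dim = c(nrow(rec$data), chunk_size, nchunks)
  )
  apply(dim3, c(1, 3), mean)
}

#' Magnitude response of an n-sample moving average
#'
#' Chunk averaging of `n` samples at rate `fs` is a moving-average filter
#' with magnitude response `|H(f)| = |sin(pi f n / fs) / (n sin(pi f /
#' fs))|`. The lowest -3 dB frequency is located by bisection.
#'
#' @param n samples per average (>= 1).
#' @param sample_rate sampling rate in Hz.
#' @return List with `gain` (vectorised function of frequency in Hz) and
#'   `minus3db` (lowest frequency where the gain crosses 1/sqrt(2), Hz;
#'   `NA` if there is none below Nyquist, e.g. for `n = 1`).
#' @examples
#' moving_average_response(60, 6000)$minus3db # ~44 Hz
#' @export
moving_average_response <- function(n, sample_rate) {
  stopifnot(n >= 1, sample_rate > 0)
  gain <- function(f) {
    g <- ifelse(
      abs(f) < 1e-300, 1,
      abs(sin(pi * f * n / sample_rate) / (n * sin(pi * f / sample_rate)))
    )
    g[abs(sin(pi * f / sample_rate)) < 1e-15 & abs(f) >= 1e-300] <- 1
    g
  }
  target <- 1 / sqrt(2)
  nyq <- sample_rate / 2
  minus3db <- NA_real_
  if (n > 1L && gain(nyq) < target) {
    lo <- 0
    hi <- nyq
    # bracket the first crossing: walk up until gain dips below target
    grid <- seq(0, nyq, length.out = 4096L)
    below <- which(gain(grid) < target)
    if (length(below) > 0L) {
      hi <- grid[below[1]]
      lo <- grid[below[1] - 1L]
      while (hi - lo > 1e-6) {
        mid <- (lo + hi) / 2
        if (gain(mid) < target) hi <- mid else lo <- mid
      }
      minus3db <- (lo + hi) / 2
    }
  }
  list(gain = gain, minus3db = minus3db)
}
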