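#' Multichannel magnetometer recording
#'
#' Container for a uniformly sampled multichannel time series in tesla:
#' a channels x samples matrix, the sampling rate, the start time, and an
#' optional per-sample logical saturation mask of the same shape.
#'
#' @param data channels x samples numeric matrix (T). Row names, if set,
#'   are the channel labels.
#' @param fs sampling rate in Hz.
#' @param labels optional channel labels (defaults to row names or
#'   `ch01`...).
#' @param t0 time of the first sample in seconds (default 0).
#' @param mask optional logical matrix, same shape as `data`, `TRUE` where
#'   a sample is saturated/invalid.
#' @return An object of class `recording`.
#' @export
recording <- function(data, fs, labels = NULL, t0 = 0, mask = NULL) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), fs > 0)
  if (is.null(labels)) {
    labels <- rownames(data)
    if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(nrow(data)))
  }
  if (length(labels) != nrow(data)) stop("one label per channel required")
  rownames(data) <- labels
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(data))) {
      stop("mask must have the same shape as data")
    }
    mask <- matrix(as.logical(mask), nrow(data), ncol(data))
    rownames(mask) <- labels
  }
  structure(
    list(data = data, fs = fs, t0 = t0, mask = mask),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs
  ))
  if (!is.null(x$mask)) {
    cat(sprintf("  saturated samples: %d (%.2f%%)\n",
      sum(x$mask), 100 * mean(x$mask)
    ))
  }
  invisible(x)
}

#' Sample times of a recording
#' @param rec a [recording()].
#' @return Numeric vector of sample times in seconds.
#' @export
sample_times <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  rec$t0 + (seq_len(ncol(rec$data)) - 1L) / rec$fs
}

#' Read a recording from a delimited file
#'
#' Expects a header row `time_s` followed by one column per channel, values
#' in tesla. The sampling rate is inferred from the time column and checked
#' for uniformity to 1 ppm of the sampling interval.
#'
#' @param path TSV/CSV file (delimiter inferred: `.csv` uses comma).
#' @param layout optional [sensor_array()]; if given, the file must contain
#'   every layout channel, and columns are reordered to layout order.
#' @param downsample integer factor; if > 1 the data are low-pass filtered
#'   and decimated on load.
#' @return A [recording()].
#' @export
read_recording <- function(path, layout = NULL, downsample = 1L) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  if (names(df)[1] != "time_s") stop("first column must be 'time_s'")
  tt <- df[[1]]
  if (length(tt) < 2L) stop("recording needs at least 2 samples")
  dt <- diff(tt)
  dt0 <- stats::median(dt)
  worst <- max(abs(dt - dt0))
  if (worst > 1e-6 * dt0) {
    stop(sprintf(
      "non-uniform sampling: worst interval deviation %.3g s (median interval %.6g s)",
      worst, dt0
    ))
  }
  dat <- t(as.matrix(df[, -1, drop = FALSE]))
  if (!is.null(layout)) {
    want <- channel_labels(layout)
    miss <- setdiff(want, rownames(dat))
    if (length(miss) > 0L) {
      stop("recording is missing layout channel(s): ", paste(miss, collapse = ", "))
    }
    dat <- dat[want, , drop = FALSE]
  }
  rec <- recording(dat, fs = 1 / dt0, t0 = tt[1])
  if (downsample > 1L) rec <- downsample_recording(rec, as.integer(downsample))
  rec
}

#' Write a recording to a delimited file
#'
#' @param rec a [recording()].
#' @param path output path (`.csv` for comma-separated, else TSV).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(time_s = sample_times(rec), t(rec$data), check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Downsample a recording by an integer factor
#'
#' Anti-alias low-pass (8th-order Chebyshev type I, as in a conventional
#' decimator) then keep every `factor`-th sample. The saturation mask, if
#' present, is decimated by logical OR over each kept sample's window so
#' that no saturated stretch is lost.
#'
#' @param rec a [recording()].
#' @param factor integer >= 2.
#' @return A [recording()] at `fs / factor`.
#' @export
downsample_recording <- function(rec, factor) {
  stopifnot(inherits(rec, "recording"), factor >= 2)
  factor <- as.integer(factor)
  n <- ncol(rec$data)
  keep <- seq(1L, n, by = factor)
  dat <- t(apply(rec$data, 1L, function(x) {
    signal::decimate(x, factor, ftype = "iir")
  }))
  dat <- dat[, seq_along(keep), drop = FALSE]
  mask <- NULL
  if (!is.null(rec$mask)) {
    grp <- rep(seq_along(keep), each = factor, length.out = n)
    mask <- t(apply(rec$mask, 1L, function(m) {
      as.logical(tapply(m, grp, any))
    }))
  }
  recording(dat, fs = rec$fs / factor, labels = rownames(rec$data),
    t0 = rec$t0, mask = mask)
}
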