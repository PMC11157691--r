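#' Welch amplitude spectral density of a recording
#'
#' Welch's method on consecutive segments (default 20 s, Hann window, 50%
#' overlap, mean averaging): the per-channel power spectral density is the
#' average of windowed periodograms, returned as an amplitude spectral
#' density (field / sqrt(Hz)), the scale on which OPM noise floors are
#' quoted. Frequencies start at `1 / segment_s` (DC is dropped). Segments
#' are not detrended, so the slowest resolvable drift bins keep their
#' power. Restrict `rec` to the analysis window of interest (e.g. the
#' feedback-on period) before calling.
#'
#' @param rec a [recording()].
#' @param segment_s segment length in seconds (default 20).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return An object of class `psd_result`: list with `frequencies` (Hz),
#'   `asd` (channels x frequencies), `segment_s`, `n_segments`,
#'   `estimator = "welch"`.
#' @export
welch_psd <- function(rec, segment_s = 20, overlap = 0.5) {
  stopifnot(inherits(rec, "recording"), segment_s > 0,
    overlap >= 0, overlap < 1)
  fs <- rec$fs
  nseg <- floor(segment_s * fs)
  n <- ncol(rec$data)
  if (n < 2 * nseg * (1 - overlap) + nseg * overlap) {
    stop("recording must span at least 2 (overlapping) segments")
  }
  hop <- max(1L, floor(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1)) # Hann
  norm <- 2 / (fs * sum(w^2)) # one-sided PSD scale
  nf <- nseg %/% 2L
  acc <- matrix(0, nrow(rec$data), nf)
  for (s0 in starts) {
    seg <- rec$data[, s0:(s0 + nseg - 1L), drop = FALSE]
    segw <- sweep(seg, 2L, w, `*`)
    X <- t(stats::mvfft(t(segw)))
    acc <- acc + norm * Mod(X[, 2L:(nf + 1L), drop = FALSE])^2
  }
  psd <- acc / length(starts)
  structure(
    list(
      frequencies = (seq_len(nf)) * fs / nseg,
      asd = sqrt(psd),
      segment_s = segment_s, n_segments = length(starts),
      estimator = "welch", labels = rownames(rec$data)
    ),
    class = "psd_result"
  )
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf(
    "<psd_result> %d channels, %.3g-%.3g Hz (%d bins), %d x %g s Welch segments\n",
    nrow(x$asd), min(x$frequencies), max(x$frequencies),
    length(x$frequencies), x$n_segments, x$segment_s
  ))
  invisible(x)
}

#' Median shielding factor between two conditions
#'
#' `mSF(f) = 20 log10( median_channels ASD_off / median_channels ASD_on )`,
#' in dB: positive where the feedback reduces the noise, negative where it
#' raises the floor. The median over channels is taken of each condition's
#' spectrum first, then the ratio, and the uncertainty band propagates the
#' standard error of each median (normal approximation,
#' `1.2533 * sd / sqrt(n)`) to the dB ratio.
#'
#' The spectra are amplitude spectral densities, so the conventional
#' field-attenuation factor uses `db_factor = 20`; set `db_factor = 10`
#' to express the same ratio as a power quantity.
#'
#' @param psd_off,psd_on [welch_psd()] results on identical frequency
#'   grids (feedback off and on).
#' @param db_factor 20 (amplitude dB, default) or 10.
#' @return Data frame with `frequency` (Hz), `msf_db`, `se_db`.
#' @export
median_shielding_factor <- function(psd_off, psd_on, db_factor = 20) {
  stopifnot(inherits(psd_off, "psd_result"), inherits(psd_on, "psd_result"))
  if (!isTRUE(all.equal(psd_off$frequencies, psd_on$frequencies))) {
    stop("frequency grids do not match")
  }
  med_se <- function(m) {
    med <- apply(m, 2L, stats::median)
    se <- 1.2533 * apply(m, 2L, stats::sd) / sqrt(nrow(m))
    list(med = med, se = se)
  }
  off <- med_se(psd_off$asd)
  on <- med_se(psd_on$asd)
  if (any(off$med <= 0) || any(on$med <= 0)) {
    stop("zero median spectral density; cannot form the shielding factor")
  }
  msf <- db_factor * log10(off$med / on$med)
  se_db <- db_factor / log(10) *
    sqrt((off$se / off$med)^2 + (on$se / on$med)^2)
  data.frame(frequency = psd_off$frequencies, msf_db = msf, se_db = se_db)
}

#' Offline preprocessing for evoked analysis
#'
#' Downsamples (default to 1 kHz), applies band-stop filters at the line
#' and camera interference frequencies (50, 83, 120 Hz by default), then a
#' 2 Hz high-pass and a 40 Hz low-pass. All filters are Butterworth
#' (default order 5) applied forward-backward (`filtfilt`) for zero phase
#' shift. Band-stops whose upper edge reaches Nyquist are skipped with a
#' warning.
#'
#' @param rec a [recording()].
#' @param downsample_to target rate in Hz (`NULL` to keep the input rate;
#'   the input rate must be an integer multiple of the target).
#' @param band_stop_hz centre frequencies of the band-stop filters.
#' @param stop_half_width_hz half-width of each stop band (default 2 Hz).
#' @param high_pass_hz,low_pass_hz band-pass corners (2 and 40 Hz).
#' @param order Butterworth order for every filter (default 5).
#' @return The filtered [recording()].
#' @export
preprocess_evoked <- function(rec, downsample_to = 1000,
                              band_stop_hz = c(50, 83, 120),
                              stop_half_width_hz = 2,
                              high_pass_hz = 2, low_pass_hz = 40,
                              order = 5) {
  stopifnot(inherits(rec, "recording"))
  if (!is.null(downsample_to) && downsample_to < rec$fs) {
    factor <- rec$fs / downsample_to
    if (abs(factor - round(factor)) > 1e-9) {
      stop("input rate must be an integer multiple of the target rate")
    }
    rec <- downsample_recording(rec, round(factor))
  }
  fs <- rec$fs
  nyq <- fs / 2
  filters <- list()
  for (f0 in band_stop_hz) {
    edges <- c(f0 - stop_half_width_hz, f0 + stop_half_width_hz)
    if (edges[2] >= nyq) {
      warning(sprintf("band-stop at %g Hz reaches Nyquist (%g Hz); skipped", f0, nyq))
      next
    }
    filters[[length(filters) + 1L]] <- signal::butter(order, edges / nyq, "stop")
  }
  filters[[length(filters) + 1L]] <- signal::butter(order, high_pass_hz / nyq, "high")
  filters[[length(filters) + 1L]] <- signal::butter(order, low_pass_hz / nyq, "low")
  dat <- rec$data
  for (bf in filters) {
    dat <- t(apply(dat, 1L, function(x) signal::filtfilt(bf, x)))
  }
  recording(dat, fs = fs, labels = rownames(rec$data), t0 = rec$t0,
    mask = rec$mask)
}

#' Epoch a recording and average over trials
#'
#' Cuts fixed windows around stimulus onsets (default -200 ms to +500 ms),
#' optionally keeps only a subset of trials (e.g. after saturation
#' rejection) and optionally randomly subsamples them to equalise trial
#' counts between conditions, then returns the per-channel mean waveform
#' and the one-sample t-statistic over trials at every channel-time point.
#' Channel-time points with zero variance across trials get `t = NA` and
#' the result is flagged `degenerate`.
#'
#' @param rec a [recording()] (preprocessed; see [preprocess_evoked()]).
#' @param events schedule with `onset_s`.
#' @param keep integer indices of trials to keep (default all usable).
#' @param n_subsample if non-`NULL`, randomly keep this many trials.
#' @param seed seed for the subsample draw.
#' @param pre_s,post_s epoch window, s.
#' @param baseline_correct subtract the pre-stimulus mean per trial and
#'   channel (default FALSE; the 2 Hz high-pass already centres trials).
#' @return An object of class `evoked_result`: list with `time` (s,
#'   relative to onset), `mean` and `t_stat` (channels x time),
#'   `n_trials`, `degenerate`.
#' @export
epoch_and_average <- function(rec, events, keep = NULL, n_subsample = NULL,
                              seed = 1L, pre_s = 0.2, post_s = 0.5,
                              baseline_correct = FALSE) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs
  win <- epoch_windows(events$onset_s, fs, rec$t0, ncol(rec$data), pre_s, post_s)
  usable <- which(win$usable)
  if (is.null(keep)) keep <- usable else keep <- intersect(keep, usable)
  if (length(keep) == 0L) stop("no usable trials in the keep set")
  if (!is.null(n_subsample) && n_subsample < length(keep)) {
    keep <- with_seed(seed, sort(sample(keep, n_subsample)))
  }
  nt <- win$hi[keep[1]] - win$lo[keep[1]] + 1L
  nch <- nrow(rec$data)
  cube <- array(0, dim = c(nch, nt, length(keep)))
  for (k in seq_along(keep)) {
    tr <- rec$data[, win$lo[keep[k]]:win$hi[keep[k]], drop = FALSE]
    if (baseline_correct) {
      base <- rowMeans(tr[, seq_len(round(pre_s * fs)), drop = FALSE])
      tr <- tr - base
    }
    cube[, , k] <- tr
  }
  m <- apply(cube, c(1, 2), mean)
  sdv <- apply(cube, c(1, 2), stats::sd)
  n <- length(keep)
  tmat <- m / (sdv / sqrt(n))
  degenerate <- any(sdv == 0)
  if (degenerate) tmat[sdv == 0] <- NA_real_
  rownames(m) <- rownames(tmat) <- rownames(rec$data)
  structure(
    list(
      time = (seq_len(nt) - 1L) / fs - round(pre_s * fs) / fs,
      mean = m, t_stat = tmat, n_trials = n,
      degenerate = degenerate, trials = keep
    ),
    class = "evoked_result"
  )
}

#' @export
print.evoked_result <- function(x, ...) {
  cat(sprintf(
    "<evoked_result> %d channels, %.0f..%.0f ms, %d trials%s\n",
    nrow(x$mean), 1000 * min(x$time), 1000 * max(x$time), x$n_trials,
    if (x$degenerate) " (degenerate variance at some points)" else ""
  ))
  invisible(x)
}

#' SNR change between two evoked results
#'
#' SNR is the square of the maximum absolute t-statistic over channels and
#' time within the response window (default 95-105 ms), a power ratio.
#' Returns the percent change from `a` to `b`:
#' `100 * (max|t_b|^2 - max|t_a|^2) / max|t_a|^2`.
#'
#' @param a,b [epoch_and_average()] results (e.g. feedback off and on).
#' @param window response window in seconds (default `c(0.095, 0.105)`).
#' @return Percent SNR change (scalar); the two SNRs are attached as
#'   attributes `snr_a`, `snr_b`.
#' @export
snr_ratio <- function(a, b, window = c(0.095, 0.105)) {
  peak_t2 <- function(ev) {
    sel <- ev$time >= window[1] & ev$time <= window[2]
    if (!any(sel)) stop("response window not covered by the epoch")
    max(abs(ev$t_stat[, sel]), na.rm = TRUE)^2
  }
  sa <- peak_t2(a)
  sb <- peak_t2(b)
  structure(100 * (sb - sa) / sa, snr_a = sa, snr_b = sb)
}

#' Project averaged data to source time series
#'
#' `X = pinv(L) Y`: least-squares projection of the averaged sensor data
#' onto user-supplied lead fields (e.g. the two auditory-cortex lead
#' fields of a forward model). If the data were HFC-denoised, correct the
#' lead fields with [correct_lead_fields()] first.
#'
#' @param L channels x sources lead-field matrix.
#' @param evoked an [epoch_and_average()] result (its `mean` is used), or
#'   a channels x time matrix.
#' @return sources x time matrix.
#' @export
source_timeseries <- function(L, evoked) {
  Y <- if (inherits(evoked, "evoked_result")) evoked$mean else as.matrix(evoked)
  L <- as.matrix(L)
  if (nrow(L) != nrow(Y)) stop("lead-field rows must match data channels")
  pinv_svd(L)$pinv %*% Y
}

#' Write PSD / mSF tables as TSV
#'
#' @param x a `psd_result` or the data frame from
#'   [median_shielding_factor()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path) {
  df <- if (inherits(x, "psd_result")) {
    out <- data.frame(frequency = x$frequencies, t(x$asd), check.names = FALSE)
    names(out)[-1] <- if (!is.null(x$labels)) x$labels else {
      sprintf("ch%02d", seq_len(nrow(x$asd)))
    }
    out
  } else {
    as.data.frame(x)
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
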