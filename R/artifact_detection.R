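#' Detect saturated samples by amplitude histogram
#'
#' The OPM saturation level is only approximately known and varies between
#' sensors, so saturation is detected from each channel's own amplitude
#' distribution: the block is discretised by amplitude into 1 pT bins
#' (ignoring time). Clipping piles samples into the extreme bins, so if the
#' top `tail_bins` bins together hold more than `ratio` times the count of
#' the adjacent previous `tail_bins` bins, those top bins are marked
#' saturated (likewise the bottom bins). Samples falling in marked bins are
#' masked, but only if their magnitude is at least `floor` (1 nT): no
#' sample below the floor can be marked, which suppresses spurious
#' detections when the data are not approximately Gaussian.
#'
#' The comparison is strict ("more than" `ratio` times); a tail exactly at
#' the ratio is not marked. Channels with fewer than `10 * tail_bins`
#' occupied bins (including constant channels) are skipped with a warning.
#'
#' @param block a [recording()] (one experiment block).
#' @param bin_width histogram bin width, T (default 1e-12).
#' @param tail_bins bins per tail (default 5).
#' @param ratio detection threshold on the tail/previous count ratio
#'   (default 2).
#' @param floor minimum magnitude a sample must have to be maskable, T
#'   (default 1e-9).
#' @return An object of class `saturation_report`: list with `mask`
#'   (channels x samples logical), `channel` (per-channel list of marked
#'   amplitude ranges, T), `skipped` (labels of channels not assessed).
#' @export
detect_saturation <- function(block, bin_width = 1e-12, tail_bins = 5L,
                              ratio = 2.0, floor = 1e-9) {
  stopifnot(inherits(block, "recording"), bin_width > 0, tail_bins >= 1)
  dat <- block$data
  nch <- nrow(dat)
  mask <- matrix(FALSE, nch, ncol(dat))
  ranges <- vector("list", nch)
  names(ranges) <- rownames(dat)
  skipped <- character(0)
  for (i in seq_len(nch)) {
    x <- dat[i, ]
    lo <- min(x)
    hi <- max(x)
    ranges[[i]] <- list()
    if (hi - lo < bin_width) {
      skipped <- c(skipped, rownames(dat)[i])
      warning(sprintf("channel %s is (near) constant; saturation not assessed",
        rownames(dat)[i]))
      next
    }
    # bins anchored at the data minimum; empty interior bins count as zero
    nbins <- as.integer(ceiling((hi - lo) / bin_width)) + 1L
    bin <- pmin(nbins, pmax(1L, floor((x - lo) / bin_width) + 1L))
    counts <- tabulate(bin, nbins)
    if (sum(counts > 0L) < 10L * tail_bins) {
      skipped <- c(skipped, rownames(dat)[i])
      warning(sprintf(
        "channel %s occupies %d bins (< %d); saturation not assessed",
        rownames(dat)[i], sum(counts > 0L), 10L * tail_bins
      ))
      next
    }
    top <- (nbins - tail_bins + 1L):nbins
    top_prev <- top - tail_bins
    bot <- 1L:tail_bins
    bot_prev <- bot + tail_bins
    marked_bins <- integer(0)
    if (sum(counts[top]) > ratio * sum(counts[top_prev])) {
      marked_bins <- c(marked_bins, top)
      ranges[[i]] <- c(ranges[[i]], list(c(
        lo + (top[1] - 1L) * bin_width, hi
      )))
    }
    if (sum(counts[bot]) > ratio * sum(counts[bot_prev])) {
      marked_bins <- c(marked_bins, bot)
      ranges[[i]] <- c(ranges[[i]], list(c(
        lo, lo + bot[tail_bins] * bin_width
      )))
    }
    if (length(marked_bins) > 0L) {
      mask[i, ] <- (bin %in% marked_bins) & (abs(x) >= floor)
    }
  }
  rownames(mask) <- rownames(dat)
  structure(
    list(
      mask = mask, channel = ranges, skipped = skipped,
      bin_width = bin_width, tail_bins = tail_bins,
      ratio = ratio, floor = floor
    ),
    class = "saturation_report"
  )
}

#' @export
print.saturation_report <- function(x, ...) {
  nmarked <- sum(vapply(x$channel, length, 0L) > 0L)
  cat(sprintf(
    "<saturation_report> %d/%d channels with saturated amplitude ranges; %.2f%% of samples masked\n",
    nmarked, nrow(x$mask), 100 * mean(x$mask)
  ))
  if (length(x$skipped) > 0L) {
    cat("  skipped channels:", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

# Internal: sample-index windows for each stimulus onset.
epoch_windows <- function(onsets, fs, t0, n, pre_s = 0.2, post_s = 0.5) {
  i_on <- round((onsets - t0) * fs) + 1L
  lo <- i_on - round(pre_s * fs)
  hi <- i_on + round(post_s * fs)
  ok <- lo >= 1L & hi <= n
  data.frame(onset_s = onsets, lo = lo, hi = hi, usable = ok)
}

#' Reject trials containing saturated samples
#'
#' A trial is rejected if any sample of any channel inside its window
#' (default -200 ms to +500 ms around the tone) is masked as saturated.
#'
#' @param events a [make_stimuli()] schedule (or any data frame with an
#'   `onset_s` column).
#' @param report a [detect_saturation()] report (or any logical channels x
#'   samples mask).
#' @param fs sampling rate of the mask's time base, Hz.
#' @param t0 time of the mask's first sample, s.
#' @param pre_s,post_s epoch window, s.
#' @return List with `kept` and `rejected` (integer trial indices) and the
#'   per-trial logical `rejected_flag` (trials whose window falls outside
#'   the recording are dropped entirely and flagged `NA`).
#' @export
reject_trials <- function(events, report, fs, t0 = 0,
                          pre_s = 0.2, post_s = 0.5) {
  mask <- if (inherits(report, "saturation_report")) report$mask else report
  win <- epoch_windows(events$onset_s, fs, t0, ncol(mask), pre_s, post_s)
  anysat <- colSums(mask) > 0L
  flag <- rep(NA, nrow(win))
  for (k in seq_len(nrow(win))) {
    if (!win$usable[k]) next
    flag[k] <- any(anysat[win$lo[k]:win$hi[k]])
  }
  list(
    kept = which(!is.na(flag) & !flag),
    rejected = which(!is.na(flag) & flag),
    rejected_flag = flag
  )
}

#' Classify trials by distance from the room centre
#'
#' A trial is "outside" if at any within-trial time point the tracked head
#' position lies outside the given horizontal radius from the room centre.
#' Linearly interpolated motion samples (gaps shorter than 0.2 s) are
#' trusted; any within-trial sample belonging to a longer, cubic-filled
#' gap forces the trial to "outside" regardless of the interpolated
#' values, as does any unfilled gap.
#'
#' @param events schedule with `onset_s`.
#' @param traj a gap-filled trajectory from [fill_gaps()] (columns
#'   `interpolated`, `gap_s` used to grade trust).
#' @param radius metres (default 0.5).
#' @param linear_max_s trust threshold matching [fill_gaps()] (default
#'   0.2).
#' @param pre_s,post_s epoch window, s.
#' @return Character vector per trial: `"inside"` or `"outside"` (`NA` if
#'   the window is not covered by the trajectory).
#' @export
classify_trials_by_radius <- function(events, traj, radius = 0.5,
                                      linear_max_s = 0.2,
                                      pre_s = 0.2, post_s = 0.5) {
  tt <- traj$time_s
  r <- sqrt(traj$x_m^2 + traj$y_m^2)
  untrusted <- traj$tracked != 1L &
    (is.na(traj$x_m) |
      (if (!is.null(traj$gap_s)) traj$gap_s >= linear_max_s else FALSE))
  out <- character(nrow(events))
  for (k in seq_len(nrow(events))) {
    w <- tt >= events$onset_s[k] - pre_s & tt <= events$onset_s[k] + post_s
    if (!any(w)) {
      out[k] <- NA_character_
      next
    }
    if (any(untrusted[w]) || any(r[w] > radius, na.rm = TRUE)) {
      out[k] <- "outside"
    } else {
      out[k] <- "inside"
    }
  }
  out
}

#' Trial-count summary table by radius and feedback condition
#'
#' Crosses the inside/outside classification with the saturation-rejection
#' outcome for one condition, in the unsaturated/total layout used to
#' report feedback performance.
#'
#' @param classification output of [classify_trials_by_radius()].
#' @param rejection output of [reject_trials()] for the same trials.
#' @return Data frame with rows inside/outside and columns `unsaturated`,
#'   `total`.
#' @export
trial_count_table <- function(classification, rejection) {
  ok <- !is.na(classification) & !is.na(rejection$rejected_flag)
  cls <- classification[ok]
  rej <- rejection$rejected_flag[ok]
  data.frame(
    region = c("inside", "outside"),
    unsaturated = c(sum(cls == "inside" & !rej), sum(cls == "outside" & !rej)),
    total = c(sum(cls == "inside"), sum(cls == "outside"))
  )
}

#' Write a saturation mask and summary
#'
#' Writes a long-format TSV (`time_s`, `channel`, `flag`) of masked samples
#' and a JSON summary of per-channel saturated amplitude ranges.
#'
#' @param report a [detect_saturation()] report.
#' @param rec the [recording()] the report was computed from.
#' @param tsv_path,json_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the summary list.
#' @export
write_saturation_report <- function(report, rec, tsv_path = NULL,
                                    json_path = NULL) {
  stopifnot(inherits(report, "saturation_report"))
  if (!is.null(tsv_path)) {
    idx <- which(report$mask, arr.ind = TRUE)
    df <- data.frame(
      time_s = sample_times(rec)[idx[, 2]],
      channel = rownames(report$mask)[idx[, 1]],
      flag = rep(1L, nrow(idx))
    )
    df <- df[order(df$time_s, df$channel), ]
    utils::write.table(df, tsv_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  summary <- list(
    n_channels = nrow(report$mask),
    masked_fraction = mean(report$mask),
    skipped_channels = report$skipped,
    saturated_ranges_T = report$channel[vapply(report$channel, length, 0L) > 0L]
  )
  if (!is.null(json_path)) {
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(summary)
}
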