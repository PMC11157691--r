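#' Rigid OPM sensor array
#'
#' A `sensor_array` describes the rigid geometry of a multichannel OPM array:
#' one row per recording channel, with its position (m) and unit orientation
#' in a coordinate frame fixed to the array (e.g. the scanner-cast frame),
#' the sensitive-axis tag (`"Y"` = radial, `"Z"` = tangential for dual-axis
#' sensors), and whether the channel's on-board coil is used for feedback.
#' Channel order is stable and defines the row order of every matrix built
#' from the array.
#'
#' @param channels data frame with columns `label`, `x`, `y`, `z` (m),
#'   `ox`, `oy`, `oz` (unit orientation), `axis` (`"Y"` or `"Z"`) and
#'   `feedback` (logical).
#' @param frame character tag naming the rigid frame (default
#'   `"scanner-cast"`).
#' @return An object of class `sensor_array`.
#' @examples
#' arr <- example_scanner_cast_array(n_opms = 4)
#' n_channels(arr)
#' @export
sensor_array <- function(channels, frame = "scanner-cast") {
  stopifnot(is.data.frame(channels))
  needed <- c("label", "x", "y", "z", "ox", "oy", "oz", "axis", "feedback")
  missing <- setdiff(needed, names(channels))
  if (length(missing) > 0L) {
    stop("sensor layout is missing column(s): ", paste(missing, collapse = ", "))
  }
  channels$label <- as.character(channels$label)
  channels$axis <- as.character(channels$axis)
  channels$feedback <- as.logical(channels$feedback)
  if (anyDuplicated(channels$label)) {
    stop("channel labels must be unique")
  }
  if (!all(channels$axis %in% c("Y", "Z"))) {
    stop("channel axis must be 'Y' or 'Z'")
  }
  onorm <- sqrt(channels$ox^2 + channels$oy^2 + channels$oz^2)
  if (any(abs(onorm - 1) > 1e-9)) {
    bad <- channels$label[abs(onorm - 1) > 1e-9]
    stop("orientations must have unit norm (1e-9): ", paste(bad, collapse = ", "))
  }
  obj <- list(channels = channels, frame = as.character(frame))
  class(obj) <- "sensor_array"
  obj
}

#' @export
print.sensor_array <- function(x, ...) {
  nfb <- sum(x$channels$feedback)
  cat(sprintf(
    "<sensor_array> %d channels (%d feedback-enabled), frame '%s'\n",
    nrow(x$channels), nfb, x$frame
  ))
  cat(sprintf(
    "  axes: %d Y (radial), %d Z (tangential)\n",
    sum(x$channels$axis == "Y"), sum(x$channels$axis == "Z")
  ))
  invisible(x)
}

#' Number of channels in a sensor array
#' @param array a [sensor_array()].
#' @return Integer channel count.
#' @export
n_channels <- function(array) {
  stopifnot(inherits(array, "sensor_array"))
  nrow(array$channels)
}

#' Channel positions of a sensor array
#' @param array a [sensor_array()].
#' @return channels x 3 matrix of positions (m).
#' @export
channel_positions <- function(array) {
  stopifnot(inherits(array, "sensor_array"))
  m <- as.matrix(array$channels[, c("x", "y", "z")])
  rownames(m) <- array$channels$label
  m
}

#' Channel orientations of a sensor array
#' @param array a [sensor_array()].
#' @return channels x 3 matrix of unit orientations.
#' @export
channel_orientations <- function(array) {
  stopifnot(inherits(array, "sensor_array"))
  m <- as.matrix(array$channels[, c("ox", "oy", "oz")])
  rownames(m) <- array$channels$label
  m
}

#' Channel labels of a sensor array
#' @param array a [sensor_array()].
#' @return Character vector of labels in channel order.
#' @export
channel_labels <- function(array) {
  stopifnot(inherits(array, "sensor_array"))
  array$channels$label
}

#' Indices of feedback-enabled channels
#' @param array a [sensor_array()].
#' @return Integer indices into the channel order.
#' @export
feedback_channels <- function(array) {
  stopifnot(inherits(array, "sensor_array"))
  which(array$channels$feedback)
}

#' Read a sensor layout from a JSON sidecar or TSV
#'
#' JSON layout:
#' `{"frame": "scanner-cast", "channels": [{"label": ..., "position_m":
#' [x,y,z], "orientation": [x,y,z], "axis": "Y"|"Z", "feedback": true}, ...]}`.
#' TSV layout: one header row with columns
#' `label, x, y, z, ox, oy, oz, axis, feedback`.
#'
#' @param path file path; format inferred from the `.json` extension,
#'   anything else is read as TSV.
#' @return A [sensor_array()].
#' @export
read_sensor_layout <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    spec <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    ch <- do.call(rbind, lapply(spec$channels, function(c0) {
      data.frame(
        label = c0$label,
        x = c0$position_m[[1]], y = c0$position_m[[2]], z = c0$position_m[[3]],
        ox = c0$orientation[[1]], oy = c0$orientation[[2]],
        oz = c0$orientation[[3]],
        axis = c0$axis, feedback = isTRUE(c0$feedback),
        stringsAsFactors = FALSE
      )
    }))
    frame <- if (!is.null(spec$frame)) spec$frame else "scanner-cast"
    sensor_array(ch, frame = frame)
  } else {
    ch <- utils::read.delim(path, stringsAsFactors = FALSE)
    sensor_array(ch)
  }
}

#' Write a sensor layout
#'
#' @param array a [sensor_array()].
#' @param path output path; `.json` writes the JSON sidecar form, anything
#'   else a TSV.
#' @return `path`, invisibly.
#' @export
write_sensor_layout <- function(array, path) {
  stopifnot(inherits(array, "sensor_array"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    ch <- array$channels
    spec <- list(
      frame = array$frame,
      channels = lapply(seq_len(nrow(ch)), function(i) {
        list(
          label = ch$label[i],
          position_m = c(ch$x[i], ch$y[i], ch$z[i]),
          orientation = c(ch$ox[i], ch$oy[i], ch$oz[i]),
          axis = ch$axis[i],
          feedback = ch$feedback[i]
        )
      })
    )
    jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(array$channels, path,
      sep = "\t", row.names = FALSE, quote = FALSE
    )
  }
  invisible(path)
}

#' Deterministic example scanner-cast array
#'
#' Builds a dual-axis OPM array on the upper hemisphere of a sphere of
#' radius `head_radius` centred at the origin of the array frame, using a
#' Fibonacci lattice so that any number of sensors gives reasonable
#' coverage. Each OPM contributes two channels: a radial `Y` channel
#' (oriented along the outward normal) and a tangential `Z` channel.
#'
#' @param n_opms number of dual-axis sensors (default 17, the auditory
#'   experiment layout size).
#' @param head_radius sphere radius in m (default 0.1).
#' @param feedback_opms indices of OPMs (not channels) whose coils feed
#'   back; default all.
#' @return A [sensor_array()] with `2 * n_opms` channels, all Y channels
#'   first ordering interleaved per sensor (Y then Z).
#' @export
example_scanner_cast_array <- function(n_opms = 17, head_radius = 0.1,
                                       feedback_opms = seq_len(n_opms)) {
  stopifnot(n_opms >= 2)
  golden <- (1 + sqrt(5)) / 2
  i <- seq_len(n_opms)
  # upper hemisphere: polar angle in (0, ~80 deg)
  zfrac <- 1 - (i - 0.5) / n_opms * 0.85
  theta <- acos(zfrac)
  phi <- 2 * pi * i / golden
  nx <- sin(theta) * cos(phi)
  ny <- sin(theta) * sin(phi)
  nz <- cos(theta)
  rows <- vector("list", 2L * n_opms)
  for (k in i) {
    pos <- head_radius * c(nx[k], ny[k], nz[k])
    radial <- c(nx[k], ny[k], nz[k])
    # tangential direction: project global +x (or +y near the pole) onto
    # the tangent plane
    ref <- if (abs(radial[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    tang <- ref - sum(ref * radial) * radial
    tang <- tang / sqrt(sum(tang^2))
    fb <- k %in% feedback_opms
    rows[[2L * k - 1L]] <- data.frame(
      label = sprintf("OPM%02d-Y", k),
      x = pos[1], y = pos[2], z = pos[3],
      ox = radial[1], oy = radial[2], oz = radial[3],
      axis = "Y", feedback = fb, stringsAsFactors = FALSE
    )
    rows[[2L * k]] <- data.frame(
      label = sprintf("OPM%02d-Z", k),
      x = pos[1], y = pos[2], z = pos[3],
      ox = tang[1], oy = tang[2], oz = tang[3],
      axis = "Z", feedback = fb, stringsAsFactors = FALSE
    )
  }
  sensor_array(do.call(rbind, rows))
}

#' Example environmental-noise array
#'
#' 21 dual-axis OPMs (42 channels) with feedback enabled on 11 of them
#' (22 channels), mirroring the empty-room noise-recording layout where
#' feedback-on and feedback-off channels are recorded simultaneously.
#'
#' @return A [sensor_array()].
#' @export
example_noise_array <- function() {
  example_scanner_cast_array(n_opms = 21, feedback_opms = 1:11)
}
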