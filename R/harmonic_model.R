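#' @keywords internal
#' SVD pseudo-inverse with a relative singular-value cutoff.
#'
#' Directions whose singular value falls below `rtol * max(singular values)`
#' are dropped (treated as zero) and reported via the `dropped` element, so
#' a near-degenerate array geometry degrades gracefully instead of
#' amplifying noise.
pinv_svd <- function(A, rtol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > rtol * sv$d[1]
  r <- sum(keep)
  if (r == 0L) stop("matrix is numerically zero; cannot form pseudo-inverse")
  pinv <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  list(pinv = pinv, rank = r, dropped = ncol(A) - r, d = sv$d)
}

# Harmonic polynomials of degree 2 whose gradients span the five independent
# traceless-symmetric linear field-gradient terms:
#   xy, xz, yz, x^2 - y^2, 2 z^2 - x^2 - y^2.
# grad_terms(p) returns the 3 x 5 matrix of gradient fields at position p.
grad_terms <- function(p) {
  x <- p[1]; y <- p[2]; z <- p[3]
  cbind(
    c(y, x, 0),            # d/dr (xy)
    c(z, 0, x),            # d/dr (xz)
    c(0, z, y),            # d/dr (yz)
    c(2 * x, -2 * y, 0),   # d/dr (x^2 - y^2)
    c(-2 * x, -2 * y, 4 * z) # d/dr (2 z^2 - x^2 - y^2)
  )
}

#' Build the interference basis for a sensor array
#'
#' Constructs the matrix `N` whose columns span the field patterns the
#' background-interference model can express, evaluated at the array's
#' channels. At order 1 the model is a spatially homogeneous field, so row
#' `i` is simply the channel orientation and `N` is position-independent.
#' At order 2 five columns are appended for the independent linear field
#' gradients (gradients of the degree-2 harmonic polynomials `xy, xz, yz,
#' x^2 - y^2, 2z^2 - x^2 - y^2`), evaluated at the channel positions and
#' projected onto the channel orientations.
#'
#' @param array a [sensor_array()].
#' @param order 1 (homogeneous) or 2 (homogeneous + linear gradients).
#' @return channels x terms numeric matrix (3 columns at order 1, 8 at
#'   order 2), rows in array channel order.
#' @export
build_basis <- function(array, order = 1) {
  stopifnot(inherits(array, "sensor_array"))
  if (!order %in% c(1, 2)) stop("order must be 1 or 2")
  O <- channel_orientations(array)
  nterms <- if (order == 1) 3L else 8L
  if (nrow(O) < nterms) {
    stop(sprintf(
      "rank deficiency: %d channels cannot support a %d-term order-%d basis",
      nrow(O), nterms, order
    ))
  }
  if (order == 1) {
    N <- O
  } else {
    P <- channel_positions(array)
    G <- t(vapply(
      seq_len(nrow(O)),
      function(i) as.numeric(O[i, ] %*% grad_terms(P[i, ])),
      numeric(5)
    ))
    N <- cbind(O, G)
  }
  colnames(N) <- c("Bx", "By", "Bz", if (order == 2) {
    c("g_xy", "g_xz", "g_yz", "g_xx-yy", "g_2zz")
  })
  rownames(N) <- channel_labels(array)
  N
}

#' Fit the background-field model to one multichannel sample
#'
#' Least-squares fit of the harmonic coefficients to a channel vector:
#' `b = pinv(N) y`, the minimiser of ||N b - y||. At order 1 the
#' coefficients are the homogeneous background field `[Bx, By, Bz]` (T).
#' Saturated samples are the caller's responsibility: drop the affected
#' rows of both `N` and `y` before fitting rather than imputing them.
#'
#' @param N basis matrix from [build_basis()].
#' @param y numeric channel vector (T), or a channels x samples matrix for
#'   many fits at once.
#' @return A `field_model`: list with `order` and `coefficients` (a vector,
#'   or terms x samples matrix if `y` was a matrix).
#' @export
fit_field_model <- function(N, y) {
  y <- as.matrix(y)
  if (nrow(y) != nrow(N)) stop("length of y must equal the number of rows of N")
  if (anyNA(y)) stop("y contains NA/NaN; mask or remove saturated samples before fitting")
  pv <- pinv_svd(N)
  if (pv$rank < ncol(N)) {
    stop(sprintf(
      "degenerate array geometry: basis rank %d < %d terms (e.g. coplanar orientations)",
      pv$rank, ncol(N)
    ))
  }
  b <- pv$pinv %*% y
  coefs <- if (ncol(b) == 1L) drop(b) else b
  structure(
    list(order = if (ncol(N) == 3L) 1L else 2L, coefficients = coefs),
    class = "field_model"
  )
}

#' @export
print.field_model <- function(x, ...) {
  cat(sprintf("<field_model> order %d\n", x$order))
  if (is.matrix(x$coefficients)) {
    cat(sprintf("  %d fitted samples\n", ncol(x$coefficients)))
  } else {
    cat("  coefficients (T):", format(x$coefficients, digits = 4), "\n")
  }
  invisible(x)
}

#' Build the HFC feedback and denoising projectors
#'
#' From the array geometry, forms the recording-orientation basis `N`, the
#' feedback-coil orientation matrix `M` (the rows of `N` belonging to
#' feedback-enabled channels — on these sensors the coils share the
#' recording-channel orientations), the SVD pseudo-inverse of `N`, the
#' feedback projector `M pinv(N)` mapping a channel vector to the field to
#' feed back at each coil, and the denoising projector `I - N pinv(N)`
#' that removes the modelled interference from data offline.
#'
#' Because the array is rigid, these matrices are constant in the array
#' frame regardless of participant movement and can be precomputed.
#'
#' @param array a [sensor_array()].
#' @param order basis order, 1 or 2 (see [build_basis()]).
#' @return An object of class `hfc_projector` with elements `N`, `M`,
#'   `pinvN`, `feedback_matrix`, `denoise_matrix`, `feedback_idx`, `order`,
#'   `dropped` (count of SVD directions below the cutoff).
#' @export
hfc_projector <- function(array, order = 1) {
  N <- build_basis(array, order)
  idx <- feedback_channels(array)
  M <- N[idx, , drop = FALSE]
  pv <- pinv_svd(N)
  if (pv$dropped > 0L) {
    warning(sprintf(
      "%d basis direction(s) below the singular-value cutoff were dropped",
      pv$dropped
    ))
  }
  obj <- list(
    N = N, M = M, pinvN = pv$pinv,
    feedback_matrix = M %*% pv$pinv,
    denoise_matrix = diag(nrow(N)) - N %*% pv$pinv,
    feedback_idx = idx, order = order, dropped = pv$dropped,
    labels = rownames(N), axes = array$channels$axis
  )
  class(obj) <- "hfc_projector"
  obj
}

#' @export
print.hfc_projector <- function(x, ...) {
  cat(sprintf(
    "<hfc_projector> order %d: %d channels, %d basis terms, %d feedback channels\n",
    x$order, nrow(x$N), ncol(x$N), length(x$feedback_idx)
  ))
  invisible(x)
}

#' Desired feedback fields for one estimated-field vector
#'
#' The control law of the loop: given `u`, the per-channel estimate of the
#' field that would be seen with no feedback applied, returns
#' `M pinv(N) u` — the model's prediction of the interference at each
#' feedback coil, i.e. the field each coil should null. Rows follow the
#' feedback-channel subset of the array channel order.
#'
#' @param proj an [hfc_projector()].
#' @param u numeric vector of length `nrow(N)` (or channels x samples
#'   matrix).
#' @return Numeric vector (or matrix) with one row per feedback channel.
#' @export
desired_feedback <- function(proj, u) {
  stopifnot(inherits(proj, "hfc_projector"))
  u <- as.matrix(u)
  if (nrow(u) != nrow(proj$N)) {
    stop("u must have one entry per channel (rows of N)")
  }
  out <- proj$feedback_matrix %*% u
  if (ncol(out) == 1L) drop(out) else out
}

#' Apply HFC denoising to a recording offline
#'
#' Replaces every sample by `(I - N pinv(N)) sample`, removing the
#' component explained by the interference basis. The residual at each
#' time point is orthogonal to the basis columns. The same operator is
#' applied whether or not real-time feedback was active during the
#' recording, so that conditions remain comparable.
#'
#' @param proj an [hfc_projector()].
#' @param data a [recording()] whose channels match the projector's rows.
#' @return A [recording()] of identical shape with the modelled
#'   interference removed.
#' @export
apply_hfc_offline <- function(proj, data) {
  stopifnot(inherits(proj, "hfc_projector"), inherits(data, "recording"))
  if (nrow(data$data) != nrow(proj$N)) {
    stop("recording channel count does not match projector")
  }
  out <- data
  out$data <- proj$denoise_matrix %*% data$data
  dimnames(out$data) <- dimnames(data$data)
  out
}

#' Correct lead fields for HFC
#'
#' When measured data have been multiplied by the denoising projector, the
#' forward-model lead fields must be multiplied by the same matrix before
#' source analysis, otherwise the projected data and unprojected model are
#' inconsistent.
#'
#' @param proj an [hfc_projector()].
#' @param L channels x sources lead-field matrix.
#' @return The corrected lead-field matrix `denoise_matrix %*% L`.
#' @export
correct_lead_fields <- function(proj, L) {
  stopifnot(inherits(proj, "hfc_projector"))
  L <- as.matrix(L)
  if (nrow(L) != nrow(proj$N)) {
    stop("lead-field row count does not match projector channels")
  }
  proj$denoise_matrix %*% L
}
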