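test_that("order-1 basis is the orientation matrix", {
  ch <- data.frame(
    label = c("a", "b", "c"),
    x = 0, y = 0, z = 0,
    ox = c(1, 0, 0), oy = c(0, 1, 0), oz = c(0, 0, 1),
    axis = "Y", feedback = TRUE
  )
  arr <- sensor_array(ch)
  N <- build_basis(arr, 1)
  expect_equal(unname(N), diag(3))

  arr2 <- random_array(10)
  N2 <- build_basis(arr2, 1)
  expect_identical(ncol(N2), 3L)
  expect_equal(unname(N2), unname(channel_orientations(arr2)))

  expect_error(build_basis(sensor_array(ch[1:2, ]), 2), "rank")
})

test_that("order-2 gradient columns match finite differences of harmonic polynomials", {
  polys <- list(
    function(p) p[1] * p[2],
    function(p) p[1] * p[3],
    function(p) p[2] * p[3],
    function(p) p[1]^2 - p[2]^2,
    function(p) 2 * p[3]^2 - p[1]^2 - p[2]^2
  )
  fd_grad <- function(f, p, h = 1e-6) {
    vapply(1:3, function(i) {
      e <- numeric(3); e[i] <- h
      (f(p + e) - f(p - e)) / (2 * h)
    }, 0)
  }
  arr <- random_array(6, seed = 3)
  N <- build_basis(arr, 2)
  P <- channel_positions(arr)
  O <- channel_orientations(arr)
  for (i in seq_len(nrow(N))) {
    for (k in 1:5) {
      expect_equal(N[i, 3 + k], sum(O[i, ] * fd_grad(polys[[k]], P[i, ])),
        tolerance = 1e-6
      )
    }
  }
  # each gradient field solves Laplace's equation: zero divergence and curl
  for (k in 1:5) {
    f <- polys[[k]]
    p0 <- c(0.03, -0.05, 0.08)
    h <- 1e-4
    grad_at <- function(p) fd_grad(f, p, h = 1e-6)
    div <- sum(vapply(1:3, function(i) {
      e <- numeric(3); e[i] <- h
      (grad_at(p0 + e)[i] - grad_at(p0 - e)[i]) / (2 * h)
    }, 0))
    expect_lt(abs(div), 1e-4)
    curl_z <- {
      ex <- c(h, 0, 0); ey <- c(0, h, 0)
      (grad_at(p0 + ex)[2] - grad_at(p0 - ex)[2]) / (2 * h) -
        (grad_at(p0 + ey)[1] - grad_at(p0 - ey)[1]) / (2 * h)
    }
    expect_lt(abs(curl_z), 1e-4)
  }
})

test_that("field-model fit recovers homogeneous fields and matches normal equations", {
  arr <- random_array(5, seed = 7)
  N <- build_basis(arr, 1)
  B <- c(1.2e-9, -0.4e-9, 0.7e-9)
  fm <- fit_field_model(N, N %*% B)
  expect_equal(fm$coefficients, B, tolerance = 1e-12)
  expect_equal(fit_field_model(N, rep(0, nrow(N)))$coefficients, c(0, 0, 0),
    ignore_attr = TRUE
  )

  set.seed(42)
  y <- N %*% B + stats::rnorm(nrow(N), sd = 1e-11)
  oracle <- drop(solve(t(N) %*% N) %*% t(N) %*% y)
  expect_equal(unname(fit_field_model(N, y)$coefficients), unname(oracle),
    tolerance = 1e-10
  )

  expect_error(fit_field_model(N, c(NaN, rep(0, nrow(N) - 1L))), "NA/NaN")
  # coplanar orientations: rank-2 geometry
  ch <- data.frame(
    label = letters[1:4], x = 0, y = 0, z = 0,
    ox = c(1, 0, 0.7071067811865475, -0.7071067811865476),
    oy = c(0, 1, 0.7071067811865476, 0.7071067811865475), oz = 0,
    axis = "Y", feedback = TRUE
  )
  expect_error(
    suppressWarnings(fit_field_model(build_basis(sensor_array(ch), 1), rep(1e-9, 4))),
    "degenerate"
  )
})

test_that("desired feedback equals the two-step fit/predict oracle", {
  arr <- random_array(21, seed = 5, feedback_opms = 1:11) # 42 ch, 22 feedback
  proj <- hfc_projector(arr, 1)
  # u in the column space: projection returns it exactly at feedback rows
  B <- c(2e-10, 1e-10, -3e-10)
  u <- drop(proj$N %*% B)
  expect_equal(desired_feedback(proj, u), u[proj$feedback_idx], tolerance = 1e-12)
  # orthogonal u: zero feedback
  up <- orthogonal_vector(proj$N, seed = 2)
  expect_lt(max(abs(desired_feedback(proj, up))), 1e-10 * sqrt(sum(up^2)))
  # subset layout vs explicit fit-then-predict
  set.seed(9)
  u2 <- stats::rnorm(nrow(proj$N), sd = 1e-10)
  fit <- drop(solve(t(proj$N) %*% proj$N) %*% t(proj$N) %*% u2)
  oracle <- drop(proj$M %*% fit)
  fb <- desired_feedback(proj, u2)
  expect_length(fb, 22L)
  expect_equal(unname(fb), unname(oracle), tolerance = 1e-12)
})

test_that("offline HFC removes modelled interference and is idempotent", {
  arr <- random_array(12, seed = 11)
  proj <- hfc_projector(arr, 1)
  n <- nrow(proj$N)
  # homogeneous field time series -> ~0
  B <- matrix(stats::rnorm(3 * 50, sd = 1e-9), 3, 50)
  rec <- recording(proj$N %*% B, fs = 100)
  out <- apply_hfc_offline(proj, rec)
  expect_lt(max(abs(out$data)), 1e-9 * 1e-10)
  # data orthogonal to the basis pass unchanged
  xo <- orthogonal_vector(proj$N, seed = 3)
  rec2 <- recording(outer(xo, sin(1:40)), fs = 100)
  out2 <- apply_hfc_offline(proj, rec2)
  expect_equal(out2$data, rec2$data, tolerance = 1e-10)
  # random data vs per-sample loop oracle, plus residual orthogonality
  set.seed(13)
  X <- matrix(stats::rnorm(n * 30, sd = 1e-10), n, 30)
  rec3 <- recording(X, fs = 100)
  out3 <- apply_hfc_offline(proj, rec3)
  oracle <- X
  for (s in seq_len(ncol(X))) {
    b <- solve(t(proj$N) %*% proj$N) %*% t(proj$N) %*% X[, s]
    oracle[, s] <- X[, s] - proj$N %*% b
  }
  expect_equal(unname(out3$data), unname(oracle), tolerance = 1e-12)
  inner <- t(proj$N) %*% out3$data
  expect_lt(max(abs(inner)), 1e-10 * max(sqrt(colSums(X^2))))
  # idempotence
  twice <- apply_hfc_offline(proj, out3)
  expect_equal(twice$data, out3$data, tolerance = 1e-10)
})

test_that("lead-field correction agrees with column-wise denoising", {
  arr <- random_array(10, seed = 17)
  proj <- hfc_projector(arr, 1)
  n <- nrow(proj$N)
  # columns inside the model space vanish
  Lin <- proj$N %*% matrix(stats::rnorm(6), 3, 2)
  expect_lt(max(abs(correct_lead_fields(proj, Lin))), 1e-9 * max(abs(Lin)))
  # orthogonal columns unchanged
  Lo <- cbind(orthogonal_vector(proj$N, 4), orthogonal_vector(proj$N, 5))
  expect_equal(correct_lead_fields(proj, Lo), Lo,
    tolerance = 1e-10, ignore_attr = TRUE
  )
  # random L: column oracle via apply_hfc_offline
  set.seed(19)
  L <- matrix(stats::rnorm(n * 3), n, 3)
  viaRec <- apply_hfc_offline(proj, recording(L, fs = 1))$data
  expect_equal(unname(correct_lead_fields(proj, L)), unname(viaRec),
    tolerance = 1e-12
  )
  expect_error(correct_lead_fields(proj, L[-1, ]), "row count")
})

test_that("fitted coefficients are frame covariant", {
  arr <- random_array(8, seed = 23)
  # random rotation via QR of a random matrix
  set.seed(29)
  R <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  ch <- arr$channels
  P <- as.matrix(ch[, c("x", "y", "z")]) %*% t(R)
  O <- as.matrix(ch[, c("ox", "oy", "oz")]) %*% t(R)
  ch2 <- ch
  ch2[, c("x", "y", "z")] <- P
  ch2[, c("ox", "oy", "oz")] <- O
  arr2 <- sensor_array(ch2)
  B <- c(0.9e-9, -0.2e-9, 0.5e-9)
  y <- build_basis(arr, 1) %*% B # same channel readings in either frame
  b1 <- fit_field_model(build_basis(arr, 1), y)$coefficients
  b2 <- fit_field_model(build_basis(arr2, 1), y)$coefficients
  expect_equal(unname(b2), unname(drop(R %*% b1)), tolerance = 1e-9)
})

test_that("projection cannot increase white-noise energy and fit errors match least-squares theory", {
  arr <- random_array(12, seed = 31) # 24 channels
  proj <- hfc_projector(arr, 1)
  n <- nrow(proj$N)
  set.seed(37)
  X <- matrix(stats::rnorm(n * 2000), n, 2000)
  Y <- proj$denoise_matrix %*% X
  expect_true(all(apply(Y, 1, stats::var) <= apply(X, 1, stats::var)))

  # RMSE of fitted coefficients vs closed-form covariance sigma^2 (N'N)^-1
  sigma <- 1e-12
  B <- c(3e-10, -1e-10, 2e-10)
  set.seed(41)
  E <- matrix(stats::rnorm(n * 1000, sd = sigma), n, 1000)
  fits <- fit_field_model(proj$N, drop(proj$N %*% B) + E)$coefficients
  emp_var <- apply(fits - B, 1, function(v) mean(v^2))
  theo_var <- sigma^2 * diag(solve(t(proj$N) %*% proj$N))
  expect_equal(unname(emp_var), unname(theo_var), tolerance = 0.2)
})
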