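test_that("centering removes per-channel means and records them", {
  out <- center_channels(matrix(c(1, 2, 3, 2), 2))
  expect_equal(out$x, matrix(c(-1, 0, 1, 0), 2))
  expect_equal(out$mean, c(2, 2))

  z <- matrix(0, 2, 10)
  expect_equal(center_channels(z)$x, z)

  set.seed(1)
  big <- matrix(rnorm(4 * 10000, mean = 5), 4)
  expect_lt(max(abs(rowMeans(center_channels(big)$x))), 1e-10)

  bad <- matrix(c(1, NA, 2, 3, 1, 1), 2)
  expect_error(center_channels(bad), "non-finite")
})

test_that("whitening yields identity covariance and orthonormal eigenvectors", {
  set.seed(2)
  A <- matrix(c(2, 1.5, 0.5, 1), 2)
  x <- A %*% matrix(rnorm(2 * 5000), 2)
  out <- whiten_channels(center_channels(x)$x)
  n <- ncol(out$z)
  expect_equal(tcrossprod(out$z) / (n - 1), diag(2), tolerance = 1e-6)
  expect_equal(crossprod(out$model$E), diag(2), tolerance = 1e-8)

  # already-white input stays white and the transform is near-orthonormal
  w2 <- whiten_channels(center_channels(out$z)$x)
  expect_equal(tcrossprod(w2$z) / (n - 1), diag(2), tolerance = 1e-6)
  expect_equal(crossprod(w2$model$transform), diag(2), tolerance = 1e-4)

  dup <- rbind(x[1, ], x[1, ], x[2, ])
  expect_error(whiten_channels(center_channels(dup)$x), "rank deficient")
})

test_that("cubic contrast and its derivative", {
  expect_equal(contrast_cube(2), list(g = 8, gprime = 12))
  expect_equal(contrast_cube(0), list(g = 0, gprime = 0))
  expect_equal(contrast_cube(c(-1, 1)), list(g = c(-1, 1), gprime = c(3, 3)))
})

test_that("residual matches a brute-force oracle and is orthogonal to w", {
  z <- matrix(c(1, 1, -1, 1), 2) / sqrt(1)
  w <- c(1, 0)
  got <- ica_residual(w, z)
  want <- oracle_residual(w, z)
  expect_equal(got$f, want$f, tolerance = 1e-12)
  expect_equal(got$jf, want$jf, tolerance = 1e-12)

  wh <- fix_whitened()
  set.seed(3)
  for (i in 1:5) {
    w <- rnorm(4); w <- w / sqrt(sum(w^2))
    r <- ica_residual(w, wh$z)
    # beta is the projection of E{x g} onto w, so F is orthogonal to w
    expect_lt(abs(sum(r$f * w)), 1e-8)
  }
})

test_that("residual vanishes on Gaussian data up to sampling noise", {
  set.seed(4)
  n <- 100000
  z <- matrix(rnorm(2 * n), 2)
  z <- whiten_channels(center_channels(z)$x)$z
  w <- c(1, 0)
  r <- ica_residual(w, z)
  expect_lt(sqrt(sum(r$f^2)), 5 / sqrt(n))
})

test_that("conventional update has unit norm and fixes true directions", {
  u2 <- fix_uniform2()
  for (i in 1:2) {
    w <- u2$Wtrue[i, ]
    wn <- ica_update(w, u2$z)
    expect_equal(sum(wn^2), 1, tolerance = 1e-12)
    expect_lt(angular_distance(wn, w), 2e-3)
  }

  # repeated application converges: successive iterates align
  set.seed(5)
  w <- rnorm(2); w <- w / sqrt(sum(w^2))
  for (k in 1:50) {
    wn <- ica_update(w, u2$z)
    step <- min(sqrt(sum((wn - w)^2)), sqrt(sum((wn + w)^2)))
    w <- wn
    if (step < 1e-8) break
  }
  expect_lt(step, 1e-8)
})

test_that("overrelaxation selection equals the exhaustive grid oracle", {
  wh <- fix_whitened()
  set.seed(6)
  for (i in 1:5) {
    w <- rnorm(4); w <- w / sqrt(sum(w^2))
    expect_equal(select_relaxation(w, wh$z, N = 100),
                 oracle_relaxation(w, wh$z, N = 100))
  }
  # the candidate grid is 1.01 .. 1.99: returned values live there or at 1
  a <- select_relaxation(c(1, 0, 0, 0), wh$z, N = 100)
  expect_true(a == 1 || (a > 1 && a < 2 && abs(a * 100 - round(a * 100)) < 1e-9))
})

test_that("relaxation is inert at a converged direction", {
  wh <- fix_whitened()
  f4 <- fastica(fix_mixture()$X, method = "conventional", eps = 1e-9,
                max.iter = 2000, seed = 8)
  w <- f4$W[1, ]
  # the residual has already vanished ...
  expect_lt(sqrt(sum(ica_residual(w, wh$z)$f^2)), 1e-5)
  # ... so whatever alpha the grid settles on, the relaxed step stays put
  a <- select_relaxation(w, wh$z)
  expect_true(a == 1 || (a > 1 && a < 2))
  wn <- ica_update_relaxed(w, wh$z, a)
  expect_lt(min(sqrt(sum((wn - w)^2)), sqrt(sum((wn + w)^2))), 1e-4)
})

test_that("overrelaxed two-stage update converges to a true direction", {
  u2 <- fix_uniform2()
  set.seed(7)
  w <- rnorm(2); w <- w / sqrt(sum(w^2))
  alpha <- select_relaxation(w, u2$z)
  for (k in 1:200) {
    wn <- ica_update_relaxed(w, u2$z, alpha)
    expect_equal(sum(wn^2), 1, tolerance = 1e-12)
    step <- min(sqrt(sum((wn - w)^2)), sqrt(sum((wn + w)^2)))
    w <- wn
    if (step < 1e-6) break
  }
  d <- min(angular_distance(w, u2$Wtrue[1, ]), angular_distance(w, u2$Wtrue[2, ]))
  expect_lt(d, 2e-3)

  # the printed-plus variant is exposed and also returns a unit vector
  wp <- ica_update_relaxed(w, u2$z, alpha, sign = "plus")
  expect_equal(sum(wp^2), 1, tolerance = 1e-12)
})

test_that("full separation is orthonormal, deterministic and recovers mixing", {
  mx <- fix_mixture()
  fit <- fastica(mx$X, method = "improved", seed = 11)
  expect_equal(fit$W %*% t(fit$W), diag(4), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(rowSums(fit$W^2), rep(1, 4), tolerance = 1e-8,
               ignore_attr = TRUE)
  n <- ncol(fit$S)
  expect_equal(tcrossprod(fit$S) / (n - 1), diag(4), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_lt(amari_index(coef(fit), mx$A), 0.05)
  expect_equal(fit$total_iterations, sum(fit$iterations))

  fit2 <- fastica(mx$X, method = "improved", seed = 11)
  expect_identical(fit$W, fit2$W)
  expect_identical(fit$iterations, fit2$iterations)

  fitc <- fastica(mx$X, method = "conventional", seed = 11)
  expect_lt(amari_index(coef(fitc), mx$A), 0.05)
  expect_true(all(is.na(fitc$alpha)))
})

test_that("starting at a fixed point converges in one iteration", {
  mx <- fix_mixture()
  fit <- fastica(mx$X, method = "conventional", eps = 1e-5, seed = 12)
  W0 <- fit$W
  refit <- fastica(mx$X, n.comp = 4, method = "conventional", eps = 1e-3,
                   w.init = W0)
  expect_true(all(refit$converged))
  expect_equal(refit$iterations[1], 1L)
})

test_that("separation methods honour configuration validation", {
  mx <- fix_mixture()
  expect_error(fastica(mx$X, eps = 2), "eps")
  expect_error(fastica(mx$X, n.comp = 5), "n.comp")
  expect_error(fastica(mx$X, max.iter = 0), "max.iter")
  expect_error(fastica(mx$X, alpha.grid.N = 1), "alpha.grid.N")
})

test_that("coef/predict reproduce the separated sources", {
  mx <- fix_mixture()
  fit <- fastica(mx$X, seed = 13)
  expect_equal(predict(fit, mx$X), fit$S, tolerance = 1e-10)
  expect_equal(dim(coef(fit)), c(4, 4))
  sm <- summary(fit)
  expect_s3_class(sm, "summary.fastica")
  expect_equal(nrow(sm$table), 4)
})
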