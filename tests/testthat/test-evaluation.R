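test_that("segment matrix standardizes columns and applies boundary rules", {
  sim <- synth_ecg(fs = 500, duration_s = 20, hr_bpm = 70, jitter_pct = 0)
  U <- segment_matrix(sim$signal, sim$beats, pre_ms = 100, post_ms = 100)
  expect_equal(ncol(U), length(sim$beats))
  expect_equal(nrow(U), 0.2 * 500 + 1)
  expect_lt(max(abs(colMeans(U))), 1e-8)
  expect_equal(apply(U, 2, stats::var), rep(1, ncol(U)), tolerance = 1e-6)

  # a beat too close to the record start is dropped
  b2 <- beats(c(5, sim$beats$samples), fs = 500)
  U2 <- segment_matrix(sim$signal, b2, pre_ms = 100, post_ms = 100)
  expect_equal(ncol(U2), ncol(U))
  expect_equal(attr(U2, "dropped"), 1)

  flat <- beats(c(100, 200, 300), fs = 500)
  expect_error(
    suppressWarnings(segment_matrix(rep(1, 1000), flat, 50, 50)),
    "fewer than 2")
})

test_that("eigenvalue SNR closed forms and eigendecomposition oracle", {
  n <- 100
  u <- c(rep(1, 50), rep(-1, 50))
  v <- rep(c(1, -1), each = 25, times = 2)
  U <- cbind(u, v) / stats::sd(u)        # orthogonal, standardized
  expect_equal(snr_eig(U), 1.0)

  same <- cbind(u, u, u) / stats::sd(u)  # rank-1 Gram matrix
  expect_identical(snr_eig(same), Inf)

  set.seed(31)
  R <- matrix(rnorm(250 * 20), 250, 20)
  R <- scale(R)
  lam <- eigen(t(R) %*% R, symmetric = TRUE)$values  # independent recompute
  expect_equal(snr_eig(R), max(lam) / (sum(lam) - max(lam)), tolerance = 1e-12)
})

test_that("cross-correlation SNR closed forms and brute-force eta", {
  n <- 100
  u <- c(rep(1, 50), rep(-1, 50)) / 10   # unit norm, zero mean
  v <- rep(c(1, -1), each = 25, times = 2) / 10
  expect_lt(abs(sum(u * v)), 1e-12)

  # eta = 0.5 by construction: columns sqrt(3)u + v and sqrt(3)u - v
  U <- cbind(sqrt(3) * u + v, sqrt(3) * u - v)
  expect_equal(snr_rms(U), 1.0, tolerance = 1e-12)

  expect_identical(snr_rms(cbind(u, u, u)), Inf)
  expect_warning(got <- snr_rms(cbind(u, -u)), "non-positive")
  expect_equal(got, 0)

  # random correlated U: eta equals the explicit pairwise double sum
  set.seed(32)
  R <- scale(matrix(rnorm(80 * 6), 80, 6) +
               outer(sin(seq_len(80) / 5), rep(0.8, 6)))
  Rn <- sweep(R, 2, sqrt(colSums(R^2)), "/")
  M <- ncol(Rn)
  eta <- 0
  for (i in 1:(M - 1)) for (k in (i + 1):M) eta <- eta + sum(Rn[, i] * Rn[, k])
  eta <- 2 * eta / (M * (M - 1))
  expect_equal(snr_rms(R), eta / (1 - eta), tolerance = 1e-12)
})

test_that("beat matching is one-to-one within tolerance", {
  fs <- 1000
  r <- beats(c(100, 600, 1100), fs)
  m <- match_beats(r, r)
  expect_equal(c(m$TP, m$FP, m$FN), c(3, 0, 0))

  far <- beats(c(100, 600, 1100) + 200, fs)
  m2 <- match_beats(far, r, tol_ms = 50)
  expect_equal(c(m2$TP, m2$FP, m2$FN), c(0, 3, 3))

  # the toy instance matches an exhaustive optimal assignment
  det <- beats(c(100, 200), fs)
  ref <- beats(c(120, 500), fs)
  m3 <- match_beats(det, ref, tol_ms = 50)
  expect_equal(c(m3$TP, m3$FP, m3$FN), c(1, 1, 1))
  # brute force over all one-to-one assignments within tolerance
  best <- 0
  for (perm in list(c(1, NA), c(2, NA), c(NA, 1), c(NA, 2), c(1, 2), c(2, 1))) {
    ok <- TRUE; tp <- 0
    for (i in 1:2) {
      j <- perm[i]
      if (!is.na(j)) {
        if (abs(det$samples[i] - ref$samples[j]) <= 50) tp <- tp + 1
        else ok <- FALSE
      }
    }
    if (ok) best <- max(best, tp)
  }
  expect_equal(m3$TP, best)

  expect_error(match_beats(det, beats(c(1, 2), fs = 500)), "sampling rates")
})

test_that("detection statistics and their conventions", {
  st <- detection_stats(list(TP = 10, FP = 0, FN = 0))
  expect_equal(unname(st), c(100, 100, 100))
  expect_warning(st0 <- detection_stats(list(TP = 0, FP = 0, FN = 5)),
                 "no detections")
  expect_equal(unname(st0), c(0, 0, 0))
  expect_error(detection_stats(list(TP = 0, FP = 3, FN = 0)), "reference")
})

test_that("Amari index is zero exactly on scaled permutations", {
  set.seed(33)
  A <- matrix(rnorm(16), 4)
  expect_equal(amari_index(solve(A), A), 0, tolerance = 1e-12)
  P <- diag(c(3, -2, 0.5, 1))[c(2, 4, 1, 3), ]
  expect_lt(amari_index(P %*% solve(A), A), 1e-10)
  W <- matrix(rnorm(16), 4)
  idx <- amari_index(W, A)
  expect_gt(idx, 0)
  expect_lte(idx, 1)
  expect_error(amari_index(diag(4), matrix(0, 4, 4)), "singular")
})

test_that("SNR metrics are invariant to column order and sign flips", {
  set.seed(34)
  U <- scale(matrix(rnorm(120 * 8), 120, 8) +
               outer(sin(seq_len(120) / 6), rep(1, 8)))
  perm <- sample(8)
  signs <- sample(c(-1, 1), 8, replace = TRUE)
  U2 <- sweep(U[, perm], 2, signs, "*")
  # per-column sign flips are a similarity transform of the Gram matrix
  expect_equal(snr_eig(U2), snr_eig(U), tolerance = 1e-10)
  # snr_rms is invariant to column order and to a global sign flip
  expect_equal(snr_rms(U[, perm]), snr_rms(U), tolerance = 1e-10)
  expect_equal(snr_rms(-U), snr_rms(U), tolerance = 1e-10)
})
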