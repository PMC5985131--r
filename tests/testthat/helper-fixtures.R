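# Shared fixtures, built once per test run. Everything is generated in code
# from fixed seeds; no data files.

.fix <- new.env(parent = emptyenv())

# 4-source Laplace mixture (clean), 5000 samples
fix_mixture <- function() {
  if (is.null(.fix$mx)) .fix$mx <- synth_mixture(4, 5000, seed = 42)
  .fix$mx
}

# whitened version of the fixture mixture
fix_whitened <- function() {
  if (is.null(.fix$z)) {
    mx <- fix_mixture()
    cen <- center_channels(mx$X)
    wh <- whiten_channels(cen$x)
    .fix$z <- list(z = wh$z, model = wh$model, mean = cen$mean, A = mx$A)
  }
  .fix$z
}

# default-conditions synthetic abdominal record, shortened to 30 s
fix_record <- function() {
  if (is.null(.fix$rec))
    .fix$rec <- synth_abdominal(synth_config(duration_s = 30, seed = 7))
  .fix$rec
}

# noiseless 2-source mixture of uniform (sub-Gaussian) sources, whitened,
# with the true unmixing directions in whitened coordinates
fix_uniform2 <- function() {
  if (is.null(.fix$u2)) {
    set.seed(99)
    S <- matrix(stats::runif(2 * 50000, -sqrt(3), sqrt(3)), 2)
    A <- matrix(c(1.2, 0.4, -0.3, 0.9), 2)
    X <- A %*% S
    cen <- center_channels(X)
    wh <- whiten_channels(cen$x)
    # rows of solve(whitening %*% A) are the true unmixing directions
    M <- solve(wh$model$transform %*% A)
    Wtrue <- M / sqrt(rowSums(M^2))
    .fix$u2 <- list(z = wh$z, Wtrue = Wtrue, A = A, model = wh$model)
  }
  .fix$u2
}

# independent brute-force residual evaluation: plain loops over samples
oracle_residual <- function(w, z) {
  n <- ncol(z)
  Exg <- rep(0, nrow(z))
  beta <- 0
  Egp <- 0
  for (t in seq_len(n)) {
    y <- sum(w * z[, t])
    Exg <- Exg + z[, t] * y^3
    beta <- beta + y * y^3
    Egp <- Egp + 3 * y^2
  }
  Exg <- Exg / n; beta <- beta / n; Egp <- Egp / n
  list(f = Exg - beta * w, jf = Egp - beta, Exg = Exg, Egp = Egp, beta = beta)
}

# exhaustive grid oracle for the overrelaxation factor (mirrors the
# definition: trial points renormalized, residual fully re-evaluated)
oracle_relaxation <- function(w, z, N = 100) {
  r0 <- oracle_residual(w, z)
  dw <- r0$f / r0$jf
  f0sq <- sum(r0$f^2)
  best_alpha <- 1
  best_tf <- Inf
  for (k in 1:(N - 1)) {
    a <- 1 + k / N
    trial <- w - a * dw
    trial <- trial / sqrt(sum(trial^2))
    fsq <- sum(oracle_residual(trial, z)$f^2)
    if (fsq < f0sq && sqrt(fsq) < best_tf) {
      best_tf <- sqrt(fsq)
      best_alpha <- a
    }
  }
  best_alpha
}

beat_rate_ok <- function(b, band) {
  rate <- 60 / mean(diff(b$samples) / b$fs)
  rate >= band[1] && rate <= band[2]
}

angular_distance <- function(u, v) {
  c <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, c))
}
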