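#' Center a multichannel signal
#'
#' Subtracts the per-channel mean so every row of the output has zero mean.
#' The mean vector is returned so the transform can be inverted or applied
#' to new data.
#'
#' @param x a \code{\link{recording}} or a channels-by-samples numeric matrix.
#' @return A list with \code{x} (centered matrix) and \code{mean} (per-channel
#'   mean vector).
#' @examples
#' center_channels(matrix(c(1, 2, 3, 2), 2))
#' @export
center_channels <- function(x) {
  m <- as_channel_matrix(x)
  if (!all(is.finite(m)))
    stop("input contains non-finite values")
  mu <- rowMeans(m)
  list(x = m - mu, mean = mu)
}

#' PCA whitening of a centered signal
#'
#' Eigendecomposes the sample covariance C = E diag(d) E^T of the centered
#' channels and applies the symmetric (ZCA) whitening transform
#' E diag(d)^{-1/2} E^T, after which the sample covariance of the output is
#' the identity.
#'
#' @param xc centered channels-by-samples matrix (rows must have zero mean).
#' @param eigenvalue_floor eigenvalues below \code{eigenvalue_floor} times the
#'   largest eigenvalue flag the input as rank deficient.
#' @return A list with \code{z} (whitened matrix, same shape) and
#'   \code{model}, a \code{"whitening"} object holding \code{E}
#'   (orthonormal eigenvectors), \code{d} (eigenvalues) and \code{transform}
#'   (the composed whitening matrix).
#' @examples
#' xc <- center_channels(matrix(rnorm(400), 4))$x
#' w <- whiten_channels(xc)
#' round(tcrossprod(w$z) / (ncol(xc) - 1), 6)
#' @export
whiten_channels <- function(xc, eigenvalue_floor = 1e-10) {
  xc <- as_channel_matrix(xc)
  if (max(abs(rowMeans(xc))) > 1e-6 * max(1, max(abs(xc))))
    stop("rows must be centered before whitening; call center_channels() first")
  n <- ncol(xc)
  C <- tcrossprod(xc) / (n - 1)
  eg <- eigen(C, symmetric = TRUE)
  d <- eg$values
  floor_val <- eigenvalue_floor * max(d)
  ok <- d > floor_val
  if (!all(ok))
    stop(sprintf(
      "covariance is rank deficient: only %d of %d channels carry independent signal",
      sum(ok), nrow(xc)))
  E <- eg$vectors
  transform <- E %*% (t(E) / sqrt(d))
  model <- structure(list(E = E, d = d, transform = transform),
                     class = "whitening")
  list(z = transform %*% xc, model = model)
}

#' Cubic contrast nonlinearity
#'
#' The nonlinearity used in the negentropy contrast: g(u) = u^3 and its
#' derivative g'(u) = 3 u^2.
#'
#' @param u numeric vector.
#' @return A list with \code{g} and \code{gprime}.
#' @examples
#' contrast_cube(2)
#' @export
contrast_cube <- function(u) {
  list(g = u^3, gprime = 3 * u^2)
}

# Residual F(w) = E{x g(w'x)} - beta w with beta = E{w'x g(w'x)}, and the
# scalar diagonal jf = E{g'(w'x)} - beta of the approximated Jacobian.
# Expectations are sample means over the columns of z. `check_unit` is
# relaxed during overrelaxation trial evaluations, where the trial point
# w - alpha*dw is not normalized.
ica_residual_ <- function(w, z, check_unit = TRUE) {
  if (check_unit && abs(sqrt(sum(w^2)) - 1) > 1e-6)
    stop("'w' must have unit norm")
  wx <- drop(crossprod(w, z))          # projections w^T x, length n
  gc <- contrast_cube(wx)
  Exg <- drop(z %*% gc$g) / length(wx) # E{x g(w^T x)}
  beta <- mean(wx * gc$g)
  f <- Exg - beta * w
  jf <- mean(gc$gprime) - beta
  list(f = f, jf = jf, Exg = Exg, Egp = mean(gc$gprime), beta = beta)
}

#' Kuhn-Tucker residual and approximated Jacobian
#'
#' Evaluates F(w) = E\{x g(w^T x)\} - beta w with beta = E\{w^T x g(w^T x)\},
#' and the scalar jf = E\{g'(w^T x)\} - beta that the whitening approximation
#' reduces the Jacobian to. The Newton step is F(w)/jf.
#'
#' @param w unit-norm weight vector.
#' @param z whitened channels-by-samples matrix.
#' @return A list with vector \code{f} and scalar \code{jf}.
#' @export
ica_residual <- function(w, z) {
  out <- ica_residual_(w, z, check_unit = TRUE)
  if (abs(out$jf) < 1e-12)
    stop("singular Jacobian: |E{g'(w'x)} - beta| < 1e-12; re-randomize w")
  list(f = out$f, jf = out$jf)
}

#' One conventional fixed-point update
#'
#' The simplified fixed-point iteration
#' w_next = E\{x g(w^T x)\} - E\{g'(w^T x)\} w, renormalized to unit length.
#'
#' @inheritParams ica_residual
#' @return The updated unit-norm weight vector.
#' @export
ica_update <- function(w, z) {
  r <- ica_residual_(w, z, check_unit = FALSE)
  w1 <- r$Exg - r$Egp * w
  nrm <- sqrt(sum(w1^2))
  if (nrm < 1e-300)
    stop("degenerate update: pre-normalization vector has zero norm")
  w1 / nrm
}

#' Select the overrelaxation factor by grid search
#'
#' Steps through the candidate grid alpha_k = 1 + k/N (k = 1, ..., N-1) and
#' keeps the candidates for which the relaxed Newton trial point
#' w - alpha_k * F(w)/jf strictly decreases the squared residual norm,
#' \eqn{\|F(w - \alpha_k \Delta w)\|^2 < \|F(w)\|^2}. Among those it returns
#' the alpha minimizing TF = \eqn{\|F(w - \alpha_k \Delta w)\|}. If no
#' candidate decreases the residual the plain Newton step alpha = 1 is
#' returned. The residual at each trial point is fully re-evaluated there
#' (beta included), after renormalizing the trial point onto the unit
#' sphere where the residual is defined.
#'
#' @inheritParams ica_residual
#' @param N grid density; candidates are 1 + 1/N, ..., 1 + (N-1)/N.
#'   Default 100, i.e. the grid 1.01, 1.02, ..., 1.99.
#' @return The selected overrelaxation factor, a scalar in [1, 2).
#' @export
select_relaxation <- function(w, z, N = 100) {
  if (N < 2) stop("'N' must be at least 2")
  r <- ica_residual(w, z)
  dw <- r$f / r$jf
  f0sq <- sum(r$f^2)
  alphas <- 1 + seq_len(N - 1) / N
  tf <- rep(NA_real_, N - 1)
  for (i in seq_along(alphas)) {
    trial <- w - alphas[i] * dw
    # the residual is defined on the unit sphere (the constraint set), and
    # every iterate of the algorithm is renormalized, so the trial point is
    # renormalized before evaluating F; off the sphere the residual is
    # dominated by the radial constraint violation and no candidate would
    # ever pass the decrease filter
    nrm <- sqrt(sum(trial^2))
    if (nrm < 1e-300) next
    ft <- ica_residual_(trial / nrm, z, check_unit = FALSE)$f
    fsq <- sum(ft^2)
    if (fsq < f0sq) tf[i] <- sqrt(fsq)
  }
  if (all(is.na(tf))) return(1)
  alphas[which.min(tf)]
}

#' One overrelaxed two-stage update
#'
#' The improved iteration: an overrelaxed first stage
#' w' = E\{x g(w^T x)\} -/+ alpha E\{g'(w^T x)\} w followed by a correction
#' stage w'' = E\{x g(w^T x)\} -/+ E\{g'(w'^T x)\} w, returned normalized.
#' \code{sign = "minus"} (default) keeps the sign convention of the
#' conventional update; \code{sign = "plus"} uses plus in both stages.
#'
#' @inheritParams ica_residual
#' @param alpha overrelaxation factor in [1, 2).
#' @param sign \code{"minus"} or \code{"plus"}; see Details.
#' @return The updated unit-norm weight vector.
#' @export
ica_update_relaxed <- function(w, z, alpha, sign = c("minus", "plus")) {
  sign <- match.arg(sign)
  s <- if (sign == "minus") -1 else 1
  r <- ica_residual_(w, z, check_unit = FALSE)
  w1 <- r$Exg + s * alpha * r$Egp * w
  n1 <- sqrt(sum(w1^2))
  if (n1 < 1e-300)
    stop("degenerate update: overrelaxed stage collapsed to zero")
  # evaluate g' at the normalized intermediate direction: every iterate of
  # the algorithm is unit-norm, and the quadratic scaling of g' would
  # otherwise let the length of the unnormalized stage dominate the update
  w1x <- drop(crossprod(w1 / n1, z))
  Egp1 <- mean(contrast_cube(w1x)$gprime)
  w2 <- r$Exg + s * Egp1 * w
  nrm <- sqrt(sum(w2^2))
  if (nrm < 1e-300)
    stop("degenerate update: pre-normalization vector has zero norm")
  w2 / nrm
}

# Gram-Schmidt deflation: remove the projections of w onto previously
# accepted rows (rows of Wprev), then renormalize. Returns NULL when the
# projection leaves essentially nothing.
deflate_ <- function(w, Wprev) {
  if (!is.null(Wprev) && nrow(Wprev) > 0L)
    w <- w - drop(crossprod(Wprev, Wprev %*% w))
  nrm <- sqrt(sum(w^2))
  if (nrm < 1e-10) return(NULL)
  w / nrm
}

# Extract one component by fixed-point iteration with deflation against
# Wprev. Convergence is sign-invariant: min(|w+ - w|, |w+ + w|) < eps.
# For the improved method alpha is selected once from the (deflated) initial
# vector, or re-selected every iteration when realpha = TRUE.
extract_component_ <- function(z, w0, method, eps, max_iter, alpha_grid_N,
                               sign, realpha, Wprev = NULL) {
  w <- deflate_(w0, Wprev)
  if (is.null(w)) stop("initial vector lies in the span of accepted components")
  alpha <- NA_real_
  if (method == "improved" && !realpha)
    alpha <- select_relaxation(w, z, alpha_grid_N)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (method == "improved") {
      a <- if (realpha) select_relaxation(w, z, alpha_grid_N) else alpha
      if (realpha) alpha <- a
      wn <- ica_update_relaxed(w, z, a, sign)
    } else {
      wn <- ica_update(w, z)
    }
    wn <- deflate_(wn, Wprev)
    if (is.null(wn)) stop("degenerate update: direction collapsed into accepted span")
    step <- min(sqrt(sum((wn - w)^2)), sqrt(sum((wn + w)^2)))
    w <- wn
    if (step < eps) { converged <- TRUE; break }
  }
  list(w = w, n_iter = iter, converged = converged, alpha = alpha)
}

#' Deflationary FastICA with optional overrelaxation
#'
#' Fits a blind source separation model to a multichannel signal by the
#' fixed-point FastICA algorithm with the cubic negentropy contrast
#' g(y) = y^3. The signal is centered and PCA-whitened, then unit-norm
#' unmixing directions are extracted one at a time (deflation with
#' Gram-Schmidt decorrelation). \code{method = "improved"} incorporates an
#' overrelaxation factor, chosen by grid search over (1, 2), into the
#' approximated Newton iteration; this relaxes the dependence on the random
#' initial weight vector and typically reduces the iteration count.
#' \code{method = "conventional"} is the plain simplified fixed-point update.
#'
#' @param x a \code{\link{recording}} or channels-by-samples numeric matrix.
#' @param n.comp number of components to extract (at most the channel count).
#' @param method \code{"improved"} (overrelaxed, default) or
#'   \code{"conventional"}.
#' @param eps convergence tolerance on the (sign-invariant) change of the
#'   weight vector, in (0, 1). Default 1e-4.
#' @param max.iter iteration cap per component. Default 1000.
#' @param alpha.grid.N grid density for the overrelaxation search; candidates
#'   are 1 + k/N for k = 1..N-1. Default 100.
#' @param update.sign sign convention of the two-stage overrelaxed update;
#'   see \code{\link{ica_update_relaxed}}.
#' @param realpha if \code{TRUE}, re-select the overrelaxation factor every
#'   iteration instead of once per component from the initial vector.
#' @param w.init optional n.comp-by-n.comp matrix of initial weight vectors
#'   (rows); drawn from the current RNG stream when NULL.
#' @param seed optional integer seed applied before drawing \code{w.init}.
#'
#' @return An object of class \code{"fastica"}: a list with
#'   \item{W}{unmixing matrix in whitened space, rows unit-norm and mutually
#'     orthogonal;}
#'   \item{whitening}{the \code{"whitening"} model (E, d, transform);}
#'   \item{center}{the per-channel mean removed before whitening;}
#'   \item{S}{the separated sources, n.comp by n_samples;}
#'   \item{iterations, total_iterations, converged, alpha}{per-component
#'     iteration counts, their sum, convergence flags, and the
#'     overrelaxation factors used (NA for the conventional method).}
#' @examples
#' set.seed(1)
#' S <- matrix(sign(rnorm(2 * 2000)) * rexp(2 * 2000), 2)  # super-Gaussian
#' X <- matrix(rnorm(4), 2) %*% S
#' fit <- fastica(X, method = "improved", seed = 7)
#' fit
#' @seealso \code{\link{extract_fecg}} for the full pipeline,
#'   \code{\link{amari_index}} to score recovery of a known mixing matrix.
#' @export
fastica <- function(x, n.comp = NULL, method = c("improved", "conventional"),
                    eps = 1e-4, max.iter = 1000, alpha.grid.N = 100,
                    update.sign = c("minus", "plus"), realpha = FALSE,
                    w.init = NULL, seed = NULL) {
  method <- match.arg(method)
  update.sign <- match.arg(update.sign)
  if (!(eps > 0 && eps < 1)) stop("'eps' must lie in (0, 1)")
  if (max.iter < 1) stop("'max.iter' must be at least 1")
  if (alpha.grid.N < 2) stop("'alpha.grid.N' must be at least 2")
  m <- as_channel_matrix(x)
  if (is.null(n.comp)) n.comp <- nrow(m)
  if (n.comp > nrow(m)) stop("'n.comp' cannot exceed the number of channels")

  cen <- center_channels(m)
  wh <- whiten_channels(cen$x)
  z <- wh$z
  p <- nrow(z)

  if (!is.null(seed)) set.seed(seed)
  if (is.null(w.init)) {
    w.init <- matrix(stats::rnorm(n.comp * p), n.comp, p)
  } else {
    w.init <- as.matrix(w.init)
    if (!all(dim(w.init) == c(n.comp, p)))
      stop(sprintf("'w.init' must be a %d x %d matrix", n.comp, p))
  }

  W <- matrix(0, 0, p)
  iterations <- integer(n.comp)
  converged <- logical(n.comp)
  alpha_used <- rep(NA_real_, n.comp)
  for (i in seq_len(n.comp)) {
    w0 <- w.init[i, ]
    w0 <- w0 / sqrt(sum(w0^2))
    res <- NULL
    for (try in 1:6) {
      res <- tryCatch(
        extract_component_(z, w0, method, eps, max.iter, alpha.grid.N,
                           update.sign, realpha, Wprev = W),
        error = function(e) e)
      if (!inherits(res, "error")) break
      if (try == 6)
        stop(sprintf("component %d failed after re-randomization (%d recovered): %s",
                     i, i - 1L, conditionMessage(res)))
      w0 <- stats::rnorm(p)
      w0 <- w0 / sqrt(sum(w0^2))
    }
    W <- rbind(W, res$w)
    iterations[i] <- res$n_iter
    converged[i] <- res$converged
    alpha_used[i] <- res$alpha
  }
  rownames(W) <- paste0("IC", seq_len(n.comp))

  S <- W %*% z
  fs <- if (inherits(x, "recording")) x$fs else NA_real_
  structure(list(W = W, whitening = wh$model, center = cen$mean, S = S,
                 iterations = iterations,
                 total_iterations = sum(iterations),
                 converged = converged, alpha = alpha_used,
                 method = method, eps = eps, update.sign = update.sign,
                 fs = fs, n.comp = n.comp),
            class = "fastica")
}

#' @export
print.fastica <- function(x, ...) {
  cat(sprintf("FastICA separation (%s method), %d component(s)\n",
              x$method, x$n.comp))
  cat(sprintf("Iterations per component: %s (total %d)\n",
              paste(x$iterations, collapse = ", "), x$total_iterations))
  if (x$method == "improved")
    cat("Overrelaxation factors:", paste(format(x$alpha, digits = 3),
                                         collapse = ", "), "\n")
  if (!all(x$converged))
    cat("Warning: component(s)", paste(which(!x$converged), collapse = ", "),
        "did not converge\n")
  invisible(x)
}

#' @export
summary.fastica <- function(object, ...) {
  n <- ncol(object$S)
  kurt <- apply(object$S, 1, function(s) mean(s^4) / mean(s^2)^2 - 3)
  out <- data.frame(component = rownames(object$W),
                    iterations = object$iterations,
                    converged = object$converged,
                    alpha = object$alpha,
                    excess_kurtosis = kurt,
                    row.names = NULL)
  structure(list(table = out, method = object$method,
                 total_iterations = object$total_iterations,
                 n_samples = n),
            class = "summary.fastica")
}

#' @export
print.summary.fastica <- function(x, ...) {
  cat(sprintf("FastICA (%s), %d samples, total iterations %d\n",
              x$method, x$n_samples, x$total_iterations))
  print(x$table, digits = 4)
  invisible(x)
}

#' @describeIn fastica the overall unmixing matrix, composing whitening and
#'   the rotation \code{W}, so that \code{coef(fit) \%*\% (x - center)}
#'   reproduces the sources.
#' @param object,... method arguments.
#' @export
coef.fastica <- function(object, ...) {
  object$W %*% object$whitening$transform
}

#' @describeIn fastica apply the fitted unmixing to new data recorded with
#'   the same channel layout; returns a sources matrix.
#' @param newdata a \code{recording} or channels-by-samples matrix with the
#'   same number of channels the model was fitted to.
#' @export
predict.fastica <- function(object, newdata, ...) {
  m <- as_channel_matrix(newdata)
  if (nrow(m) != length(object$center))
    stop("'newdata' must have the same number of channels as the fitted data")
  coef(object) %*% (m - object$center)
}

#' @describeIn fastica plot the separated source signals stacked in time.
#' @param max.seconds show at most this many seconds per component.
#' @export
plot.fastica <- function(x, max.seconds = 10, ...) {
  fs <- if (is.finite(x$fs)) x$fs else 1
  n <- min(ncol(x$S), round(max.seconds * fs))
  t <- (seq_len(n) - 1) / fs
  old <- graphics::par(mfrow = c(x$n.comp, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  for (i in seq_len(x$n.comp))
    graphics::plot(t, x$S[i, seq_len(n)], type = "l",
                   xlab = if (is.finite(x$fs)) "time (s)" else "sample",
                   ylab = rownames(x$W)[i], ...)
  invisible(x)
}
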