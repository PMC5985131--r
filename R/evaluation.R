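#' Beat-aligned segment matrix
#'
#' Cuts one window per R-peak out of a single-channel signal, each window
#' spanning \code{pre_ms} before to \code{post_ms} after the R sample so
#' that it contains the complete QRS wave, and stacks them as the columns of
#' an N-by-M matrix U (N samples per segment, M segments). Each column is
#' standardized to zero mean and unit variance. Beats whose window falls
#' outside the record, or whose segment is constant, are dropped.
#'
#' @param x numeric vector, single-channel signal.
#' @param b a \code{\link{beats}} annotation for \code{x}.
#' @param pre_ms,post_ms window extent around each R-peak, in ms.
#' @return A standardized N-by-M matrix with attribute \code{"dropped"}
#'   giving the number of discarded beats.
#' @examples
#' sim <- synth_ecg(fs = 500, duration_s = 20, hr_bpm = 70, seed = 1)
#' U <- segment_matrix(sim$signal, sim$beats, 100, 100)
#' dim(U)
#' @export
segment_matrix <- function(x, b, pre_ms = 100, post_ms = 100) {
  stopifnot(inherits(b, "beats"))
  x <- as.numeric(x)
  pre <- round(pre_ms * b$fs / 1000)
  post <- round(post_ms * b$fs / 1000)
  lo <- b$samples - pre
  hi <- b$samples + post
  usable <- which(lo >= 1L & hi <= length(x))
  dropped <- length(b$samples) - length(usable)
  cols <- lapply(usable, function(i) x[lo[i]:hi[i]])
  sds <- vapply(cols, stats::sd, numeric(1))
  flat <- sds < 1e-300
  if (any(flat)) {
    warning(sprintf("%d zero-variance segment(s) dropped", sum(flat)))
    cols <- cols[!flat]
    dropped <- dropped + sum(flat)
  }
  if (length(cols) < 2L)
    stop("fewer than 2 usable beat segments")
  U <- vapply(cols, function(s) (s - mean(s)) / stats::sd(s),
              numeric(pre + post + 1L))
  attr(U, "dropped") <- dropped
  U
}

#' Eigenvalue-based SNR of a segment matrix
#'
#' Signal-to-noise ratio of beat-aligned segments from the eigenvalues of
#' the Gram matrix U^T U: SNR = lambda_max / (sum(lambda) - lambda_max).
#' Mutually consistent beats concentrate energy in the leading eigenvalue,
#' yielding a high ratio; identical segments give a rank-one Gram matrix and
#' the ratio is reported as \code{Inf}.
#'
#' @param U a standardized segment matrix from \code{\link{segment_matrix}}
#'   (N samples by M segments, M >= 2).
#' @return A non-negative scalar, possibly \code{Inf}.
#' @export
snr_eig <- function(U) {
  U <- as.matrix(U)
  if (ncol(U) < 2L) stop("segment matrix needs at least 2 columns")
  lam <- eigen(crossprod(U), symmetric = TRUE, only.values = TRUE)$values
  lmax <- max(lam)
  denom <- sum(lam) - lmax
  if (denom < 1e-12) return(Inf)
  lmax / denom
}

#' Cross-correlation-based SNR of a segment matrix
#'
#' Computes eta, the mean pairwise inner product
#' (2 / (M (M - 1))) * sum_{i<k} f(i)^T f(k) over segment columns scaled to
#' unit Euclidean norm (so each inner product is the Pearson correlation of
#' the standardized segments), and returns SNR = eta / (1 - eta). Identical
#' segments (eta -> 1) give \code{Inf}; non-positive eta is floored at 0
#' with a warning.
#'
#' @inheritParams snr_eig
#' @return A non-negative scalar, possibly \code{Inf}.
#' @export
snr_rms <- function(U) {
  U <- as.matrix(U)
  M <- ncol(U)
  if (M < 2L) stop("segment matrix needs at least 2 columns")
  V <- sweep(U, 2, sqrt(colSums(U^2)), "/")
  G <- crossprod(V)
  eta <- (sum(G) - M) / (M * (M - 1))
  if (eta >= 1 - 1e-12) return(Inf)
  if (eta <= 0) {
    warning("mean pairwise correlation is non-positive; SNR floored at 0")
    return(0)
  }
  eta / (1 - eta)
}

#' Match detected beats to reference beats
#'
#' Greedy nearest-neighbour one-to-one matching: candidate pairs within
#' \code{tol_ms} are ranked by absolute time difference and assigned
#' greedily, each beat used at most once. Matched pairs count as true
#' positives, unmatched detections as false positives, unmatched references
#' as false negatives.
#'
#' @param detected,reference \code{\link{beats}} objects at the same
#'   sampling rate.
#' @param tol_ms matching tolerance, default 50 ms.
#' @return A list of class \code{"detection_counts"} with integer
#'   \code{TP}, \code{FP}, \code{FN}.
#' @examples
#' d <- beats(c(100, 200), fs = 1000)
#' r <- beats(c(120, 500), fs = 1000)
#' match_beats(d, r, tol_ms = 50)
#' @export
match_beats <- function(detected, reference, tol_ms = 50) {
  stopifnot(inherits(detected, "beats"), inherits(reference, "beats"))
  if (detected$fs != reference$fs)
    stop("detected and reference annotations have different sampling rates")
  tol <- tol_ms * detected$fs / 1000
  nd <- length(detected$samples)
  nr <- length(reference$samples)
  if (nd == 0L || nr == 0L) {
    counts <- list(TP = 0L, FP = nd, FN = nr)
    class(counts) <- "detection_counts"
    return(counts)
  }
  dt <- abs(outer(detected$samples, reference$samples, "-"))
  pairs <- which(dt <= tol, arr.ind = TRUE)
  tp <- 0L
  if (nrow(pairs)) {
    ord <- order(dt[pairs])
    used_d <- logical(nd)
    used_r <- logical(nr)
    for (k in ord) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (!used_d[i] && !used_r[j]) {
        used_d[i] <- TRUE; used_r[j] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  counts <- list(TP = tp, FP = nd - tp, FN = nr - tp)
  class(counts) <- "detection_counts"
  counts
}

#' @export
print.detection_counts <- function(x, ...) {
  cat(sprintf("Beat matching: TP=%d FP=%d FN=%d\n", x$TP, x$FP, x$FN))
  invisible(x)
}

#' Beat-detection statistics
#'
#' Sensitivity Sens = TP/(TP+FN), positive predictive accuracy
#' PPA = TP/(TP+FP), and their harmonic mean F1 = 2 TP/(2 TP + FN + FP),
#' each as a percentage reported to two decimals.
#'
#' @param counts a \code{"detection_counts"} object or a list with integer
#'   \code{TP}, \code{FP}, \code{FN}.
#' @return Named numeric vector \code{c(Sens=, PPA=, F1=)} in percent.
#' @examples
#' detection_stats(list(TP = 3171, FP = 32, FN = 20))
#' @export
detection_stats <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN
  if (any(c(TP, FP, FN) < 0)) stop("counts must be non-negative")
  if (TP + FN == 0) stop("no reference beats (TP + FN = 0)")
  sens <- 100 * TP / (TP + FN)
  if (TP + FP == 0) {
    warning("no detections (TP + FP = 0); PPA reported as 0")
    ppa <- 0
  } else {
    ppa <- 100 * TP / (TP + FP)
  }
  f1 <- 100 * 2 * TP / (2 * TP + FN + FP)
  round(c(Sens = sens, PPA = ppa, F1 = f1), 2)
}

#' Amari separation performance index
#'
#' Permutation- and scale-invariant distance between an estimated unmixing
#' matrix W and a true mixing matrix A, computed from P = W A: the index is
#' 0 exactly when P is a scaled permutation (perfect separation) and grows
#' toward 1 as rows/columns of P mix. When the unmixing was estimated in
#' whitened coordinates, pass the composed matrix (e.g.
#' \code{coef(fit) \%*\% A} for the overall unmixing).
#'
#' @param W estimated unmixing matrix (n x n).
#' @param A true mixing matrix (n x n).
#' @return A scalar in [0, 1].
#' @examples
#' A <- matrix(rnorm(9), 3)
#' amari_index(solve(A), A)  # 0
#' @export
amari_index <- function(W, A) {
  W <- as.matrix(W); A <- as.matrix(A)
  if (!all(dim(W) == dim(A)) || nrow(W) != ncol(W))
    stop("'W' and 'A' must be square matrices of equal size")
  if (abs(det(A)) < 1e-300) stop("'A' is singular")
  P <- abs(W %*% A)
  n <- nrow(P)
  rows <- sum(rowSums(P / apply(P, 1, max)) - 1)
  cols <- sum(colSums(sweep(P, 2, apply(P, 2, max), "/")) - 1)
  (rows + cols) / (2 * n * (n - 1))
}
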