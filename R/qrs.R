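#' Pan-Tompkins R-peak detection
#'
#' The classic real-time QRS detection chain applied offline: zero-phase
#' band-pass filter, five-point derivative, squaring, moving-window
#' integration, then adaptive dual-threshold peak classification with
#' search-back and a refractory period. Detected peaks are refined to the
#' local extremum of the absolute band-passed signal within +/- 40 ms, which
#' also makes detection polarity-invariant. The adaptive thresholds track
#' running signal/noise peak estimates, so detection is invariant to global
#' amplitude scaling.
#'
#' \code{mode = "adult"} uses the classic parameterization (5-15 Hz band,
#' 150 ms integration window, 200 ms refractory), appropriate for maternal
#' beats. \code{mode = "fetal"} narrows the chain for the faster, narrower
#' fetal QRS (10-25 Hz band, 80 ms window, 150 ms refractory).
#'
#' @param x numeric vector, a single-channel signal.
#' @param fs sampling rate in Hz; at least 100.
#' @param mode parameter set, \code{"adult"} (default) or \code{"fetal"}.
#' @param band band-pass corner frequencies in Hz; overrides the mode preset.
#' @param mwi_ms moving-window integration length in ms.
#' @param refractory_ms minimum spacing between detections in ms.
#' @return A \code{\link{beats}} annotation object.
#' @examples
#' sim <- synth_ecg(fs = 500, duration_s = 20, hr_bpm = 70, seed = 1)
#' det <- detect_rpeaks(sim$signal, fs = 500)
#' length(det)
#' @export
detect_rpeaks <- function(x, fs, mode = c("adult", "fetal"),
                          band = NULL, mwi_ms = NULL, refractory_ms = NULL) {
  mode <- match.arg(mode)
  if (fs < 100) stop("'fs' must be at least 100 Hz")
  x <- as.numeric(x)
  if (length(x) < 2 * fs) stop("signal must be at least 2 s long")
  if (!all(is.finite(x))) stop("signal contains non-finite values")

  preset <- switch(mode,
    adult = list(band = c(5, 15), mwi_ms = 150, refractory_ms = 200),
    fetal = list(band = c(10, 25), mwi_ms = 80, refractory_ms = 150))
  if (is.null(band)) band <- preset$band
  if (is.null(mwi_ms)) mwi_ms <- preset$mwi_ms
  if (is.null(refractory_ms)) refractory_ms <- preset$refractory_ms

  # stage 1: zero-phase band-pass (keeps R-peak timing); reflected padding
  # avoids filtfilt start-up transients
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  xb <- filtfilt_padded_(bf, x, min(length(x) - 1L, round(fs)))
  # stage 2: five-point derivative
  xd <- stats::filter(xb, c(1, 2, 0, -2, -1) / 8, sides = 2)
  xd[is.na(xd)] <- 0
  # stages 3-4: squaring and moving-window integration
  xs <- as.numeric(xd)^2
  nw <- max(1L, round(mwi_ms * fs / 1000))
  mwi <- as.numeric(stats::filter(xs, rep(1 / nw, nw), sides = 2))
  mwi[is.na(mwi)] <- 0

  if (max(mwi) <= 0) return(beats(integer(0), fs))

  refr <- round(refractory_ms * fs / 1000)
  cand <- local_maxima_(mwi, min_dist = max(1L, round(0.06 * fs)))
  if (!length(cand)) return(beats(integer(0), fs))

  # stage 5: adaptive dual thresholds with search-back
  init <- mwi[seq_len(min(length(mwi), 2L * round(fs)))]
  spki <- max(init) / 3
  npki <- mean(init) / 2
  rr_hist <- numeric(0)
  accepted <- integer(0)
  skipped <- integer(0)   # sub-threshold candidates, kept for search-back
  for (p in cand) {
    thr1 <- npki + 0.25 * (spki - npki)
    if (length(accepted) && (p - accepted[length(accepted)]) < refr) next
    if (mwi[p] > thr1) {
      spki <- 0.125 * mwi[p] + 0.875 * spki
      if (length(accepted)) {
        rr_hist <- c(rr_hist, p - accepted[length(accepted)])
        if (length(rr_hist) > 8) rr_hist <- rr_hist[-1]
      }
      accepted <- c(accepted, p)
    } else {
      npki <- 0.125 * mwi[p] + 0.875 * npki
      skipped <- c(skipped, p)
      # search-back: missed beat if the gap exceeds 166% of the average RR
      if (length(accepted) && length(rr_hist) >= 2) {
        rr_avg <- mean(rr_hist)
        gap <- p - accepted[length(accepted)]
        if (gap > 1.66 * rr_avg) {
          thr2 <- 0.5 * thr1
          inside <- skipped[skipped > accepted[length(accepted)] + refr &
                            skipped < p]
          inside <- inside[mwi[inside] > thr2]
          if (length(inside)) {
            best <- inside[which.max(mwi[inside])]
            spki <- 0.25 * mwi[best] + 0.75 * spki
            accepted <- c(accepted, best)
            rr_hist <- c(rr_hist, best - accepted[length(accepted) - 1L])
            if (length(rr_hist) > 8) rr_hist <- rr_hist[-1]
          }
        }
      }
    }
  }
  if (!length(accepted)) return(beats(integer(0), fs))
  accepted <- sort(accepted)

  # refine to the extremum of |band-passed| near the MWI peak; all stages
  # are zero-phase/centered so the R wave sits within about half the
  # integration window of the MWI maximum, plus a 40 ms margin
  half <- as.integer(round(0.04 * fs) + ceiling(nw / 2))
  refined <- vapply(accepted, function(p) {
    lo <- max(1L, p - half)
    hi <- min(length(xb), p + half)
    as.integer(lo + which.max(abs(xb[lo:hi])) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))

  # enforce refractory after refinement, keeping the larger peak
  if (length(refined) > 1) {
    keep <- refined[1]
    for (p in refined[-1]) {
      last <- keep[length(keep)]
      if (p - last >= refr) keep <- c(keep, p)
      else if (abs(xb[p]) > abs(xb[last])) keep[length(keep)] <- p
    }
    refined <- keep
  }
  beats(refined, fs)
}

# indices of strict local maxima separated by at least min_dist samples
local_maxima_ <- function(y, min_dist = 1L) {
  n <- length(y)
  if (n < 3) return(integer(0))
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (!length(idx) || min_dist <= 1L) return(idx)
  keep <- idx[1]
  for (p in idx[-1]) {
    last <- keep[length(keep)]
    if (p - last >= min_dist) keep <- c(keep, p)
    else if (y[p] > y[last]) keep[length(keep)] <- p
  }
  keep
}
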