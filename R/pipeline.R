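#' Pipeline configuration
#'
#' Tunable parameters of the fetal ECG extraction pipeline. Baseline wander
#' is estimated per channel with a 3rd-order low-pass Butterworth filter at
#' 5 Hz (applied forward-backward, so the estimate is zero-phase) and
#' subtracted. Maternal beats are cancelled by a rank-limited SVD
#' reconstruction of beat-aligned windows spanning 100 ms before to 150 ms
#' after each maternal R-peak, cross-faded over 10 ms at the window edges.
#'
#' @param baseline_cutoff_hz baseline low-pass cutoff, Hz.
#' @param baseline_order Butterworth order of the baseline estimator.
#' @param svd_rank rank of the maternal template subspace.
#' @param beat_pre_ms,beat_post_ms maternal cancellation window around each
#'   R-peak, ms.
#' @param fade_ms raised-cosine cross-fade at window edges, ms.
#' @param maternal_hr_band,fetal_hr_band plausible heart-rate ranges, bpm.
#' @param match_tol_ms beat-matching tolerance used in reports, ms.
#' @param method,eps,max.iter,alpha.grid.N,update.sign separation settings
#'   passed to \code{\link{fastica}}.
#' @return A list of class \code{"fecg_config"}.
#' @export
fecg_config <- function(baseline_cutoff_hz = 5, baseline_order = 3,
                        svd_rank = 2, beat_pre_ms = 100, beat_post_ms = 150,
                        fade_ms = 10, maternal_hr_band = c(40, 120),
                        fetal_hr_band = c(100, 180), match_tol_ms = 50,
                        method = "improved", eps = 1e-4, max.iter = 1000,
                        alpha.grid.N = 100, update.sign = "minus") {
  if (svd_rank < 1) stop("'svd_rank' must be at least 1")
  if (beat_pre_ms <= 0 || beat_post_ms <= 0)
    stop("beat window extents must be positive")
  structure(as.list(environment()), class = "fecg_config")
}

#' Remove baseline wander
#'
#' Estimates the baseline of each channel with a low-pass Butterworth filter
#' (default 3rd order, 5 Hz cutoff) applied forward-backward for zero phase,
#' and subtracts it, leaving the cardiac content untouched above the cutoff.
#'
#' @param rec a \code{\link{recording}} or channels-by-samples matrix (then
#'   \code{fs} must be given).
#' @param cutoff_hz,order baseline estimator settings.
#' @param fs sampling rate when \code{rec} is a bare matrix.
#' @return The baseline-corrected input, same class and shape.
#' @export
remove_baseline <- function(rec, cutoff_hz = 5, order = 3, fs = NULL) {
  m <- as_channel_matrix(rec)
  if (inherits(rec, "recording")) fs <- rec$fs
  if (is.null(fs)) stop("'fs' is required for matrix input")
  if (cutoff_hz >= fs / 2)
    stop("baseline cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  pad <- min(ncol(m) - 1L, ceiling(6 * fs / cutoff_hz))
  out <- t(apply(m, 1, function(ch) {
    # demean first: the filter has unit DC gain, so the mean passes through
    # the baseline estimate exactly and edge transients shrink accordingly
    mu <- mean(ch)
    base <- mu + filtfilt_padded_(bf, ch - mu, pad)
    ch - base
  }))
  if (inherits(rec, "recording"))
    return(recording(out, fs, rec$labels))
  out
}

# zero-phase filtering with even (reflected) padding: filtfilt alone starts
# from zero state, which leaves large transients at the record edges
filtfilt_padded_ <- function(filt, x, pad) {
  n <- length(x)
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filtfilt(filt, ext)
  y[(pad + 1):(pad + n)]
}

#' Select the maternal component among separated sources
#'
#' Runs R-peak detection on every separated component (the detector is
#' polarity-invariant) and keeps the components whose beat rate falls in the
#' plausible maternal band. Among those, the component with the most regular
#' rhythm (smallest RR-interval coefficient of variation) is chosen; ties go
#' to the component with larger excess kurtosis (the more ECG-like,
#' spike-dominated waveform).
#'
#' @param S sources matrix (components by samples) or a \code{"fastica"} fit.
#' @param fs sampling rate in Hz.
#' @param hr_band plausible maternal heart-rate range, bpm.
#' @return A list with \code{index} and \code{beats}.
#' @export
select_maternal_component <- function(S, fs, hr_band = c(40, 120)) {
  if (inherits(S, "fastica")) S <- S$S
  S <- as.matrix(S)
  diag_tab <- data.frame(component = seq_len(nrow(S)), n_beats = NA_integer_,
                         rate_bpm = NA_real_, rr_cv = NA_real_,
                         kurtosis = NA_real_)
  dets <- vector("list", nrow(S))
  for (i in seq_len(nrow(S))) {
    b <- detect_rpeaks(S[i, ], fs, mode = "adult")
    dets[[i]] <- b
    diag_tab$n_beats[i] <- length(b)
    if (length(b) >= 5L) {
      rr <- diff(b$samples) / fs
      diag_tab$rate_bpm[i] <- 60 / mean(rr)
      diag_tab$rr_cv[i] <- stats::sd(rr) / mean(rr)
    }
    diag_tab$kurtosis[i] <- mean(S[i, ]^4) / mean(S[i, ]^2)^2 - 3
  }
  ok <- which(!is.na(diag_tab$rate_bpm) &
              diag_tab$rate_bpm >= hr_band[1] & diag_tab$rate_bpm <= hr_band[2])
  if (!length(ok)) {
    stop(paste0("no component shows a plausible maternal rhythm:\n",
                paste(utils::capture.output(print(diag_tab)), collapse = "\n")))
  }
  cv <- diag_tab$rr_cv[ok]
  best <- ok[order(cv, -diag_tab$kurtosis[ok])][1]
  list(index = best, beats = dets[[best]], diagnostics = diag_tab)
}

#' Cancel maternal beats by SVD template subtraction
#'
#' For each channel, windows spanning \code{pre_ms} before to \code{post_ms}
#' after every maternal R-peak are stacked into a beats-by-window matrix.
#' A rank-\code{rank} SVD reconstruction captures the repeating maternal
#' waveform (and its slow morphological variation) and is subtracted inside
#' each window; a raised-cosine cross-fade over \code{fade_ms} at the window
#' edges avoids subtraction discontinuities. Samples outside all windows
#' pass through unchanged, preserving the asynchronous fetal beats. Windows
#' that would run past the record bounds are dropped.
#'
#' The template is fitted robustly: fetal QRS complexes that land inside a
#' maternal window are sparse, large-amplitude deviations from the
#' maternal waveform, and a plain truncated SVD partially absorbs them
#' (severely so when the two rhythms are near-commensurate, e.g. 80 vs
#' 140 bpm is a 4:7 resonance, so fetal beats recur at nearly fixed offsets
#' inside the maternal windows). The template is therefore initialized from
#' per-column medians (immune to minority contamination at any column) and
#' refined by an iteratively reweighted SVD with Tukey bisquare weights on
#' the per-column robust residual scale, so the subtraction removes the
#' maternal waveform while leaving superimposed fetal complexes in place.
#'
#' @param x channels-by-samples matrix or \code{\link{recording}}.
#' @param maternal_beats maternal \code{\link{beats}}.
#' @param pre_ms,post_ms window extent around each maternal R-peak, ms.
#' @param rank SVD template rank.
#' @param fade_ms edge cross-fade, ms.
#' @return The residual matrix (or recording), maternal content removed.
#' @export
cancel_maternal <- function(x, maternal_beats, pre_ms = 100, post_ms = 150,
                            rank = 2, fade_ms = 10) {
  stopifnot(inherits(maternal_beats, "beats"))
  m <- as_channel_matrix(x)
  fs <- maternal_beats$fs
  if (!length(maternal_beats$samples))
    stop("maternal beat list is empty")
  pre <- round(pre_ms * fs / 1000)
  post <- round(post_ms * fs / 1000)
  L <- pre + post + 1L
  lo <- maternal_beats$samples - pre
  hi <- maternal_beats$samples + post
  usable <- which(lo >= 1L & hi <= ncol(m))
  n_drop <- length(maternal_beats$samples) - length(usable)
  if (n_drop > 0)
    message(sprintf("cancel_maternal: %d beat window(s) outside the record dropped",
                    n_drop))
  if (length(usable) < rank + 1L)
    stop(sprintf("need at least rank + 1 = %d complete maternal beats, have %d",
                 rank + 1L, length(usable)))

  nf <- max(1L, round(fade_ms * fs / 1000))
  taper <- rep(1, L)
  ramp <- 0.5 * (1 - cos(pi * seq_len(nf) / (nf + 1)))
  taper[seq_len(nf)] <- ramp
  taper[L - nf + seq_len(nf)] <- rev(ramp)

  out <- m
  for (ch in seq_len(nrow(m))) {
    B <- t(vapply(usable, function(i) m[ch, lo[i]:hi[i]], numeric(L)))
    M <- nrow(B)
    r <- min(rank, M - 1L, L)
    # robust init: per-column medians resist sparse fetal contamination
    tmpl <- matrix(apply(B, 2, stats::median), M, L, byrow = TRUE)
    for (it in 1:5) {
      R <- B - tmpl
      scol <- 1.4826 * apply(abs(R), 2, stats::median)
      scol <- pmax(scol, 0.25 * stats::median(scol),
                   1e-9 * max(abs(B), 1))  # guard exact-repeat degeneracy
      u <- abs(R) / rep(4.685 * scol, each = M)
      W <- ifelse(u < 1, (1 - u^2)^2, 0)
      sv <- svd(W * B + (1 - W) * tmpl, nu = r, nv = r)
      tmpl <- sv$u %*% (sv$d[seq_len(r)] * t(sv$v))
    }
    for (k in seq_along(usable)) {
      i <- usable[k]
      out[ch, lo[i]:hi[i]] <- out[ch, lo[i]:hi[i]] - taper * tmpl[k, ]
    }
  }
  if (inherits(x, "recording")) return(recording(out, x$fs, x$labels))
  out
}

#' Select the channel carrying the clearest fetal rhythm
#'
#' Detects fetal beats (fetal detector parameter set) on every residual
#' channel, keeps channels whose rate falls in the fetal band, and returns
#' the one whose beat-aligned segments are most mutually consistent, as
#' measured by the eigenvalue SNR of the segment matrix.
#'
#' @param residuals channels-by-samples matrix or \code{\link{recording}} of
#'   maternal-cancelled signals.
#' @param fs sampling rate in Hz.
#' @param hr_band plausible fetal heart-rate range, bpm.
#' @return A list with \code{index}, \code{beats} and \code{snr_eig}.
#' @export
select_fetal_channel <- function(residuals, fs = NULL, hr_band = c(100, 180)) {
  m <- as_channel_matrix(residuals)
  if (inherits(residuals, "recording")) fs <- residuals$fs
  if (is.null(fs)) stop("'fs' is required for matrix input")
  best <- NULL
  diag_tab <- data.frame(channel = seq_len(nrow(m)), n_beats = NA_integer_,
                         rate_bpm = NA_real_, snr_eig = NA_real_)
  for (i in seq_len(nrow(m))) {
    b <- detect_rpeaks(m[i, ], fs, mode = "fetal")
    diag_tab$n_beats[i] <- length(b)
    if (length(b) < 5L) next
    rate <- beat_rate(b)
    diag_tab$rate_bpm[i] <- rate
    if (rate < hr_band[1] || rate > hr_band[2]) next
    U <- tryCatch(segment_matrix(m[i, ], b, pre_ms = 60, post_ms = 60),
                  error = function(e) NULL)
    if (is.null(U)) next
    s <- snr_eig(U)
    diag_tab$snr_eig[i] <- s
    if (is.null(best) || s > best$snr_eig)
      best <- list(index = i, beats = b, snr_eig = s)
  }
  if (is.null(best))
    stop(paste0("no residual channel shows a plausible fetal rhythm:\n",
                paste(utils::capture.output(print(diag_tab)), collapse = "\n")))
  best$diagnostics <- diag_tab
  best
}

#' Extract the fetal ECG from an abdominal recording
#'
#' The complete extraction pipeline: baseline-wander removal, centering and
#' PCA whitening, deflationary FastICA separation (conventional or
#' overrelaxed), maternal component selection and R-peak detection, SVD
#' cancellation of the maternal beats in every baseline-corrected channel,
#' selection of the residual channel with the clearest fetal rhythm, and
#' fetal R-peak detection on it.
#'
#' @param rec a \code{\link{recording}} with at least 2 channels and at
#'   least 10 s of signal.
#' @param config a \code{\link{fecg_config}}.
#' @param seed optional integer seed for the random initial weight vectors.
#' @param w.init optional initial weight matrix passed to
#'   \code{\link{fastica}}.
#' @return An object of class \code{"fecg"}: a list with
#'   \code{fetal_signal}, \code{fetal_beats}, \code{maternal_beats},
#'   \code{maternal_component}, \code{fetal_channel},
#'   \code{residual_channels} (a recording), \code{separation} (the
#'   \code{"fastica"} fit), \code{baseline_corrected} and \code{config}.
#' @examples
#' \donttest{
#' rec <- synth_abdominal(synth_config(duration_s = 30, seed = 2))
#' fit <- extract_fecg(rec$recording, seed = 2)
#' fit
#' }
#' @export
extract_fecg <- function(rec, config = fecg_config(), seed = NULL,
                         w.init = NULL) {
  stopifnot(inherits(rec, "recording"), inherits(config, "fecg_config"))
  if (n_channels(rec) < 2L)
    stop("extraction needs at least 2 abdominal channels")
  if (n_samples(rec) / rec$fs < 10)
    stop("extraction needs at least 10 s of signal")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  corrected <- stage("baseline",
    remove_baseline(rec, config$baseline_cutoff_hz, config$baseline_order))
  fit <- stage("separation",
    fastica(corrected, method = config$method, eps = config$eps,
            max.iter = config$max.iter, alpha.grid.N = config$alpha.grid.N,
            update.sign = config$update.sign, seed = seed, w.init = w.init))
  maternal <- stage("maternal-selection",
    select_maternal_component(fit, rec$fs, config$maternal_hr_band))
  residuals <- stage("maternal-cancellation",
    cancel_maternal(corrected, maternal$beats, config$beat_pre_ms,
                    config$beat_post_ms, config$svd_rank, config$fade_ms))
  fetal <- stage("fetal-selection",
    select_fetal_channel(residuals, rec$fs, config$fetal_hr_band))

  structure(list(
    fetal_signal = as_channel_matrix(residuals)[fetal$index, ],
    fetal_beats = fetal$beats,
    maternal_beats = maternal$beats,
    maternal_component = maternal$index,
    fetal_channel = fetal$index,
    fetal_snr_eig = fetal$snr_eig,
    residual_channels = residuals,
    separation = fit,
    baseline_corrected = corrected,
    fs = rec$fs,
    config = config), class = "fecg")
}

#' @export
print.fecg <- function(x, ...) {
  cat("Fetal ECG extraction\n")
  cat(sprintf("  separation: %s FastICA, total iterations %d\n",
              x$separation$method, x$separation$total_iterations))
  cat(sprintf("  maternal component: IC%d, %d beats (~%.0f bpm)\n",
              x$maternal_component, length(x$maternal_beats),
              beat_rate(x$maternal_beats)))
  cat(sprintf("  fetal channel: %d, %d beats (~%.0f bpm), SNR_Eig %.2f\n",
              x$fetal_channel, length(x$fetal_beats),
              beat_rate(x$fetal_beats), x$fetal_snr_eig))
  invisible(x)
}

#' @export
summary.fecg <- function(object, ...) {
  U <- segment_matrix(object$fetal_signal, object$fetal_beats,
                      pre_ms = 60, post_ms = 60)
  out <- list(
    method = object$separation$method,
    total_iterations = object$separation$total_iterations,
    alpha = object$separation$alpha,
    maternal_rate_bpm = beat_rate(object$maternal_beats),
    fetal_rate_bpm = beat_rate(object$fetal_beats),
    n_fetal_beats = length(object$fetal_beats),
    snr_eig = snr_eig(U),
    snr_rms = snr_rms(U))
  class(out) <- "summary.fecg"
  out
}

#' @export
print.summary.fecg <- function(x, ...) {
  cat(sprintf("Fetal ECG extraction (%s FastICA)\n", x$method))
  cat(sprintf("  total iterations: %d\n", x$total_iterations))
  cat(sprintf("  maternal rate: %.1f bpm; fetal rate: %.1f bpm (%d beats)\n",
              x$maternal_rate_bpm, x$fetal_rate_bpm, x$n_fetal_beats))
  cat(sprintf("  fetal segment SNR_Eig: %.3f, SNR_RMS: %.3f\n",
              x$snr_eig, x$snr_rms))
  invisible(x)
}

#' @export
plot.fecg <- function(x, max.seconds = 10, ...) {
  n <- min(length(x$fetal_signal), round(max.seconds * x$fs))
  t <- (seq_len(n) - 1) / x$fs
  graphics::plot(t, x$fetal_signal[seq_len(n)], type = "l",
                 xlab = "time (s)", ylab = "fetal ECG", ...)
  bb <- x$fetal_beats$samples[x$fetal_beats$samples <= n]
  graphics::points((bb - 1) / x$fs, x$fetal_signal[bb], col = 2, pch = 19)
  invisible(x)
}
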