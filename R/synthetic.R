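#' ECG morphology templates
#'
#' Gaussian-bump parameterization of one heartbeat: centers (ms relative to
#' the R-peak), amplitudes (R normalized to 1) and widths (ms, Gaussian
#' sigma) for the P, Q, R, S and T waves. The fetal preset narrows and
#' compresses the adult waveform, reflecting the shorter fetal cardiac
#' cycle.
#'
#' @param type \code{"adult"} or \code{"fetal"}.
#' @return A list with numeric vectors \code{mu_ms}, \code{amp},
#'   \code{sigma_ms}.
#' @export
ecg_morphology <- function(type = c("adult", "fetal")) {
  type <- match.arg(type)
  adult <- list(mu_ms = c(-170, -25, 0, 25, 190),
                amp = c(0.12, -0.12, 1.00, -0.22, 0.30),
                sigma_ms = c(20, 6, 9, 7, 35))
  if (type == "adult") return(adult)
  list(mu_ms = adult$mu_ms * 0.6, amp = adult$amp,
       sigma_ms = adult$sigma_ms * 0.55)
}

#' Synthesize a single-channel ECG with known R-peak locations
#'
#' Template-sum model: a beat template (sum of Gaussian bumps for the P, Q,
#' R, S, T waves) is placed at RR intervals 60/hr * (1 + jitter), where the
#' jitter draws are uniform on [-jitter_pct, +jitter_pct] percent. The
#' returned annotations are the exact template R centers, giving analytic
#' ground truth for detector and pipeline tests.
#'
#' @param fs sampling rate in Hz.
#' @param duration_s record length in seconds.
#' @param hr_bpm mean heart rate in beats per minute.
#' @param jitter_pct RR-interval jitter as a percentage of the mean RR.
#' @param morphology a template from \code{\link{ecg_morphology}}.
#' @param seed optional integer seed for the jitter draws.
#' @return A list with \code{signal} (numeric vector, R amplitude 1) and
#'   \code{beats} (a \code{\link{beats}} object).
#' @examples
#' sim <- synth_ecg(fs = 1000, duration_s = 30, hr_bpm = 60, jitter_pct = 0)
#' length(sim$beats)       # 30 beats
#' diff(sim$beats$samples)[1]  # 1000 ms spacing
#' @export
synth_ecg <- function(fs = 1000, duration_s = 60, hr_bpm = 80,
                      jitter_pct = 5, morphology = ecg_morphology("adult"),
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rr <- 60 / hr_bpm
  tmpl_extent <- max(abs(morphology$mu_ms) + 4 * morphology$sigma_ms) / 1000
  if (rr < 1.2 * tmpl_extent)
    stop("heart rate too high for the template extent at this morphology")
  if (fs < 100) stop("'fs' too low to resolve the QRS template")
  n <- round(duration_s * fs)
  # R times: first beat at rr/2, then jittered RR intervals
  times <- rr / 2
  repeat {
    jit <- if (jitter_pct > 0) stats::runif(1, -1, 1) * jitter_pct / 100 else 0
    nxt <- times[length(times)] + rr * (1 + jit)
    if (nxt >= duration_s) break
    times <- c(times, nxt)
  }
  r_idx <- round(times * fs) + 1L
  r_idx <- r_idx[r_idx >= 1L & r_idx <= n]

  # one template evaluated on an integer grid, added at each R index
  half <- ceiling(tmpl_extent * fs)
  grid_ms <- 1000 * (-half:half) / fs
  tmpl <- rep(0, length(grid_ms))
  for (k in seq_along(morphology$mu_ms))
    tmpl <- tmpl + morphology$amp[k] *
      exp(-0.5 * ((grid_ms - morphology$mu_ms[k]) / morphology$sigma_ms[k])^2)
  x <- numeric(n)
  for (r in r_idx) {
    lo <- max(1L, r - half); hi <- min(n, r + half)
    x[lo:hi] <- x[lo:hi] + tmpl[(lo - r + half + 1L):(hi - r + half + 1L)]
  }
  list(signal = x, beats = beats(r_idx, fs))
}

#' Simulator configuration
#'
#' Conditions of the default synthetic abdominal recording: 1 kHz sampling,
#' four abdominal channels, maternal rhythm near 80 bpm and fetal rhythm
#' near 140 bpm (incommensurate, so the two beat trains stay asynchronous),
#' and a maternal-to-fetal amplitude ratio of 4 at the strongest channel,
#' inside the physiological 2-10 range for abdominal leads. Baseline wander
#' is a sub-0.5 Hz sinusoid per channel; powerline interference is off by
#' default.
#'
#' @param fs sampling rate in Hz.
#' @param duration_s record length in seconds (at least 10).
#' @param maternal_hr_bpm,fetal_hr_bpm mean heart rates.
#' @param jitter_pct RR jitter for both rhythms, percent.
#' @param amplitude_ratio maternal/fetal peak-to-peak ratio at the strongest
#'   channel; must lie in [2, 10].
#' @param n_channels number of abdominal channels.
#' @param noise_std per-channel additive white Gaussian noise sd, in the
#'   units where the strongest maternal R peak-to-peak is 1.
#' @param baseline_amp,baseline_freq_hz sinusoidal baseline wander amplitude
#'   and frequency (frequency must stay below 0.5 Hz).
#' @param powerline_hz powerline tone frequency (0 disables it).
#' @param powerline_amp powerline tone amplitude.
#' @param muscle_std sd of an optional shared broadband muscle-noise source
#'   routed through the mixing matrix (0 disables it).
#' @param seed integer seed; the full record is reproducible from the
#'   configuration and this seed.
#' @return A list of class \code{"synth_config"}.
#' @export
synth_config <- function(fs = 1000, duration_s = 60, maternal_hr_bpm = 80,
                         fetal_hr_bpm = 140, jitter_pct = 5,
                         amplitude_ratio = 4, n_channels = 4,
                         noise_std = 0.02, baseline_amp = 0.5,
                         baseline_freq_hz = 0.25, powerline_hz = 0,
                         powerline_amp = 0.1, muscle_std = 0, seed = 1) {
  if (amplitude_ratio < 2 || amplitude_ratio > 10)
    stop("'amplitude_ratio' must lie in [2, 10]")
  if (duration_s < 10) stop("'duration_s' must be at least 10 s")
  if (baseline_freq_hz >= 0.5) stop("'baseline_freq_hz' must be below 0.5 Hz")
  if (fs <= 2 * max(50, powerline_hz)) stop("'fs' too low for the configured tones")
  structure(as.list(environment()), class = "synth_config")
}

#' Synthesize a multichannel abdominal recording with ground truth
#'
#' Generates maternal and fetal single-channel ECGs (plus an optional shared
#' muscle-noise source), mixes them through a random full-rank matrix whose
#' columns are scaled so the maternal/fetal peak-to-peak ratio at the
#' strongest channel equals \code{amplitude_ratio} (per-channel ratios then
#' stay within the physiological 2-10 band at the default mixing spread),
#' and adds per-channel white noise, sinusoidal baseline wander and an
#' optional powerline tone. The mixing matrix, clean sources, and both beat
#' trains are retained as ground truth.
#'
#' @param config a \code{\link{synth_config}}.
#' @return A list of class \code{"synth_record"} with \code{recording} (a
#'   \code{\link{recording}}), \code{mixing}, \code{sources},
#'   \code{maternal_beats}, \code{fetal_beats} and \code{config}.
#' @examples
#' rec <- synth_abdominal(synth_config(duration_s = 12, seed = 3))
#' rec$recording
#' @export
synth_abdominal <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  fs <- config$fs
  n <- round(config$duration_s * fs)

  mat <- synth_ecg(fs, config$duration_s, config$maternal_hr_bpm,
                   config$jitter_pct, ecg_morphology("adult"))
  fet <- synth_ecg(fs, config$duration_s, config$fetal_hr_bpm,
                   config$jitter_pct, ecg_morphology("fetal"))
  sources <- rbind(maternal = mat$signal, fetal = fet$signal)
  if (config$muscle_std > 0)
    sources <- rbind(sources, muscle = stats::rnorm(n, sd = config$muscle_std))
  ns <- nrow(sources)
  if (ns > config$n_channels)
    stop("more sources than channels: the mixing cannot be full rank")

  # mixing magnitudes in [0.7, 1.3] with random signs keep per-channel
  # maternal/fetal ratios inside [2, 10] once columns are scaled
  repeat {
    A <- matrix(stats::runif(config$n_channels * ns, 0.7, 1.3),
                config$n_channels, ns) *
         matrix(sample(c(-1, 1), config$n_channels * ns, replace = TRUE),
                config$n_channels, ns)
    if (min(svd(A)$d) > 0.1) break
  }
  # scale columns: strongest fetal channel has pk-pk 0.25 units, strongest
  # maternal channel amplitude_ratio times that
  pk_m <- diff(range(sources["maternal", ]))
  pk_f <- diff(range(sources["fetal", ]))
  A[, 2] <- A[, 2] * 0.25 / (max(abs(A[, 2])) * pk_f)
  A[, 1] <- A[, 1] * config$amplitude_ratio * 0.25 / (max(abs(A[, 1])) * pk_m)

  X <- A %*% sources
  if (config$noise_std > 0)
    X <- X + matrix(stats::rnorm(length(X), sd = config$noise_std), nrow(X))
  if (config$baseline_amp > 0) {
    t <- (seq_len(n) - 1) / fs
    for (i in seq_len(nrow(X)))
      X[i, ] <- X[i, ] + config$baseline_amp *
        sin(2 * pi * config$baseline_freq_hz * t + stats::runif(1, 0, 2 * pi))
  }
  if (config$powerline_hz > 0) {
    t <- (seq_len(n) - 1) / fs
    for (i in seq_len(nrow(X)))
      X[i, ] <- X[i, ] + config$powerline_amp *
        sin(2 * pi * config$powerline_hz * t + stats::runif(1, 0, 2 * pi))
  }

  structure(list(
    recording = recording(X, fs, paste0("abd", seq_len(nrow(X)))),
    mixing = A, sources = sources,
    maternal_beats = mat$beats, fetal_beats = fet$beats,
    config = config), class = "synth_record")
}

#' @export
print.synth_record <- function(x, ...) {
  cat("Synthetic abdominal record\n")
  print(x$recording)
  cat(sprintf("Maternal: %d beats (~%.0f bpm); fetal: %d beats (~%.0f bpm)\n",
              length(x$maternal_beats), beat_rate(x$maternal_beats),
              length(x$fetal_beats), beat_rate(x$fetal_beats)))
  invisible(x)
}

#' Seeded super-Gaussian test mixture
#'
#' Draws independent unit-variance Laplace sources, mixes them through a
#' random well-conditioned square matrix, and optionally adds white Gaussian
#' sensor noise at a given SNR. Used to exercise the separation algorithms
#' against a known mixing matrix (see \code{\link{amari_index}}).
#'
#' @param n_sources number of sources (= channels).
#' @param n_samples samples per source.
#' @param noise_db sensor SNR in dB; \code{Inf} (default) for noiseless.
#' @param seed optional integer seed.
#' @return A list with \code{X} (mixed channels), \code{A} (mixing matrix)
#'   and \code{S} (sources).
#' @export
synth_mixture <- function(n_sources = 4, n_samples = 10000, noise_db = Inf,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  # unit-variance Laplace via difference of exponentials
  S <- matrix(stats::rexp(n_sources * n_samples, rate = sqrt(2)) -
              stats::rexp(n_sources * n_samples, rate = sqrt(2)),
              n_sources, n_samples)
  repeat {
    A <- matrix(stats::rnorm(n_sources^2), n_sources)
    if (min(svd(A)$d) > 0.2) break
  }
  X <- A %*% S
  if (is.finite(noise_db)) {
    sig_pow <- mean(X^2)
    X <- X + matrix(stats::rnorm(length(X),
                                 sd = sqrt(sig_pow / 10^(noise_db / 10))),
                    nrow(X))
  }
  list(X = X, A = A, S = S)
}
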