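#' Multichannel recording container
#'
#' Bundles a channels-by-samples numeric matrix with its sampling rate and
#' channel labels. All pipeline stages consume and return this container so
#' that sample indices keep a fixed time base throughout.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate in Hz.
#' @param labels optional character vector of channel names; defaults to
#'   \code{ch1, ch2, ...}.
#'
#' @return An object of class \code{"recording"}: a list with elements
#'   \code{data}, \code{fs} and \code{labels}.
#' @examples
#' rec <- recording(matrix(rnorm(200), 2), fs = 100)
#' n_samples(rec)
#' @export
recording <- function(data, fs, labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 1L)
    stop("recording needs at least one channel")
  if (ncol(data) <= nrow(data))
    stop("recording needs more samples than channels (is the matrix transposed?)")
  if (!all(is.finite(data)))
    stop("recording contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a positive scalar sampling rate in Hz")
  if (is.null(labels))
    labels <- paste0("ch", seq_len(nrow(data)))
  if (length(labels) != nrow(data))
    stop("'labels' length must match the number of channels")
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = as.character(labels)),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("Multichannel recording: %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("Channels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.matrix.recording <- function(x, ...) x$data

#' @rdname recording
#' @param x a \code{recording}.
#' @export
n_channels <- function(x) nrow(as_channel_matrix(x))

#' @rdname recording
#' @export
n_samples <- function(x) ncol(as_channel_matrix(x))

# Accept either a recording or a bare channels x samples matrix.
as_channel_matrix <- function(x) {
  if (inherits(x, "recording")) return(x$data)
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  m
}

#' R-peak annotation container
#'
#' Ordered R-peak sample indices for a single signal. Indices are 1-based
#' sample positions (R convention); \code{write_beats()} serializes both the
#' index and the time in seconds.
#'
#' @param samples integer vector of strictly increasing sample indices.
#' @param fs sampling rate in Hz of the annotated signal.
#' @return An object of class \code{"beats"}.
#' @examples
#' beats(c(100, 600, 1100), fs = 500)
#' @export
beats <- function(samples, fs) {
  samples <- as.integer(round(samples))
  if (length(samples) && any(diff(samples) <= 0L))
    stop("beat sample indices must be strictly increasing")
  if (length(samples) && samples[1] < 1L)
    stop("beat sample indices must be >= 1")
  if (!is.numeric(fs) || fs <= 0)
    stop("'fs' must be a positive sampling rate")
  structure(list(samples = samples, fs = fs), class = "beats")
}

#' @export
print.beats <- function(x, ...) {
  n <- length(x$samples)
  cat(sprintf("Beat annotations: %d beats @ %g Hz", n, x$fs))
  if (n >= 2L) {
    rr <- diff(x$samples) / x$fs
    cat(sprintf("; mean rate %.1f bpm", 60 / mean(rr)))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.beats <- function(x) length(x$samples)

# heart rate in bpm from annotations (NA if fewer than 2 beats)
beat_rate <- function(b) {
  if (length(b$samples) < 2L) return(NA_real_)
  60 / mean(diff(b$samples) / b$fs)
}
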