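#' Benchmark separation methods on one recording
#'
#' Repeats the full extraction with fresh random initial weight vectors for
#' each method and tabulates, per repeat, the total iteration count across
#' the deflation stages and the fetal-segment SNR metrics; when ground-truth
#' fetal annotations are available (a synthetic record, or reference
#' annotations) the beat-detection statistics are added. An averages row per
#' method closes the table. Because iteration counts depend on the random
#' initial weight vector, the run-to-run spread is part of the result.
#'
#' @param x a \code{\link{recording}} or a \code{"synth_record"} from
#'   \code{\link{synth_abdominal}} (whose ground truth is then used).
#' @param n_repeats repeats per method (default 10).
#' @param methods methods to compare.
#' @param config a \code{\link{fecg_config}}; its \code{method} field is
#'   overridden per run.
#' @param reference optional fetal reference \code{\link{beats}} when
#'   \code{x} is a plain recording.
#' @param seed integer seed for the stream of initial weight vectors.
#' @return A data.frame of class \code{"fecg_benchmark"} with one row per
#'   (method, repeat) plus one averages row per method; columns
#'   \code{method}, \code{repeat_no}, \code{total_iterations},
#'   \code{snr_eig}, \code{snr_rms}, and when a reference is available
#'   \code{TP}, \code{FP}, \code{FN}, \code{Sens}, \code{PPA}, \code{F1}.
#' @export
run_benchmark <- function(x, n_repeats = 10,
                          methods = c("improved", "conventional"),
                          config = fecg_config(), reference = NULL,
                          seed = 1) {
  if (inherits(x, "synth_record")) {
    reference <- x$fetal_beats
    x <- x$recording
  }
  stopifnot(inherits(x, "recording"), n_repeats >= 1)
  set.seed(seed)
  p <- n_channels(x)
  inits <- lapply(seq_len(n_repeats),
                  function(i) matrix(stats::rnorm(p * p), p, p))
  rows <- list()
  for (method in methods) {
    cfg <- config
    cfg$method <- method
    for (r in seq_len(n_repeats)) {
      row <- data.frame(method = method, repeat_no = r,
                        total_iterations = NA_integer_,
                        snr_eig = NA_real_, snr_rms = NA_real_,
                        error = NA_character_)
      fit <- tryCatch(extract_fecg(x, cfg, w.init = inits[[r]]),
                      error = function(e) e)
      if (inherits(fit, "error")) {
        row$error <- conditionMessage(fit)
      } else {
        row$total_iterations <- fit$separation$total_iterations
        U <- tryCatch(segment_matrix(fit$fetal_signal, fit$fetal_beats,
                                     pre_ms = 60, post_ms = 60),
                      error = function(e) NULL)
        if (!is.null(U)) {
          row$snr_eig <- snr_eig(U)
          row$snr_rms <- snr_rms(U)
        }
        if (!is.null(reference)) {
          counts <- match_beats(fit$fetal_beats, reference,
                                tol_ms = config$match_tol_ms)
          st <- detection_stats(counts)
          row$TP <- counts$TP; row$FP <- counts$FP; row$FN <- counts$FN
          row$Sens <- st["Sens"]; row$PPA <- st["PPA"]; row$F1 <- st["F1"]
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  # averages row per method over successful repeats
  for (method in methods) {
    sub <- tab[tab$method == method & is.na(tab$error), , drop = FALSE]
    if (!nrow(sub)) next
    avg <- sub[1, ]
    avg$repeat_no <- NA_integer_
    num <- setdiff(names(sub)[vapply(sub, is.numeric, logical(1))], "repeat_no")
    for (cn in num) avg[[cn]] <- mean(sub[[cn]], na.rm = TRUE)
    avg$method <- paste0(method, " (average)")
    tab <- rbind(tab, avg)
  }
  rownames(tab) <- NULL
  class(tab) <- c("fecg_benchmark", class(tab))
  tab
}

#' @export
print.fecg_benchmark <- function(x, ...) {
  y <- as.data.frame(x)
  y$error <- NULL
  print(y, digits = 4, row.names = FALSE)
  n_err <- sum(!is.na(x$error))
  if (n_err) cat(sprintf("(%d repeat(s) failed; see $error)\n", n_err))
  invisible(x)
}
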