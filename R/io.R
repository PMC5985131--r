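#' Read a multichannel recording
#'
#' Loads a recording from CSV, EDF or WFDB files into a
#' \code{\link{recording}}.
#'
#' CSV dialect: comma-separated with a header row of channel labels, one
#' sample per row, '.' decimal separator; an optional first column named
#' \code{time_s} carries the time axis (used to infer \code{fs} when it is
#' not supplied). EDF support covers continuous EDF/EDF+ records with a
#' common sampling rate across the selected signals. WFDB support covers the
#' text \code{.hea} header plus format-16 (little-endian 16-bit) \code{.dat}
#' files, the layout used by the abdominal/direct fetal ECG database
#' records. For five-channel records laid out as a direct fetal scalp
#' reference plus abdominal leads, channels whose label contains
#' \code{"direct"} or \code{"scalp"} are split off: they are excluded from
#' the returned abdominal matrix and attached as the \code{"reference"}
#' attribute (a single-channel recording) instead.
#'
#' @param path file path (.csv, .edf, or a WFDB .hea/.dat basename).
#' @param format \code{"auto"} (by extension), \code{"csv"}, \code{"edf"} or
#'   \code{"wfdb"}.
#' @param fs sampling rate override for CSV files without a time column.
#' @param drop_reference split off direct fetal scalp channels (default
#'   TRUE); see Details.
#' @return A \code{\link{recording}}, possibly with a \code{"reference"}
#'   attribute.
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf", "wfdb"),
                           fs = NULL, drop_reference = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", edf = "edf", hea = "wfdb",
                     dat = "wfdb",
                     stop(sprintf("cannot infer the format of '%s'", path)))
  }
  rec <- switch(format,
                csv = read_recording_csv_(path, fs),
                edf = read_edf_(path),
                wfdb = read_wfdb_(path))
  if (drop_reference) {
    is_ref <- grepl("direct|scalp", rec$labels, ignore.case = TRUE)
    if (any(is_ref) && !all(is_ref)) {
      ref <- rec$data[is_ref, , drop = FALSE]
      rec2 <- recording(rec$data[!is_ref, , drop = FALSE], rec$fs,
                        rec$labels[!is_ref])
      attr(rec2, "reference") <- list(data = ref, fs = rec$fs,
                                      labels = rec$labels[is_ref])
      return(rec2)
    }
  }
  rec
}

read_recording_csv_ <- function(path, fs = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (!nrow(df)) stop("empty CSV recording")
  has_time <- identical(names(df)[1], "time_s")
  if (has_time) {
    tcol <- df[[1]]
    df <- df[-1]
    if (is.null(fs)) {
      dt <- diff(tcol)
      fs <- 1 / stats::median(dt)
    }
  }
  if (is.null(fs))
    stop("CSV has no 'time_s' column; supply 'fs'")
  recording(t(as.matrix(df)), fs, names(df))
}

#' Write a recording to CSV
#'
#' Serializes a \code{\link{recording}} in the package's CSV dialect (header
#' row of channel labels, one sample per row, optional leading
#' \code{time_s} column). Values are written with 17 significant digits so a
#' write-read round trip is bit-identical.
#'
#' @param rec a \code{\link{recording}}.
#' @param path output file path.
#' @param time_column include the \code{time_s} column (default TRUE).
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(rec, path, time_column = TRUE) {
  stopifnot(inherits(rec, "recording"))
  m <- t(rec$data)
  cols <- lapply(seq_len(ncol(m)), function(j)
    formatC(m[, j], digits = 17, format = "g"))
  names(cols) <- rec$labels
  if (time_column) {
    t_s <- formatC((seq_len(nrow(m)) - 1) / rec$fs, digits = 17, format = "g")
    cols <- c(list(time_s = t_s), cols)
  }
  df <- as.data.frame(cols, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write beat annotations
#'
#' Beat annotations are serialized as a two-column CSV
#' (\code{sample_index}, \code{time_s}); \code{sample_index} is the 1-based
#' sample position of each R-peak.
#'
#' @param b a \code{\link{beats}} object.
#' @param path file path.
#' @param fs sampling rate used to reconstruct annotations when reading a
#'   file whose time column is missing; normally inferred from the file.
#' @return \code{write_beats} returns \code{path} invisibly;
#'   \code{read_beats} returns a \code{\link{beats}} object.
#' @export
write_beats <- function(b, path) {
  stopifnot(inherits(b, "beats"))
  df <- data.frame(sample_index = b$samples,
                   time_s = (b$samples - 1) / b$fs)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_beats
#' @export
read_beats <- function(path, fs = NULL) {
  df <- utils::read.csv(path)
  if (is.null(fs)) {
    if (!"time_s" %in% names(df) || nrow(df) < 2)
      stop("cannot infer 'fs'; supply it explicitly")
    fs <- (df$sample_index[2] - df$sample_index[1]) /
      (df$time_s[2] - df$time_s[1])
  }
  beats(df$sample_index, fs)
}

# --- minimal EDF reader (continuous EDF/EDF+, int16 samples) ---------------
read_edf_ <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_chr <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  hdr_num <- function(n) as.numeric(hdr_chr(n))
  hdr_chr(8)                       # version
  hdr_chr(80); hdr_chr(80)         # patient / recording id
  hdr_chr(8); hdr_chr(8)           # start date / time
  hdr_num(8)                       # header bytes
  hdr_chr(44)                      # reserved
  n_rec <- hdr_num(8)
  rec_dur <- hdr_num(8)
  ns <- as.integer(hdr_num(4))
  field <- function(w) vapply(seq_len(ns), function(i) hdr_chr(w), character(1))
  labels <- field(16)
  field(80); field(8)              # transducer, physical dimension
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80)                        # prefiltering
  nsamp <- as.integer(field(8))    # samples per data record, per signal
  field(32)                        # reserved
  if (n_rec < 0) stop("EDF header does not declare the number of data records")
  keep <- !grepl("^EDF Annotations", labels)
  if (length(unique(nsamp[keep])) != 1L)
    stop("EDF signals have differing sampling rates; not supported")
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- vector("list", ns)
  for (i in seq_len(ns)) data[[i]] <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = nsamp[i], size = 2,
                     signed = TRUE, endian = "little")
      data[[i]][[r]] <- raw
    }
  }
  sig <- lapply(which(keep), function(i)
    phys_min[i] + gain[i] * (unlist(data[[i]]) - dig_min[i]))
  fs <- nsamp[keep][1] / rec_dur
  recording(do.call(rbind, sig), fs, labels[keep])
}

# --- minimal WFDB reader (.hea text header + format-16 .dat) ---------------
read_wfdb_ <- function(path) {
  base <- sub("\\.(hea|dat)$", "", path)
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) stop(sprintf("file not found: '%s'", hea))
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  ns <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*", "", top[3])) else 250
  n_samp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig_lines <- lines[2:(1 + ns)]
  parse_sig <- function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    fmt <- sub("x.*", "", f[2])
    gain_field <- if (length(f) >= 3) f[3] else "200"
    baseline <- 0
    if (grepl("\\(", gain_field))
      baseline <- as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_field))
    gain <- as.numeric(sub("[(/].*", "", gain_field))
    if (!is.finite(gain) || gain == 0) gain <- 200
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ")
            else paste0("sig", f[1])
    list(file = f[1], fmt = fmt, gain = gain, baseline = baseline, desc = desc)
  }
  sigs <- lapply(sig_lines, parse_sig)
  fmts <- unique(vapply(sigs, `[[`, character(1), "fmt"))
  if (!identical(fmts, "16"))
    stop(sprintf("only WFDB format 16 is supported (found: %s)",
                 paste(fmts, collapse = ", ")))
  datf <- file.path(dirname(hea), unique(vapply(sigs, `[[`, character(1), "file")))
  if (length(datf) != 1L) stop("multi-file WFDB records are not supported")
  raw <- readBin(datf, "integer", n = file.size(datf) / 2, size = 2,
                 signed = TRUE, endian = "little")
  n_avail <- length(raw) %/% ns
  if (is.na(n_samp)) n_samp <- n_avail
  m <- matrix(raw[seq_len(ns * n_samp)], nrow = ns)
  for (i in seq_len(ns))
    m[i, ] <- (m[i, ] - sigs[[i]]$baseline) / sigs[[i]]$gain
  recording(m, fs, vapply(sigs, `[[`, character(1), "desc"))
}

#' Load a pipeline / simulator configuration from YAML
#'
#' Reads a YAML file whose top-level keys match the arguments of
#' \code{\link{fecg_config}} (section \code{pipeline}) and
#' \code{\link{synth_config}} (section \code{synth}); missing keys keep
#' their defaults.
#'
#' @param path YAML file path.
#' @return A list with elements \code{pipeline} and \code{synth}.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  pl <- do.call(fecg_config, y$pipeline %||% list())
  sy <- do.call(synth_config, y$synth %||% list())
  list(pipeline = pl, synth = sy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run report
#'
#' Serializes the configuration snapshot, seed, per-component iteration
#' counts and overrelaxation factors, selected components and any warnings
#' of an extraction run to JSON, sufficient to re-run it identically.
#'
#' @param fit an \code{"fecg"} result from \code{\link{extract_fecg}}.
#' @param path output JSON path.
#' @param seed the seed the run was started with.
#' @param warnings character vector of warnings to record.
#' @return The report list, invisibly.
#' @export
write_run_report <- function(fit, path, seed = NULL, warnings = character(0)) {
  stopifnot(inherits(fit, "fecg"))
  report <- list(
    seed = seed,
    config = unclass(fit$config),
    method = fit$separation$method,
    iterations = fit$separation$iterations,
    total_iterations = fit$separation$total_iterations,
    alpha = fit$separation$alpha,
    converged = fit$separation$converged,
    maternal_component = fit$maternal_component,
    fetal_channel = fit$fetal_channel,
    n_maternal_beats = length(fit$maternal_beats),
    n_fetal_beats = length(fit$fetal_beats),
    warnings = warnings)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}
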