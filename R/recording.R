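#' Multichannel recording container
#'
#' Light S3 container for a sampled multichannel time series: a numeric
#' matrix (samples in rows, channels in columns), the sampling rate, channel
#' labels and two pieces of study metadata, the condition (`"W"` wakefulness
#' or `"A"` anaesthesia) and the modality (`"ECOG"` for intracranial,
#' `"RS"` for reconstructed sources, `"SYNTH"` for synthetic data).
#'
#' @param data numeric matrix, `n_samples x n_channels`.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_labels character vector, one label per column. Defaults to
#'   existing column names or `ch1, ch2, ...`.
#' @param condition `"W"`, `"A"` or `NA`.
#' @param modality `"ECOG"`, `"RS"`, `"SYNTH"` or `NA`.
#'
#' @return An object of class `mc_recording` with fields `data`, `fs`,
#'   `channel_labels`, `condition`, `modality`.
#' @export
mc_recording <- function(data, fs, channel_labels = NULL,
                         condition = NA_character_, modality = NA_character_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 1L) stop("recording must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar (Hz)")
  if (is.null(channel_labels)) {
    channel_labels <- colnames(data)
    if (is.null(channel_labels))
      channel_labels <- paste0("ch", seq_len(ncol(data)))
  }
  if (length(channel_labels) != ncol(data))
    stop("channel_labels length (", length(channel_labels),
         ") does not match number of channels (", ncol(data), ")")
  if (!is.na(condition)) condition <- match.arg(condition, c("W", "A"))
  if (!is.na(modality)) modality <- match.arg(modality, c("ECOG", "RS", "SYNTH"))
  colnames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = as.character(channel_labels),
         condition = condition, modality = modality),
    class = "mc_recording")
}

#' @export
print.mc_recording <- function(x, ...) {
  cat(sprintf("<mc_recording> %d samples x %d channels @ %g Hz (%.3g s)\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$data) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  cat("  condition:", x$condition, " modality:", x$modality, "\n")
  invisible(x)
}

n_channels <- function(rec) ncol(rec$data)
n_samples <- function(rec) nrow(rec$data)

#' Read a multichannel recording from delimited text
#'
#' The delimited dialect is comma-separated with one header row of channel
#' labels followed by numeric rows (one sample per row, `.` decimal mark).
#' The sampling rate is not stored in the file and must be supplied.
#'
#' @param path file path.
#' @param fs sampling rate in Hz.
#' @param format only `"delimited"` is supported.
#' @param condition,modality optional metadata tags, see [mc_recording()].
#' @return An [mc_recording()].
#' @export
read_timeseries <- function(path, fs, format = c("delimited"),
                            condition = NA_character_, modality = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("file must contain a header row and data rows: ", path)
  labels <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  k <- length(labels)
  rows <- strsplit(lines[-1L], ",", fixed = TRUE)
  nfield <- lengths(rows)
  if (any(nfield != k)) {
    bad <- which(nfield != k)[1L]
    stop(sprintf("ragged row %d: expected %d fields, found %d",
                 bad + 1L, k, nfield[bad]))
  }
  cells <- unlist(rows, use.names = FALSE)
  vals <- suppressWarnings(as.numeric(cells))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    row <- (bad - 1L) %/% k + 2L   # 1-based file row incl. header
    col <- (bad - 1L) %% k + 1L
    stop(sprintf("non-numeric value %s at row %d, column %d (%s)",
                 dQuote(cells[bad]), row, col, labels[col]))
  }
  data <- matrix(vals, ncol = k, byrow = TRUE)
  mc_recording(data, fs = fs, channel_labels = trimws(labels),
               condition = condition, modality = modality)
}

#' Write a multichannel recording as delimited text
#'
#' Inverse of [read_timeseries()]; values are written with full double
#' precision (17 significant digits) so a write/read round trip reproduces
#' the matrix to better than 1e-12.
#'
#' @param rec an [mc_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(rec, path) {
  stopifnot(inherits(rec, "mc_recording"))
  header <- paste(rec$channel_labels, collapse = ",")
  body <- apply(rec$data, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = ","))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Set of equal-length analysis segments
#'
#' @param segments list of numeric matrices, all `seg_len x n_channels`.
#' @param fs sampling rate in Hz.
#' @param labels optional channel labels (default: column names of the
#'   first segment).
#' @param condition,modality metadata inherited from the parent recording.
#' @return An object of class `segment_set`.
#' @export
segment_set <- function(segments, fs, labels = NULL,
                        condition = NA_character_,
                        modality = NA_character_) {
  stopifnot(is.list(segments), length(segments) >= 1L)
  dims <- vapply(segments, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("all segments must share the same dimensions")
  if (is.null(labels)) labels <- colnames(segments[[1L]])
  if (is.null(labels)) labels <- paste0("ch", seq_len(dims[2L, 1L]))
  structure(
    list(segments = segments, fs = fs,
         seg_duration_s = dims[1L, 1L] / fs, labels = labels,
         condition = condition, modality = modality),
    class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  d <- dim(x$segments[[1L]])
  cat(sprintf("<segment_set> %d segments of %g s (%d x %d) @ %g Hz [%s/%s]\n",
              length(x$segments), x$seg_duration_s, d[1L], d[2L], x$fs,
              x$condition, x$modality))
  invisible(x)
}
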