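#' Construct a uniformly sampled single-channel time series
#'
#' The basic container for one physiological channel (blood pressure in mmHg,
#' or a transillumination quotient in arbitrary units). Samples must be finite
#' and uniformly spaced at sampling rate `fs`.
#'
#' @param samples Numeric vector of signal values (length >= 2, all finite).
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_label Channel name, e.g. `"BP"`, `"TQ_LEFT"`.
#' @param subject_id Subject identifier.
#' @return An object of class `sas_ts` with fields `samples`, `fs`,
#'   `channel_label`, `subject_id`.
#' @examples
#' ts <- time_series(sin(2 * pi * (0:99) / 10), fs = 10, channel_label = "BP")
#' ts$fs
#' @export
time_series <- function(samples, fs, channel_label = "signal",
                        subject_id = "subject") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("time series must contain at least 2 samples")
  if (!all(is.finite(samples)))
    stop("time series contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number (Hz)")
  structure(
    list(samples = samples, fs = fs,
         channel_label = as.character(channel_label),
         subject_id = as.character(subject_id)),
    class = "sas_ts"
  )
}

#' @export
print.sas_ts <- function(x, ...) {
  cat(sprintf("<sas_ts> %s / %s: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$channel_label, length(x$samples), x$fs,
              (length(x$samples) - 1) / x$fs))
  invisible(x)
}

#' @export
length.sas_ts <- function(x) length(x$samples)

#' Sample times of a time series
#'
#' @param ts A [time_series()] object.
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
sample_times <- function(ts) {
  stopifnot(inherits(ts, "sas_ts"))
  (seq_along(ts$samples) - 1) / ts$fs
}

#' Construct a multi-channel record
#'
#' Bundles simultaneously recorded channels (typically BP, TQ_LEFT, TQ_RIGHT)
#' that share a sampling rate and length.
#'
#' @param channels Named list of [time_series()] objects with equal `fs` and
#'   length; names must be unique.
#' @param subject_id Subject identifier (propagated to all channels).
#' @return An object of class `sas_record`.
#' @export
multi_channel_record <- function(channels, subject_id = "subject") {
  if (!is.list(channels) || length(channels) == 0L)
    stop("'channels' must be a non-empty named list of time series")
  nm <- names(channels)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    stop("channel names must be present and unique")
  if (!all(vapply(channels, inherits, logical(1), "sas_ts")))
    stop("all channels must be 'sas_ts' objects")
  fs <- vapply(channels, `[[`, numeric(1), "fs")
  len <- vapply(channels, function(ch) length(ch$samples), integer(1))
  if (length(unique(fs)) != 1L)
    stop("all channels must share the same sampling rate")
  if (length(unique(len)) != 1L)
    stop("all channels must have the same length")
  subject_id <- as.character(subject_id)
  for (i in seq_along(channels)) {
    channels[[i]]$subject_id <- subject_id
    channels[[i]]$channel_label <- nm[i]
  }
  structure(list(channels = channels, subject_id = subject_id),
            class = "sas_record")
}

#' @export
print.sas_record <- function(x, ...) {
  ch <- x$channels[[1L]]
  cat(sprintf("<sas_record> %s: %s | %d samples @ %g Hz\n", x$subject_id,
              paste(names(x$channels), collapse = ", "),
              length(ch$samples), ch$fs))
  invisible(x)
}

# Guess the field delimiter of a delimited text line (comma beats tab beats
# whitespace).
.guess_sep <- function(line) {
  if (grepl(",", line, fixed = TRUE)) return(",")
  if (grepl("\t", line, fixed = TRUE)) return("\t")
  ""
}

#' Read a delimited multi-channel signal table
#'
#' Reads a CSV/TSV file with one column per channel. If the first row is
#' non-numeric it is treated as a header; header names are used as channel
#' names when `channel_names` is omitted. Any non-numeric or missing cell in
#' the body is an error that names the offending row and column -- values are
#' never silently dropped.
#'
#' @param path Path to the delimited text file.
#' @param fs Sampling rate in Hz of the recording (the file carries no rate).
#' @param channel_names Optional character vector of channel names overriding
#'   the header (or naming headerless columns).
#' @param subject_id Subject identifier.
#' @param sep Field separator; guessed from the first line by default.
#' @return A [multi_channel_record()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(BP = rnorm(10), TQL = rnorm(10)), f, row.names = FALSE)
#' rec <- read_signal_table(f, fs = 10)
#' names(rec$channels)
#' @export
read_signal_table <- function(path, fs, channel_names = NULL,
                              subject_id = "subject", sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path)
  if (is.null(sep)) sep <- .guess_sep(first)
  fields <- if (sep == "") strsplit(trimws(first), "[[:space:]]+")[[1L]] else
    strsplit(first, sep, fixed = TRUE)[[1L]]
  has_header <- any(is.na(suppressWarnings(as.numeric(fields))))
  raw <- utils::read.table(path, header = has_header, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE)
  if (!is.null(channel_names)) {
    if (length(channel_names) != ncol(raw))
      stop(sprintf("column count mismatch: file has %d columns, %d names given",
                   ncol(raw), length(channel_names)))
    names(raw) <- channel_names
  } else if (!has_header) {
    names(raw) <- paste0("ch", seq_len(ncol(raw)))
  }
  mat <- suppressWarnings(vapply(raw, as.numeric, numeric(nrow(raw))))
  mat <- matrix(mat, nrow = nrow(raw), dimnames = list(NULL, names(raw)))
  bad <- which(!is.finite(mat), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric or missing value at data row %d, column '%s' in %s",
                 bad[1L, 1L], colnames(mat)[bad[1L, 2L]], path))
  }
  channels <- lapply(colnames(mat), function(nm)
    time_series(mat[, nm], fs = fs, channel_label = nm,
                subject_id = subject_id))
  names(channels) <- colnames(mat)
  multi_channel_record(channels, subject_id = subject_id)
}

#' Write a multi-channel record as a delimited table
#'
#' Inverse of [read_signal_table()]: one column per channel with a header row.
#'
#' @param record A [multi_channel_record()].
#' @param path Output file path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(record, path, sep = ",") {
  stopifnot(inherits(record, "sas_record"))
  df <- as.data.frame(lapply(record$channels, function(ch)
    sprintf("%.17g", ch$samples)), check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a JSON sidecar describing a recording
#'
#' The sidecar carries the metadata a bare signal table cannot: sampling rate,
#' subject id and channel roles.
#'
#' @param path Sidecar file path.
#' @param fs Sampling rate in Hz.
#' @param subject_id Subject identifier.
#' @param channels Character vector of channel names, in column order.
#' @return `write_sidecar()` returns `path` invisibly; `read_sidecar()`
#'   returns a list with elements `fs`, `subject_id`, `channels`.
#' @export
write_sidecar <- function(path, fs, subject_id, channels) {
  jsonlite::write_json(
    list(fs = fs, subject_id = subject_id, channels = as.list(channels)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sidecar
#' @export
read_sidecar <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(fs = as.numeric(meta$fs), subject_id = as.character(meta$subject_id),
       channels = as.character(meta$channels))
}

#' Read a cohort metadata table
#'
#' @param path CSV file with columns `subject_id`, `age`, `sex`.
#' @return A data frame with those columns validated (unique ids, age > 0,
#'   sex in male/female).
#' @export
read_cohort_metadata <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "sex")
  if (!all(need %in% names(meta)))
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(meta$subject_id)) stop("duplicate subject_id in metadata")
  if (any(!is.finite(meta$age)) || any(meta$age <= 0))
    stop("ages must be positive")
  if (!all(meta$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  meta
}
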