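#' EEG recording container
#'
#' An `eeg_record` holds a multichannel EEG signal as a channels-by-time
#' matrix of amplitudes in microvolts, together with its sampling rate and
#' channel labels. All downstream stages (artifact handling, rhythm
#' extraction, fatigue scoring) operate on this container.
#'
#' @param samples numeric matrix, channels x time, amplitudes in uV. A plain
#'   numeric vector is treated as a single channel.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param channel_labels character vector of channel names; defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @param start_time optional `POSIXct` start time of the recording.
#'
#' @return an object of class `eeg_record` with elements `samples`,
#'   `sampling_rate`, `channel_labels`, `start_time`.
#' @examples
#' rec <- eeg_record(sin(2 * pi * 10 * seq(0, 1, by = 1 / 256)), 256)
#' n_samples(rec)
#' @export
eeg_record <- function(samples, sampling_rate, channel_labels = NULL,
                       start_time = NULL) {
  if (is.vector(samples) && is.numeric(samples)) {
    samples <- matrix(samples, nrow = 1)
  }
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric matrix (channels x time) or vector")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number (Hz)")
  }
  if (any(!is.finite(samples))) {
    stop("`samples` must be finite (no NA/NaN/Inf amplitudes)")
  }
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(samples)))
  }
  if (length(channel_labels) != nrow(samples)) {
    stop("`channel_labels` length must equal the number of channels")
  }
  dimnames(samples) <- NULL
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         channel_labels = as.character(channel_labels),
         start_time = start_time),
    class = "eeg_record"
  )
}

#' @rdname eeg_record
#' @param x an `eeg_record`.
#' @export
n_samples <- function(x) ncol(x$samples)

#' @rdname eeg_record
#' @export
n_channels <- function(x) nrow(x$samples)

#' @rdname eeg_record
#' @export
duration_s <- function(x) ncol(x$samples) / x$sampling_rate

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d channel(s) x %d samples @ %g Hz (%.2f s)\n",
              n_channels(x), n_samples(x), x$sampling_rate, duration_s(x)))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Read an EEG recording from disk
#'
#' Supports two formats: a CSV dialect (header row; first column time in
#' seconds from record start; one column per channel, amplitudes in uV) and
#' EDF (European Data Format, 16-bit). The format is inferred from the file
#' extension unless given explicitly.
#'
#' @param path path to the file.
#' @param format `"csv"`, `"edf"`, or `"auto"` (default; by extension).
#' @return an [eeg_record()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", edf = "edf",
                     stop("cannot infer format from extension '", ext,
                          "'; pass `format` explicitly"))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format, csv = read_eeg_csv(path), edf = read_eeg_edf(path))
}

#' Write an EEG recording to disk
#'
#' @param record an [eeg_record()].
#' @param path output path.
#' @param format `"csv"`, `"edf"`, or `"auto"` (by extension).
#' @param digits significant digits for CSV amplitudes (default 10).
#' @return `path`, invisibly.
#' @export
write_recording <- function(record, path, format = c("auto", "csv", "edf"),
                            digits = 10) {
  stopifnot(inherits(record, "eeg_record"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", edf = "edf",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  switch(format,
         csv = write_eeg_csv(record, path, digits = digits),
         edf = write_eeg_edf(record, path))
  invisible(path)
}

read_eeg_csv <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = "character"),
    error = function(e) stop("malformed CSV '", path, "': ", conditionMessage(e))
  )
  if (ncol(df) < 2) stop("CSV must have a time column plus >= 1 channel column")
  num <- suppressWarnings(
    vapply(df, as.numeric, numeric(nrow(df)))
  )
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1, dimnames = list(NULL, names(df)))
  bad <- which(!is.finite(num) , arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric value in CSV '%s' at data row %d, column '%s'",
                 path, bad[1, 1], names(df)[bad[1, 2]]))
  }
  tsec <- num[, 1]
  if (nrow(num) >= 2) {
    dt <- diff(tsec)
    if (any(dt <= 0)) stop("time column must be strictly increasing")
    rate <- 1 / stats::median(dt)
  } else {
    stop("CSV recording must contain at least 2 samples")
  }
  eeg_record(t(num[, -1, drop = FALSE]), sampling_rate = rate,
             channel_labels = colnames(num)[-1])
}

write_eeg_csv <- function(record, path, digits = 10) {
  n <- n_samples(record)
  tsec <- (seq_len(n) - 1) / record$sampling_rate
  df <- data.frame(time_s = signif(tsec, 12))
  for (i in seq_len(n_channels(record))) {
    df[[record$channel_labels[i]]] <- signif(record$samples[i, ], digits)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
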