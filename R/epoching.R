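#' Split a recording into fixed-length analysis epochs
#'
#' Produces the ordered sequence of windows over which spectra and fatigue
#' scores are computed. With window length `W` samples and step
#' `S = W * (1 - overlap)` samples, the number of epochs is
#' `floor((N - W) / S) + 1`; a trailing partial window is discarded.
#'
#' @param record an [eeg_record()].
#' @param epoch_length epoch length in seconds; `epoch_length * sampling_rate`
#'   must be a positive integer. Default 2 s.
#' @param overlap fractional overlap between consecutive epochs, in `[0, 1)`.
#' @return a list of epochs, each a list with `index` (0-based), `samples`
#'   (channels x window matrix) and `start_offset` (seconds from record
#'   start); class `epoch_stream`.
#' @examples
#' rec <- eeg_record(matrix(rnorm(1024), 1), 256)
#' length(epoch_stream(rec, epoch_length = 1))
#' @export
epoch_stream <- function(record, epoch_length = 2, overlap = 0) {
  stopifnot(inherits(record, "eeg_record"))
  if (!is.numeric(overlap) || overlap < 0 || overlap >= 1) {
    stop("`overlap` must lie in [0, 1)")
  }
  w_exact <- epoch_length * record$sampling_rate
  w <- round(w_exact)
  if (w <= 0 || abs(w_exact - w) > 1e-8) {
    stop("`epoch_length` * sampling_rate must be a positive integer ",
         "(got ", w_exact, ")")
  }
  n <- n_samples(record)
  if (n < w) {
    stop("record (", n, " samples) is shorter than one epoch (", w, " samples)")
  }
  step <- max(1L, as.integer(round(w * (1 - overlap))))
  n_ep <- (n - w) %/% step + 1L
  out <- vector("list", n_ep)
  for (i in seq_len(n_ep)) {
    s0 <- (i - 1L) * step
    out[[i]] <- list(
      index = i - 1L,
      samples = record$samples[, (s0 + 1):(s0 + w), drop = FALSE],
      start_offset = s0 / record$sampling_rate
    )
  }
  structure(out, class = "epoch_stream",
            epoch_length = epoch_length, overlap = overlap,
            sampling_rate = record$sampling_rate)
}
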