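# Minimal EDF (European Data Format) support: fixed 256-byte ASCII header,
# one 256-byte signal header block per channel, then data records of 16-bit
# little-endian integers. Amplitudes are mapped between physical (uV) and
# digital ranges by the per-signal scaling fields, so the round trip is lossy
# only by the quantization step (phys_range / 65534).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 8, width = 1)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

write_eeg_edf <- function(record, path) {
  ns <- n_channels(record)
  n <- n_samples(record)
  rate <- record$sampling_rate
  # one data record per second when the rate is integral, else one big record
  if (abs(rate - round(rate)) < 1e-9 && n %% round(rate) == 0) {
    spr <- as.integer(round(rate))          # samples per record per signal
    n_rec <- n %/% spr
    rec_dur <- 1
  } else {
    spr <- n
    n_rec <- 1L
    rec_dur <- n / rate
  }
  phys_max <- max(1e-6, max(abs(record$samples)))
  dig_max <- 32767L
  scale <- dig_max / phys_max
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),                        # version
    edf_pad("X X X X", 80),                 # patient id
    edf_pad("Startdate X X X X", 80),       # recording id
    edf_pad("01.01.00", 8),                 # start date
    edf_pad("00.00.00", 8),                 # start time
    edf_pad(256 * (1 + ns), 8),             # header bytes
    edf_pad("", 44),                        # reserved
    edf_pad(n_rec, 8),
    edf_num(rec_dur, 8),
    edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  per_sig <- function(field, width) {
    for (v in field) writeChar(edf_pad(v, width), con, eos = NULL)
  }
  per_sig(record$channel_labels, 16)                 # label
  per_sig(rep("", ns), 80)                           # transducer
  per_sig(rep("uV", ns), 8)                          # physical dimension
  per_sig(rep(edf_num(-phys_max, 8), ns), 8)         # physical min
  per_sig(rep(edf_num(phys_max, 8), ns), 8)          # physical max
  per_sig(rep("-32767", ns), 8)                      # digital min
  per_sig(rep("32767", ns), 8)                       # digital max
  per_sig(rep("", ns), 80)                           # prefiltering
  per_sig(rep(spr, ns), 8)                           # samples per record
  per_sig(rep("", ns), 32)                           # reserved
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- as.integer(pmax(-dig_max, pmin(dig_max,
                                            round(record$samples[ch, idx] * scale))))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_eeg_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    raw <- readChar(con, width, useBytes = TRUE)
    if (nchar(raw, type = "bytes") < width) stop("truncated EDF header in ", path)
    trimws(raw)
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (!is.finite(ns) || ns < 1) stop("malformed EDF '", path, "': bad signal count")
  sig <- function(width) vapply(seq_len(ns), function(i) rd(width), character(1))
  labels <- sig(16); sig(80); sig(8)
  pmin_ <- as.numeric(sig(8)); pmax_ <- as.numeric(sig(8))
  dmin_ <- as.numeric(sig(8)); dmax_ <- as.numeric(sig(8))
  sig(80)
  spr <- as.integer(sig(8))
  sig(32)
  if (any(!is.finite(c(pmin_, pmax_, dmin_, dmax_, spr)))) {
    stop("malformed EDF '", path, "': bad scaling fields")
  }
  expect_pos <- 256L * (1L + ns)
  if (!is.na(hdr_bytes) && hdr_bytes != expect_pos) {
    seek(con, hdr_bytes)
  }
  total <- spr[1] * n_rec
  out <- matrix(0, nrow = ns, ncol = total)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2,
                     endian = "little", signed = TRUE)
      if (length(dig) < spr[ch]) {
        stop("truncated EDF data in '", path, "' at record ", r)
      }
      gain <- (pmax_[ch] - pmin_[ch]) / (dmax_[ch] - dmin_[ch])
      phys <- pmin_[ch] + (dig - dmin_[ch]) * gain
      out[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <- phys
    }
  }
  rate <- spr[1] / rec_dur
  eeg_record(out, sampling_rate = rate, channel_labels = labels)
}

#' Quantization step of an EDF file
#'
#' The worst-case amplitude error of the EDF round trip is half this step.
#'
#' @param record the record that was (or will be) written.
#' @return quantization step in uV.
#' @export
edf_quantization_step <- function(record) {
  phys_max <- max(1e-6, max(abs(record$samples)))
  2 * phys_max / 65534
}
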