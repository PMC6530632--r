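## Minimal EDF (European Data Format) reader/writer for continuous EEG.
##
## Implements the standard EDF layout: a 256-byte fixed header, 256 bytes of
## per-signal header fields (field-major), then data records of little-endian
## 16-bit integers with per-signal physical/digital scaling. Only equal-rate
## signals are supported, which covers EEG exports for this pipeline. The
## true sample count is stored as "NSAMP=<n>" in the reserved header field so
## a final partial record round-trips exactly; other readers see trailing
## zeros in the last record.

edf_num <- function(x) {
  # render a number into at most 8 ASCII characters
  for (digits in c(7, 6, 5, 4, 3, 2, 1)) {
    s <- formatC(signif(x, digits), format = "g", digits = digits, width = 1)
    if (nchar(s) <= 8) return(s)
  }
  pk_stop("cannot render %g in 8 characters", x)
}

edf_field <- function(s, width) {
  s <- as.character(s)
  if (nchar(s) > width) pk_stop("EDF field '%s' exceeds %d characters", s, width)
  sprintf(paste0("%-", width, "s"), s)
}

#' Write a continuous multichannel signal as EDF
#'
#' @param signal Channels x samples matrix, microvolts.
#' @param sample_rate Sampling rate in Hz (must be a positive integer).
#' @param labels Channel labels, one per row of `signal`.
#' @param path Output path.
#' @param patient,recording Free-text header identification fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signal, sample_rate, labels, path,
                      patient = "X", recording = "phasekin export") {
  signal <- as_channel_matrix(signal)
  ns <- nrow(signal); n <- ncol(signal)
  if (length(labels) != ns) pk_stop("need one label per channel")
  if (sample_rate != round(sample_rate) || sample_rate <= 0) {
    pk_stop("EDF writer requires an integer sample rate (got %g)", sample_rate)
  }
  spr <- as.integer(sample_rate)          # one-second data records
  n_rec <- as.integer(ceiling(n / spr))

  pmax_ <- apply(abs(signal), 1L, max)
  pmax_[pmax_ == 0] <- 1
  pmax_ <- pmax_ * 1.0001                 # keep extremes inside the digital range
  dig_max <- 32767L; dig_min <- -32767L

  header_bytes <- 256L + 256L * ns
  con <- tryCatch(file(path, "wb"), error = function(e) {
    pk_stop("cannot open '%s' for writing: %s", path, conditionMessage(e))
  })
  on.exit(close(con))
  put <- function(s, w) writeChar(edf_field(s, w), con, nchars = w, eos = NULL)

  put("0", 8); put(patient, 80); put(recording, 80)
  put("01.01.00", 8); put("00.00.00", 8)
  put(header_bytes, 8); put(sprintf("NSAMP=%d", n), 44)
  put(n_rec, 8); put("1", 8); put(ns, 4)

  for (lab in labels) put(lab, 16)
  for (i in seq_len(ns)) put("", 80)                      # transducer
  for (i in seq_len(ns)) put("uV", 8)                     # physical dimension
  for (i in seq_len(ns)) put(edf_num(-pmax_[i]), 8)       # physical minimum
  for (i in seq_len(ns)) put(edf_num(pmax_[i]), 8)        # physical maximum
  for (i in seq_len(ns)) put(dig_min, 8)
  for (i in seq_len(ns)) put(dig_max, 8)
  for (i in seq_len(ns)) put("", 80)                      # prefiltering
  for (i in seq_len(ns)) put(spr, 8)
  for (i in seq_len(ns)) put("", 32)                      # per-signal reserved

  # physical -> digital, zero-padded to whole records
  padded <- matrix(0L, nrow = ns, ncol = n_rec * spr)
  for (i in seq_len(ns)) {
    scale <- (dig_max - dig_min) / (2 * pmax_[i])
    padded[i, seq_len(n)] <- as.integer(round(signal[i, ] * scale))
  }
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(ns)) {
      writeBin(padded[i, cols], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return A list with `signal` (channels x samples, physical units),
#'   `sample_rate` (Hz) and `labels`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) pk_stop("no such file: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  get <- function(w) {
    raw <- readBin(con, "raw", n = w)
    if (length(raw) < w) pk_stop("'%s' is truncated inside the EDF header", path)
    trimws(rawToChar(raw))
  }
  version <- get(8)
  if (version != "0") pk_stop("'%s' is not an EDF file (version field '%s')", path, version)
  get(80); get(80); get(8); get(8)
  header_bytes <- as.integer(get(8))
  reserved <- get(44)
  n_rec <- as.integer(get(8))
  rec_dur <- as.numeric(get(8))
  ns <- as.integer(get(4))
  if (is.na(ns) || ns < 1L) pk_stop("'%s': malformed signal count", path)

  labels <- vapply(seq_len(ns), function(i) get(16), character(1))
  for (i in seq_len(ns)) get(80)
  dims <- vapply(seq_len(ns), function(i) get(8), character(1))
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) get(8), character(1)))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) get(8), character(1)))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) get(8), character(1)))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) get(8), character(1)))
  for (i in seq_len(ns)) get(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) get(8), character(1)))
  for (i in seq_len(ns)) get(32)
  if (anyNA(c(phys_min, phys_max, dig_min, dig_max, spr))) {
    pk_stop("'%s': malformed per-signal header numbers", path)
  }
  if (length(unique(spr / rec_dur)) != 1L) {
    pk_stop("'%s': signals with mixed sampling rates are not supported", path)
  }
  sample_rate <- spr[1L] / rec_dur

  n_total <- n_rec * spr[1L]
  signal <- matrix(NA_real_, nrow = ns, ncol = n_total)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      vals <- readBin(con, "integer", n = spr[i], size = 2L,
                      endian = "little", signed = TRUE)
      if (length(vals) < spr[i]) {
        pk_stop("'%s' is truncated in data record %d, signal %d (%s)",
                path, r, i, labels[i])
      }
      scale <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
      cols <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
      signal[i, cols] <- phys_min[i] + (vals - dig_min[i]) * scale
    }
  }
  m <- regmatches(reserved, regexec("NSAMP=([0-9]+)", reserved))[[1L]]
  if (length(m) == 2L) {
    n_true <- as.integer(m[2L])
    if (n_true <= n_total) signal <- signal[, seq_len(n_true), drop = FALSE]
  }
  list(signal = signal, sample_rate = sample_rate, labels = labels, units = dims)
}
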