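# Minimal EDF (European Data Format) reader/writer: 16-bit integer samples,
# equal sampling rate across signals, 1-second data records.  Covers the
# interchange needs of the synthetic cohort; no EDF+ annotations.

#' @noRd
edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

#' Write a recording to an EDF file
#'
#' Samples are scaled per channel to the 16-bit digital range using the
#' observed physical extrema.  The record duration is 1 s, so `fs` must be
#' an integer and the recording is truncated to whole seconds.
#'
#' @param rec a `phfa_recording` with integer `fs`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "phfa_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires integer fs")
  fs <- as.integer(round(fs))
  ns <- ncol(rec$samples)
  n_rec <- nrow(rec$samples) %/% fs
  if (n_rec < 1) stop("recording shorter than one EDF record (1 s)")
  x <- rec$samples[seq_len(n_rec * fs), , drop = FALSE]
  pmin_ <- apply(x, 2, min); pmax_ <- apply(x, 2, max)
  flat <- pmax_ - pmin_ <= 0
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field(rec$patient, 80),
    edf_field("phfa synthetic", 80),
    edf_field("01.01.00", 8), edf_field("00.00.00", 8),
    edf_field(256 * (1 + ns), 8),
    edf_field("", 44),
    edf_field(n_rec, 8),
    edf_field(1, 8),
    edf_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  per <- function(vals, width)
    writeChar(paste(vapply(vals, edf_field, "", width = width), collapse = ""),
              con, eos = NULL)
  per(colnames(x), 16)
  per(rep("", ns), 80)
  per(rep("uV", ns), 8)
  per(formatC(pmin_, format = "g", digits = 7), 8)
  per(formatC(pmax_, format = "g", digits = 7), 8)
  per(rep(dmin, ns), 8)
  per(rep(dmax, ns), 8)
  per(rep("", ns), 80)
  per(rep(fs, ns), 8)
  per(rep("", ns), 32)
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  dig <- matrix(0L, nrow(x), ns)
  for (j in seq_len(ns))
    dig[, j] <- as.integer(round((x[, j] - pmin_[j]) * scale[j]) + dmin)
  dim(dig) <- c(fs, n_rec, ns)
  out <- aperm(dig, c(1, 3, 2))  # sample, signal, record
  writeBin(as.integer(out), con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return list with `samples` (matrix, samples x channels, physical
#'   units), `fs`, `labels`, `patient`, `n_records`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) trimws(readChar(con, nc, useBytes = TRUE))
  rd(8)                               # version
  patient <- rd(80); rd(80); rd(8); rd(8)
  rd(8)                               # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- fld(16); fld(80); fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  if (length(unique(spr)) != 1)
    stop("reader supports equal sampling rate across signals only")
  raw <- readBin(con, integer(), n = n_rec * sum(spr), size = 2,
                 endian = "little")
  dim(raw) <- c(spr[1], ns, n_rec)
  x <- matrix(0, n_rec * spr[1], ns)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (j in seq_len(ns))
    x[, j] <- (as.vector(raw[, j, ]) - dmin[j]) * scale[j] + pmin_[j]
  colnames(x) <- labels
  list(samples = x, fs = spr[1] / rec_dur, labels = labels,
       patient = patient, n_records = n_rec)
}
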