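#' Z-score normalization of a sample vector
#'
#' Subtracts the mean and divides by the sample (n-1) standard deviation.
#' All but one of the morphology features are computed on this normalized
#' trace, so amplitude information enters through a single feature (the raw
#' standard deviation in dB).
#'
#' @param x numeric vector with positive spread.
#' @return normalized vector with mean 0 and sd 1.
#' @export
hfa_normalize <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s <= 0)
    stop("degenerate signal: standard deviation is zero")
  (x - mean(x)) / s
}

#' Morphology transforms
#'
#' The four sample-wise transforms underlying the feature set, each applied
#' to a (normalized) trace `y` sampled at `fs_khz` kHz:
#' * `rectify(y)`: \eqn{|y_j|}, length n;
#' * `line_length(y, fs_khz)`: \eqn{|y_{j+1}-y_j| f_S}, length n-1
#'   (rectified first difference, a roughness measure);
#' * `curvature(y, fs_khz)`: \eqn{|y_{j+2}+y_j-2y_{j+1}| f_S^2}, length n-2
#'   (rectified second difference);
#' * `teager(y, fs_khz)`: \eqn{(y_j^2-y_{j+1}y_{j-1}) f_S^2}, length n-2,
#'   the Teager-Kaiser instantaneous energy.
#'
#' The sampling-rate factors in kHz give the transforms units per
#' millisecond rather than per sample interval, so features generalize
#' across sampling rates.
#'
#' @param y numeric vector (length >= 3 for the second-difference
#'   transforms).
#' @param fs_khz sampling rate in kHz.
#' @return numeric vector of transformed samples.
#' @name transforms
NULL

#' @rdname transforms
#' @export
rectify <- function(y) abs(y)

#' @noRd
signed_diff <- function(y, fs_khz) {
  if (length(y) < 2) stop("need at least 2 samples for a first difference")
  diff(y) * fs_khz
}

#' @rdname transforms
#' @export
line_length <- function(y, fs_khz) abs(signed_diff(y, fs_khz))

#' @rdname transforms
#' @export
curvature <- function(y, fs_khz) {
  n <- length(y)
  if (n < 3) stop("need at least 3 samples for curvature")
  abs(y[3:n] + y[1:(n - 2)] - 2 * y[2:(n - 1)]) * fs_khz^2
}

#' @rdname transforms
#' @export
teager <- function(y, fs_khz) {
  n <- length(y)
  if (n < 3) stop("need at least 3 samples for Teager-Kaiser energy")
  (y[2:(n - 1)]^2 - y[3:n] * y[1:(n - 2)]) * fs_khz^2
}

#' First four statistical moments of a sample
#'
#' Mean, sample (n-1) standard deviation, skewness
#' \eqn{m_3/m_2^{3/2}} and kurtosis \eqn{m_4/m_2^2} from central sample
#' moments \eqn{m_k}.  Kurtosis is non-excess by default (3 for a normal
#' distribution), which keeps the log-scaled kurtosis features defined for
#' every sample; excess kurtosis is available for comparison with
#' accumulator libraries that report it.  Accumulation uses R's long-double
#' summation, so results are permutation-invariant to well below 1e-9
#' relative error.
#'
#' @param v numeric vector, length >= 4.
#' @param excess_kurtosis subtract 3 from kurtosis if TRUE.
#' @return named list (mean, sd, skew, kurt).
#' @export
signal_moments <- function(v, excess_kurtosis = FALSE) {
  n <- length(v)
  if (n < 4) stop("need at least 4 samples for four moments")
  cm <- .central_moments(v)
  m2 <- cm[2]
  if (m2 <= 0) stop("degenerate sample: zero variance")
  ku <- cm[4] / m2^2
  if (excess_kurtosis) ku <- ku - 3
  list(mean = cm[1], sd = sqrt(m2 * n / (n - 1)), skew = cm[3] / m2^1.5,
       kurt = ku)
}

#' @noRd
db10 <- function(z) {
  ifelse(is.finite(z) & z > 0, 10 * log10(z), NA_real_)
}

#' Names of the 19 per-band features
#' @return character vector "f1".."f19".
#' @export
feature_names <- function() paste0("f", 1:19)

#' Compute the 19 morphology features for one channel/epoch/band
#'
#' Takes the band-filtered samples of one epoch as a list of contiguous
#' segments (the pieces left after HFO/artifact redaction).  The raw
#' segments are pooled to estimate the epoch mean and standard deviation;
#' each segment is normalized with those pooled statistics; the transforms
#' are applied within each segment (no differences are taken across
#' redaction gaps); and the transformed samples are pooled before the
#' moment statistics.  Scaling is 10*log10 (decibels) for all mean / sd /
#' kurtosis features and arctangent for the skewness features (log-like
#' compression that tolerates negative values).
#'
#' Feature grid (per band): f1-f4 = dB mean of R, L, C, T of y; f5 = dB sd
#' of the raw signal x (the only non-normalized feature); f6 = dB sd of the
#' signed first difference D(y)*fS; f7-f9 = dB sd of L, C, T; f10-f14 =
#' atan skew of y, R, L, C, T; f15 = dB kurtosis of y; f16 = dB kurtosis of
#' D(y)*fS; f17-f19 = dB kurtosis of L, C, T.
#'
#' @param segments list of numeric vectors (contiguous filtered samples).
#' @param fs sampling rate in Hz.
#' @param excess_kurtosis kurtosis convention flag, see [signal_moments()].
#' @return named numeric vector f1..f19 plus `n_samples_used`; all NA (with
#'   attribute `reason`) when the epoch is degenerate or a log argument is
#'   non-positive.
#' @export
compute_epoch_features <- function(segments, fs, excess_kurtosis = FALSE) {
  stopifnot(is.list(segments), length(segments) >= 1)
  segments <- segments[lengths(segments) > 0]
  x <- unlist(segments, use.names = FALSE)
  n <- length(x)
  fail <- function(reason) {
    out <- rep(NA_real_, 20)
    names(out) <- c(feature_names(), "n_samples_used")
    out["n_samples_used"] <- n
    attr(out, "reason") <- reason
    out
  }
  if (n < 4) return(fail("too few samples"))
  sx <- sd(x)
  if (!is.finite(sx) || sx <= 0) return(fail("zero variance"))
  mx <- mean(x)
  fs_khz <- fs / 1000
  ysegs <- lapply(segments, function(s) (s - mx) / sx)
  pool <- function(f) unlist(lapply(ysegs, f), use.names = FALSE)
  y <- unlist(ysegs, use.names = FALSE)
  long <- lengths(segments) >= 3
  if (!any(long)) return(fail("segments too short for transforms"))
  Ry <- abs(y)
  Dy <- unlist(lapply(ysegs[lengths(segments) >= 2], signed_diff, fs_khz),
               use.names = FALSE)
  Ly <- abs(Dy)
  Cy <- unlist(lapply(ysegs[long], curvature, fs_khz), use.names = FALSE)
  Ty <- unlist(lapply(ysegs[long], teager, fs_khz), use.names = FALSE)
  mom <- lapply(list(y = y, R = Ry, D = Dy, L = Ly, C = Cy, T = Ty),
                function(v) tryCatch(signal_moments(v, excess_kurtosis),
                                     error = function(e) NULL))
  if (any(vapply(mom, is.null, TRUE))) return(fail("degenerate transform"))
  out <- c(
    db10(mom$R$mean), db10(mom$L$mean), db10(mom$C$mean), db10(mom$T$mean),
    db10(sx),
    db10(mom$D$sd), db10(mom$L$sd), db10(mom$C$sd), db10(mom$T$sd),
    atan(mom$y$skew), atan(mom$R$skew), atan(mom$L$skew),
    atan(mom$C$skew), atan(mom$T$skew),
    db10(mom$y$kurt), db10(mom$D$kurt), db10(mom$L$kurt),
    db10(mom$C$kurt), db10(mom$T$kurt))
  names(out) <- feature_names()
  if (anyNA(out)) return(fail("non-positive log argument"))
  c(out, n_samples_used = n)
}

#' Per-epoch feature table for one patient
#'
#' Runs band filtering on the full common-average-referenced record of each
#' channel (so redaction gaps create no filter transients), cuts the
#' redacted segments of each usable epoch from the filtered trace, and
#' computes the 19 features per band.  Epochs retaining fewer than
#' `min_frac` of their nominal samples on a channel are dropped.
#'
#' @param rec a `phfa_recording` (after [common_average_reference()]).
#' @param segs a `phfa_segments` from [redact_events()].
#' @param bands list of [band_spec()]; default the 30-80 / 80-500 Hz pair.
#' @param min_frac minimum usable fraction of an epoch (default 0.25).
#' @param excess_kurtosis kurtosis convention flag.
#' @return data.frame with columns patient, channel, epoch, band,
#'   f1..f19, n_samples_used.
#' @export
compute_feature_table <- function(rec, segs, bands = default_bands(),
                                  min_frac = 0.25, excess_kurtosis = FALSE) {
  stopifnot(inherits(rec, "phfa_recording"), inherits(segs, "phfa_segments"))
  grid <- segs$grid
  nominal <- grid$epoch_length_s * rec$fs
  usable <- grid$epochs[grid$epochs$usable, , drop = FALSE]
  filters <- lapply(bands, design_bandpass, fs = rec$fs)
  rows <- list()
  for (ci in seq_len(ncol(rec$samples))) {
    ch <- rec$channels$name[ci]
    traces <- lapply(filters, function(f) apply_filter(rec$samples[, ci], f))
    for (ei in seq_len(nrow(usable))) {
      ep <- usable$index[ei]
      iv <- segs$segments[[ch]][[as.character(ep)]]
      if (is.null(iv) || nrow(iv) == 0) next
      if (sum(iv$end - iv$start) < min_frac * nominal) next
      for (bi in seq_along(bands)) {
        segl <- lapply(seq_len(nrow(iv)), function(k)
          traces[[bi]][(iv$start[k] + 1):iv$end[k]])
        fv <- compute_epoch_features(segl, rec$fs, excess_kurtosis)
        rows[[length(rows) + 1L]] <- data.frame(
          patient = rec$patient, channel = ch, epoch = ep,
          band = bands[[bi]]$name, t(fv),
          valid = !anyNA(fv[feature_names()]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(patient = character(), channel = character(),
                      epoch = integer(), band = character())
    for (f in feature_names()) out[[f]] <- numeric()
    out$n_samples_used <- numeric(); out$valid <- logical()
    return(out)
  }
  do.call(rbind, rows)
}
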