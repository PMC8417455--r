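#' Construct a multichannel iEEG recording
#'
#' @param samples numeric matrix, samples x channels, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channels data.frame with columns `name`, `kind` (one of "depth",
#'   "grid", "strip"), and binary label columns `soz`, `rv`, `tl`.
#' @param patient patient identifier.
#' @param t0 recording start time in seconds (default 0).
#' @return a `phfa_recording`.
#' @export
recording <- function(samples, fs, channels, patient = "P1", t0 = 0) {
  samples <- as.matrix(samples)
  stopifnot(is.numeric(samples), nrow(samples) > 0)
  assert_scalar_num(fs, "fs", 0, strict_lo = TRUE)
  req <- c("name", "kind", "soz", "rv", "tl")
  if (!all(req %in% names(channels)))
    stop("channels must have columns: ", paste(req, collapse = ", "))
  if (nrow(channels) != ncol(samples))
    stop("channel metadata rows must match sample matrix columns")
  if (!all(channels$kind %in% c("depth", "grid", "strip")))
    stop("channel kind must be depth, grid or strip")
  if (!all(unlist(channels[c("soz", "rv", "tl")]) %in% c(0, 1)))
    stop("soz/rv/tl labels must be binary")
  colnames(samples) <- channels$name
  structure(list(samples = samples, fs = fs,
                 channels = as.data.frame(channels),
                 patient = as.character(patient), t0 = t0),
            class = "phfa_recording")
}

#' @export
print.phfa_recording <- function(x, ...) {
  cat(sprintf("phfa_recording: patient %s, %d channels x %d samples @ %g Hz (%.1f min)\n",
              x$patient, ncol(x$samples), nrow(x$samples), x$fs,
              nrow(x$samples) / x$fs / 60))
  invisible(x)
}

#' Construct an annotation set
#'
#' @param seizures data.frame with `t_start`, `t_end` in seconds (`t_end`
#'   may be NA when unknown); NULL for none.
#' @param events data.frame with `channel`, `t_start`, `t_end`, `kind`
#'   ("hfo" or "artifact"); NULL for none.
#' @return a `phfa_annotations`.
#' @export
annotation_set <- function(seizures = NULL, events = NULL) {
  if (is.null(seizures))
    seizures <- data.frame(t_start = numeric(), t_end = numeric())
  if (is.null(events))
    events <- data.frame(channel = character(), t_start = numeric(),
                         t_end = numeric(), kind = character())
  ok <- is.na(seizures$t_end) | seizures$t_start < seizures$t_end
  if (!all(ok)) stop("seizure intervals must have t_start < t_end")
  if (nrow(events) && !all(events$t_start < events$t_end))
    stop("event intervals must have t_start < t_end")
  if (nrow(events) && !all(events$kind %in% c("hfo", "artifact")))
    stop("event kind must be hfo or artifact")
  structure(list(seizures = as.data.frame(seizures),
                 events = as.data.frame(events)),
            class = "phfa_annotations")
}

#' Group-wise common average reference
#'
#' Subtracts, at every time point, the mean over depth channels from each
#' depth channel and the mean over grid+strip channels from each grid or
#' strip channel.  Referencing is idempotent and leaves each group with
#' zero mean at every sample.
#'
#' @param rec a `phfa_recording`.
#' @return re-referenced `phfa_recording`.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "phfa_recording"))
  groups <- list(depth = rec$channels$kind == "depth",
                 surface = rec$channels$kind %in% c("grid", "strip"))
  for (g in names(groups)) {
    idx <- which(groups[[g]])
    if (!length(idx)) { next }
    ref <- rowMeans(rec$samples[, idx, drop = FALSE])
    rec$samples[, idx] <- rec$samples[, idx, drop = FALSE] - ref
  }
  rec
}

#' Interictal sample mask
#'
#' TRUE where a sample is usable: at least `margin_s` seconds away from
#' every seizure start, and outside the seizure interval itself whenever
#' the end time is known (ictal data must never leak into the background
#' analysis, even though the distance criterion is stated from seizure
#' start only).
#'
#' @param ann a `phfa_annotations`.
#' @param rec a `phfa_recording`.
#' @param margin_s exclusion margin around each seizure start (default
#'   1800 s = 30 min).
#' @return logical vector, one element per sample.
#' @export
interictal_mask <- function(ann, rec, margin_s = 1800) {
  stopifnot(inherits(ann, "phfa_annotations"), inherits(rec, "phfa_recording"))
  assert_scalar_num(margin_s, "margin_s", 0)
  n <- nrow(rec$samples)
  dur <- n / rec$fs
  mask <- rep(TRUE, n)
  sz <- ann$seizures
  for (i in seq_len(nrow(sz))) {
    s <- sz$t_start[i] - rec$t0
    e <- if (is.na(sz$t_end[i])) s else sz$t_end[i] - rec$t0
    if (e < 0 || s > dur) {
      warning(sprintf("seizure at %g s lies outside the recording span; ignored",
                      sz$t_start[i]))
      next
    }
    lo <- max(0, s - margin_s)
    hi <- min(dur, max(s + margin_s, e))
    a <- floor(lo * rec$fs) + 1L
    b <- min(n, ceiling(hi * rec$fs))
    if (b >= a) mask[a:b] <- FALSE
  }
  mask
}

#' Cut a recording into aligned epochs
#'
#' Consecutive non-overlapping epochs anchored at the recording start.  An
#' epoch is usable only when every sample in it is interictal; partially
#' masked epochs are dropped rather than trimmed or shifted.
#'
#' @param mask logical interictal mask (one element per sample).
#' @param fs sampling rate in Hz.
#' @param epoch_length_s epoch duration in seconds (default 300 = 5 min);
#'   `epoch_length_s * fs` must be an integer.
#' @return a `phfa_epochs` with the epoch table (`index`, `start_sample`,
#'   `end_sample` as 0-based half-open bounds, `usable`).
#' @export
build_epochs <- function(mask, fs, epoch_length_s = 300) {
  stopifnot(is.logical(mask))
  len <- epoch_length_s * fs
  if (abs(len - round(len)) > 1e-9)
    stop("epoch_length_s * fs must be an integer number of samples")
  len <- as.integer(round(len))
  k <- length(mask) %/% len
  if (k == 0)
    return(structure(list(epoch_length_s = epoch_length_s, fs = fs,
                          epochs = data.frame(index = integer(),
                                              start_sample = integer(),
                                              end_sample = integer(),
                                              usable = logical())),
                     class = "phfa_epochs"))
  start <- (seq_len(k) - 1L) * len
  usable <- vapply(seq_len(k),
                   function(i) all(mask[(start[i] + 1L):(start[i] + len)]),
                   TRUE)
  structure(list(epoch_length_s = epoch_length_s, fs = fs,
                 epochs = data.frame(index = seq_len(k),
                                     start_sample = start,
                                     end_sample = start + len,
                                     usable = usable)),
            class = "phfa_epochs")
}

#' @noRd
subtract_intervals <- function(start, end, cuts) {
  # cuts: data.frame(start, end), 0-based half-open; returns kept intervals
  if (is.null(cuts) || nrow(cuts) == 0)
    return(data.frame(start = start, end = end))
  cuts <- cuts[cuts$end > start & cuts$start < end, , drop = FALSE]
  if (nrow(cuts) == 0) return(data.frame(start = start, end = end))
  cuts$start <- pmax(cuts$start, start)
  cuts$end <- pmin(cuts$end, end)
  cuts <- cuts[order(cuts$start), , drop = FALSE]
  # merge overlapping/abutting cuts, then take the complement within the epoch
  ms <- cuts$start[1]; me <- cuts$end[1]
  merged_s <- integer(); merged_e <- integer()
  for (i in seq_len(nrow(cuts))[-1]) {
    if (cuts$start[i] <= me) me <- max(me, cuts$end[i])
    else { merged_s <- c(merged_s, ms); merged_e <- c(merged_e, me)
           ms <- cuts$start[i]; me <- cuts$end[i] }
  }
  merged_s <- c(merged_s, ms); merged_e <- c(merged_e, me)
  pos <- start
  seg_s <- integer(); seg_e <- integer()
  for (i in seq_along(merged_s)) {
    if (merged_s[i] > pos) { seg_s <- c(seg_s, pos); seg_e <- c(seg_e, merged_s[i]) }
    pos <- max(pos, merged_e[i])
  }
  if (pos < end) { seg_s <- c(seg_s, pos); seg_e <- c(seg_e, end) }
  data.frame(start = as.integer(seg_s), end = as.integer(seg_e))
}

#' Redact HFO and artifact samples from each epoch
#'
#' Per channel and usable epoch, returns the ordered contiguous sample
#' intervals remaining after removal of that channel's HFO and artifact
#' annotations (events on one channel never redact another).  Some epochs
#' therefore carry less than their nominal duration; an epoch entirely
#' covered by events yields an empty interval list and is skipped
#' downstream.
#'
#' @param rec a `phfa_recording`.
#' @param grid a `phfa_epochs`.
#' @param ann a `phfa_annotations`.
#' @return a `phfa_segments`: per-channel, per-epoch interval tables
#'   (0-based half-open sample indices) plus the epoch grid.
#' @export
redact_events <- function(rec, grid, ann) {
  stopifnot(inherits(rec, "phfa_recording"), inherits(grid, "phfa_epochs"),
            inherits(ann, "phfa_annotations"))
  ev <- ann$events
  if (nrow(ev) && !all(ev$channel %in% rec$channels$name))
    stop("events reference unknown channels")
  usable <- grid$epochs[grid$epochs$usable, , drop = FALSE]
  out <- list()
  for (ch in rec$channels$name) {
    che <- ev[ev$channel == ch, , drop = FALSE]
    cuts <- if (nrow(che))
      data.frame(start = floor((che$t_start - rec$t0) * rec$fs),
                 end = ceiling((che$t_end - rec$t0) * rec$fs))
    else NULL
    chl <- list()
    for (i in seq_len(nrow(usable))) {
      chl[[as.character(usable$index[i])]] <-
        subtract_intervals(usable$start_sample[i], usable$end_sample[i], cuts)
    }
    out[[ch]] <- chl
  }
  structure(list(grid = grid, segments = out), class = "phfa_segments")
}

#' Per-channel HFO rates over analysed interictal time
#'
#' Counts HFO annotations on each channel whose onset falls inside a usable
#' epoch and divides by the analysed duration in minutes (number of usable
#' epochs times the epoch length).
#'
#' @param ann a `phfa_annotations`.
#' @param grid a `phfa_epochs`.
#' @param rec a `phfa_recording`.
#' @return data.frame (patient, channel, hfo_rate) in events/min.
#' @export
hfo_rates <- function(ann, grid, rec) {
  usable <- grid$epochs[grid$epochs$usable, , drop = FALSE]
  minutes <- nrow(usable) * grid$epoch_length_s / 60
  ev <- ann$events
  ev <- ev[ev$kind == "hfo", , drop = FALSE]
  in_usable <- function(t) {
    s <- floor((t - rec$t0) * rec$fs)
    any(s >= usable$start_sample & s < usable$end_sample)
  }
  counts <- vapply(rec$channels$name, function(ch) {
    che <- ev[ev$channel == ch, , drop = FALSE]
    if (!nrow(che)) return(0L)
    sum(vapply(che$t_start, in_usable, TRUE))
  }, 0L)
  data.frame(patient = rec$patient, channel = rec$channels$name,
             hfo_rate = if (minutes > 0) counts / minutes else NA_real_,
             row.names = NULL, stringsAsFactors = FALSE)
}
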