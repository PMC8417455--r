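# Synthetic iEEG cohort generator.  Emulates the statistical contrast the
# pipeline is designed to detect: 1/f background plus white noise on every
# channel, elevated 80-500 Hz power and intermittent high-kurtosis bursts on
# pathological (SOZ) channels, and injectable HFO-like transients and
# artifacts with exact ground-truth annotations.

#' Specification of a synthetic cohort
#'
#' Defaults define the package's simulation-study conditions: 20 patients,
#' 8 depth channels each (2 in the SOZ, 3 in the RV), 20 epochs of 30 s at
#' 2048 Hz, a 4-fold elevation of 80-500 Hz band power on SOZ channels,
#' 6 bursts/min, HFO rates of 2/min inside and 0.2/min outside the SOZ,
#' and 1 artifact/min everywhere.
#'
#' @param n_patients number of patients.
#' @param channels_per_patient channels per patient (>= 4).
#' @param n_soz,n_rv pathological channel counts per patient (SOZ within
#'   RV; `n_soz <= n_rv <= channels_per_patient`).
#' @param epoch_count number of epochs per recording.
#' @param epoch_length_s epoch duration in seconds.
#' @param fs sampling rate in Hz (> 1000).
#' @param band_power_gain multiplicative elevation of 80-500 Hz power on
#'   SOZ channels (1 = null effect).
#' @param burst_rate Laplace-amplitude burst rate on SOZ channels
#'   (events/min).
#' @param hfo_rate_in,hfo_rate_out injected HFO rates (events/min) on
#'   SOZ / non-SOZ channels.
#' @param artifact_rate injected artifact rate (events/min), all channels.
#' @param seed master seed; patient `i` uses `seed + i`.
#' @return a validated `phfa_cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 20, channels_per_patient = 8,
                        n_soz = 2, n_rv = 3,
                        epoch_count = 20, epoch_length_s = 30,
                        fs = 2048,
                        band_power_gain = 4, burst_rate = 6,
                        hfo_rate_in = 2, hfo_rate_out = 0.2,
                        artifact_rate = 1, seed = 1) {
  spec <- list(n_patients = n_patients,
               channels_per_patient = channels_per_patient,
               n_soz = n_soz, n_rv = n_rv, epoch_count = epoch_count,
               epoch_length_s = epoch_length_s, fs = fs,
               band_power_gain = band_power_gain, burst_rate = burst_rate,
               hfo_rate_in = hfo_rate_in, hfo_rate_out = hfo_rate_out,
               artifact_rate = artifact_rate, seed = seed)
  if (channels_per_patient < 4)
    stop("invalid spec: channels_per_patient must be >= 4")
  if (n_soz > channels_per_patient)
    stop("invalid spec: n_soz must not exceed channels_per_patient")
  if (n_rv < n_soz || n_rv > channels_per_patient)
    stop("invalid spec: n_rv must lie between n_soz and channels_per_patient")
  if (fs <= 1000) stop("invalid spec: fs must exceed 1000 Hz")
  for (f in c("band_power_gain", "burst_rate", "hfo_rate_in",
              "hfo_rate_out", "artifact_rate"))
    if (spec[[f]] < 0) stop(sprintf("invalid spec: %s must be >= 0", f))
  if (band_power_gain < 1)
    stop("invalid spec: band_power_gain must be >= 1")
  if (n_patients < 1 || epoch_count < 1)
    stop("invalid spec: n_patients and epoch_count must be >= 1")
  structure(spec, class = "phfa_cohort_spec")
}

#' @noRd
one_over_f_noise <- function(n, fs) {
  # Gaussian noise with 1/f amplitude spectrum (alpha = 1 in power ~ 1/f^alpha
  # terms of amplitude ~ 1/sqrt(f)), unit variance.
  w <- stats::rnorm(n)
  X <- fft(w)
  f <- seq(0, fs, length.out = n + 1)[1:n]
  f[f > fs / 2] <- fs - f[f > fs / 2]
  a <- 1 / sqrt(pmax(f, 1))
  a[1] <- 0
  x <- Re(fft(X * a, inverse = TRUE)) / n
  x / sd(x)
}

#' Inject transient events into a signal
#'
#' HFO events are Hann-windowed sinusoidal bursts (frequency uniform in
#' 80-250 Hz, duration uniform in 20-100 ms); artifacts are broadband sharp
#' transients (signed exponential-decay spikes, 5-50 ms).  Event count is
#' Poisson with mean `rate * duration_min`; the returned table lists every
#' injected event exactly.
#'
#' @param x numeric sample vector.
#' @param kind "hfo" or "artifact".
#' @param rate events/min (>= 0).
#' @param seed integer seed (determinism contract).
#' @param fs sampling rate in Hz.
#' @param amp event amplitude scale in signal units (default 5 x the
#'   signal's standard deviation).
#' @return list with `signal` (vector with events added) and `events`
#'   (data.frame t_start, t_end, kind in seconds).
#' @export
inject_events <- function(x, kind = c("hfo", "artifact"), rate, seed, fs,
                          amp = NULL) {
  kind <- match.arg(kind)
  assert_scalar_num(rate, "rate", 0)
  n <- length(x)
  dur_min <- n / fs / 60
  empty <- data.frame(t_start = numeric(), t_end = numeric(),
                      kind = character())
  if (rate == 0) return(list(signal = x, events = empty))
  if (is.null(amp)) amp <- 5 * sd(x)
  with_seed(seed, {
    k <- stats::rpois(1, rate * dur_min)
    lens <- if (k == 0) numeric()
            else if (kind == "hfo") runif(k, 0.02, 0.1)
            else runif(k, 0.005, 0.05)
    starts <- if (k == 0) numeric() else runif(k, 0, n / fs - max(lens))
    freqs <- runif(k, 80, 250)
    phases <- runif(k, 0, 2 * pi)
    signs <- sample(c(-1, 1), k, replace = TRUE)
    amps <- amp * runif(k, 0.5, 1.5)
    for (i in seq_len(k)) {
      i0 <- floor(starts[i] * fs)            # 0-based
      m <- max(3L, as.integer(round(lens[i] * fs)))
      idx <- (i0 + 1):(i0 + m)
      tt <- (seq_len(m) - 1) / fs
      wave <- if (kind == "hfo") {
        win <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = m)))
        amps[i] * win * sin(2 * pi * freqs[i] * tt + phases[i])
      } else {
        signs[i] * 3 * amps[i] * exp(-tt / (lens[i] / 4))
      }
      x[idx] <- x[idx] + wave
    }
    ev <- if (k == 0) empty
          else data.frame(t_start = starts, t_end = starts + lens, kind = kind)
    list(signal = x, events = ev)
  })
}

#' Generate one synthetic patient
#'
#' Deterministic given `(spec$seed, patient_index)`.  Channels 1..n_soz are
#' the SOZ, channels 1..n_rv the RV; temporal-lobe flags are drawn at
#' random (p = 0.5).  The background is unit-variance 1/f noise (20 uV)
#' plus white noise (5 uV); SOZ channels additionally receive 80-500 Hz
#' band-limited noise scaled so the band power is multiplied by
#' `band_power_gain`, and Hann-windowed broadband bursts with
#' Laplace-distributed amplitude at Poisson times.  Injected HFOs and
#' artifacts are recorded exactly in the annotation set.
#'
#' @param spec a [cohort_spec()].
#' @param patient_index patient number (1-based).
#' @return list with `recording` (`phfa_recording`), `annotations`
#'   (`phfa_annotations`) and `truth` (channel flags and per-channel true
#'   event tables).
#' @export
generate_patient <- function(spec, patient_index) {
  stopifnot(inherits(spec, "phfa_cohort_spec"))
  pid <- sprintf("S%02d", patient_index)
  nch <- spec$channels_per_patient
  n <- as.integer(spec$epoch_count * spec$epoch_length_s * spec$fs)
  seed_p <- spec$seed + patient_index
  band2 <- design_bandpass(band_spec("band2", 80, 500), spec$fs)
  with_seed(seed_p, {
    tl <- stats::rbinom(nch, 1, 0.5)
    channels <- data.frame(
      name = sprintf("%s_ch%02d", pid, seq_len(nch)),
      kind = "depth",
      soz = as.integer(seq_len(nch) <= spec$n_soz),
      rv = as.integer(seq_len(nch) <= spec$n_rv),
      tl = tl, stringsAsFactors = FALSE)
    samples <- matrix(0, n, nch)
    events <- list()
    minutes <- n / spec$fs / 60
    for (ci in seq_len(nch)) {
      bg <- 20 * one_over_f_noise(n, spec$fs) + 5 * stats::rnorm(n)
      patho <- channels$soz[ci] == 1
      if (patho && spec$band_power_gain > 1) {
        base_band_sd <- sd(apply_filter(bg, band2))
        extra <- apply_filter(stats::rnorm(n), band2)
        extra <- extra / sd(extra) *
          base_band_sd * sqrt(spec$band_power_gain - 1)
        bg <- bg + extra
      }
      if (patho && spec$burst_rate > 0) {
        kb <- stats::rpois(1, spec$burst_rate * minutes)
        if (kb > 0) {
          m <- max(3L, as.integer(round(0.03 * spec$fs)))
          win <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = m)))
          bstart <- floor(runif(kb, 0, n - m - 1))
          bamp <- 15 * (stats::rexp(kb) - stats::rexp(kb))  # Laplace
          for (b in seq_len(kb)) {
            idx <- (bstart[b] + 1):(bstart[b] + m)
            bg[idx] <- bg[idx] + bamp[b] * win * stats::rnorm(m)
          }
        }
      }
      hrate <- if (patho) spec$hfo_rate_in else spec$hfo_rate_out
      r1 <- inject_events(bg, "hfo", hrate,
                          seed = sample.int(2^31 - 1, 1), fs = spec$fs)
      r2 <- inject_events(r1$signal, "artifact", spec$artifact_rate,
                          seed = sample.int(2^31 - 1, 1), fs = spec$fs)
      samples[, ci] <- r2$signal
      ev <- rbind(r1$events, r2$events)
      if (nrow(ev)) ev <- data.frame(channel = channels$name[ci], ev)
      events[[ci]] <- ev
    }
    events <- events[vapply(events, NROW, 0L) > 0]
    events <- if (length(events)) do.call(rbind, events) else NULL
    rec <- recording(samples, spec$fs, channels, patient = pid)
    ann <- annotation_set(seizures = NULL, events = events)
    list(recording = rec, annotations = ann,
         truth = list(channels = channels, events = ann$events))
  })
}

#' Generate a full cohort
#' @param spec a [cohort_spec()].
#' @return list of per-patient lists as from [generate_patient()].
#' @export
generate_cohort <- function(spec) {
  lapply(seq_len(spec$n_patients), function(i) generate_patient(spec, i))
}

#' Write a synthetic patient to disk
#'
#' One EDF file, a JSON annotation file (records with channel, t_start_s,
#' t_end_s, kind) and a CSV channel-metadata table (patient, channel, kind,
#' soz, rv, tl).
#'
#' @param pat a list from [generate_patient()].
#' @param dir output directory (created if needed).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_patient <- function(pat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pid <- pat$recording$patient
  paths <- c(edf = file.path(dir, paste0(pid, ".edf")),
             annotations = file.path(dir, paste0(pid, "_annotations.json")),
             channels = file.path(dir, paste0(pid, "_channels.csv")))
  write_edf(pat$recording, paths["edf"])
  ev <- pat$annotations$events
  jsonlite::write_json(
    data.frame(channel = ev$channel, t_start_s = ev$t_start,
               t_end_s = ev$t_end, kind = ev$kind),
    paths["annotations"], dataframe = "rows", auto_unbox = TRUE, digits = NA)
  ch <- pat$recording$channels
  write.csv(data.frame(patient = pid, channel = ch$name, kind = ch$kind,
                       soz = ch$soz, rv = ch$rv, tl = ch$tl),
            paths["channels"], row.names = FALSE)
  invisible(paths)
}
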