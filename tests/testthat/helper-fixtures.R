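# Shared fixtures, all generated in code.  Expensive cohort runs are
# memoised so several test files can reuse them within one run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Small, fast synthetic patient: 6 channels, 4 epochs of 10 s at 2048 Hz.
tiny_spec <- function(...) {
  cohort_spec(n_patients = 3, channels_per_patient = 6, n_soz = 2, n_rv = 3,
              epoch_count = 4, epoch_length_s = 10, fs = 2048,
              hfo_rate_in = 2, hfo_rate_out = 0.5, artifact_rate = 1,
              seed = 42, ...)
}

tiny_patient <- function() cached("tiny_patient", generate_patient(tiny_spec(), 1))

# A recording with known structure and no stochastic events.
flat_recording <- function(n = 4096, nch = 4, fs = 2048, kind = "depth") {
  ch <- data.frame(name = paste0("c", seq_len(nch)), kind = kind,
                   soz = rep(0, nch), rv = rep(0, nch), tl = rep(0, nch))
  recording(matrix(rnorm(n * nch), n, nch), fs, ch)
}

# Direct per-epoch feature table simulation (no signal processing): one row
# per (patient, channel, epoch, band) with iid normal features, plus an
# additive shift `effect` on all band2 features of SOZ channels.
sim_feature_table <- function(n_pat = 6, n_ch = 8, n_ep = 10, n_soz = 2,
                              effect = 0, seed = 1) {
  set.seed(seed)
  pats <- sprintf("P%02d", seq_len(n_pat))
  rows <- expand.grid(epoch = seq_len(n_ep), channel = seq_len(n_ch),
                      band = c("band1", "band2"), patient = pats,
                      stringsAsFactors = FALSE)
  rows$channel <- sprintf("%s_c%02d", rows$patient, rows$channel)
  soz <- as.integer(sub(".*_c", "", rows$channel) %in%
                      sprintf("%02d", seq_len(n_soz)))
  for (f in feature_names()) {
    v <- rnorm(nrow(rows))
    v <- v + effect * soz * (rows$band == "band2")
    rows[[f]] <- v
  }
  rows$n_samples_used <- 1000
  rows$valid <- TRUE
  labels <- unique(data.frame(patient = rows$patient, channel = rows$channel))
  labels$soz <- as.integer(sub(".*_c", "", labels$channel) %in%
                             sprintf("%02d", seq_len(n_soz)))
  labels$rv <- as.integer(sub(".*_c", "", labels$channel) %in%
                            sprintf("%02d", seq_len(n_soz + 1)))
  labels$tl <- rep_len(c(0L, 1L), nrow(labels))
  list(features = rows, labels = labels)
}

# The simulation-study cohorts used by the acceptance checks (criterion-scale).
effect_cohort_result <- function() cached("effect_res", {
  spec <- cohort_spec(seed = 1)
  suppressWarnings(run_phfa(generate_cohort(spec),
                            phfa_config(epoch_length_s = spec$epoch_length_s)))
})

null_cohort_result <- function() cached("null_res", {
  spec <- cohort_spec(band_power_gain = 1, burst_rate = 0,
                      hfo_rate_in = 0.5, hfo_rate_out = 0.5, seed = 1)
  suppressWarnings(run_phfa(generate_cohort(spec),
                            phfa_config(epoch_length_s = spec$epoch_length_s)))
})
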