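# End-to-end orchestration: simulate (or load) -> preprocess -> filter ->
# features -> integrate -> associate -> score -> asymmetry, with provenance
# capture in a manifest.

#' Pipeline configuration
#'
#' @param bands list of c(lo, hi) Hz pairs (default the two-band analysis).
#' @param epoch_length_s epoch duration in seconds.
#' @param margin_s interictal margin around seizure starts in seconds.
#' @param percentile time-integration percentile (default 0.75).
#' @param var_frac PCA explained-variance threshold (default 0.95).
#' @param excess_kurtosis kurtosis convention (default FALSE = non-excess).
#' @param n_tests Bonferroni denominator (default 39).
#' @param n_boot bootstrap resamples for asymmetry CIs.
#' @param min_frac minimum usable fraction of an epoch.
#' @param seed master seed.
#' @return a validated `phfa_config` list.
#' @export
phfa_config <- function(bands = list(c(30, 80), c(80, 500)),
                        epoch_length_s = 30, margin_s = 1800,
                        percentile = 0.75, var_frac = 0.95,
                        excess_kurtosis = FALSE, n_tests = 39,
                        n_boot = 10000, min_frac = 0.25, seed = 1) {
  cfg <- list(bands = bands, epoch_length_s = epoch_length_s,
              margin_s = margin_s, percentile = percentile,
              var_frac = var_frac, excess_kurtosis = excess_kurtosis,
              n_tests = n_tests, n_boot = n_boot, min_frac = min_frac,
              seed = seed)
  stopifnot(length(bands) >= 1, epoch_length_s > 0, margin_s >= 0,
            percentile > 0, percentile < 1, var_frac > 0, var_frac <= 1,
            n_tests >= 1, n_boot >= 1, min_frac > 0, min_frac <= 1)
  structure(cfg, class = "phfa_config")
}

#' Per-epoch features for one patient, from raw recording to table
#'
#' Applies the preprocessing chain (group-wise common average reference,
#' interictal restriction, epoching, HFO/artifact redaction) and computes
#' the per-epoch feature table and HFO rates.
#'
#' @param pat list with `recording` and `annotations` (as from
#'   [generate_patient()] or assembled from files).
#' @param config a [phfa_config()].
#' @return list with `features` (per-epoch table) and `hfo_rates`.
#' @export
process_patient <- function(pat, config = phfa_config()) {
  rec <- common_average_reference(pat$recording)
  mask <- interictal_mask(pat$annotations, rec, margin_s = config$margin_s)
  grid <- build_epochs(mask, rec$fs, epoch_length_s = config$epoch_length_s)
  segs <- redact_events(rec, grid, pat$annotations)
  feats <- compute_feature_table(rec, segs, bands = default_bands(config$bands),
                                 min_frac = config$min_frac,
                                 excess_kurtosis = config$excess_kurtosis)
  list(features = feats, hfo_rates = hfo_rates(pat$annotations, grid, rec))
}

#' Downstream analysis from a per-epoch feature table
#'
#' Runs integration, association, LOPO pHFA scoring and asymmetry
#' statistics from an already-computed per-epoch feature table (columns
#' patient, channel, epoch, band, f1..f19), e.g. one exported from another
#' feature-extraction run.  This is the entry point for re-analysing
#' derived feature data without raw recordings.
#'
#' @param feats per-epoch feature table.
#' @param channel_labels data.frame (patient, channel, soz, rv, tl).
#' @param rates optional data.frame (patient, channel, hfo_rate).
#' @param config a [phfa_config()].
#' @return list with `channels`, `association`, `correlation`, `scores`,
#'   `asymmetries`, `summaries`.
#' @export
downstream_from_features <- function(feats, channel_labels, rates = NULL,
                                     config = phfa_config()) {
  integ <- integrate_features(feats, probs = config$percentile)
  x <- merge(integ, channel_labels, by = c("patient", "channel"),
             sort = FALSE)
  if (!is.null(rates))
    x <- merge(x, rates[, c("patient", "channel", "hfo_rate")],
               by = c("patient", "channel"), sort = FALSE)
  assoc <- associate_features(x, n_tests = config$n_tests)
  corr <- feature_correlation(x)
  scores <- if (length(unique(x$patient)) >= 3)
    lopo_scores(x, var_frac = config$var_frac) else NULL
  asym <- NULL; summaries <- NULL
  if (!is.null(scores)) {
    if ("hfo_rate" %in% names(scores))
      scores$product <- product_score(scores$phfa, scores$hfo_rate)
    asym <- asymmetry_table(scores)
    if (!is.null(asym)) {
      summaries <- do.call(rbind, lapply(split(asym, asym[c("biomarker", "label")]),
        function(g) {
          if (!nrow(g) || sum(is.finite(g$A)) == 0) return(NULL)
          data.frame(biomarker = g$biomarker[1], label = g$label[1],
                     suppressWarnings(cohort_summary(g$A,
                       n_boot = config$n_boot, seed = config$seed)))
        }))
      rownames(summaries) <- NULL
    }
  }
  list(channels = x, association = assoc, correlation = corr,
       scores = scores, asymmetries = asym, summaries = summaries)
}

#' Run the full pipeline on a cohort
#'
#' @param cohort list of patients (each with `recording`, `annotations`),
#'   e.g. from [generate_cohort()].
#' @param config a [phfa_config()].
#' @param out_dir optional directory; when given, every stage output is
#'   written as CSV together with a JSON manifest (config, config hash,
#'   per-stage row counts).
#' @return list with `features`, `hfo_rates` and all tables from
#'   [downstream_from_features()], plus `manifest`.
#' @export
run_phfa <- function(cohort, config = phfa_config(), out_dir = NULL) {
  per <- lapply(cohort, process_patient, config = config)
  feats <- do.call(rbind, lapply(per, `[[`, "features"))
  rates <- do.call(rbind, lapply(per, `[[`, "hfo_rates"))
  labels <- do.call(rbind, lapply(cohort, function(p)
    data.frame(patient = p$recording$patient,
               p$recording$channels[, c("name", "soz", "rv", "tl")])))
  names(labels)[names(labels) == "name"] <- "channel"
  down <- downstream_from_features(feats, labels, rates, config)
  res <- c(list(features = feats, hfo_rates = rates), down)
  res$manifest <- pipeline_manifest(config, res)
  if (!is.null(out_dir)) write_outputs(res, out_dir)
  res
}

#' @noRd
pipeline_manifest <- function(config, res) {
  cfg <- unclass(config)
  tf <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  counts <- lapply(res, function(t) if (is.data.frame(t)) nrow(t) else NULL)
  list(config = cfg, config_md5 = hash,
       row_counts = counts[!vapply(counts, is.null, TRUE)],
       r_version = as.character(getRversion()),
       percentile_convention = "type-5 (half-sample offset)",
       weight_scale = "mean-1 (per-patient totals equal)")
}

#' @noRd
write_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("features", "hfo_rates", "channels", "association",
               "scores", "asymmetries", "summaries")) {
    t <- res[[nm]]
    if (is.data.frame(t))
      write.csv(t, file.path(out_dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  if (!is.null(res$correlation))
    write.csv(res$correlation, file.path(out_dir, "correlation.csv"))
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
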