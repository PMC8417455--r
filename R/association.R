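# Internal association analysis: one patient-weighted logistic regression per
# feature, with features standardized by their scaled median absolute
# deviation so odds ratios are comparable across features in different units.

#' Scaled median absolute deviation
#'
#' `median(|v - median(v)|) / qnorm(0.75)`, a robust spread estimate that
#' equals the standard deviation asymptotically for normal data but is not
#' dominated by the heavy-tailed channels the analysis is trying to find.
#'
#' @param v numeric vector with at least 2 distinct values.
#' @return the sMAD scale.
#' @export
smad <- function(v) {
  v <- v[is.finite(v)]
  if (length(unique(v)) < 2) stop("sMAD needs at least 2 distinct values")
  stats::mad(v, constant = 1 / qnorm(0.75))
}

#' Patient-equalizing observation weights
#'
#' Each patient's channels share that patient's total weight, so every
#' patient contributes equally to a fit regardless of implant size.  The
#' weights are normalized to mean 1 (total = number of channels): the
#' absolute weight scale sets the information scale of a weighted GLM, and
#' mean-1 weights keep Wald inference at its nominal calibration (they
#' reduce to the unweighted fit when all patients have equally many
#' channels).  The scale convention is recorded on the result.
#'
#' @param patient vector of patient ids, one per channel.
#' @return numeric weights, mean 1.
#' @export
patient_weights <- function(patient) {
  counts <- table(patient)
  w <- (length(patient) / length(counts)) / as.numeric(counts[as.character(patient)])
  as.numeric(w)
}

#' Weighted logistic association of one feature with a channel label
#'
#' Fits `label ~ feature/sMAD` by logistic regression with patient-equal
#' weights and returns the odds ratio per one-sMAD increase with Wald 95%
#' CI and p-value.  Complete separation is reported as a flagged
#' infinite-OR result rather than a number.
#'
#' @param values numeric feature values, one per channel.
#' @param labels binary 0/1 labels.
#' @param patient patient id per channel.
#' @return one-row data.frame: odds_ratio, ci_lo, ci_hi, p_value,
#'   n_channels, n_patients, separation flag.
#' @export
fit_feature_model <- function(values, labels, patient) {
  stopifnot(length(values) == length(labels),
            length(values) == length(patient))
  keep <- is.finite(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]; patient <- patient[keep]
  if (length(unique(patient)) < 2) stop("need at least 2 patients")
  if (length(unique(labels)) < 2) stop("both label classes must be present")
  s <- smad(values)
  if (s == 0) stop("sMAD is zero; feature carries no spread")
  z <- values / s
  w <- patient_weights(patient)
  fit <- suppressWarnings(glm(labels ~ z, family = binomial(), weights = w))
  beta <- coef(fit)[["z"]]
  se <- sqrt(vcov(fit)["z", "z"])
  sep <- !fit$converged || abs(beta) > 15 || se > 100
  res <- data.frame(
    odds_ratio = if (sep) NA_real_ else exp(beta),
    ci_lo = if (sep) NA_real_ else exp(beta - 1.96 * se),
    ci_hi = if (sep) NA_real_ else exp(beta + 1.96 * se),
    p_value = if (sep) NA_real_ else 2 * pnorm(-abs(beta / se)),
    n_channels = length(values),
    n_patients = length(unique(patient)),
    separation = sep)
  attr(res, "weight_scale") <- "mean-1 (per-patient totals equal)"
  res
}

#' Bonferroni significance tiers
#'
#' Tier t (1..4) means p < {0.05, 0.01, 0.001, 0.0001}/n_tests with strict
#' inequality; 0 means not significant after correction.
#'
#' @param p numeric p-values.
#' @param n_tests number of tests corrected for (default 39: 38 features
#'   plus the HFO rate).
#' @return integer tiers, same length as `p`.
#' @export
bonferroni_flags <- function(p, n_tests = 39) {
  stopifnot(n_tests >= 1)
  cuts <- c(0.05, 0.01, 0.001, 0.0001) / n_tests
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_integer_)
    sum(pi < cuts)
  }, 0L)
}

#' Association table over all features and labels
#'
#' Runs [fit_feature_model()] for every time-integrated feature column
#' against each requested label and attaches Bonferroni tiers.  An
#' `hfo_rate` column, when present in `x`, is tested alongside the
#' features (the comparison biomarker).
#'
#' @param x data.frame from [integrate_features()] with label columns
#'   (soz/rv/tl) merged in, one row per channel.
#' @param labels label columns to model (default c("soz", "rv", "tl")).
#' @param n_tests Bonferroni denominator (default 39).
#' @return data.frame (feature, label, odds_ratio, ci_lo, ci_hi, p_value,
#'   tier, ...).
#' @export
associate_features <- function(x, labels = c("soz", "rv", "tl"),
                               n_tests = 39) {
  fcols <- integrated_feature_cols(x)
  if ("hfo_rate" %in% names(x)) fcols <- c(fcols, "hfo_rate")
  if (!length(fcols)) stop("no feature columns found")
  out <- NULL
  for (lab in labels) {
    if (!lab %in% names(x) || length(unique(x[[lab]])) < 2) next
    for (f in fcols) {
      row <- tryCatch(fit_feature_model(x[[f]], x[[lab]], x$patient),
                      error = function(e) NULL)
      if (is.null(row)) next
      out <- rbind(out, data.frame(feature = f, label = lab, row))
    }
  }
  if (!is.null(out)) out$tier <- bonferroni_flags(out$p_value, n_tests)
  out
}

#' Feature-feature Pearson correlation matrix
#'
#' Pearson correlations between time-integrated features (plus HFO rate if
#' present), pooled across patients.
#'
#' @param x data.frame from [integrate_features()].
#' @return correlation matrix.
#' @export
feature_correlation <- function(x) {
  fcols <- integrated_feature_cols(x)
  if ("hfo_rate" %in% names(x)) fcols <- c(fcols, "hfo_rate")
  stats::cor(as.matrix(x[, fcols, drop = FALSE]),
             use = "pairwise.complete.obs", method = "pearson")
}
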