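# Asymmetry statistics: scale-invariant effect sizes comparing a channel
# biomarker inside versus outside a labelled region, per patient, with
# cohort medians and bootstrap confidence intervals.

#' Asymmetry of a biomarker with respect to a channel label
#'
#' `A = (mean_in - mean_out) / (mean_in + mean_out)` over the analysed
#' channels inside and outside the labelled region.  For nonnegative
#' biomarkers A lies in \[-1, 1\] and is invariant to rescaling the
#' biomarker, so measures in different units can be compared.
#'
#' @param values nonnegative biomarker values, one per channel.
#' @param in_mask logical/binary membership per channel.
#' @return the asymmetry, or NA (flagged missing) when both group means
#'   are zero.
#' @export
asymmetry <- function(values, in_mask) {
  in_mask <- as.logical(in_mask)
  stopifnot(length(values) == length(in_mask))
  keep <- is.finite(values) & !is.na(in_mask)
  values <- values[keep]; in_mask <- in_mask[keep]
  if (!any(in_mask) || all(in_mask))
    stop("both groups must be non-empty")
  if (any(values < 0)) stop("asymmetry is defined for nonnegative biomarkers")
  xin <- mean(values[in_mask])
  xout <- mean(values[!in_mask])
  if (xin + xout == 0) return(NA_real_)
  (xin - xout) / (xin + xout)
}

#' @noRd
boot_median_ci <- function(v, n_boot = 10000, seed = 1, level = 0.95) {
  with_seed(seed, {
    meds <- vapply(seq_len(n_boot), function(i)
      median(sample(v, length(v), replace = TRUE)), 0)
    quantile(meds, c((1 - level) / 2, 1 - (1 - level) / 2),
             names = FALSE, type = 5)
  })
}

#' Cohort median asymmetry with bootstrap CI
#'
#' Sample median over patients with a 95% percentile-bootstrap CI of the
#' median (10,000 resamples, fixed seed).  With fewer than 3 patients the
#' median is returned with the CI flagged unavailable.
#'
#' @param A per-patient asymmetry values.
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed bootstrap seed (default 1).
#' @return one-row data.frame (n, median, ci_lo, ci_hi).
#' @export
cohort_summary <- function(A, n_boot = 10000, seed = 1) {
  A <- A[is.finite(A)]
  if (!length(A)) stop("no finite asymmetry values")
  if (length(A) < 3) {
    warning("fewer than 3 patients; CI unavailable")
    return(data.frame(n = length(A), median = median(A),
                      ci_lo = NA_real_, ci_hi = NA_real_))
  }
  ci <- boot_median_ci(A, n_boot, seed)
  data.frame(n = length(A), median = median(A), ci_lo = ci[1], ci_hi = ci[2])
}

#' Paired difference in asymmetry between two biomarkers
#'
#' Per-patient `delta = A_b - A_a` with cohort median and bootstrap CI;
#' positive values mean biomarker `b` is the more asymmetric (more
#' label-concentrated) of the two.  Patients missing either biomarker are
#' excluded.
#'
#' @param A_a,A_b named per-patient asymmetry vectors (names = patients).
#' @param n_boot,seed bootstrap parameters as in [cohort_summary()].
#' @return list with `delta` (per patient) and `summary` (one-row
#'   data.frame).
#' @export
paired_difference <- function(A_a, A_b, n_boot = 10000, seed = 1) {
  common <- intersect(names(A_a)[is.finite(A_a)], names(A_b)[is.finite(A_b)])
  if (!length(common)) stop("no patients present for both biomarkers")
  delta <- A_b[common] - A_a[common]
  list(delta = delta, summary = cohort_summary(delta, n_boot, seed))
}

#' Per-patient asymmetry table for scored channels
#'
#' Computes the asymmetry of each biomarker (hfo_rate, phfa, product)
#' with respect to each label (soz, rv, tl) for every patient that has
#' channels on both sides of the label.
#'
#' @param scores data.frame with one row per channel: patient, label
#'   columns, and biomarker columns.
#' @param biomarkers,labels columns to cross (defaults cover the full
#'   grid).
#' @return long data.frame (patient, biomarker, label, A, n_in, n_out).
#' @export
asymmetry_table <- function(scores,
                            biomarkers = c("hfo_rate", "phfa", "product"),
                            labels = c("soz", "rv", "tl")) {
  biomarkers <- intersect(biomarkers, names(scores))
  labels <- intersect(labels, names(scores))
  out <- NULL
  for (p in unique(scores$patient)) {
    sp <- scores[scores$patient == p, , drop = FALSE]
    for (lab in labels) {
      m <- sp[[lab]] == 1
      if (!any(m) || all(m)) next
      for (b in biomarkers) {
        A <- tryCatch(asymmetry(sp[[b]], m), error = function(e) NA_real_)
        out <- rbind(out, data.frame(patient = p, biomarker = b,
                                     label = lab, A = A,
                                     n_in = sum(m), n_out = sum(!m)))
      }
    }
  }
  out
}
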