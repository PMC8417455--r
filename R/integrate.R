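# Reduction of per-epoch features to one time-integrated value per channel:
# subtract the across-channel median within each epoch (removing shared
# temporal drifts), then take the 75th percentile of each channel's adjusted
# values over epochs.

#' Subtract the across-channel median within each epoch
#'
#' Removes shifts common to all channels of a patient (amplifier or state
#' changes), leaving each feature as a measure relative to the other
#' channels at the same time.  Columns are epochs, rows channels.
#'
#' @param F numeric matrix, channels x epochs, of one feature.
#' @return matrix of the same shape whose per-epoch median is 0.
#' @export
median_adjust <- function(F) {
  F <- as.matrix(F)
  if (nrow(F) < 2)
    stop("median adjustment needs at least 2 channels")
  med <- apply(F, 2, median, na.rm = TRUE)
  sweep(F, 2, med)
}

#' 75th percentile under the half-sample-offset convention
#'
#' The k-th order statistic of n values sits at percentile
#' 100*(k - 0.5)/n, with linear interpolation between order statistics and
#' clamping at the extremes (R's quantile type 5, the convention of common
#' numerical environments' percentile functions).  Missing values are
#' removed first.
#'
#' @param v numeric vector of adjusted per-epoch values.
#' @param probs percentile (default 0.75).
#' @return the time-integrated value; NA with a warning when no finite
#'   value remains.
#' @export
integrate_q75 <- function(v, probs = 0.75) {
  v <- v[is.finite(v)]
  if (!length(v)) {
    warning("no finite epoch values; channel value is missing")
    return(NA_real_)
  }
  unname(quantile(v, probs = probs, type = 5))
}

#' Time-integrated channel feature vectors
#'
#' Converts a per-epoch feature table (one patient; long in band) into one
#' row per channel with 38 time-integrated features (19 per band, columns
#' `<band>_f<k>`).  Within each feature and band the across-channel median
#' of each epoch is subtracted, then each channel's 75th percentile over
#' epochs is taken.  Epochs flagged invalid are excluded; channels of a
#' patient are adjusted over all analysed channels pooled across electrode
#' kinds.
#'
#' @param feats data.frame from [compute_feature_table()].
#' @param probs percentile for the time integration (default 0.75).
#' @return data.frame (patient, channel, `<band>_f1..f19`, n_epochs_used).
#' @export
integrate_features <- function(feats, probs = 0.75) {
  stopifnot(all(c("patient", "channel", "epoch", "band") %in% names(feats)))
  if (!nrow(feats)) stop("empty feature table")
  if ("valid" %in% names(feats)) feats <- feats[feats$valid, , drop = FALSE]
  out <- NULL
  for (pat in unique(feats$patient)) {
    fp <- feats[feats$patient == pat, , drop = FALSE]
    channels <- sort(unique(fp$channel))
    res <- data.frame(patient = pat, channel = channels,
                      stringsAsFactors = FALSE)
    n_used <- rep(0L, length(channels))
    for (b in sort(unique(fp$band))) {
      fb <- fp[fp$band == b, , drop = FALSE]
      epochs <- sort(unique(fb$epoch))
      for (f in feature_names()) {
        M <- matrix(NA_real_, length(channels), length(epochs),
                    dimnames = list(channels, epochs))
        M[cbind(match(fb$channel, channels), match(fb$epoch, epochs))] <- fb[[f]]
        A <- median_adjust(M)
        res[[paste0(b, "_", f)]] <-
          vapply(seq_along(channels),
                 function(i) suppressWarnings(integrate_q75(A[i, ], probs)),
                 0)
      }
      n_used <- pmax(n_used, vapply(channels, function(ch)
        sum(fb$channel == ch), 0L))
    }
    res$n_epochs_used <- n_used
    out <- rbind(out, res)
  }
  out
}

#' Columns holding time-integrated features
#' @param x a data.frame from [integrate_features()].
#' @return character vector of feature column names.
#' @export
integrated_feature_cols <- function(x) {
  grep("^band[0-9]+_f[0-9]+$", names(x), value = TRUE)
}
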