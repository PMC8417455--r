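# Predictive pHFA score: whitening -> PCA (95% variance) -> logistic
# regression, trained under hold-out-one-patient cross-validation so every
# channel is scored by a model that never saw its patient.

#' Fit a pHFA model on training channels
#'
#' Whitens the 38 time-integrated features with training mean and sample
#' standard deviation, takes principal components until at least
#' `var_frac` of the training variance is captured, and fits an unweighted
#' logistic regression of SOZ membership on the component scores.  A
#' zero-variance training feature gets sd 1 (no information, no division
#' by zero) with a warning; on complete separation the logistic fit falls
#' back to a small ridge penalty (1e-6) with a warning, keeping the model
#' deterministic.
#'
#' @param X numeric matrix, training channels x features.
#' @param y binary SOZ labels.
#' @param var_frac cumulative explained-variance threshold (default 0.95).
#' @param weights optional observation weights (default unweighted; the
#'   patient-equalizing variant is available via [patient_weights()]).
#' @return a `phfa_model`: whitening mean/sd, loadings, explained-variance
#'   fractions, k, logistic coefficients.
#' @export
fit_fold <- function(X, y, var_frac = 0.95, weights = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) stop("both classes must be present in training")
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  if (any(sdev == 0)) {
    warning("zero-variance training feature(s); sd set to 1")
    sdev[sdev == 0] <- 1
  }
  W <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  pc <- prcomp(W, center = FALSE, scale. = FALSE)
  evf <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(evf) >= var_frac)[1]
  if (is.na(k)) k <- length(evf)
  L <- pc$rotation[, seq_len(k), drop = FALSE]
  S <- W %*% L
  df <- data.frame(y = y, S)
  fit <- withCallingHandlers(
    glm(y ~ ., family = binomial(), data = df, weights = weights),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- coef(fit)
  if (!fit$converged || any(!is.finite(beta)) || max(abs(beta[-1])) > 15) {
    warning("separation in logistic fit; using ridge penalty 1e-6")
    beta <- ridge_logistic(cbind(1, S), y, lambda = 1e-6,
                           weights = weights %||% rep(1, length(y)))
  }
  structure(list(mean = mu, sd = sdev, loadings = L,
                 explained_var = evf, k = k,
                 coefficients = unname(beta), var_frac = var_frac),
            class = "phfa_model")
}

# Deterministic Newton-Raphson ridge logistic regression (intercept
# unpenalized); fallback under separation.
#' @noRd
ridge_logistic <- function(X, y, lambda = 1e-6, weights = rep(1, length(y)),
                           maxit = 100, tol = 1e-10) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    wv <- weights * mu * (1 - mu)
    g <- drop(crossprod(X, weights * (y - mu))) - drop(pen %*% beta)
    H <- crossprod(X, X * wv) + pen
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

#' Score held-out channels with a fitted pHFA model
#'
#' Transforms test channels with the training whitening and loadings only
#' and applies the logistic model, giving a score in \[0, 1\] per channel
#' (0 = least, 1 = most likely pathological).
#'
#' @param model a `phfa_model`.
#' @param X numeric matrix, test channels x features (same feature space
#'   as training).
#' @return numeric pHFA scores; channels with missing features are NA.
#' @export
score_channels <- function(model, X) {
  stopifnot(inherits(model, "phfa_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$mean))
    stop("test data must be in the same feature space as training")
  ok <- apply(X, 1, function(r) all(is.finite(r)))
  W <- sweep(sweep(X[ok, , drop = FALSE], 2, model$mean), 2, model$sd, "/")
  S <- W %*% model$loadings
  eta <- drop(cbind(1, S) %*% model$coefficients)
  out <- rep(NA_real_, nrow(X))
  out[ok] <- plogis(eta)
  out
}

#' Hold-out-one-patient cross-validated pHFA scores
#'
#' For each patient in turn, fits a pHFA model on all other patients'
#' channels and scores the held-out patient's channels, so every channel
#' is scored exactly once without in-sample training.  A fold whose
#' training set lacks a class fails loudly (warning, NA scores) while the
#' other folds proceed.
#'
#' @param x data.frame with one row per channel: `patient`, `soz`, and the
#'   time-integrated feature columns.
#' @param var_frac PCA explained-variance threshold (default 0.95).
#' @param weighted use patient-equalizing weights in the fold fits
#'   (default FALSE; the stated procedure weights the association models
#'   only).
#' @return `x` with columns `phfa` and `fold_k` (per-fold component count)
#'   appended.
#' @export
lopo_scores <- function(x, var_frac = 0.95, weighted = FALSE) {
  stopifnot(all(c("patient", "soz") %in% names(x)))
  fcols <- integrated_feature_cols(x)
  if (!length(fcols)) stop("no feature columns found")
  patients <- unique(x$patient)
  if (length(patients) < 3) stop("need at least 3 patients for LOPO-CV")
  x$phfa <- NA_real_
  x$fold_k <- NA_integer_
  for (p in patients) {
    tr <- x$patient != p
    Xtr <- as.matrix(x[tr, fcols])
    keep <- apply(Xtr, 1, function(r) all(is.finite(r)))
    model <- tryCatch(
      fit_fold(Xtr[keep, , drop = FALSE], x$soz[tr][keep], var_frac,
               weights = if (weighted) patient_weights(x$patient[tr][keep])),
      error = function(e) {
        warning(sprintf("fold for patient %s failed: %s", p,
                        conditionMessage(e)))
        NULL
      })
    if (is.null(model)) next
    x$phfa[!tr] <- score_channels(model, as.matrix(x[!tr, fcols]))
    x$fold_k[!tr] <- model$k
  }
  x
}

#' HFO-rate x pHFA product biomarker
#'
#' Channel-wise product, a concordance score analogous to a logical "and":
#' it is large only where both the HFO rate and the pHFA score are large,
#' and insensitive to the different units of the two measures.
#'
#' @param phfa pHFA scores in \[0, 1\].
#' @param hfo_rate HFO rates in events/min (>= 0).
#' @return product in events/min.
#' @export
product_score <- function(phfa, hfo_rate) {
  stopifnot(length(phfa) == length(hfo_rate))
  if (any(hfo_rate < 0, na.rm = TRUE)) stop("hfo_rate must be >= 0")
  phfa * hfo_rate
}
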