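test_that("component count k is the smallest capturing 95% of training variance", {
  set.seed(20)
  n <- 2000
  u <- rnorm(n)
  # two features sharing one latent component; after whitening the PCA
  # eigenvalues are 1 +/- rho, so rho = 0.92 splits variance 96%/4%
  e <- sqrt((1 - 0.92) / 0.92)
  X <- cbind(u + e * rnorm(n), u + e * rnorm(n))
  y <- rbinom(n, 1, plogis(u))
  m <- fit_fold(X, y)
  expect_equal(m$k, 1)
  # isotropic noise needs most of the dimensions
  Xi <- matrix(rnorm(300 * 38), 300, 38)
  mi <- fit_fold(Xi, rbinom(300, 1, 0.3))
  expect_gte(mi$k, 20)
})

test_that("whitening uses training statistics and normalizes exactly", {
  set.seed(21)
  X <- matrix(rnorm(100 * 5, mean = 3, sd = 2), 100, 5)
  y <- rbinom(100, 1, 0.4)
  m <- fit_fold(X, y)
  W <- sweep(sweep(X, 2, m$mean), 2, m$sd, "/")
  expect_lt(max(abs(colMeans(W))), 1e-9)
  expect_lt(max(abs(apply(W, 2, sd) - 1)), 1e-9)
  expect_identical(m, fit_fold(X, y))    # deterministic refit
  expect_warning(fit_fold(cbind(X, 7), c(y[-1], 1 - y[1])), "zero-variance")
})

test_that("scores are the logistic output in the training PCA space", {
  set.seed(22)
  X <- matrix(rnorm(200 * 6), 200, 6)
  y <- rbinom(200, 1, plogis(X[, 1]))
  m <- fit_fold(X, y)
  s <- score_channels(m, X)
  expect_true(all(s >= 0 & s <= 1))
  # a channel at the training mean scores logistic(intercept)
  at_mean <- matrix(m$mean, 1)
  expect_equal(score_channels(m, at_mean), plogis(m$coefficients[1]),
               tolerance = 1e-12)
  # monotone along the discriminant direction
  dir <- drop(m$loadings %*% m$coefficients[-1]) * m$sd
  line <- t(sapply(seq(-3, 3, length.out = 13), function(a) m$mean + a * dir))
  expect_true(all(diff(score_channels(m, line)) > 0))
})

test_that("LOPO scores every channel once by a model that never saw its patient", {
  sim <- sim_feature_table(n_pat = 6, n_ch = 8, n_ep = 6, effect = 2,
                           seed = 23)
  integ <- integrate_features(sim$features)
  x <- merge(integ, sim$labels, by = c("patient", "channel"))
  s <- suppressWarnings(lopo_scores(x))
  expect_true(all(is.finite(s$phfa)))
  expect_equal(nrow(s), nrow(x))
  expect_true(all(s$fold_k >= 1))
  # corrupting a held-out patient's features leaves that fold's model bit-identical
  fcols <- integrated_feature_cols(x)
  tr <- x$patient != "P01"
  m1 <- suppressWarnings(fit_fold(as.matrix(x[tr, fcols]), x$soz[tr]))
  xc <- x
  xc[!tr, fcols] <- xc[!tr, fcols] * 100 + 7
  m2 <- suppressWarnings(fit_fold(as.matrix(xc[tr, fcols]), xc$soz[tr]))
  expect_identical(m1, m2)
  # and scores for a patient don't depend on the order of the others
  perm <- x[order(match(x$patient, c("P03", "P01", "P05", "P02", "P06", "P04"))), ]
  s2 <- suppressWarnings(lopo_scores(perm))
  # row order changes floating-point summation, not the model: scores agree
  # to far below any meaningful resolution
  expect_lt(max(abs(s2$phfa[match(paste(s$patient, s$channel),
                                  paste(s2$patient, s2$channel))] - s$phfa)),
            1e-6)
})

test_that("a fold without both classes fails loudly while others proceed", {
  sim <- sim_feature_table(n_pat = 4, n_ch = 6, n_ep = 5, seed = 24)
  integ <- integrate_features(sim$features)
  x <- merge(integ, sim$labels, by = c("patient", "channel"))
  # make P01 the only patient with any SOZ channel
  x$soz[x$patient != "P01"] <- 0
  w <- capture_warnings(s <- lopo_scores(x))
  expect_true(any(grepl("failed", w)))
  expect_true(all(is.na(s$phfa[s$patient == "P01"])))
  expect_true(all(is.finite(s$phfa[s$patient != "P01"])))
})

test_that("the product biomarker is an and-like combination", {
  expect_equal(product_score(c(0.2, 0.9), c(0, 3)), c(0, 2.7))
  expect_equal(product_score(rep(1, 3), c(1, 2, 3)), c(1, 2, 3))
  expect_error(product_score(0.5, -1), ">= 0")
})
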