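test_that("normalization follows the sample-sd convention and is affine invariant", {
  expect_equal(hfa_normalize(c(1, 2, 3)), c(-1, 0, 1))
  x <- rnorm(100)
  y <- hfa_normalize(x)
  expect_equal(mean(y), 0, tolerance = 1e-9)
  expect_equal(sd(y), 1, tolerance = 1e-9)
  expect_equal(hfa_normalize(3.7 * x + 11), y, tolerance = 1e-9)
  expect_error(hfa_normalize(rep(2, 10)), "degenerate")
})

test_that("transform operators match their closed forms", {
  fS <- 4.096
  # constant input: all difference-based transforms vanish
  cst <- rep(2, 50)
  expect_true(all(line_length(cst, fS) == 0))
  expect_true(all(curvature(cst, fS) == 0))
  expect_true(all(teager(cst, fS) == 0))
  expect_equal(rectify(c(-1, 2, -3)), c(1, 2, 3))
  # Teager-Kaiser on a normalized tone is constant: 2*sin^2(pi/16)*fS^2
  y <- sqrt(2) * sin(pi * (1:1000) / 16)   # 128 Hz at 4096 Hz
  tk <- teager(y, fS)
  expect_lt(max(abs(tk - 2 * sin(pi / 16)^2 * fS^2)), 1e-9)
  # alternating sequence: line length constant 2*fS
  alt <- rep(c(1, -1), 32)
  expect_true(all(abs(line_length(alt, fS) - 8.192) < 1e-12))
  # output lengths n, n-1, n-2, n-2
  expect_length(rectify(y), 1000)
  expect_length(line_length(y, fS), 999)
  expect_length(curvature(y, fS), 998)
  expect_length(teager(y, fS), 998)
})

test_that("moments match hand computation and the normal-law limit", {
  m <- signal_moments(c(1, 2, 3, 4))
  expect_equal(m$mean, 2.5)
  expect_equal(m$sd, sd(1:4))
  expect_equal(m$skew, 0)
  expect_equal(m$kurt, 1.64)    # m4/m2^2 = 2.5625/1.5625
  expect_equal(signal_moments(c(1, 2, 3, 4), excess_kurtosis = TRUE)$kurt,
               1.64 - 3)
  set.seed(4)
  z <- rnorm(1e6)
  expect_equal(signal_moments(z)$kurt, 3.0, tolerance = 0.1 / 3)
  expect_error(signal_moments(rep(1, 10)), "zero variance")
})

test_that("moment accumulation is permutation invariant", {
  set.seed(5)
  v <- rnorm(1e5) * 1e3 + 1e6   # offset stresses the accumulation
  a <- signal_moments(v)
  b <- signal_moments(rev(v))
  d <- signal_moments(sample(v))
  for (f in names(a)) {
    expect_lt(abs(a[[f]] - b[[f]]) / max(1, abs(a[[f]])), 1e-9)
    expect_lt(abs(a[[f]] - d[[f]]) / max(1, abs(a[[f]])), 1e-9)
  }
})

test_that("epoch features hit their closed-form oracles", {
  set.seed(6)
  z <- rnorm(1e6)
  fv <- compute_epoch_features(list(z), fs = 4096)
  # E|Z| = sqrt(2/pi) for standard normal
  expect_equal(unname(fv["f1"]), 10 * log10(sqrt(2 / pi)), tolerance = 0.02)
  expect_equal(unname(fv["f15"]), 10 * log10(3), tolerance = 0.05)
  expect_equal(unname(fv["f10"]), 0, tolerance = 0.01)
  # pure normalized tone: f4 from the Teager constant
  y <- sqrt(2) * sin(pi * (1:100000) / 16)
  fv2 <- compute_epoch_features(list(y), fs = 4096)
  expect_equal(unname(fv2["f4"]),
               10 * log10(2 * sin(pi / 16)^2 * 4.096^2), tolerance = 1e-3)
  expect_equal(unname(fv2["f10"]), 0, tolerance = 1e-6)
})

test_that("exactly 19 features per band are emitted, 38 for two bands", {
  expect_length(feature_names(), 19)
  p <- tiny_patient()
  pp <- process_patient(p, phfa_config(epoch_length_s = 10))
  fcols <- intersect(names(pp$features), feature_names())
  expect_length(fcols, 19)
  expect_setequal(unique(pp$features$band), c("band1", "band2"))
  one <- pp$features[pp$features$channel == pp$features$channel[1] &
                       pp$features$epoch == pp$features$epoch[1], ]
  expect_equal(nrow(one), 2)                 # two bands
  expect_equal(2 * length(fcols), 38)
  expect_true(all(pp$features$f10 > -pi / 2 & pp$features$f10 < pi / 2))
})

test_that("all features except f5 are amplitude invariant; f5 shifts by 10*log10(a)", {
  set.seed(7)
  x <- as.numeric(arima.sim(list(ar = 0.6), 20000))
  a <- 12.5
  f_base <- compute_epoch_features(list(x), fs = 2048)
  f_scaled <- compute_epoch_features(list(a * x), fs = 2048)
  expect_equal(unname(f_scaled["f5"] - f_base["f5"]), 10 * log10(a),
               tolerance = 1e-9)
  others <- setdiff(feature_names(), "f5")
  expect_lt(max(abs(f_scaled[others] - f_base[others])), 1e-6)
})

test_that("splitting an epoch into segments changes features only at the cut margins", {
  set.seed(8)
  x <- as.numeric(arima.sim(list(ar = 0.5), 2e5))
  whole <- compute_epoch_features(list(x), fs = 2048)
  cut <- 81000
  split2 <- compute_epoch_features(list(x[1:cut], x[(cut + 1):length(x)]),
                                   fs = 2048)
  expect_lt(max(abs(whole[feature_names()] - split2[feature_names()])), 1e-3)
})

test_that("degenerate epochs are flagged, not propagated", {
  fv <- compute_epoch_features(list(rep(1, 1000)), fs = 2048)
  expect_true(all(is.na(fv[feature_names()])))
  expect_equal(attr(fv, "reason"), "zero variance")
  fv2 <- compute_epoch_features(list(c(1, 2)), fs = 2048)
  expect_equal(attr(fv2, "reason"), "too few samples")
})
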