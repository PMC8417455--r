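test_that("common average reference zeroes group means and is idempotent", {
  set.seed(1)
  rec <- flat_recording(n = 2048, nch = 4)
  out <- common_average_reference(rec)
  expect_lt(max(abs(rowMeans(out$samples))), 1e-10)
  twice <- common_average_reference(out)
  expect_lt(max(abs(twice$samples - out$samples)), 1e-10)
})

test_that("identical channels cancel and zero-mean pairs pass through", {
  ch <- data.frame(name = c("a", "b"), kind = "depth", soz = 0, rv = 0, tl = 0)
  v <- rnorm(100)
  rec <- recording(cbind(v, v), 2048, ch)
  expect_true(all(common_average_reference(rec)$samples == 0))
  rec2 <- recording(cbind(rep(1, 100), rep(-1, 100)), 2048, ch)
  expect_equal(common_average_reference(rec2)$samples, rec2$samples)
})

test_that("depth and grid/strip channels are referenced separately", {
  set.seed(2)
  ch <- data.frame(name = paste0("c", 1:4),
                   kind = c("depth", "depth", "grid", "strip"),
                   soz = 0, rv = 0, tl = 0)
  rec <- recording(matrix(rnorm(400), 100, 4), 2048, ch)
  out <- common_average_reference(rec)
  expect_lt(max(abs(rowMeans(out$samples[, 1:2]))), 1e-10)
  expect_lt(max(abs(rowMeans(out$samples[, 3:4]))), 1e-10)
  # depth reference must not leak into the surface group
  expect_false(isTRUE(all.equal(out$samples[, 3],
                                rec$samples[, 3] - rowMeans(rec$samples))))
})

test_that("interictal mask excludes the margin around each seizure start", {
  rec <- flat_recording(n = 7200 * 10, nch = 4, fs = 10)  # 2 h at 10 Hz
  ann <- annotation_set(seizures = data.frame(t_start = 3600, t_end = NA))
  m <- interictal_mask(ann, rec, margin_s = 1800)
  t <- (seq_along(m) - 1) / 10
  expect_true(all(!m[t >= 1800 & t < 5400]))
  expect_true(all(m[t < 1799.8]))
  expect_true(all(m[t > 5400.2]))
  # no seizures -> all usable
  expect_true(all(interictal_mask(annotation_set(), rec)))
})

test_that("overlapping exclusion windows merge and the ictal interval itself is excluded", {
  rec <- flat_recording(n = 10000 * 10, nch = 4, fs = 10)
  ann <- annotation_set(seizures = data.frame(t_start = c(2000, 2500),
                                              t_end = c(4500, NA)))
  m <- interictal_mask(ann, rec, margin_s = 600)
  t <- (seq_along(m) - 1) / 10
  # union of [1400, 4500] (start1 margin + known end) and [1900, 3100]
  expect_true(all(!m[t >= 1400 & t < 4500]))
  expect_true(all(m[t < 1399.8]))
  expect_true(all(m[t > 4500.2]))
  expect_warning(
    interictal_mask(annotation_set(
      seizures = data.frame(t_start = 99999, t_end = NA)), rec),
    "outside")
})

test_that("epoch grids tile the recording and flag partially masked epochs", {
  mask <- rep(TRUE, 4096 * 3600)
  g <- build_epochs(mask, fs = 4096, epoch_length_s = 300)
  expect_equal(nrow(g$epochs), 12)
  expect_true(all(g$epochs$usable))
  expect_equal(g$epochs$end_sample - g$epochs$start_sample,
               rep(1228800L, 12))
  mask[4096 * 400] <- FALSE   # inside epoch 2
  g2 <- build_epochs(mask, fs = 4096, epoch_length_s = 300)
  expect_equal(which(!g2$epochs$usable), 2L)
  expect_equal(nrow(build_epochs(rep(TRUE, 100), 4096, 300)$epochs), 0)
})

test_that("redaction cuts events out of epochs per channel and conserves samples", {
  fs <- 1000
  rec <- flat_recording(n = fs * 20, nch = 4, fs = fs)
  g <- build_epochs(rep(TRUE, fs * 20), fs, epoch_length_s = 10)
  # no events: one full segment
  s0 <- redact_events(rec, g, annotation_set())
  expect_equal(s0$segments[["c1"]][["1"]],
               data.frame(start = 0L, end = fs * 10))
  # one 100 ms event mid-epoch on c1 only
  ann <- annotation_set(events = data.frame(
    channel = "c1", t_start = 5, t_end = 5.1, kind = "hfo"))
  s1 <- redact_events(rec, g, ann)
  seg <- s1$segments[["c1"]][["1"]]
  expect_equal(nrow(seg), 2)
  expect_equal(sum(seg$end - seg$start), fs * 10 - 0.1 * fs)
  expect_equal(s1$segments[["c2"]][["1"]],
               data.frame(start = 0L, end = fs * 10))
  # abutting events merge into one gap
  ann2 <- annotation_set(events = data.frame(
    channel = "c1", t_start = c(5, 5.1), t_end = c(5.1, 5.2), kind = "hfo"))
  expect_equal(nrow(redact_events(rec, g, ann2)$segments[["c1"]][["1"]]), 2)
  # event covering the whole epoch empties it
  ann3 <- annotation_set(events = data.frame(
    channel = "c1", t_start = 0, t_end = 10, kind = "artifact"))
  expect_equal(nrow(redact_events(rec, g, ann3)$segments[["c1"]][["1"]]), 0)
})

test_that("redaction conserves total samples for random event sets", {
  fs <- 500
  rec <- flat_recording(n = fs * 30, nch = 4, fs = fs)
  g <- build_epochs(rep(TRUE, fs * 30), fs, epoch_length_s = 10)
  set.seed(9)
  for (i in 1:5) {
    st <- sort(runif(10, 0, 29))
    ev <- data.frame(channel = "c2", t_start = st,
                     t_end = st + runif(10, 0.01, 1), kind = "hfo")
    segs <- redact_events(rec, g, annotation_set(events = ev))
    cuts <- data.frame(start = floor(ev$t_start * fs),
                       end = ceiling(ev$t_end * fs))
    for (ep in 1:3) {
      lo <- (ep - 1) * fs * 10; hi <- ep * fs * 10
      cut_samples <- sum(vapply(seq_len(nrow(cuts)), function(k)
        max(0, min(hi, cuts$end[k]) - max(lo, cuts$start[k])), 0))
      # overlapping cuts may double count; compute union length instead
      covered <- rep(FALSE, hi - lo)
      for (k in seq_len(nrow(cuts))) {
        a <- max(lo, cuts$start[k]); b <- min(hi, cuts$end[k])
        if (b > a) covered[(a - lo + 1):(b - lo)] <- TRUE
      }
      seg <- segs$segments[["c2"]][[as.character(ep)]]
      expect_equal(sum(seg$end - seg$start) + sum(covered), hi - lo)
    }
  }
})

test_that("HFO rates count annotations over analysed minutes", {
  fs <- 1000
  rec <- flat_recording(n = fs * 120, nch = 4, fs = fs)
  g <- build_epochs(rep(TRUE, fs * 120), fs, epoch_length_s = 60)
  ann <- annotation_set(events = data.frame(
    channel = c("c1", "c1", "c1", "c2"),
    t_start = c(10, 50, 70, 30), t_end = c(10.05, 50.05, 70.05, 30.05),
    kind = c("hfo", "hfo", "hfo", "artifact")))
  r <- hfo_rates(ann, g, rec)
  expect_equal(r$hfo_rate[r$channel == "c1"], 1.5)  # 3 HFOs / 2 min
  expect_equal(r$hfo_rate[r$channel == "c2"], 0)    # artifacts don't count
})
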