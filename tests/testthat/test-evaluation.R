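test_that("tolerance matching handles the canonical cases", {
  # within the +-150 ms window
  m1 <- match_events(10.10, 10.00, 0.150)
  expect_equal(nrow(m1$tp), 1)
  # outside it: one FP and one FN
  m2 <- match_events(10.20, 10.00, 0.150)
  expect_equal(nrow(m2$tp), 0)
  expect_length(m2$fp, 1); expect_length(m2$fn, 1)
  # two detections compete for one reference: the closer one wins
  m3 <- match_events(c(9.95, 10.06), 10.00, 0.150)
  expect_equal(nrow(m3$tp), 1)
  expect_equal(m3$tp$detection, 9.95)
  expect_length(m3$fp, 1)
  # detections near an excluded (fusion) reference are set aside
  m4 <- match_events(c(5.0, 10.0), 10.0, 0.150, excluded_times = 5.05)
  expect_equal(nrow(m4$tp), 1)
  expect_length(m4$fp, 0)
  expect_length(m4$excluded, 1)
})

test_that("matching equals exhaustive optimal assignment on random instances", {
  set.seed(101)
  for (k in 1:300) {
    det <- sort(stats::runif(sample(0:8, 1), 0, 3))
    ref <- sort(stats::runif(sample(0:8, 1), 0, 3))
    m <- match_events(det, ref, 0.15)
    expect_identical(nrow(m$tp), brute_force_matches(det, ref, 0.15))
    # bookkeeping identities
    expect_equal(nrow(m$tp) + length(m$fp) + length(m$excluded), length(det))
    expect_equal(nrow(m$tp) + length(m$fn), length(ref))
    if (nrow(m$tp))
      expect_true(all(abs(m$tp$detection - m$tp$reference) <= 0.15))
  }
})

test_that("beat metrics reproduce the published benchmark arithmetic", {
  # counts constructed to give the printed 87.9 / 96.4 / 91.9
  ms <- beat_metrics(list(tp = 879, fp = 33, fn = 121),
                     n_detected_beats = 50000)
  expect_equal(round(100 * ms$sensitivity, 1), 87.9)
  expect_equal(round(100 * ms$ppv, 1), 96.4)
  expect_equal(round(100 * ms$f1, 1), 91.9)

  z <- beat_metrics(list(tp = 0, fp = 5, fn = 10), 100)
  expect_equal(z$sensitivity, 0); expect_equal(z$f1, 0)

  p <- beat_metrics(list(tp = 10, fp = 0, fn = 0), 100)
  expect_equal(p$ppv, 1); expect_equal(p$specificity, 1)

  u <- beat_metrics(list(tp = 0, fp = 0, fn = 0), 100)
  expect_true(is.na(u$sensitivity)); expect_true(is.na(u$ppv))

  expect_error(beat_metrics(list(tp = 10, fp = 10, fn = 0), 5), "at least")
})

test_that("F1 is the symmetric harmonic mean with its standard bounds", {
  set.seed(103)
  for (k in 1:50) {
    s <- stats::runif(1); p <- stats::runif(1)
    expect_equal(f1_score(s, p), f1_score(p, s))
    expect_lte(f1_score(s, p), max(s, p) + 1e-12)
    expect_gte(f1_score(s, p), min(s, p) - 1e-12)
    expect_equal(f1_score(s, s), s)
  }
  expect_true(is.na(f1_score(NA_real_, 0.5)))
})

test_that("patient averaging is unweighted and skips undefined entries", {
  p1 <- beat_metrics(list(tp = 80, fp = 0, fn = 20), 1000)
  p2 <- beat_metrics(list(tp = 60, fp = 0, fn = 40), 1000)
  pa <- patient_average(list(p1, p2))
  expect_equal(pa$sensitivity, 0.70)
  expect_equal(patient_average(list(p1))$sensitivity, p1$sensitivity)

  # a high-volume patient dominates the gross metric but not the average
  big <- beat_metrics(list(tp = 9000, fp = 0, fn = 1000), 99000)
  small <- beat_metrics(list(tp = 1, fp = 0, fn = 9), 1000)
  gross <- beat_metrics(list(tp = 9001, fp = 0, fn = 1009), 100000)
  pa2 <- patient_average(list(big, small))
  expect_equal(gross$sensitivity, 9001 / 10010)
  expect_equal(pa2$sensitivity, (0.9 + 0.1) / 2)
  expect_false(isTRUE(all.equal(gross$sensitivity, pa2$sensitivity)))

  # undefined sensitivity (no reference PVCs) is skipped, not zeroed
  none <- beat_metrics(list(tp = 0, fp = 0, fn = 0), 1000)
  pa3 <- patient_average(list(p1, none))
  expect_equal(pa3$sensitivity, p1$sensitivity)
})

test_that("GEE-adjusted proportion matches the reference implementation", {
  # regenerate the frozen fixture: 15 beta-binomial clusters
  set.seed(42)
  rows <- do.call(rbind, lapply(1:15, function(i) {
    ni <- sample(5:40, 1); p <- stats::rbeta(1, 4, 2)
    data.frame(id = i, y = stats::rbinom(ni, 1, p))
  }))
  s <- tapply(rows$y, rows$id, sum)
  n <- tapply(rows$y, rows$id, length)
  g <- gee_adjusted(as.numeric(s), as.numeric(n))
  # expected values computed once with statsmodels GEE (binomial link,
  # exchangeable correlation, robust covariance) on this exact dataset
  expect_equal(g$proportion, 0.748827995457, tolerance = 1e-6)
  expect_equal(g$ci_lo, 0.642306397314, tolerance = 1e-6)
  expect_equal(g$ci_hi, 0.831928075202, tolerance = 1e-6)
})

test_that("GEE degenerates gracefully and matches observed proportions", {
  # every cluster at exactly one half
  g <- gee_adjusted(c(5, 10, 20), c(10, 20, 40))
  expect_equal(g$proportion, 0.5, tolerance = 1e-10)
  # equal cluster sizes: weights are uniform regardless of correlation
  g2 <- gee_adjusted(c(3, 5, 7), c(10, 10, 10))
  expect_equal(g2$proportion, 0.5, tolerance = 1e-10)
  # all-zero outcome: degenerate CI marker
  g0 <- gee_adjusted(c(0, 0, 0), c(5, 10, 2))
  expect_equal(g0$proportion, 0)
  expect_true(is.na(g0$ci_lo))
  expect_error(gee_adjusted(1, 2), "2 clusters")
})

test_that("burden agreement returns r, bias and limits of agreement", {
  est <- c(1, 5, 10, 20, 30)
  a <- burden_agreement(est, est)
  expect_equal(a$r, 1); expect_equal(a$bias, 0)

  # uniform underestimation reproduces the constructed bias exactly
  a2 <- burden_agreement(est - 1.83, est)
  expect_equal(a2$bias, -1.83)
  expect_equal(a2$r, 1)
  expect_equal(a2$loa_lo, -1.83); expect_equal(a2$loa_hi, -1.83)

  set.seed(104)
  x <- stats::runif(20, 0, 30); y <- x + stats::rnorm(20)
  a3 <- burden_agreement(x, y)
  expect_equal(a3$r, stats::cor(x, y), tolerance = 1e-12)
  d <- x - y
  expect_equal(a3$loa_hi - a3$loa_lo, 2 * 1.96 * stats::sd(d))

  expect_true(is.na(burden_agreement(rep(5, 4), c(1, 2, 3, 4))$r))
  expect_error(burden_agreement(1:2, 1:2), "3 pairs")
})

test_that("patient-level threshold metrics reproduce the 38-patient case", {
  # 38 reference-positive patients; 32 detected, 6 missed, no false alarms
  ref <- c(rep(15, 38), rep(2, 51))
  est <- c(rep(15, 32), rep(8, 6), rep(2, 51))
  tm <- threshold_metrics(est, ref, 10)
  expect_equal(tm$tp, 32); expect_equal(tm$fn, 6); expect_equal(tm$fp, 0)
  expect_equal(round(100 * tm$sensitivity), 84)
  expect_equal(tm$ppv, 1)
  expect_equal(tm$specificity, 1)

  expect_equal(threshold_metrics(ref, ref, 10)$sensitivity, 1)

  # lowering the device threshold (reference positives fixed) never lowers
  # patient-level sensitivity
  set.seed(105)
  est2 <- stats::runif(40, 0, 25); ref2 <- stats::runif(40, 0, 25)
  sens <- vapply(c(20, 15, 10, 5, 0), function(th)
    threshold_metrics(est2, ref2, th, ref_threshold_pct = 10)$sensitivity, 0)
  expect_true(all(diff(sens) >= -1e-12))
  expect_equal(sens[length(sens)], 1)  # threshold 0: everything flagged
})
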