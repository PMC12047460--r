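# a toy record of identical NSR beats plus helpers for feature tests
toy_identical <- function(n_beats = 20, fs = 256, amp = 500) {
  proto <- synth_prototypes(fs, amp)
  tt <- seq(2, n_beats + 1)
  x <- rep(0, fs * (n_beats + 3))
  t0 <- attr(proto, "t")
  for (b in tt) {
    idx <- round((b + t0) * fs) + 1
    x[idx] <- x[idx] + proto$nsr
  }
  sig <- ecg_signal(x, fs = fs)
  beats <- data.frame(time = tt, peak_amp = amp, source = "detected",
                      in_noise = FALSE)
  list(sig = sig, beats = beats, proto = proto,
       tmpl = form_template(sig, beats, at_time = max(tt) + 1,
                            detector_config()))
}

cand_row <- function(time, prematurity = 1, rr_next = 1, rr_local_mean = 1,
                     amp_ratio = 1, seq_type = "single") {
  data.frame(beat_index = 1L, time = time, seq_type = seq_type,
             member_index = 0L, rr_prev = prematurity * rr_local_mean,
             rr_next = rr_next, rr_local_mean = rr_local_mean,
             prematurity = prematurity, amp_ratio = amp_ratio,
             stringsAsFactors = FALSE)
}

test_that("features vanish for a beat identical to the template", {
  toy <- toy_identical()
  fv <- extract_features(toy$sig, cand_row(10), toy$tmpl)
  expect_lt(fv[["one_minus_cwa"]], 1e-6)
  expect_lt(fv[["one_minus_dcwa"]], 1e-6)
  expect_equal(fv[["prematurity"]], 1)
  expect_equal(fv[["slew_ratio"]], 1, tolerance = 1e-6)
  expect_equal(fv[["width_ratio"]], 1, tolerance = 1e-6)
})

test_that("a wide generator PVC is morphologically far from the template", {
  toy <- toy_identical()
  fs <- 256
  # overwrite one beat with the wide PVC prototype
  sig <- toy$sig
  t0 <- attr(toy$proto, "t")
  idx <- round((10 + t0) * fs) + 1
  sig$samples[idx] <- toy$proto$pvc_wide
  fv <- extract_features(sig, cand_row(10, prematurity = 0.72,
                                       rr_next = 1.28), toy$tmpl)
  expect_gte(fv[["one_minus_cwa"]], 0.5)
  expect_gt(fv[["width_ratio"]], 1.5)
})

test_that("CWA scale-invariance: doubled amplitude changes amp_ratio only", {
  toy <- toy_identical()
  sig <- toy$sig
  fs <- 256
  t0 <- attr(toy$proto, "t")
  idx <- round((10 + t0) * fs) + 1
  sig$samples[idx] <- 2 * toy$proto$nsr
  fv <- extract_features(sig, cand_row(10, amp_ratio = 2), toy$tmpl)
  expect_lt(fv[["one_minus_cwa"]], 1e-6)
  expect_equal(fv[["amp_ratio"]], 2)
})

test_that("a window beyond the record bounds drops the candidate", {
  toy <- toy_identical()
  expect_null(extract_features(toy$sig, cand_row(0.01), toy$tmpl))
  bad_tmpl <- toy$tmpl; bad_tmpl$valid <- FALSE
  expect_error(extract_features(toy$sig, cand_row(10), bad_tmpl), "valid")
})

test_that("classification equals a hand-computed logistic evaluation", {
  fn <- c("one_minus_cwa", "one_minus_dcwa", "prematurity",
          "compensatory_ratio", "amp_ratio", "slew_ratio", "width_ratio")
  w <- c(2, 1.5, -1, 0.5, 0.25, 1, 0.75)
  model <- structure(list(seq_type = "single", feature_names = fn,
                          center = stats::setNames(rep(0, 7), fn),
                          scale = stats::setNames(rep(1, 7), fn),
                          weights = stats::setNames(w, fn),
                          intercept = -0.3, threshold = 0.5),
                     class = "pvc_model")
  fv <- stats::setNames(c(0.8, 0.7, 0.72, 1.28, 1.4, 1.8, 1.9), fn)
  attr(fv, "seq_type") <- "single"
  eta <- sum(w * fv) - 0.3
  res <- classify(fv, model)
  expect_equal(res$probability, stats::plogis(eta), tolerance = 1e-12)
  expect_equal(res$label, if (stats::plogis(eta) >= 0.5) "PVC" else "non-PVC")

  # all-zero standardised features with zero intercept: probability 1/2
  fv0 <- stats::setNames(rep(0, 7), fn); attr(fv0, "seq_type") <- "single"
  m0 <- model; m0$weights[] <- 1; m0$intercept <- 0
  expect_equal(classify(fv0, m0)$probability, 0.5)
  # saturation
  fvbig <- stats::setNames(rep(50, 7), fn); attr(fvbig, "seq_type") <- "single"
  expect_gt(classify(fvbig, m0)$probability, 1 - 1e-12)
  # sequence-type mismatch refused
  mm <- model; mm$seq_type <- "couplet"
  expect_error(classify(fv, mm), "mismatch")
})

test_that("training separates separable data and is seed-deterministic", {
  set.seed(77)
  n <- 200
  X <- matrix(stats::rnorm(n * 7), n, 7,
              dimnames = list(NULL, c("one_minus_cwa", "one_minus_dcwa",
                                      "prematurity", "compensatory_ratio",
                                      "amp_ratio", "slew_ratio",
                                      "width_ratio")))
  y <- X[, "one_minus_cwa"] + X[, "slew_ratio"] > 0
  X[y, "one_minus_cwa"] <- X[y, "one_minus_cwa"] + 4   # wide margin
  m1 <- train_model(X, y, "single", seed = 5)
  m2 <- train_model(X, y, "single", seed = 5)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$threshold, m2$threshold)

  pred <- vapply(seq_len(n), function(i) {
    fv <- X[i, ]; attr(fv, "seq_type") <- "single"
    classify(fv, m1)$label == "PVC"
  }, TRUE)
  expect_gte(mean(pred == y), 0.99)

  expect_error(train_model(X, rep(TRUE, n), "single"), "both")
  expect_error(train_model(X[1:20, ], y[1:20], "single"), "50")
})

test_that("shuffled labels give chance-level held-out performance", {
  set.seed(78)
  n <- 400
  X <- matrix(stats::rnorm(n * 7), n, 7,
              dimnames = list(NULL, c("one_minus_cwa", "one_minus_dcwa",
                                      "prematurity", "compensatory_ratio",
                                      "amp_ratio", "slew_ratio",
                                      "width_ratio")))
  y_true <- X[, 1] > 0
  y_shuf <- sample(y_true)
  m <- train_model(X, y_shuf, "single", seed = 9)
  # fresh evaluation set from the same null distribution
  Xe <- matrix(stats::rnorm(n * 7), n, 7, dimnames = dimnames(X))
  ye <- sample(y_true)
  pred <- vapply(seq_len(n), function(i) {
    fv <- Xe[i, ]; attr(fv, "seq_type") <- "single"
    classify(fv, m)$label == "PVC"
  }, TRUE)
  tp <- sum(pred & ye); fp <- sum(pred & !ye); fn <- sum(!pred & ye)
  f1 <- if (tp > 0) 2 * tp / (2 * tp + fp + fn) else 0
  prev_f1 <- 2 * mean(ye) / (1 + mean(ye))   # F1 of an always-PVC guesser
  expect_lte(f1, prev_f1 + 0.10)
})

test_that("models survive a JSON round-trip", {
  m <- fx_models()$single
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f)
  back <- read_model(f)
  expect_equal(back$weights, m$weights, tolerance = 1e-12)
  expect_equal(back$threshold, m$threshold)
  expect_identical(back$seq_type, m$seq_type)
})

test_that("the full pipeline labels a pure-NSR record PVC-free", {
  rec <- simulate_record(synth_config(duration = 300, target_burden_pct = 0,
                                      seed = 55))
  lab <- pipeline_labels(rec)
  expect_equal(sum(lab$label == "PVC"), 0)
})

test_that("detected PVC count tracks ground truth on a 10% record", {
  rec <- fx_rec10()
  lab <- detect_pvcs(rec$working, rec$beats, NULL, fx_cfg(), fx_models())
  n_true <- sum(rec$annotations$symbol == "V")
  n_det <- sum(lab$label == "PVC")
  expect_lte(abs(n_det - n_true) / n_true, 0.10)
})

test_that("couplet members are found and sequence sensitivity holds up", {
  cfg <- fx_cfg()
  rec <- simulate_record(synth_config(
    duration = 900, target_burden_pct = 12,
    seq_mix = c(single = 0.25, bigeminy = 0.15, couplet = 0.35,
                triplet = 0.25), seed = 56))
  lab <- pipeline_labels(rec)
  det <- lab$time[lab$label == "PVC"]
  tr <- rec$truth$beats
  seq_v <- tr$time[tr$symbol == "V" & tr$pattern %in% c("couplet", "triplet")]
  single_v <- tr$time[tr$symbol == "V" &
                        tr$pattern %in% c("single", "bigeminy")]
  hit <- function(times) mean(vapply(times, function(t)
    any(abs(det - t) <= 0.150), TRUE))
  expect_gt(hit(seq_v), 0)
  expect_true(any(lab$seq_type[lab$label == "PVC"] %in%
                    c("couplet", "triplet")))
  # sequence-beat sensitivity within 20% of single-beat sensitivity
  expect_gte(hit(seq_v), 0.8 * hit(single_v))
})
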