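steady_beats <- function(n = 20, rr = 1, amp = 500) {
  data.frame(time = seq_len(n) * rr, peak_amp = amp, source = "detected",
             in_noise = FALSE)
}

test_that("interval features are exact on constructed RR patterns", {
  b <- steady_beats()
  f <- interval_features(b, 10)
  expect_equal(f$prematurity, 1.0)
  expect_equal(f$amp_ratio, 1.0)
  expect_equal(f$rr_local_mean, 1.0)

  # a beat arriving 0.70 s after its predecessor against a 1.00 s local mean
  b2 <- steady_beats()
  b2$time[10:nrow(b2)] <- b2$time[10:nrow(b2)] - 0.30
  f2 <- interval_features(b2, 10, rr_pool = rep(1, 8))
  expect_equal(f2$rr_prev, 0.70)
  expect_equal(f2$prematurity, 0.70)

  expect_error(interval_features(b, 1), "boundary")
  expect_error(interval_features(b, nrow(b)), "boundary")
})

test_that("prematurity recovers the generator's coupling factor in bigeminy", {
  cfg <- fx_cfg()
  rec <- simulate_record(synth_config(
    duration = 240, target_burden_pct = 20, coupling_factor = 0.75,
    rr_cv = 0.02,
    seq_mix = c(single = 0, bigeminy = 1, couplet = 0, triplet = 0),
    seed = 41))
  sigw <- preprocess(rec$signal, cfg$band_lo, cfg$band_hi, cfg$working_fs)
  beats <- beats_from_annotations(rec$annotations, sigw)
  cand <- trigger_scan(beats, NULL, cfg)
  vt <- rec$annotations$time[rec$annotations$symbol == "V"]
  ect <- cand[vapply(cand$time, function(t) min(abs(vt - t)) < 0.05, TRUE), ]
  expect_gt(nrow(ect), 10)
  expect_true(all(abs(ect$prematurity - 0.75) <= 0.05))
})

test_that("steady NSR yields no candidates and low trigger burden", {
  b <- steady_beats(50)
  expect_equal(nrow(trigger_scan(b, NULL, fx_cfg())), 0)

  cfg <- fx_cfg()
  rec <- simulate_record(synth_config(duration = 600, target_burden_pct = 0,
                                      seed = 43))
  sigw <- preprocess(rec$signal, cfg$band_lo, cfg$band_hi, cfg$working_fs)
  beats <- detect_beats(sigw, cfg)
  cand <- trigger_scan(beats, NULL, cfg)
  expect_lte(nrow(cand) / nrow(beats), 0.02)
})

test_that("one premature wide beat becomes exactly one single candidate", {
  b <- steady_beats(15)
  # interpolate an early large beat between beats 7 and 8
  extra <- data.frame(time = 7.7, peak_amp = -800, source = "detected",
                      in_noise = FALSE)
  b <- rbind(b[1:7, ], extra, b[8:15, ])
  cand <- trigger_scan(b, NULL, fx_cfg())
  expect_equal(nrow(cand), 1)
  expect_equal(cand$seq_type, "single")
  expect_equal(cand$time, 7.7)
})

test_that("couplets and triplets are tagged with member indices", {
  b <- steady_beats(16)
  # two premature beats then a compensatory pause after beat 8
  coup <- data.frame(time = c(8.7, 9.15), peak_amp = -800,
                     source = "detected", in_noise = FALSE)
  b2 <- rbind(b[1:8, ], coup, b[10:16, ])
  cand <- trigger_scan(b2, NULL, fx_cfg())
  expect_equal(nrow(cand), 2)
  expect_true(all(cand$seq_type == "couplet"))
  expect_equal(cand$member_index, c(0L, 1L))

  # runs of four or more stay untagged and out of PVC candidacy
  run4 <- data.frame(time = c(8.6, 8.95, 9.3, 9.65), peak_amp = -800,
                     source = "detected", in_noise = FALSE)
  b3 <- rbind(b[1:8, ], run4, b[11:16, ])
  cand3 <- trigger_scan(b3, NULL, fx_cfg())
  expect_true(all(cand3$seq_type == "run"))
  expect_equal(nrow(cand3), 4)
})

test_that("amplitude-only path catches non-premature ectopy", {
  b <- steady_beats(15)
  b$peak_amp[8] <- 1500   # on time but 3x the neighbours
  cand <- trigger_scan(b, NULL, fx_cfg())
  expect_equal(nrow(cand), 1)
  expect_equal(cand$beat_index, 8)
  expect_gt(cand$amp_ratio, 2.2)
})

test_that("trigger sensitivity on synthetic ectopy is at least 98%", {
  cfg <- fx_cfg()
  rec <- fx_rec10()
  beats <- beats_from_annotations(rec$annotations, rec$working)
  cand <- trigger_scan(beats, NULL, cfg)
  vt <- rec$annotations$time[rec$annotations$symbol == "V"]
  hit <- vapply(vt, function(t) any(abs(cand$time - t) < 0.05), TRUE)
  expect_gte(mean(hit), 0.98)
})
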