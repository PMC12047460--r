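test_that("configuration invariants are enforced", {
  expect_error(synth_config(target_burden_pct = 60), "\\[0, 50\\]")
  expect_error(synth_config(seq_mix = c(single = 0.5, bigeminy = 0.5,
                                        couplet = 0.5, triplet = 0.5)),
               "sum to 1")
  expect_error(simulate_record(synth_config(
    target_burden_pct = 50,
    seq_mix = c(single = 1, bigeminy = 0, couplet = 0, triplet = 0))),
    "infeasible")
})

test_that("a zero-burden record contains no V annotations", {
  rec <- simulate_record(synth_config(duration = 120, target_burden_pct = 0,
                                      seed = 61))
  expect_equal(sum(rec$annotations$symbol == "V"), 0)
  expect_equal(rec$truth$realized_burden_pct, 0)
})

test_that("the generator is deterministic under its seed", {
  cfg <- synth_config(duration = 600, heart_rate = 60,
                      target_burden_pct = 10, pac_rate_per_min = 2,
                      seed = 7)
  r1 <- simulate_record(cfg)
  r2 <- simulate_record(cfg)
  expect_identical(r1$signal$samples, r2$signal$samples)
  expect_identical(r1$annotations, r2$annotations)
  expect_identical(r1$truth, r2$truth)
})

test_that("realised burden lands within 1 ppt of target on an hour record", {
  for (tb in c(5, 10)) {
    rec <- simulate_record(synth_config(duration = 3600,
                                        target_burden_pct = tb,
                                        seed = 70 + tb))
    expect_lt(abs(rec$truth$realized_burden_pct - tb), 1.0)
  }
})

test_that("realised burden equals an independent annotation recount", {
  rec <- fx_rec10()
  expect_equal(realized_burden(rec$annotations),
               100 * sum(rec$annotations$symbol == "V") /
                 nrow(rec$annotations))
  expect_equal(realized_burden(rec$annotations),
               rec$truth$realized_burden_pct)
  expect_error(realized_burden(data.frame(time = 1, symbol = "+")),
               "no beat")
})

test_that("annotations carry exactly the inserted beats", {
  rec <- fx_rec10()
  expect_equal(nrow(rec$annotations), nrow(rec$truth$beats))
  expect_true(all(diff(rec$annotations$time) > 0))
  expect_true(all(rec$annotations$symbol %in% c("N", "S", "V")))
  # every ectopic pattern annotated V; PACs annotated S
  expect_true(all(rec$truth$beats$symbol[
    rec$truth$beats$pattern %in% c("single", "bigeminy", "couplet",
                                   "triplet")] == "V"))
})

test_that("prototype morphology separation is as constructed", {
  cfg <- fx_cfg()
  p <- synth_prototypes(256, 500)
  t <- attr(p, "t"); i0 <- which.min(abs(t))
  half <- (template_length(cfg, 256) - 1) / 2
  win <- function(v) v[(i0 - half):(i0 + half)]
  expect_gte(cwa(win(p$pvc_narrow), win(p$nsr)), 0.9)
  expect_lte(cwa(win(p$pvc_wide), win(p$nsr)), 0.6)
  # every prototype peaks at its fiducial
  for (v in p) expect_equal(which.max(abs(v)), i0)
})

test_that("cohorts are reproducible and respect the burden distribution", {
  c1 <- simulate_cohort(4, c(0, 0, 0, 0), seed = 3, duration = 60)
  expect_true(all(vapply(c1, function(r)
    sum(r$annotations$symbol == "V") == 0, TRUE)))

  c2 <- simulate_cohort(3, c(5, 10, 15), seed = 4, duration = 120)
  c3 <- simulate_cohort(3, c(5, 10, 15), seed = 4, duration = 120)
  expect_identical(lapply(c2, `[[`, "annotations"),
                   lapply(c3, `[[`, "annotations"))
  # patients differ from one another
  expect_false(identical(c2[[1]]$annotations, c2[[2]]$annotations))

  # truth-vs-truth threshold classification is perfect by construction
  tb <- c(2, 8, 12, 20)
  c4 <- simulate_cohort(4, tb, seed = 5, duration = 300)
  true_b <- vapply(c4, `[[`, 0, "true_burden")
  tm <- threshold_metrics(true_b, true_b, 10)
  expect_equal(tm$sensitivity, 1)
  expect_equal(tm$specificity, 1)
})
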