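#!/usr/bin/env Rscript
# Train the default per-sequence-type PVC classifiers on the synthetic
# corpus and write them to inst/extdata/models/.  Run from the repository
# root against the installed package:
#
#   Rscript scripts/train_default_models.R
#
# The corpus spans both PVC morphologies (wide and narrow-projection),
# heart rates 55-85 bpm, burdens 0-20%, R amplitudes 300-800 uV, and
# atrial ectopy with and without aberrant conduction (the hard negatives).
# Everything is seeded, so the committed models are exactly reproducible.

library(ectopy)

TRAIN_SEED <- 17

corpus <- list(
  list(target_burden_pct = 10, heart_rate = 70, seed = 101),
  list(target_burden_pct = 20, heart_rate = 55, r_amp_uv = 800, seed = 102),
  list(target_burden_pct = 5,  heart_rate = 85, r_amp_uv = 300, seed = 103),
  list(target_burden_pct = 10, pvc_morph = "narrow_projection", seed = 104),
  list(target_burden_pct = 15, heart_rate = 60,
       pvc_morph = "narrow_projection", seed = 105),
  list(target_burden_pct = 10, pac_rate_per_min = 3, seed = 106),
  list(target_burden_pct = 10, pac_rate_per_min = 3, pac_aberrant = TRUE,
       seed = 107),
  list(target_burden_pct = 8, pvc_morph = "narrow_projection",
       pac_rate_per_min = 2, pac_aberrant = TRUE, seed = 108),
  # sequence-rich records so the couplet/triplet models see enough beats
  list(target_burden_pct = 15,
       seq_mix = c(single = 0.2, bigeminy = 0.1, couplet = 0.4,
                   triplet = 0.3), seed = 109),
  list(target_burden_pct = 12, pvc_morph = "narrow_projection",
       seq_mix = c(single = 0.2, bigeminy = 0.1, couplet = 0.4,
                   triplet = 0.3), seed = 110),
  list(target_burden_pct = 15, pac_rate_per_min = 4, pac_aberrant = TRUE,
       seq_mix = c(single = 0.2, bigeminy = 0.1, couplet = 0.4,
                   triplet = 0.3), seed = 111),
  # ectopy-free records with atrial runs: pure negatives
  list(target_burden_pct = 0, pac_rate_per_min = 5, pac_aberrant = TRUE,
       seed = 112),
  list(target_burden_pct = 0, pac_rate_per_min = 5, seed = 113)
)

cfg <- detector_config()
rows <- lapply(corpus, function(args) {
  args$duration <- 600
  rec <- simulate_record(do.call(synth_config, args))
  sigw <- preprocess(rec$signal, cfg$band_lo, cfg$band_hi, cfg$working_fs)
  training_features(sigw, rec$annotations, cfg)
})
feats <- do.call(rbind, rows)
cat("harvested", nrow(feats), "candidate rows\n")
print(table(feats$seq_type, feats$is_pvc))

dir.create("inst/extdata/models", recursive = TRUE, showWarnings = FALSE)
for (st in c("single", "couplet", "triplet")) {
  d <- feats[feats$seq_type == st, , drop = FALSE]
  m <- train_model(d[, seq_len(7)], d$is_pvc, seq_type = st,
                   seed = TRAIN_SEED)
  write_model(m, file.path("inst/extdata/models", paste0(st, ".json")))
  print(m)
}
cat("models written to inst/extdata/models/\n")
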