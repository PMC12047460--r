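# Shared fixtures, built once per test run and cached.  Everything is
# generated in code from fixed seeds; no stored data.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (!exists(name, envir = .fix, inherits = FALSE))
    assign(name, fn(), envir = .fix)
  get(name, envir = .fix, inherits = FALSE)
}

fx_cfg <- function() fixture("cfg", function() detector_config())

fx_models <- function() fixture("models", function() default_models())

# 600 s, 10% wide-morphology record plus its processed derivatives
fx_rec10 <- function() fixture("rec10", function() {
  cfg <- fx_cfg()
  rec <- simulate_record(synth_config(duration = 600, target_burden_pct = 10,
                                      seed = 9001))
  rec$working <- preprocess(rec$signal, cfg$band_lo, cfg$band_hi,
                            cfg$working_fs)
  rec$beats <- detect_beats(rec$working, cfg)
  rec
})

# run the complete pipeline over a simulated record
pipeline_labels <- function(rec, cfg = fx_cfg(), models = fx_models(),
                            use_noise = FALSE) {
  nz <- if (use_noise) mark_noise(rec$signal, cfg) else NULL
  sigw <- preprocess(rec$signal, cfg$band_lo, cfg$band_hi, cfg$working_fs)
  beats <- detect_beats(sigw, cfg, noise = nz)
  detect_pvcs(sigw, beats, nz, cfg, models)
}

# score PVC labels against a record's reference annotations
score_labels <- function(labels, annotations, tolerance = 0.150) {
  det <- labels$time[labels$label == "PVC"]
  refv <- annotations$time[annotations$symbol == "V"]
  m <- match_events(det, refv, tolerance)
  beat_metrics(m, n_detected_beats = nrow(labels))
}

# a miniature WFDB database written by the package's own generator, so the
# benchmark protocol is exercised end-to-end without external data
mini_db <- function() {
  fixture("mini_db", function() {
    d <- file.path(tempdir(), "ectopy-mini-db")
    dir.create(d, showWarnings = FALSE)
    ids <- c("s01", "s02", "s03")
    tb <- c(4, 10, 18)
    for (k in 1:3) {
      rec <- simulate_record(synth_config(duration = 300,
                                          target_burden_pct = tb[k],
                                          seed = 800 + k))
      write_record(rec$signal, file.path(d, ids[k]))
      write_wfdb_annotations(rec$annotations,
                             file.path(d, paste0(ids[k], ".atr")),
                             fs = rec$signal$fs)
    }
    list(path = d, ids = ids,
         manifest = list(ds1 = character(0), ds2 = ids, lead = "SYN",
                         excluded_symbols = "F"))
  })
}

# exhaustive maximum one-to-one matching (oracle for match_events)
brute_force_matches <- function(det, ref, tol) {
  n <- length(det); m <- length(ref)
  if (n == 0 || m == 0) return(0L)
  best <- 0L
  rec <- function(i, used, cur) {
    if (cur + (n - i + 1L) <= best) return()   # bound
    if (i > n) { best <<- max(best, cur); return() }
    for (j in which(!used)) if (abs(det[i] - ref[j]) <= tol) {
      used[j] <- TRUE
      rec(i + 1L, used, cur + 1L)
      used[j] <- FALSE
    }
    rec(i + 1L, used, cur)
  }
  rec(1L, rep(FALSE, m), 0L)
  best
}
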