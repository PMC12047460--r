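#' Canonical inter-patient train/test division of the MIT-BIH records
#'
#' The 44 non-paced records split into the standard DS1 (training) and DS2
#' (testing) sets of 22 patients each, with the lead selector and the
#' scoring exclusion rules (fusion beats ambiguous; non-beat symbols
#' ignored).  The benchmark harness never downloads data; it validates a
#' user-supplied local copy of the database.
#'
#' @param lead Lead selector, default `"MLII"` (single-vector evaluation).
#' @return List: `ds1`, `ds2` (record-id character vectors), `lead`,
#'   `excluded_symbols`.
#' @export
mitbih_manifest <- function(lead = "MLII") {
  list(ds1 = c("101", "106", "108", "109", "112", "114", "115", "116",
               "118", "119", "122", "124", "201", "203", "205", "207",
               "208", "209", "215", "220", "223", "230"),
       ds2 = c("100", "103", "105", "111", "113", "117", "121", "123",
               "200", "202", "210", "212", "213", "214", "219", "221",
               "222", "228", "231", "232", "233", "234"),
       lead = lead,
       excluded_symbols = "F")
}

aami_class <- function(symbol) {
  cls <- rep("Q", length(symbol))
  cls[symbol %in% c("N", "L", "R", "e", "j", "B")] <- "N"
  cls[symbol %in% c("A", "a", "J", "S", "n", "x")] <- "S"
  cls[symbol %in% c("V", "E", "r", "!")] <- "V"
  cls[symbol == "F"] <- "F"
  cls
}

#' Summarise an annotated dataset
#'
#' Beat counts, V counts, the fraction of V beats occurring in sequences
#' (runs of 2 or more consecutive V annotations), and the mean per-record
#' burden.
#'
#' @param db_path Directory containing the WFDB records.
#' @param records Character vector of record ids.
#' @return List with `per_record` data frame and totals.
#' @export
dataset_summary <- function(db_path, records) {
  per <- lapply(records, function(id) {
    fs <- parse_wfdb_header(file.path(db_path, paste0(id, ".hea")))$fs
    ann <- read_wfdb_annotations(file.path(db_path, paste0(id, ".atr")), fs)
    ann <- ann[ann$symbol %in% .beat_symbols, , drop = FALSE]
    cls <- aami_class(ann$symbol)
    isv <- cls == "V"
    runs <- rle(isv)
    v_seq <- sum(runs$lengths[runs$values & runs$lengths >= 2])
    data.frame(record = id, n_beats = nrow(ann), n_v = sum(isv),
               n_v_in_seq = v_seq,
               burden_pct = 100 * mean(isv), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(per_record = per,
       n_beats = sum(per$n_beats), n_v = sum(per$n_v),
       v_in_sequence_frac = if (sum(per$n_v) > 0)
         sum(per$n_v_in_seq) / sum(per$n_v) else NA_real_,
       mean_burden_pct = mean(per$burden_pct))
}

#' Run the beat-classification benchmark on a local WFDB database
#'
#' Reproduces the single-lead, sensing-bypass evaluation protocol: for
#' each test record the provided annotation markers serve as beat-detection
#' locations, the two-stage detector classifies every beat, and detections
#' are scored against the V annotations with a +-150 ms tolerance, fusion
#' (F) beats excluded as ambiguous.  All scoring goes through the shared
#' evaluation functions; there is no benchmark-specific metric code.
#'
#' @param db_path Directory with the WFDB records.
#' @param manifest A [mitbih_manifest] (or compatible list); `ds2` records
#'   are evaluated.
#' @param models Per-sequence-type classifiers ([default_models]).
#' @param cfg A [detector_config].
#' @param oracle If `TRUE`, replace the classifier with the annotations
#'   themselves (labels = reference), giving the protocol's upper bound --
#'   useful for validating the harness.
#' @return List: `per_record` data frame (TP/FP/FN, sensitivity, PPV, F1,
#'   estimated and reference burden), `gross` metric set, `burden_fit`
#'   (`r2`, `rmse_pct`), and `summary` from [dataset_summary].
#' @export
run_benchmark <- function(db_path, manifest = mitbih_manifest(),
                          models = default_models(),
                          cfg = detector_config(), oracle = FALSE) {
  recs <- manifest$ds2
  missing <- recs[!file.exists(file.path(db_path, paste0(recs, ".hea")))]
  if (length(missing))
    stop("missing records under ", db_path, ": ",
         paste(missing, collapse = ", "), " -- partial runs are refused")

  per <- vector("list", length(recs))
  tot <- c(tp = 0, fp = 0, fn = 0, nbeat = 0)
  for (k in seq_along(recs)) {
    id <- recs[k]
    rec <- read_record(file.path(db_path, id), lead_selector = manifest$lead)
    sigw <- preprocess(rec$signal, cfg$band_lo, cfg$band_hi, cfg$working_fs)
    beats <- beats_from_annotations(rec$annotations, sigw)
    cls <- aami_class(rec$annotations$symbol[
      rec$annotations$symbol %in% .beat_symbols])
    ref_v <- beats$time[cls == "V"]
    excl <- beats$time[cls %in% aami_class(manifest$excluded_symbols)]
    det <- if (oracle) ref_v else {
      lab <- detect_pvcs(sigw, beats, noise = NULL, cfg = cfg,
                         models = models)
      lab$time[lab$label == "PVC"]
    }
    mr <- match_events(det, ref_v, tolerance = 0.150, excluded_times = excl)
    ms <- beat_metrics(mr, n_detected_beats = nrow(beats))
    per[[k]] <- data.frame(record = id, n_beats = nrow(beats),
                           n_ref_v = length(ref_v), tp = ms$tp, fp = ms$fp,
                           fn = ms$fn, sensitivity = ms$sensitivity,
                           ppv = ms$ppv, f1 = ms$f1,
                           est_burden_pct = 100 * length(det) / nrow(beats),
                           ref_burden_pct = 100 * length(ref_v) / nrow(beats),
                           stringsAsFactors = FALSE)
    tot <- tot + c(ms$tp, ms$fp, ms$fn, nrow(beats))
  }
  per <- do.call(rbind, per)
  gross <- beat_metrics(list(tp = unname(tot["tp"]), fp = unname(tot["fp"]),
                             fn = unname(tot["fn"])),
                        n_detected_beats = unname(tot["nbeat"]))
  fit <- stats::lm(est_burden_pct ~ ref_burden_pct, data = per)
  burden_fit <- list(
    r2 = suppressWarnings(summary(fit)$r.squared),  # exact fits warn
    rmse_pct = sqrt(mean((per$est_burden_pct - per$ref_burden_pct)^2)))
  list(per_record = per, gross = gross, burden_fit = burden_fit,
       summary = dataset_summary(db_path, recs))
}
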