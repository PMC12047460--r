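#' Interval and amplitude features for one beat
#'
#' Computes the trigger-stage quantities for beat `i`: the flanking RR
#' intervals, the local mean RR (trailing non-ectopic RR history), the
#' prematurity ratio `rr_prev / rr_local_mean`, and the peak-amplitude ratio
#' of the beat to the mean of its two neighbours.
#'
#' @param beats Beat data frame ([detect_beats]), time-sorted.
#' @param i Beat index (1-based); must be interior (`2 <= i <= n - 1`),
#'   boundary beats are not evaluable.
#' @param rr_pool Optional numeric vector of trailing non-candidate RR
#'   intervals defining the local mean; defaults to the (up to) 8 RR
#'   intervals preceding beat `i`.
#' @return Named list: `rr_prev`, `rr_next`, `rr_local_mean`, `prematurity`,
#'   `amp_ratio`.
#' @export
interval_features <- function(beats, i, rr_pool = NULL) {
  n <- nrow(beats)
  if (i < 2 || i > n - 1)
    stop("beat ", i, " is a boundary beat and not evaluable")
  tt <- beats$time
  rr_prev <- tt[i] - tt[i - 1]
  rr_next <- tt[i + 1] - tt[i]
  if (is.null(rr_pool) || !length(rr_pool)) {
    lo <- max(2L, i - 8L)
    rr_pool <- diff(tt[(lo - 1L):(i - 1L)])
  }
  rr_local_mean <- mean(rr_pool)
  nb <- mean(abs(beats$peak_amp[c(i - 1, i + 1)]))
  amp_ratio <- if (nb > 0) abs(beats$peak_amp[i]) / nb else 1
  list(rr_prev = rr_prev, rr_next = rr_next, rr_local_mean = rr_local_mean,
       prematurity = rr_prev / rr_local_mean, amp_ratio = amp_ratio)
}

#' Trigger stage: nominate PVC candidates from every detected beat
#'
#' Cheap screening applied to every beat.  A beat becomes a candidate when
#' it is premature (`prematurity <= cfg$premature_factor`) *or* its
#' amplitude ratio falls outside `[cfg$amp_lo, cfg$amp_hi]` -- the amplitude
#' path exists because ventricular ectopy is not strictly required to be
#' premature.  Runs of consecutive candidates are tagged `single`, `couplet`
#' or `triplet`; runs of four or more are emitted untagged (`seq_type =
#' "run"`) and excluded from PVC candidacy, being the province of separate
#' tachyarrhythmia detectors.  Candidates whose defining RR intervals
#' overlap a noise interval are dropped.
#'
#' The local mean RR is the mean of the trailing `cfg$rr_history`
#' non-candidate RR intervals, so ectopic intervals do not contaminate the
#' prematurity reference.
#'
#' @param beats Beat data frame, time-sorted.
#' @param noise Data frame of noise intervals (`start`, `end`), possibly
#'   empty.
#' @param cfg A [detector_config].
#' @return Data frame of candidates: `beat_index`, `time`, `seq_type`
#'   (`single`/`couplet`/`triplet`/`run`), `member_index` (0-based),
#'   `rr_prev`, `rr_next`, `rr_local_mean`, `prematurity`, `amp_ratio`.
#' @export
trigger_scan <- function(beats, noise = NULL, cfg = detector_config()) {
  empty <- data.frame(beat_index = integer(0), time = numeric(0),
                      seq_type = character(0), member_index = integer(0),
                      rr_prev = numeric(0), rr_next = numeric(0),
                      rr_local_mean = numeric(0), prematurity = numeric(0),
                      amp_ratio = numeric(0), stringsAsFactors = FALSE)
  n <- nrow(beats)
  if (n < 3) return(empty)
  if (is.null(noise)) noise <- data.frame(start = numeric(0), end = numeric(0))
  tt <- beats$time
  rr_all <- diff(tt)
  rr_pool <- rr_all[seq_len(min(2, length(rr_all)))]  # seed the history
  is_cand <- rep(FALSE, n)
  feat <- vector("list", n)
  last_noncand <- 1L

  for (i in 2:(n - 1)) {
    f <- interval_features(beats, i, rr_pool = rr_pool)
    amp_out <- f$amp_ratio < cfg$amp_lo || f$amp_ratio > cfg$amp_hi
    cand <- f$prematurity <= cfg$premature_factor || amp_out
    # conducted-beat exemption: a premature-looking beat right after a
    # candidate that falls back on the sinus grid (span since the last
    # non-candidate beat is a whole number of local RR) and resumes a
    # normal cycle is the conducted beat after an interpolated ectopic
    if (cand && !amp_out && is_cand[i - 1] && last_noncand >= 1L) {
      span <- tt[i] - tt[last_noncand]
      kk <- round(span / f$rr_local_mean)
      on_grid <- kk >= 1 &&
        abs(span / (kk * f$rr_local_mean) - 1) <= cfg$grid_tol
      if (on_grid && abs(f$rr_next / f$rr_local_mean - 1) <= cfg$grid_tol)
        cand <- FALSE
    }
    is_cand[i] <- cand
    feat[[i]] <- f
    if (!cand) last_noncand <- i
    # only RR intervals between two non-candidate beats enter the history
    if (!cand && !is_cand[i - 1]) {
      rr_pool <- c(rr_pool, f$rr_prev)
      if (length(rr_pool) > cfg$rr_history)
        rr_pool <- rr_pool[-1]
    }
  }

  idx <- which(is_cand)
  if (!length(idx)) return(empty)

  # group adjacent candidate beats into runs
  grp <- cumsum(c(1, diff(idx) != 1))
  rows <- lapply(split(idx, grp), function(run) {
    len <- length(run)
    st <- if (len == 1) "single" else if (len == 2) "couplet"
          else if (len == 3) "triplet" else "run"
    data.frame(beat_index = run, time = tt[run], seq_type = st,
               member_index = seq_along(run) - 1L,
               rr_prev = vapply(feat[run], `[[`, 0, "rr_prev"),
               rr_next = vapply(feat[run], `[[`, 0, "rr_next"),
               rr_local_mean = vapply(feat[run], `[[`, 0, "rr_local_mean"),
               prematurity = vapply(feat[run], `[[`, 0, "prematurity"),
               amp_ratio = vapply(feat[run], `[[`, 0, "amp_ratio"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL

  if (nrow(noise)) {
    a <- out$time - out$rr_prev
    b <- out$time + out$rr_next
    out <- out[!span_overlaps(a, b, noise), , drop = FALSE]
  }
  out
}
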