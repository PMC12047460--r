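#' R-wave beat detection
#'
#' Classical energy detector: the signal is band-limited to the QRS band
#' (10--30 Hz), squared and smoothed with a 120 ms moving average; envelope
#' peaks are accepted against an adaptive threshold (running signal-peak and
#' noise-peak estimates) with a refractory period and a search-back pass for
#' long gaps.  The fiducial is refined to the local extremum of the
#' preconditioned signal near each envelope peak.
#'
#' Beat sensing is deliberately decoupled from PVC classification: the
#' morphology stages accept externally supplied markers through
#' [beats_from_annotations] just as readily.
#'
#' @param signal An [ecg_signal], ideally already through [preprocess].
#' @param cfg A [detector_config].
#' @param noise Optional data frame of noise intervals (`start`, `end`);
#'   beats whose fiducial falls inside one are flagged, not dropped.
#' @return Data frame of beats: `time` (s), `peak_amp` (uV, signed),
#'   `source` (`"detected"`), `in_noise` (logical).  Empty for an all-flat
#'   signal.
#' @export
detect_beats <- function(signal, cfg = detector_config(), noise = NULL) {
  x <- signal$samples
  fs <- signal$fs
  empty <- data.frame(time = numeric(0), peak_amp = numeric(0),
                      source = character(0), in_noise = logical(0))
  if (length(x) < fs || max(abs(x)) < 1) return(empty)

  ny <- fs / 2
  # 4-22 Hz: low enough to keep the energy of wide (slow) ectopic QRS,
  # high enough to reject T waves and baseline wander
  bq <- signal::butter(2, c(4, min(22, 0.9 * ny)) / ny, type = "pass")
  e <- signal::filtfilt(bq, x)^2
  w <- max(3L, round(0.120 * fs))
  e <- as.numeric(stats::filter(e, rep(1 / w, w), sides = 2))
  e[is.na(e)] <- 0

  n <- length(e)
  is_peak <- c(FALSE, e[2:(n - 1)] > e[1:(n - 2)] & e[2:(n - 1)] >= e[3:n],
               FALSE)
  pk <- which(is_peak & e > 1e-9)
  if (!length(pk)) return(empty)

  refr <- cfg$refractory * fs
  spk <- stats::quantile(e[pk], 0.95)  # seed estimates from the envelope
  npk <- stats::quantile(e[pk], 0.25)
  thr <- function() npk + 0.25 * (spk - npk)

  qrs <- integer(0)
  rr_recent <- numeric(0)
  last <- -Inf
  for (i in pk) {
    if (i - last < refr) next
    if (e[i] >= thr()) {
      # search-back: a long gap with a sub-threshold peak in between
      if (length(qrs) >= 2 && length(rr_recent) >= 2) {
        rr_mean <- mean(rr_recent)
        if (i - last > 1.66 * rr_mean) {
          cand <- pk[pk > last + refr & pk < i - refr]
          cand <- cand[e[cand] >= 0.5 * thr()]
          if (length(cand)) {
            j <- cand[which.max(e[cand])]
            rr_recent <- c(rr_recent, j - last)[-1]
            qrs <- c(qrs, j)
            last <- j
            if (i - last < refr) next
          }
        }
      }
      if (length(qrs)) rr_recent <- utils::tail(c(rr_recent, i - last), 8)
      qrs <- c(qrs, i)
      last <- i
      spk <- 0.125 * e[i] + 0.875 * spk
    } else {
      npk <- 0.125 * e[i] + 0.875 * npk
    }
  }
  if (!length(qrs)) return(empty)

  # refine fiducial to the signal extremum within +-60 ms
  half <- as.integer(round(0.060 * fs))
  fid <- vapply(qrs, function(i) {
    a <- max(1L, as.integer(i) - half); b <- min(length(x), as.integer(i) + half)
    a + which.max(abs(x[a:b])) - 1L
  }, integer(1))
  fid <- sort(unique(fid))
  # refinement can collapse neighbours; re-enforce refractory
  keep <- c(TRUE, diff(fid) >= refr)
  fid <- fid[keep]

  times <- signal$t0 + (fid - 1) / fs
  beats <- data.frame(time = times, peak_amp = x[fid], source = "detected",
                      in_noise = FALSE, stringsAsFactors = FALSE)
  if (!is.null(noise) && nrow(noise))
    beats$in_noise <- in_any_interval(beats$time, noise)
  beats
}

#' Build beat events from reference annotations (sensing bypass)
#'
#' Reproduces the evaluation mode in which beat sensing is bypassed and the
#' database's adjudicated markers are used as beat-detection locations.
#' Annotation times are carried over bit-exactly; only beat-class symbols
#' are kept.
#'
#' @param annotations Data frame `time`, `symbol`.
#' @param signal An [ecg_signal] used to measure each beat's peak amplitude
#'   (+-50 ms window).
#' @return Data frame of beats as in [detect_beats] with
#'   `source = "external"`.
#' @export
beats_from_annotations <- function(annotations, signal) {
  ann <- annotations[annotations$symbol %in% .beat_symbols, , drop = FALSE]
  if (!nrow(ann))
    return(data.frame(time = numeric(0), peak_amp = numeric(0),
                      source = character(0), in_noise = logical(0)))
  half <- round(0.050 * signal$fs)
  n <- length(signal$samples)
  amp <- vapply(ann$time, function(t) {
    i <- time_to_index(signal, t)
    seg <- signal$samples[max(1, i - half):min(n, i + half)]
    seg[which.max(abs(seg))]
  }, 0)
  data.frame(time = ann$time, peak_amp = amp, source = "external",
             in_noise = FALSE, stringsAsFactors = FALSE)
}

#' Mark noise intervals
#'
#' Slides a window (default 1 s, half-window hop) over the signal and marks
#' it noisy when either (a) the fraction of power above the high-frequency
#' corner (default 45 Hz) exceeds `noise_hf_frac`, indicating broadband
#' myopotential artifact, or (b) the signal dwells at the ADC rail for more
#' than `rail_ms`.  Abutting or nearby windows are merged.
#'
#' Apply this to the *raw* signal, before [preprocess]: band-limiting the
#' working signal removes exactly the high-frequency content this rule
#' looks for.
#'
#' @param signal An [ecg_signal].
#' @param cfg A [detector_config].
#' @return Data frame of merged intervals `start`, `end` (seconds); zero
#'   rows for a clean record.
#' @export
mark_noise <- function(signal, cfg = detector_config()) {
  x <- signal$samples
  fs <- signal$fs
  ny <- fs / 2
  hf_lo <- min(cfg$noise_hf_lo, 0.85 * ny)
  bh <- signal::butter(2, hf_lo / ny, type = "high")
  hf <- signal::filtfilt(bh, x)

  win <- max(8L, round(cfg$noise_win * fs))
  hop <- max(1L, win %/% 2)
  starts <- seq(1L, max(1L, length(x) - win + 1L), by = hop)
  tot_floor <- 1  # uV^2, guards the ratio on silent segments
  rail_n <- round(cfg$rail_ms / 1000 * fs)

  noisy <- vapply(starts, function(a) {
    b <- a + win - 1L
    seg <- x[a:b]; segh <- hf[a:b]
    frac <- sum(segh^2) / max(sum(seg^2), tot_floor)
    railed <- seg >= cfg$rail_uv | seg <= -cfg$rail_uv
    dwell <- if (any(railed)) max(rle(railed)$lengths[rle(railed)$values]) else 0
    frac > cfg$noise_hf_frac || dwell > rail_n
  }, TRUE)

  if (!any(noisy))
    return(data.frame(start = numeric(0), end = numeric(0)))
  iv <- data.frame(start = signal$t0 + (starts[noisy] - 1) / fs,
                   end = signal$t0 + (starts[noisy] - 1 + win) / fs)
  merge_intervals(iv, gap = cfg$noise_merge_gap)
}

#' Merge overlapping or nearby intervals
#'
#' @param intervals Data frame `start`, `end`.
#' @param gap Intervals separated by less than this many seconds are merged.
#' @return Data frame of non-overlapping intervals sorted by start.
#' @export
merge_intervals <- function(intervals, gap = 0) {
  if (!nrow(intervals)) return(intervals)
  iv <- intervals[order(intervals$start), , drop = FALSE]
  out_s <- iv$start[1]; out_e <- iv$end[1]
  res_s <- numeric(0); res_e <- numeric(0)
  for (k in seq_len(nrow(iv))[-1]) {
    if (iv$start[k] <= out_e + gap) {
      out_e <- max(out_e, iv$end[k])
    } else {
      res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
      out_s <- iv$start[k]; out_e <- iv$end[k]
    }
  }
  data.frame(start = c(res_s, out_s), end = c(res_e, out_e))
}

in_any_interval <- function(times, intervals) {
  if (!nrow(intervals)) return(rep(FALSE, length(times)))
  vapply(times, function(t)
    any(t >= intervals$start & t <= intervals$end), TRUE)
}

# TRUE where the span [a, b] overlaps any interval
span_overlaps <- function(a, b, intervals) {
  if (!nrow(intervals)) return(rep(FALSE, length(a)))
  mapply(function(s, e)
    any(pmax(s, intervals$start) <= pmin(e, intervals$end)), a, b)
}
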