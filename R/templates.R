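#' Extract a fiducial-centred beat window
#'
#' @param signal An [ecg_signal].
#' @param t Fiducial time (s).
#' @param len Window length in samples (odd; from [template_length]).
#' @return Numeric vector of `len` samples, or `NULL` if the window exceeds
#'   the record bounds.
#' @export
beat_window <- function(signal, t, len) {
  half <- (len - 1L) %/% 2L
  i <- time_to_index(signal, t)
  a <- i - half; b <- i + half
  if (a < 1 || b > length(signal$samples)) return(NULL)
  signal$samples[a:b]
}

#' Template window length in samples
#'
#' The QRS analysis window is 200 ms by default (`cfg$window_ms`), long
#' enough to cover a wide ectopic QRS without reaching the T wave, forced
#' odd so it centres exactly on the fiducial.
#'
#' @param cfg A [detector_config].
#' @param fs Sampling rate (Hz); defaults to the configured working rate.
#' @return Odd integer window length.
#' @export
template_length <- function(cfg = detector_config(), fs = cfg$working_fs) {
  len <- round(cfg$window_ms / 1000 * fs)
  if (len %% 2 == 0) len <- len + 1L
  as.integer(len)
}

#' Form the average-NSR QRS template
#'
#' Template formation is *attempted*: the most recent `template_k` beats
#' before `at_time` whose surrounding RR intervals lie within
#' `template_rr_tol` of the local median RR and whose correlation to the
#' running average is at least `template_min_corr` are averaged sample-wise.
#' If fewer than `template_nmin` beats qualify the template is returned with
#' `valid = FALSE` -- a legal state during which candidates are not
#' classified.  RR gating excludes premature (ectopic) beats and the beats
#' around them, so bigeminy does not contaminate the template.
#'
#' @param signal An [ecg_signal].
#' @param beats Beat data frame ([detect_beats]).
#' @param at_time Formation time (s); only beats strictly before it are
#'   used.
#' @param cfg A [detector_config].
#' @return An `nsr_template`: list with `window` (uV vector), `formed_at`,
#'   `n_beats_used`, `valid`, `fs`.
#' @export
form_template <- function(signal, beats, at_time, cfg = detector_config()) {
  len <- template_length(cfg, signal$fs)
  tmpl <- structure(list(window = rep(0, len), formed_at = at_time,
                         n_beats_used = 0L, valid = FALSE, fs = signal$fs),
                    class = "nsr_template")
  idx <- which(beats$time < at_time & !beats$in_noise)
  if (length(idx) < 3) return(tmpl)
  idx <- utils::tail(idx, 4L * cfg$template_k)
  tt <- beats$time[idx]
  rr <- diff(tt)
  med <- stats::median(rr)
  # interior beats whose flanking RRs are both near the local median
  ok <- which(abs(rr[-length(rr)] - med) <= cfg$template_rr_tol * med &
              abs(rr[-1] - med) <= cfg$template_rr_tol * med) + 1L
  if (!length(ok)) return(tmpl)

  acc <- NULL; n_used <- 0L
  for (j in rev(ok)) {            # most recent first
    w <- beat_window(signal, tt[j], len)
    if (is.null(w)) next
    if (is.null(acc)) {
      acc <- w; n_used <- 1L
    } else if (cwa_raw(w, acc / n_used) >= cfg$template_min_corr) {
      acc <- acc + w; n_used <- n_used + 1L
    }
    if (n_used >= cfg$template_k) break
  }
  if (n_used == 0L) return(tmpl)
  tmpl$window <- acc / n_used
  tmpl$n_beats_used <- n_used
  tmpl$valid <- n_used >= cfg$template_nmin
  tmpl
}

#' @export
print.nsr_template <- function(x, ...) {
  cat(sprintf("<nsr_template> %s, %d beats averaged, formed at %.1f s, L = %d\n",
              if (x$valid) "valid" else "INVALID", x$n_beats_used,
              x$formed_at, length(x$window)))
  invisible(x)
}

# plain Pearson correlation of two equal-length vectors; 0 if degenerate
cwa_raw <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  da <- sum(a^2); db <- sum(b^2)
  if (da == 0 || db == 0) return(0)
  sum(a * b) / sqrt(da * db)
}

#' Correlation waveform analysis (CWA)
#'
#' Mean-removed normalised cross-correlation at zero lag between a beat
#' window and the NSR template -- identical to the Pearson correlation of
#' the two vectors.  Invariant to affine amplitude scaling of either input;
#' returns 0 when either vector has zero variance.
#'
#' @param beat_window Numeric vector (uV), same length as the template.
#' @param template An `nsr_template` (or bare numeric vector).
#' @return Score in `[-1, 1]`.
#' @export
cwa <- function(beat_window, template) {
  tw <- if (inherits(template, "nsr_template")) template$window else template
  if (length(beat_window) != length(tw))
    stop("beat window length (", length(beat_window),
         ") does not match template length (", length(tw), ")")
  cwa_raw(beat_window, tw)
}

#' Dynamic CWA: correlation maximised over small alignment shifts
#'
#' Evaluates [cwa] over integer shifts in `[-max_shift, max_shift]` (on the
#' overlapping portions of the two windows) and returns the maximum.  A
#' positive shift means the beat window's content is *later* than the
#' template's.  Ties are broken toward the smallest `|shift|`, then toward
#' the negative shift.
#'
#' @param beat_window Numeric vector (uV).
#' @param template An `nsr_template` (or bare numeric vector).
#' @param max_shift Maximum shift in samples (default 10, ~39 ms at
#'   256 Hz).
#' @return List with `score` and `shift`.
#' @export
dcwa <- function(beat_window, template, max_shift = 10) {
  tw <- if (inherits(template, "nsr_template")) template$window else template
  L <- length(tw)
  if (length(beat_window) != L)
    stop("beat window length does not match template length")
  if (max_shift < 0) stop("max_shift must be >= 0")
  max_shift <- min(max_shift, L - 2L)
  shifts <- seq.int(-max_shift, max_shift)
  scores <- vapply(shifts, function(s) {
    if (s >= 0) cwa_raw(beat_window[(1 + s):L], tw[1:(L - s)])
    else        cwa_raw(beat_window[1:(L + s)], tw[(1 - s):L])
  }, 0)
  best <- max(scores)
  cand <- shifts[scores >= best - 1e-15]
  sh <- cand[order(abs(cand), cand)][1]
  list(score = best, shift = as.integer(sh))
}
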