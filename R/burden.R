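#' Daily PVC burden for one window
#'
#' Burden is the number of PVC-labelled beats (singles plus couplet and
#' triplet member beats) normalised by the total number of detected beats
#' in the window, as a percentage.  A window with no detected beats yields
#' an *undefined* burden (`NA`), deliberately distinct from 0%: a dead
#' signal must not read as healthy.
#'
#' @param labels Beat-label data frame from [detect_pvcs].
#' @param window_start Window start (s from record start).
#' @param window_len Window length (s); default 86400 (24 h).
#' @param threshold_pct Alert threshold (percent); default 5, the
#'   configurable minimum.
#' @return A `burden_report`: list with `window_start`, `window_len`,
#'   `n_pvc`, `n_beats`, `burden_pct`, `sequence_ppt` (percentage points of
#'   the burden contributed by couplet/triplet beats), `alert`,
#'   `threshold_pct`, `partial`.
#' @export
daily_burden <- function(labels, window_start = 0, window_len = 86400,
                         threshold_pct = 5) {
  if (window_len <= 0) stop("window_len must be positive")
  sel <- labels$time >= window_start & labels$time < window_start + window_len
  lw <- labels[sel, , drop = FALSE]
  n_beats <- nrow(lw)
  is_pvc <- lw$label == "PVC"
  n_pvc <- sum(is_pvc)
  n_seq <- sum(is_pvc & lw$seq_type %in% c("couplet", "triplet"))
  if (n_beats == 0) {
    burden <- NA_real_; seq_ppt <- NA_real_; alert <- NA
  } else {
    burden <- 100 * n_pvc / n_beats
    seq_ppt <- 100 * n_seq / n_beats
    alert <- burden >= threshold_pct
  }
  structure(list(window_start = window_start, window_len = window_len,
                 n_pvc = n_pvc, n_beats = n_beats, burden_pct = burden,
                 sequence_ppt = seq_ppt, alert = alert,
                 threshold_pct = threshold_pct, partial = FALSE),
            class = "burden_report")
}

#' @export
print.burden_report <- function(x, ...) {
  b <- if (is.na(x$burden_pct)) "undefined (no beats)" else
    sprintf("%.2f%% (%d PVC / %d beats)", x$burden_pct, x$n_pvc, x$n_beats)
  cat(sprintf("<burden_report> [%g, %g) s: burden %s%s; alert %s\n",
              x$window_start, x$window_start + x$window_len, b,
              if (x$partial) " [partial window]" else "",
              if (isTRUE(x$alert)) "ON" else if (isFALSE(x$alert)) "off"
              else "undefined"))
  invisible(x)
}

#' Burden trend over consecutive windows
#'
#' Splits the record into consecutive non-overlapping windows anchored at
#' the recording start (record-relative, for reproducibility; pass a
#' different `anchor` to shift).  A trailing partial window is reported and
#' flagged `partial`.
#'
#' @param labels Beat-label data frame from [detect_pvcs].
#' @param record_span Total record span (s).
#' @param window_len Window length (s), default 86400.
#' @param threshold_pct Alert threshold (percent).
#' @param anchor Start of the first window (s), default 0.
#' @return List of `burden_report`s, or a data frame via
#'   [burden_series_df].
#' @export
burden_series <- function(labels, record_span, window_len = 86400,
                          threshold_pct = 5, anchor = 0) {
  if (record_span - anchor < window_len)
    stop("record span must cover at least one full window")
  starts <- seq(anchor, record_span - window_len, by = window_len)
  reports <- lapply(starts, daily_burden, labels = labels,
                    window_len = window_len, threshold_pct = threshold_pct)
  tail_start <- starts[length(starts)] + window_len
  if (record_span - tail_start > 0) {
    part <- daily_burden(labels, tail_start, record_span - tail_start,
                         threshold_pct)
    part$partial <- TRUE
    reports <- c(reports, list(part))
  }
  reports
}

#' Flatten burden reports to a data frame
#'
#' @param reports List of `burden_report`s from [burden_series].
#' @return Data frame, one row per window.
#' @export
burden_series_df <- function(reports) {
  do.call(rbind, lapply(reports, function(r)
    data.frame(window_start = r$window_start, window_len = r$window_len,
               n_pvc = r$n_pvc, n_beats = r$n_beats,
               burden_pct = r$burden_pct, sequence_ppt = r$sequence_ppt,
               alert = r$alert, partial = r$partial)))
}
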