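#' Match detections to reference events within a tolerance window
#'
#' One-to-one matching of detection times to reference PVC times with a
#' +-`tolerance` window (150 ms by default).  The pairing maximises the
#' number of matches (equivalent to the optimal assignment on the interval
#' graph) and prefers the nearest detection for each matched reference.
#' Detections that fail to match a usable reference but fall within the
#' tolerance of an *excluded* reference (ambiguous/fusion beats) are set
#' aside: they count as neither true nor false positives.
#'
#' @param detections Numeric vector of detection times (s), sorted.
#' @param references Numeric vector of usable reference PVC times (s),
#'   sorted.
#' @param tolerance Matching tolerance (s), default 0.150.
#' @param excluded_times Times of excluded-symbol references (e.g. fusion
#'   beats), default none.
#' @return A `match_result`: list with `tp` (data frame `detection`,
#'   `reference`), `fp`, `fn` (numeric vectors), `excluded` (detections
#'   absorbed by excluded references), `tolerance`.
#' @export
match_events <- function(detections, references, tolerance = 0.150,
                         excluded_times = numeric(0)) {
  det <- sort(detections); ref <- sort(references)
  n <- length(det); m <- length(ref)
  det_match <- rep(NA_integer_, n)   # index into ref

  # maximum-cardinality pass: refs in time order take the earliest free
  # detection inside their window (optimal for interval bigraphs)
  j0 <- 1L
  used <- rep(FALSE, n)
  ref_match <- rep(NA_integer_, m)
  for (j in seq_len(m)) {
    while (j0 <= n && det[j0] < ref[j] - tolerance) j0 <- j0 + 1L
    k <- j0
    while (k <= n && det[k] <= ref[j] + tolerance) {
      if (!used[k]) { used[k] <- TRUE; ref_match[j] <- k; break }
      k <- k + 1L
    }
  }
  # nearest-in-time refinement: swap in a closer unused detection
  for (j in which(!is.na(ref_match))) {
    k <- ref_match[j]
    cand <- which(!used & abs(det - ref[j]) < abs(det[k] - ref[j]) &
                  abs(det - ref[j]) <= tolerance)
    if (length(cand)) {
      k2 <- cand[which.min(abs(det[cand] - ref[j]))]
      used[k] <- FALSE; used[k2] <- TRUE; ref_match[j] <- k2
    }
  }
  det_match[ref_match[!is.na(ref_match)]] <- which(!is.na(ref_match))

  tp <- data.frame(detection = det[!is.na(det_match)],
                   reference = ref[det_match[!is.na(det_match)]])
  unmatched_det <- det[is.na(det_match)]
  excl <- logical(length(unmatched_det))
  if (length(excluded_times) && length(unmatched_det))
    excl <- vapply(unmatched_det, function(t)
      any(abs(excluded_times - t) <= tolerance), TRUE)
  structure(list(tp = tp, fp = unmatched_det[!excl],
                 fn = ref[is.na(ref_match)], excluded = unmatched_det[excl],
                 tolerance = tolerance),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP %d, FP %d, FN %d, excluded %d (tol %.0f ms)\n",
              nrow(x$tp), length(x$fp), length(x$fn), length(x$excluded),
              1000 * x$tolerance))
  invisible(x)
}

#' Beat-level detection metrics
#'
#' Sensitivity `TP/(TP+FN)`, PPV `TP/(TP+FP)`, F1 (harmonic mean of the
#' two), and the *modified* specificity normalised by detected beats:
#' `TN*/(TN*+FP)` where `TN* = n_detected_beats - TP - FP - FN` counts
#' detected beats that are neither true PVCs nor labelled PVC.  Classical
#' specificity over adjudicated normals is available via
#' `classical_n_normal`.  Zero-denominator metrics are `NA` ("undefined"),
#' never 0 or 100.
#'
#' @param m A `match_result`, or a list with numeric `tp`, `fp`, `fn`
#'   counts.
#' @param n_detected_beats Total number of detected beats in the scored
#'   span.
#' @param classical_n_normal Optional count of adjudicated non-PVC beats;
#'   when given, `specificity_classical` is also reported.
#' @return A `metric_set`: list with `sensitivity`, `specificity`, `ppv`,
#'   `f1` (fractions in `[0, 1]`), counts, and `level = "gross"`.
#' @export
beat_metrics <- function(m, n_detected_beats, classical_n_normal = NULL) {
  tp <- if (inherits(m, "match_result")) nrow(m$tp) else m$tp
  fp <- if (inherits(m, "match_result")) length(m$fp) else m$fp
  fn <- if (inherits(m, "match_result")) length(m$fn) else m$fn
  if (n_detected_beats < tp + fp)
    stop("n_detected_beats must be at least TP + FP")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  tn <- max(0, n_detected_beats - tp - fp - fn)
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  out <- list(sensitivity = sens, specificity = spec, ppv = ppv,
              f1 = f1_score(sens, ppv), tp = tp, fp = fp, fn = fn, tn = tn,
              n_detected_beats = n_detected_beats, level = "gross")
  if (!is.null(classical_n_normal)) {
    tnc <- max(0, classical_n_normal - fp)
    out$specificity_classical <-
      if (classical_n_normal > 0) tnc / classical_n_normal else NA_real_
  }
  structure(out, class = "metric_set")
}

#' Harmonic mean of sensitivity and PPV
#'
#' @param sensitivity,ppv Fractions in `[0, 1]`.
#' @return `2 s p / (s + p)`; 0 when both are 0; `NA` when either is
#'   undefined.
#' @export
f1_score <- function(sensitivity, ppv) {
  if (is.na(sensitivity) || is.na(ppv)) return(NA_real_)
  if (sensitivity + ppv == 0) return(0)
  2 * sensitivity * ppv / (sensitivity + ppv)
}

#' @export
print.metric_set <- function(x, ...) {
  pc <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("<metric_set> [%s] sensitivity %s, specificity %s, ppv %s, F1 %s\n",
              x$level, pc(x$sensitivity), pc(x$specificity), pc(x$ppv),
              pc(x$f1)))
  invisible(x)
}

#' Unweighted patient-average metrics
#'
#' The mean of each metric over patients for whom it is defined, so a
#' patient with no reference PVCs does not drag sensitivity to 0 or 100.
#'
#' @param per_patient List of `metric_set`s, one per patient.
#' @return A `metric_set` with `level = "patient_average"`.
#' @export
patient_average <- function(per_patient) {
  if (!length(per_patient)) stop("at least one patient is required")
  avg <- function(f) {
    v <- vapply(per_patient, function(p) p[[f]], 0)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  structure(list(sensitivity = avg("sensitivity"),
                 specificity = avg("specificity"), ppv = avg("ppv"),
                 f1 = avg("f1"), n_patients = length(per_patient),
                 level = "patient_average"),
            class = "metric_set")
}

#' GEE-adjusted marginal proportion with robust 95% CI
#'
#' Intercept-only generalized estimating equation for clustered binary
#' outcomes (one cluster per patient) with a binomial (logit) link and an
#' exchangeable working correlation.  The within-cluster correlation and
#' dispersion follow the usual moment estimators (Pearson residual sums
#' with a one-parameter degrees-of-freedom correction); the 95% CI comes
#' from the robust (sandwich) standard error, back-transformed from the
#' logit scale.
#'
#' @param successes,trials Integer vectors, one entry per patient/cluster.
#' @return List: `proportion` (GEE-adjusted mean), `ci_lo`, `ci_hi`,
#'   `se_logit`, `alpha` (working correlation), `n_clusters`.  With an
#'   all-zero or all-one outcome the estimate is returned with a degenerate
#'   (`NA`) CI.
#' @export
gee_adjusted <- function(successes, trials) {
  if (length(successes) != length(trials))
    stop("successes and trials must have equal length")
  if (length(successes) < 2) stop("at least 2 clusters are required")
  if (any(trials < 1)) stop("every cluster needs at least one trial")
  S <- as.numeric(successes); n <- as.numeric(trials)
  N <- sum(n); p_dim <- 1
  ybar <- S / n
  npairs <- sum(n * (n - 1) / 2)

  tot <- sum(S) / N
  if (tot == 0 || tot == 1)
    return(list(proportion = tot, ci_lo = NA_real_, ci_hi = NA_real_,
                se_logit = NA_real_, alpha = NA_real_,
                n_clusters = length(n)))

  mu <- tot; alpha <- 0
  for (it in 1:200) {
    v <- mu * (1 - mu)
    # Pearson residual sums per cluster from (S, n)
    ssr <- (S * (1 - mu)^2 + (n - S) * mu^2) / v
    rsum <- n * (ybar - mu) / sqrt(v)
    scale <- sum(ssr) / (N - p_dim)
    pairsum <- sum((rsum^2 - ssr) / 2)
    alpha <- if (npairs > p_dim) pairsum / scale / (npairs - p_dim) else 0
    w <- 1 / (1 + (n - 1) * alpha)
    mu_new <- sum(w * n * ybar) / sum(w * n)
    conv <- abs(mu_new - mu) < 1e-14
    mu <- mu_new
    if (conv) break
  }
  v <- mu * (1 - mu)
  B <- v * sum(n * w)                  # bread (naive information)
  g <- w * n * (ybar - mu)             # per-cluster score
  se_beta <- sqrt(sum(g^2)) / B        # robust sandwich SE on logit scale
  beta <- stats::qlogis(mu)
  list(proportion = mu,
       ci_lo = stats::plogis(beta - 1.96 * se_beta),
       ci_hi = stats::plogis(beta + 1.96 * se_beta),
       se_logit = se_beta, alpha = alpha, n_clusters = length(n))
}

#' Burden agreement: Pearson r, bias and limits of agreement
#'
#' @param est,ref Equal-length numeric vectors of estimated and reference
#'   burdens (percent), length >= 3.
#' @return List: `r` (Pearson correlation; `NA` when either side has zero
#'   variance), `bias` (mean of `est - ref`, percentage points), `loa_lo`,
#'   `loa_hi` (bias +- 1.96 sd of the differences), `sd_diff`, `n`.
#' @export
burden_agreement <- function(est, ref) {
  if (length(est) != length(ref)) stop("est and ref must have equal length")
  if (length(est) < 3) stop("at least 3 pairs are required")
  d <- est - ref
  r <- if (stats::sd(est) == 0 || stats::sd(ref) == 0) NA_real_ else
    stats::cor(est, ref)
  bias <- mean(d); s <- stats::sd(d)
  list(r = r, bias = bias, loa_lo = bias - 1.96 * s, loa_hi = bias + 1.96 * s,
       sd_diff = s, n = length(d))
}

#' Patient-level metrics of an elevated-burden threshold
#'
#' Patients are classified positive when their burden meets the threshold;
#' estimated classifications are scored against reference ones.
#'
#' @param est,ref Numeric vectors of per-patient burdens (percent).
#' @param threshold_pct Device threshold applied to the estimates (percent),
#'   e.g. 10.
#' @param ref_threshold_pct Threshold defining reference-positive patients;
#'   defaults to `threshold_pct`.  Holding it fixed while lowering
#'   `threshold_pct` makes patient-level sensitivity monotone
#'   non-decreasing.
#' @return List with `sensitivity`, `specificity`, `ppv` (fractions; `NA`
#'   when undefined) and the patient counts `tp`, `fp`, `fn`, `tn`.
#' @export
threshold_metrics <- function(est, ref, threshold_pct,
                              ref_threshold_pct = threshold_pct) {
  if (length(est) != length(ref)) stop("est and ref must have equal length")
  ep <- est >= threshold_pct; rp <- ref >= ref_threshold_pct
  tp <- sum(ep & rp); fp <- sum(ep & !rp)
  fn <- sum(!ep & rp); tn <- sum(!ep & !rp)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       tp = tp, fp = fp, fn = fn, tn = tn)
}
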