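#' @keywords internal
feature_names <- c("one_minus_cwa", "one_minus_dcwa", "prematurity",
                   "compensatory_ratio", "amp_ratio", "slew_ratio",
                   "width_ratio")

# QRS duration estimate: span where the median-removed window exceeds 25%
# of its peak absolute deviation
qrs_width <- function(w, fs) {
  m <- w - stats::median(w)
  th <- 0.25 * max(abs(m))
  if (th <= 0) return(0)
  above <- which(abs(m) >= th)
  (max(above) - min(above) + 1) / fs
}

#' Extract the morphology feature vector for one candidate
#'
#' Seven QRS-descriptive features: `one_minus_cwa` and `one_minus_dcwa`
#' (template dissimilarity at zero lag and after alignment), `prematurity`,
#' `compensatory_ratio` (`rr_next / rr_local_mean`), `amp_ratio`,
#' `slew_ratio` (peak `|dV/dt|` of the beat relative to the template) and
#' `width_ratio` (QRS duration estimate relative to the template's).
#'
#' @param signal An [ecg_signal].
#' @param candidate One row of the [trigger_scan] output.
#' @param template A valid `nsr_template`.
#' @param cfg A [detector_config].
#' @return Named numeric vector of length 7 with attribute `seq_type`, or
#'   `NULL` when the beat window exceeds the record bounds (candidate
#'   dropped).
#' @export
extract_features <- function(signal, candidate, template,
                             cfg = detector_config()) {
  if (!template$valid)
    stop("extract_features requires a valid template; defer the candidate")
  len <- length(template$window)
  w <- beat_window(signal, candidate$time, len)
  if (is.null(w)) return(NULL)
  d <- dcwa(w, template, max_shift = cfg$max_shift)
  tmpl_slew <- max(abs(diff(template$window)))
  tmpl_width <- qrs_width(template$window, signal$fs)
  fv <- c(one_minus_cwa = 1 - cwa(w, template),
          one_minus_dcwa = 1 - d$score,
          prematurity = candidate$prematurity,
          compensatory_ratio = candidate$rr_next / candidate$rr_local_mean,
          amp_ratio = candidate$amp_ratio,
          slew_ratio = if (tmpl_slew > 0) max(abs(diff(w))) / tmpl_slew else 1,
          width_ratio = if (tmpl_width > 0) qrs_width(w, signal$fs) / tmpl_width
                        else 1)
  attr(fv, "seq_type") <- candidate$seq_type
  fv
}

#' Classify one feature vector with a per-sequence-type model
#'
#' Features are standardised with the model's stored training means and
#' scales, then scored with the logistic regression:
#' `p = plogis(w . x + b)`; the PVC label is assigned when `p` meets the
#' model's decision threshold.
#'
#' @param fv Feature vector from [extract_features].
#' @param model A `pvc_model` ([train_model]).
#' @return List `label` (`"PVC"`/`"non-PVC"`), `probability`, `seq_type`.
#' @export
classify <- function(fv, model) {
  st <- attr(fv, "seq_type")
  if (!is.null(st) && !identical(st, model$seq_type))
    stop("sequence type mismatch: feature vector is '", st,
         "', model is '", model$seq_type, "'")
  x <- (fv[model$feature_names] - model$center) / model$scale
  eta <- sum(model$weights * x) + model$intercept
  p <- stats::plogis(eta)
  list(label = if (p >= model$threshold) "PVC" else "non-PVC",
       probability = unname(p), seq_type = model$seq_type)
}

#' Train a per-sequence-type PVC classifier
#'
#' L2-regularised (ridge) logistic regression over the seven morphology
#' features, fit with `glmnet` at a small fixed penalty.  The data are
#' split deterministically (by `seed`) into a 75% training and 25%
#' threshold-selection fold; the decision threshold is the probability cut
#' that maximises F1 on the held-out fold.  Feature standardisation
#' parameters are stored inside the model so a deployed model is
#' self-contained.
#'
#' @param features Matrix or data frame of feature rows (columns named as
#'   in [extract_features]).
#' @param labels Logical or 0/1 vector: `TRUE`/1 = PVC.
#' @param seq_type `"single"`, `"couplet"` or `"triplet"`.
#' @param seed Integer seed controlling the fold split.
#' @param lambda Ridge penalty (default 1e-3).
#' @return A `pvc_model`: list with `seq_type`, `feature_names`, `center`,
#'   `scale`, `weights`, `intercept`, `threshold`, `seed`, `data_hash`,
#'   `n_train`.
#' @export
train_model <- function(features, labels, seq_type, seed = 1,
                        lambda = 1e-3) {
  X <- as.matrix(features)[, feature_names, drop = FALSE]
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2)
    stop("training requires both PVC and non-PVC examples")
  if (nrow(X) < 50)
    stop("training requires at least 50 examples, got ", nrow(X))

  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # stratified 75/25 split
  hold <- logical(nrow(Xs))
  for (cls in c(0L, 1L)) {
    id <- which(y == cls)
    hold[sample(id, max(1L, round(length(id) * 0.25)))] <- TRUE
  }
  if (length(unique(y[!hold])) < 2) hold[] <- FALSE  # tiny data: train on all

  fit <- glmnet::glmnet(Xs[!hold, , drop = FALSE], y[!hold],
                        family = "binomial", alpha = 0, lambda = lambda,
                        standardize = FALSE)
  wts <- as.numeric(fit$beta)
  b0 <- as.numeric(fit$a0)

  p_hold <- stats::plogis(Xs[hold, , drop = FALSE] %*% wts + b0)
  y_hold <- y[hold]
  grid <- seq(0.05, 0.95, by = 0.01)
  f1s <- vapply(grid, function(th) {
    tp <- sum(p_hold >= th & y_hold == 1)
    fp <- sum(p_hold >= th & y_hold == 0)
    fn <- sum(p_hold < th & y_hold == 1)
    if (tp == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, 0)
  # F1 is often flat over a wide plateau on separable data; take the
  # plateau midpoint rather than its edge
  threshold <- if (any(f1s > 0)) {
    best <- grid[f1s >= max(f1s) - 1e-12]
    best[ceiling(length(best) / 2)]
  } else 0.5

  structure(list(seq_type = seq_type, feature_names = feature_names,
                 center = ctr, scale = scl,
                 weights = stats::setNames(wts, feature_names),
                 intercept = b0, threshold = threshold, seed = seed,
                 data_hash = dataset_hash(X, y), n_train = sum(!hold)),
            class = "pvc_model")
}

# stable fingerprint of a training set, for model provenance
dataset_hash <- function(X, y) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(round(unname(as.matrix(X)), 9), as.integer(y)), f)
  unname(tools::md5sum(f))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.pvc_model <- function(x, ...) {
  cat(sprintf("<pvc_model> %s: threshold %.2f, trained on %d rows (seed %d)\n",
              x$seq_type, x$threshold, x$n_train, x$seed))
  invisible(x)
}

#' Write / read a classifier model as JSON
#'
#' @param model A `pvc_model`.
#' @param path JSON file path.
#' @return `write_model`: `path`, invisibly. `read_model`: a `pvc_model`.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$feature_names <- as.character(m$feature_names)
  for (f in c("center", "scale", "weights"))
    m[[f]] <- stats::setNames(as.numeric(m[[f]]), m$feature_names)
  structure(m, class = "pvc_model")
}

#' Load the models shipped with the package
#'
#' Default per-sequence-type classifiers trained on the synthetic corpus
#' (see `scripts/train_default_models.R` in the source tree).
#'
#' @return Named list of `pvc_model`s: `single`, `couplet`, `triplet`.
#' @export
default_models <- function() {
  dir <- system.file("extdata", "models", package = "ectopy")
  sapply(c("single", "couplet", "triplet"), function(st)
    read_model(file.path(dir, paste0(st, ".json"))),
    simplify = FALSE)
}

#' Run the full two-stage detector over a record
#'
#' Orchestrates template maintenance, the trigger scan and per-candidate
#' morphology classification.  Template formation is attempted at
#' `cfg$template_warmup` and every `cfg$template_period` seconds thereafter
#' (2 hours by default); each candidate is scored against the most recent
#' valid template.  Candidates arriving while no valid template exists are
#' conservatively labelled non-PVC and counted in the `n_unclassifiable`
#' attribute.  Couplet and triplet members are classified with their
#' sequence-type model; runs of four or more candidates are never labelled
#' PVC.
#'
#' @param signal An [ecg_signal] (working-rate, preconditioned).
#' @param beats Beat data frame ([detect_beats] or
#'   [beats_from_annotations]).
#' @param noise Noise intervals ([mark_noise]); may be `NULL`.
#' @param cfg A [detector_config].
#' @param models Named list with `single`, `couplet`, `triplet`
#'   `pvc_model`s ([default_models]).
#' @return Data frame with one row per beat: `time`, `label`
#'   (`"PVC"`/`"non-PVC"`), `probability` (NA for non-candidates),
#'   `seq_type` (NA unless candidate).  Attribute `n_unclassifiable` counts
#'   candidates deferred for want of a valid template.
#' @export
detect_pvcs <- function(signal, beats, noise = NULL, cfg = detector_config(),
                        models = default_models()) {
  need <- c("single", "couplet", "triplet")
  if (!all(need %in% names(models)))
    stop("models for all three sequence types are required")
  labels <- data.frame(time = beats$time, label = "non-PVC",
                       probability = NA_real_, seq_type = NA_character_,
                       stringsAsFactors = FALSE)
  n_unclass <- 0L
  if (nrow(beats) >= 3) {
    if (is.null(noise)) noise <- data.frame(start = numeric(0),
                                            end = numeric(0))
    cand <- trigger_scan(beats, noise, cfg)
    if (nrow(cand)) {
      t_end <- signal$t0 + duration(signal)
      sched <- seq(signal$t0 + cfg$template_warmup, t_end,
                   by = cfg$template_period)
      templates <- lapply(sched, function(at)
        form_template(signal, beats, at, cfg))
      for (k in seq_len(nrow(cand))) {
        row <- cand[k, ]
        labels$seq_type[row$beat_index] <- row$seq_type
        if (row$seq_type == "run") next  # beyond triplet: not PVC candidacy
        live <- which(sched <= row$time)
        tmpl <- NULL
        for (j in rev(live)) if (templates[[j]]$valid) { tmpl <- templates[[j]]; break }
        if (is.null(tmpl)) { n_unclass <- n_unclass + 1L; next }
        fv <- extract_features(signal, row, tmpl, cfg)
        if (is.null(fv)) next  # window out of record bounds
        res <- classify(fv, models[[row$seq_type]])
        labels$label[row$beat_index] <- res$label
        labels$probability[row$beat_index] <- res$probability
      }
    }
  }
  attr(labels, "n_unclassifiable") <- n_unclass
  labels
}

#' Harvest labelled training features from an annotated record
#'
#' Runs the template/trigger/feature stages over a record and labels each
#' candidate by proximity (within `tol` seconds) to a reference `V`
#' annotation -- the training-harness counterpart of [detect_pvcs].
#'
#' @param signal An [ecg_signal].
#' @param annotations Reference annotations (`time`, `symbol`).
#' @param cfg A [detector_config].
#' @param beats Optional beat data frame; defaults to annotation bypass via
#'   [beats_from_annotations].
#' @param tol Labelling tolerance (s), default 0.150.
#' @return Data frame: the seven features, `seq_type`, and logical
#'   `is_pvc`.
#' @export
training_features <- function(signal, annotations, cfg = detector_config(),
                              beats = NULL, tol = 0.150) {
  if (is.null(beats)) beats <- beats_from_annotations(annotations, signal)
  noise <- data.frame(start = numeric(0), end = numeric(0))
  cand <- trigger_scan(beats, noise, cfg)
  out <- list()
  if (nrow(cand)) {
    t_end <- signal$t0 + duration(signal)
    sched <- seq(signal$t0 + cfg$template_warmup, t_end,
                 by = cfg$template_period)
    templates <- lapply(sched, function(at)
      form_template(signal, beats, at, cfg))
    v_times <- annotations$time[annotations$symbol == "V"]
    for (k in seq_len(nrow(cand))) {
      row <- cand[k, ]
      if (row$seq_type == "run") next
      live <- which(sched <= row$time)
      tmpl <- NULL
      for (j in rev(live)) if (templates[[j]]$valid) { tmpl <- templates[[j]]; break }
      if (is.null(tmpl)) next
      fv <- extract_features(signal, row, tmpl, cfg)
      if (is.null(fv)) next
      out[[length(out) + 1L]] <- data.frame(
        t(fv), seq_type = row$seq_type,
        is_pvc = length(v_times) > 0 && min(abs(v_times - row$time)) <= tol,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(stats::setNames(
      data.frame(matrix(numeric(0), ncol = 9)),
      c(feature_names, "seq_type", "is_pvc")))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
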