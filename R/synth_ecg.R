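#' Synthetic-record configuration
#'
#' Declares the conditions of a simulated single-lead recording: heart
#' rate and RR variability, the target ventricular-ectopy burden and how it
#' is apportioned among singles, bigeminy, couplets and triplets, the
#' ectopic coupling interval, the PVC morphology mode, premature atrial
#' contractions (optionally aberrantly conducted -- the classic PVC mimic),
#' and additive noise bursts.  Records start with an NSR lead-in so the
#' detector can form its first template, mirroring ambulatory practice.
#'
#' @param duration Record length (s).
#' @param heart_rate Baseline sinus rate (bpm).
#' @param rr_cv Coefficient of variation of the sinus RR interval.
#' @param target_burden_pct Intended V-beat percentage (0--50).
#' @param seq_mix Named fractions of ectopic *beats* carried by each
#'   pattern: `single`, `bigeminy`, `couplet`, `triplet`; must sum to 1.
#' @param coupling_factor Ectopic prematurity: the PVC falls at
#'   `coupling_factor * local RR` after the preceding beat (default 0.72).
#' @param intra_factor Sequences compress the intra-sequence RR to
#'   `intra_factor * coupling interval` (default 0.85).
#' @param pvc_morph `"wide"` (classic wide, high-slew, inverted QRS) or
#'   `"narrow_projection"` (a PVC whose projection on the sensing vector
#'   resembles NSR -- the documented false-negative mode).
#' @param pac_rate_per_min Premature atrial contractions per minute.
#' @param pac_aberrant If `TRUE`, PACs conduct aberrantly with a wide QRS
#'   (the documented false-positive mode); otherwise NSR-like.
#' @param pac_coupling PAC prematurity factor (default 0.80); PACs reset
#'   the sinus clock (no compensatory pause).
#' @param noise_bursts List `count`, `len_s`, `amp_uv`: additive broadband
#'   bursts.
#' @param r_amp_uv NSR R-wave amplitude (uV).
#' @param baseline_noise_uv Broadband measurement-noise sd (uV).
#' @param bigeminy_run Number of PVCs in one bigeminy episode.
#' @param nsr_lead_in Seconds of pure NSR at the record start (template
#'   formation lead-in).
#' @param fs Sampling rate (Hz).
#' @param seed Integer seed; fixes the entire record.
#' @return A `synth_config` list.
#' @export
synth_config <- function(duration = 600,
                         heart_rate = 70,
                         rr_cv = 0.04,
                         target_burden_pct = 10,
                         seq_mix = c(single = 0.60, bigeminy = 0.30,
                                     couplet = 0.07, triplet = 0.03),
                         coupling_factor = 0.72,
                         intra_factor = 0.85,
                         pvc_morph = c("wide", "narrow_projection"),
                         pac_rate_per_min = 0,
                         pac_aberrant = FALSE,
                         pac_coupling = 0.80,
                         noise_bursts = list(count = 0, len_s = 2,
                                             amp_uv = 2000),
                         r_amp_uv = 500,
                         baseline_noise_uv = 4,
                         bigeminy_run = 4,
                         nsr_lead_in = 35,
                         fs = 256,
                         seed = 1) {
  pvc_morph <- match.arg(pvc_morph)
  need <- c("single", "bigeminy", "couplet", "triplet")
  if (!all(need %in% names(seq_mix)))
    stop("seq_mix must name fractions for ", paste(need, collapse = ", "))
  seq_mix <- seq_mix[need]
  if (abs(sum(seq_mix) - 1) > 1e-8) stop("seq_mix fractions must sum to 1")
  if (target_burden_pct < 0 || target_burden_pct > 50)
    stop("target_burden_pct must lie in [0, 50]")
  structure(list(duration = duration, heart_rate = heart_rate, rr_cv = rr_cv,
                 target_burden_pct = target_burden_pct, seq_mix = seq_mix,
                 coupling_factor = coupling_factor, intra_factor = intra_factor,
                 pvc_morph = pvc_morph, pac_rate_per_min = pac_rate_per_min,
                 pac_aberrant = pac_aberrant, pac_coupling = pac_coupling,
                 noise_bursts = noise_bursts, r_amp_uv = r_amp_uv,
                 baseline_noise_uv = baseline_noise_uv,
                 bigeminy_run = bigeminy_run, nsr_lead_in = nsr_lead_in,
                 fs = fs, seed = seed),
            class = "synth_config")
}

gauss <- function(t, mu, sd) exp(-0.5 * ((t - mu) / sd)^2)

#' QRS-T prototypes used by the generator
#'
#' Sums of Gaussians give exact analytic control over the amplitude, slew
#' and width features the classifier consumes.  Each prototype peaks (in
#' absolute value) exactly at its fiducial (t = 0).
#'
#' @param fs Sampling rate (Hz).
#' @param r_amp_uv NSR R amplitude (uV).
#' @return Named list of numeric vectors (`nsr`, `pvc_wide`, `pvc_narrow`,
#'   `pac_aberrant`) with attribute `"t"` holding the common time axis.
#' @export
synth_prototypes <- function(fs = 256, r_amp_uv = 500) {
  t <- seq.int(-round(0.40 * fs), round(0.45 * fs)) / fs  # t = 0 on-grid
  A <- r_amp_uv
  nsr <- A * (gauss(t, 0, 0.012) - 0.12 * gauss(t, -0.038, 0.009) -
              0.18 * gauss(t, 0.036, 0.010) + 0.30 * gauss(t, 0.28, 0.060))
  pvc_wide <- A * (-1.5 * gauss(t, 0, 0.035) + 0.60 * gauss(t, 0.095, 0.045) +
                   0.55 * gauss(t, 0.34, 0.080))
  pvc_narrow <- A * (0.92 * gauss(t, 0, 0.015) - 0.10 * gauss(t, -0.040, 0.009) -
                     0.26 * gauss(t, 0.044, 0.014) + 0.28 * gauss(t, 0.27, 0.060))
  pac_ab <- A * (-0.95 * gauss(t, 0, 0.030) + 0.70 * gauss(t, -0.052, 0.020) +
                 0.35 * gauss(t, 0.30, 0.070))
  out <- list(nsr = nsr, pvc_wide = pvc_wide, pvc_narrow = pvc_narrow,
              pac_aberrant = pac_ab)
  # overlapping secondary components can pull the discrete extremum a
  # sample off centre; roll each prototype so it peaks exactly at t = 0
  i0 <- which.min(abs(t))
  out <- lapply(out, function(v) {
    k <- i0 - which.max(abs(v))
    if (k > 0) c(rep(0, k), v[seq_len(length(v) - k)])
    else if (k < 0) c(v[(1 - k):length(v)], rep(0, -k))
    else v
  })
  attr(out, "t") <- t
  out
}

# expected value of max(2, round(X)), X ~ Gamma(shape, mean = g)
.mean_clamped_gap <- function(g, shape = 4) {
  kmax <- max(20, ceiling(g + 12 * g / sqrt(shape)))
  k <- 2:kmax
  pk <- stats::pgamma(k + 0.5, shape, rate = shape / g) -
        stats::pgamma(k - 0.5, shape, rate = shape / g)
  p_lo <- stats::pgamma(2.5, shape, rate = shape / g)
  sum(k * pk) + 2 * (p_lo - pk[1])
}

#' Simulate an annotated single-lead ECG record
#'
#' Lays out a beat sequence (sinus beats with lognormal-free RR jitter;
#' ectopic events scheduled with gamma-jittered gaps whose mean is solved
#' so the realised V fraction matches `target_burden_pct`), then renders
#' each beat from its QRS-T prototype and adds measurement noise and any
#' configured noise bursts.  Ectopic beats are premature at
#' `coupling_factor * local RR` and followed by a compensatory pause
#' (`2 * RR - coupling interval`); PACs reset the sinus clock instead.
#'
#' @param cfg A [synth_config].
#' @return List: `signal` ([ecg_signal]), `annotations` (data frame `time`,
#'   `symbol` in {N, S, V}), `truth` (beat table with `pattern` and
#'   `member_index`, noise-burst bounds, realised burden), `cfg`.
#' @export
simulate_record <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  fs <- cfg$fs
  rr0 <- 60 / cfg$heart_rate
  f <- cfg$target_burden_pct / 100
  # the NSR lead-in carries no ectopy; concentrate the target on the rest
  f <- f * cfg$duration / max(cfg$duration - cfg$nsr_lead_in, 1)
  f <- min(f, 0.5)

  ev_types <- c("single", "bigeminy", "couplet", "triplet")
  v_per_ev <- c(single = 1, bigeminy = cfg$bigeminy_run, couplet = 2,
                triplet = 3)
  n_extra <- c(single = 0, bigeminy = cfg$bigeminy_run - 1, couplet = 0,
               triplet = 0)
  p_ev <- cfg$seq_mix / v_per_ev
  p_ev <- p_ev / sum(p_ev)
  E_V <- sum(p_ev * v_per_ev)
  # beats emitted per event: its V beats, interleaved normals, and the
  # post-pause normal that closes the event
  E_B <- sum(p_ev * (v_per_ev + n_extra)) + 1

  g_mean <- NA
  if (f > 0) {
    g_target <- E_V / f - E_B     # mean gap (sinus beats between events)
    if (g_target < 2.2)
      stop("infeasible burden/sequence-mix combination: requested ",
           cfg$target_burden_pct, "% leaves a mean inter-event gap of ",
           round(g_target, 2), " beats")
    g_mean <- stats::uniroot(function(g) .mean_clamped_gap(g) - g_target,
                             c(1.2, 10 * g_target + 20))$root
  }
  draw_gap <- function() max(2, round(stats::rgamma(1, 4, rate = 4 / g_mean)))
  rr_draw <- function() rr0 * (1 + pmax(-3, pmin(3, stats::rnorm(1))) * cfg$rr_cv)
  p_pac <- cfg$pac_rate_per_min * rr0 / 60

  times <- numeric(0); syms <- character(0)
  patt <- character(0); memb <- integer(0)
  add_beat <- function(t, s, p, m) {
    times[length(times) + 1L] <<- t
    syms[length(syms) + 1L] <<- s
    patt[length(patt) + 1L] <<- p
    memb[length(memb) + 1L] <<- m
  }

  t <- 1.0
  add_beat(t, "N", "nsr", 0L)
  lr <- rr0
  countdown <- if (f > 0) draw_gap() else Inf
  lead_in_end <- cfg$nsr_lead_in
  c_f <- cfg$coupling_factor

  while (t < cfg$duration - 1.2) {
    if (f > 0 && countdown <= 0 && t > lead_in_end) {
      ev <- sample(ev_types, 1, prob = p_ev)
      if (ev == "single") {
        add_beat(t + c_f * lr, "V", "single", 0L)
        t <- t + 2 * lr
        add_beat(t, "N", "nsr", 0L)
      } else if (ev %in% c("couplet", "triplet")) {
        nv <- if (ev == "couplet") 2L else 3L
        tv <- t + c_f * lr
        for (k in seq_len(nv)) {
          add_beat(tv, "V", ev, k - 1L)
          if (k < nv) tv <- tv + cfg$intra_factor * c_f * lr
        }
        t <- tv + (2 - c_f) * lr
        add_beat(t, "N", "nsr", 0L)
      } else {                    # bigeminy: V (N V) x (run-1)
        tv <- t + c_f * lr
        for (k in seq_len(cfg$bigeminy_run)) {
          add_beat(tv, "V", "bigeminy", k - 1L)
          tn <- tv + (2 - c_f) * lr
          if (k < cfg$bigeminy_run) {
            add_beat(tn, "N", "nsr", 0L)
            tv <- tn + c_f * lr
          }
        }
        t <- tv + (2 - c_f) * lr
        add_beat(t, "N", "nsr", 0L)
      }
      countdown <- draw_gap()
    } else if (p_pac > 0 && stats::runif(1) < p_pac && t > lead_in_end) {
      # atrial episodes come as singles, pairs or salvos of three; their
      # coupling intervals and post-episode pauses vary from beat to beat,
      # overlapping ventricular timing (which is why timing alone cannot
      # separate PACs from NSR-like PVCs)
      nrun <- sample(c(1L, 2L, 3L), 1, prob = c(0.80, 0.13, 0.07))
      ppat <- if (cfg$pac_aberrant) "pac_aberrant" else "pac"
      tp <- t
      for (k in seq_len(nrun)) {
        tp <- tp + stats::runif(1, cfg$pac_coupling - 0.10,
                                cfg$pac_coupling + 0.08) * lr
        add_beat(tp, "S", ppat, k - 1L)
      }
      # sinus resumption after an atrial beat: anywhere between a plain
      # reset and a fully compensatory pause
      t <- tp + stats::runif(1, 1.0, 1.5) * lr
      add_beat(t, "N", "nsr", 0L)
      countdown <- countdown - 1
    } else {
      rr <- rr_draw()
      t <- t + rr
      add_beat(t, "N", "nsr", 0L)
      lr <- 0.8 * lr + 0.2 * rr    # slow local-RR tracker
      countdown <- countdown - 1
    }
  }

  keep <- times < cfg$duration - 0.6
  times <- times[keep]; syms <- syms[keep]
  patt <- patt[keep]; memb <- memb[keep]

  proto <- synth_prototypes(fs, cfg$r_amp_uv)
  tproto <- attr(proto, "t")
  pvc_key <- if (cfg$pvc_morph == "wide") "pvc_wide" else "pvc_narrow"
  shape_of <- c(nsr = "nsr", single = pvc_key, bigeminy = pvc_key,
                couplet = pvc_key, triplet = pvc_key, pac = "nsr",
                pac_aberrant = "pac_aberrant")

  n <- round(cfg$duration * fs)
  x <- stats::rnorm(n, 0, cfg$baseline_noise_uv)
  off <- round(tproto[1] * fs)
  lp <- length(tproto)
  narrow <- cfg$pvc_morph == "narrow_projection"
  for (k in seq_along(times)) {
    i0 <- round(times[k] * fs) + 1L + off
    idx <- i0:(i0 + lp - 1L)
    ok <- idx >= 1L & idx <= n
    amp <- 1 + 0.03 * pmax(-3, pmin(3, stats::rnorm(1)))
    shape <- proto[[shape_of[[patt[k]]]]]
    if (narrow && syms[k] == "V") {
      # how strongly the ectopic depolarisation projects onto the sensing
      # vector varies beat to beat; at the low end the projection is
      # genuinely indistinguishable from NSR
      mu <- stats::runif(1, 0.1, 1.0)
      shape <- proto$nsr + mu * (proto$pvc_narrow - proto$nsr)
    }
    x[idx[ok]] <- x[idx[ok]] + amp * shape[ok]
  }

  nb <- cfg$noise_bursts
  bursts <- data.frame(start = numeric(0), end = numeric(0))
  if (!is.null(nb$count) && nb$count > 0) {
    st <- sort(stats::runif(nb$count, 5, max(6, cfg$duration - 5 - nb$len_s)))
    bursts <- data.frame(start = st, end = st + nb$len_s)
    for (k in seq_len(nb$count)) {
      idx <- (round(st[k] * fs) + 1L):min(n, round((st[k] + nb$len_s) * fs))
      x[idx] <- x[idx] + stats::rnorm(length(idx), 0, nb$amp_uv)
    }
  }

  sig <- ecg_signal(x, fs = fs, lead_label = "SYN")
  ann <- data.frame(time = round(times * fs) / fs, symbol = syms,
                    stringsAsFactors = FALSE)
  truth <- list(beats = data.frame(time = ann$time, symbol = syms,
                                   pattern = patt, member_index = memb,
                                   stringsAsFactors = FALSE),
                noise_bursts = bursts,
                realized_burden_pct = 100 * mean(syms == "V"))
  list(signal = sig, annotations = ann, truth = truth, cfg = cfg)
}

#' Realised ectopy burden of an annotation set
#'
#' @param annotations Data frame `time`, `symbol`.
#' @return `100 * (# V) / (# beat annotations)`.
#' @export
realized_burden <- function(annotations) {
  sym <- annotations$symbol[annotations$symbol %in% .beat_symbols]
  if (!length(sym)) stop("no beat annotations")
  100 * mean(sym == "V")
}

#' Simulate a cohort of synthetic patients
#'
#' Per-patient seeds are derived from the master seed; true burdens come
#' from `burden_distribution` (a numeric vector recycled over patients, or
#' a function of `n` returning one burden per patient).
#'
#' @param n_patients Number of patients.
#' @param burden_distribution Numeric vector of target burdens (percent) or
#'   a function `n -> burdens`.
#' @param seed Master seed.
#' @param ... Further arguments passed to [synth_config] (e.g.
#'   `duration`).
#' @return List of [simulate_record] results; each element also carries
#'   `true_burden` (the realised V percentage).
#' @export
simulate_cohort <- function(n_patients, burden_distribution, seed = 1, ...) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_patients)
  burdens <- if (is.function(burden_distribution))
    burden_distribution(n_patients)
  else rep_len(burden_distribution, n_patients)
  lapply(seq_len(n_patients), function(i) {
    rec <- simulate_record(synth_config(target_burden_pct = burdens[i],
                                        seed = seeds[i], ...))
    rec$true_burden <- rec$truth$realized_burden_pct
    rec
  })
}
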