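---
title: "Ventricular ectopy detection and daily PVC burden: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ventricular ectopy detection and daily PVC burden: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Premature ventricular contractions (PVCs) are ectopic beats of ventricular
origin, typically early and with a wide, morphologically distinct QRS.
Their *burden* — the percentage of PVC beats among all beats over a
monitoring window, conventionally 24 hours — is the quantity clinicians
track, because sustained burdens above roughly 10% are associated with
PVC-induced cardiomyopathy, and cases have been reported around 5%.
Burden varies from day to day, so long-term single-lead monitors
(insertable cardiac monitors, ICMs) are attractive: they watch every beat
for months, but must do so on a severely constrained processor and a
single sensing vector.

`ectopy` implements the class of algorithm such devices use, end to end:
beat sensing, a two-stage ectopy detector, daily burden aggregation with a
configurable alert, a scoring suite for validation studies, and a
synthetic single-lead ECG generator so that every stage is testable
without any external data.

## The two-stage detector

**Stage 1 — trigger.** Every detected beat is screened with cheap
interval and amplitude arithmetic.  Beat $i$ is a *candidate* when

$$\mathrm{prematurity}_i \;=\; \frac{RR_{i-1,i}}{\overline{RR}_{\mathrm{local}}} \le 0.88
\quad\text{or}\quad
\frac{|A_i|}{\tfrac12(|A_{i-1}|+|A_{i+1}|)} \notin [0.4,\,2.2],$$

where $\overline{RR}_{\mathrm{local}}$ is the mean of the trailing 8
RR intervals between non-candidate beats (so ectopy does not contaminate
its own reference).  The amplitude path exists because ventricular
ectopy is not strictly required to be premature — escape beats and
late-coupled ectopy still reach the morphology stage.  Runs of adjacent
candidates are tagged `single`, `couplet` or `triplet`; runs of four or
more are emitted untagged and excluded from PVC candidacy (longer runs
belong to tachyarrhythmia detectors, not a burden counter).  Candidates
whose defining RR intervals touch a marked noise interval are dropped,
which is the main defence against false positives from artifact.

One refinement proved necessary: after an *interpolated* ectopic beat the
next conducted beat arrives early relative to its predecessor, and a
naive prematurity test drags it into a spurious couplet.  A beat directly
following a candidate is therefore released from candidacy when its span
since the last non-candidate beat is a whole multiple of the local RR
(within `grid_tol`, default 12%) *and* its next interval resumes a normal
cycle — the signature of a conducted beat back on the sinus grid.

**Stage 2 — morphology.** An average-NSR QRS template (200 ms window
centred on the fiducial) is formed from the most recent 16 beats whose
flanking RR intervals sit within 12.5% of the local median and whose
correlation to the running average is at least 0.95; at least 8 such
beats are required, otherwise the template is *invalid* and candidates
are conservatively labelled non-PVC until the next attempt.  Formation is
attempted at a warm-up point (30 s) and every 2 hours thereafter,
matching device practice.

Each candidate is scored against the template with seven features:

| feature | meaning | PVC signature |
|---|---|---|
| `one_minus_cwa` | 1 − correlation waveform analysis (Pearson r at zero lag) | large |
| `one_minus_dcwa` | 1 − max r over ±10-sample alignment shifts | large |
| `prematurity` | $RR_{prev}/\overline{RR}$ | < 1 |
| `compensatory_ratio` | $RR_{next}/\overline{RR}$ | > 1 (compensatory pause) |
| `amp_ratio` | peak amplitude vs neighbours | often ≠ 1 |
| `slew_ratio` | max |dV/dt| vs template | high for wide ectopy |
| `width_ratio` | QRS duration estimate vs template | > 1 |

CWA is scale- and offset-invariant by construction, so electrode-contact
amplitude drift does not masquerade as morphology change.  DCWA's shift
convention is documented and tested: a positive shift means the beat
window's content is later than the template's; ties break to the smallest
magnitude, then negative.

Classification is a per-sequence-type L2-regularised logistic regression
(`single`, `couplet`, `triplet` each carry their own coefficients and
decision threshold) over the standardised features; the standardisation
constants live inside the model file so a deployed model is
self-contained.  The decision threshold is chosen to maximise F1 on a
held-out quarter of the training data, taking the midpoint of the optimal
plateau.  The default models shipped under `inst/extdata/models/` were
trained by `scripts/train_default_models.R` on a seeded synthetic corpus
spanning both PVC morphologies, heart rates 55–85 bpm, burdens 0–20%,
R amplitudes 300–800 µV, and atrial ectopy with and without aberrant
conduction; every model records its training seed and a data hash.

**Burden.** PVC-labelled beats (singles plus couplet/triplet members) are
summed and normalised by all detected beats in consecutive windows
anchored at the recording start (86 400 s by default), with an alert when
the percentage meets the configurable threshold (default 5%, the device
minimum).  A window with no detected beats reports an *undefined* burden,
never 0% — a dead signal must not read as healthy.  Removing sequence
detections can only lower the estimate, which is why couplet/triplet
support matters for patients whose ectopy clusters.

## Scoring

Detections are matched to reference PVC times one-to-one within ±150 ms.
The pairing maximises the number of matches and then prefers the nearest
detection; it is implemented as an earliest-free sweep over the interval
graph (optimal for this convex structure) with a nearest-in-time
refinement, and is verified in the tests against an exhaustive
optimal-assignment oracle — a plain greedy nearest-first pass provably
misses pairings in rare configurations.  Detections that fail to match a
usable reference but fall inside the window of an *excluded* reference
(fusion beats, ambiguous beats) count as neither true nor false
positives, following beat-by-beat scoring convention.

Reported metrics are sensitivity, PPV, F1, and a *modified* specificity
normalised by detected beats rather than adjudicated normals (appropriate
when beat sensing is validated separately); classical specificity is
available behind an argument.  Zero-denominator metrics are undefined
(`NA`), never 0 or 100, so empty patients cannot pollute cohort tables.
Cohort summaries come in three flavours: gross (pooled counts),
patient-average (unweighted mean over patients with defined values), and
a GEE-adjusted marginal proportion for clustered binary outcomes —
an intercept-only generalized estimating equation with binomial link and
exchangeable working correlation, moment estimators for dispersion and
correlation, and a robust sandwich CI back-transformed from the logit
scale.  The GEE implementation is written in the package (no GEE fitter
is among its dependencies) and is tested to 10⁻⁶ against an established
reference implementation on a frozen clustered fixture.  Burden agreement
is summarised by Pearson r plus Bland–Altman bias and 1.96·SD limits of
agreement, and patient-level threshold performance
(`threshold_metrics()`) classifies patients by estimated vs reference
burden; its `ref_threshold_pct` argument exists because "lowering the
threshold never lowers sensitivity" is only true when the
reference-positive set is held fixed.

## The synthetic generator

`simulate_record()` emulates the signal phenomena the detector must face,
not cardiac electrophysiology in full:

* **Beat layout.** Sinus beats with truncated-Gaussian RR jitter
  (default CV 4%); ectopic events scheduled with gamma-jittered gaps
  (shape 4) whose mean is solved numerically — including the clamping
  bias of the minimum 2-beat gap — so the realised V fraction matches the
  configured burden; an NSR lead-in (35 s) precedes ectopy so the first
  template can form, mirroring validation practice of prepending NSR to
  replayed episodes.  Singles arrive at `coupling_factor`·RR (default
  0.72) with a compensatory pause of 2·RR − coupling; sequences compress
  intra-sequence RR to 0.85 of the coupling interval; bigeminy alternates
  conducted and ectopic beats.
* **Morphology.** QRS-T prototypes are sums of Gaussians, giving exact
  analytic control of the amplitude, slew and width the classifier
  consumes.  The wide PVC is large, inverted and slow; the
  `narrow_projection` mode renders each PVC as a random blend between the
  NSR shape and a mildly distinct narrow prototype, because how strongly
  an ectopic depolarisation projects onto a single sensing vector varies
  beat to beat — at the low end it is genuinely indistinguishable from
  NSR, which is precisely the documented false-negative mode.
* **Atrial ectopy.** PACs come as singles, pairs and salvos with
  variable coupling (±10% around 0.80) and a post-episode pause drawn
  between a plain reset and a fully compensatory pause.  This timing
  overlap with ventricular ectopy is deliberate: it is the reason timing
  alone cannot separate PACs from NSR-like PVCs, and with
  `pac_aberrant = TRUE` the wide-QRS conduction makes PACs the classic
  false-positive source.
* **Noise.** Broadband bursts of configurable count, length and
  amplitude, plus a 4 µV measurement-noise floor.

What the generator does **not** emulate: atrial-fibrillation RR dynamics,
respiration and baseline wander, posture-change morphology shifts,
multi-focal PVC morphologies, and electrode noise with realistic spectra.
Passing tests therefore demonstrate algorithmic correctness and the
documented failure-mode directions under controlled conditions; they do
not certify clinical performance on real recordings, where all published
experience shows lower sensitivity and PPV than clean synthetic data
yields.

## Numerical and design choices

* Working rate 256 Hz, analysis band 0.5–40 Hz (stored-episode telemetry
  in this device class is band-limited to about 40 Hz); zero-phase
  Butterworth filtering so fiducials do not shift; cubic-spline
  resampling.  The device's true front-end is unpublished; these are
  declared, configurable stand-ins.
* Beat detection: 4–22 Hz energy envelope (low enough to keep the energy
  of wide, slow ectopic QRS — a 10–30 Hz band silently drops them), 120 ms
  smoothing, adaptive signal/noise peak tracking with a 200 ms refractory
  and a search-back pass.  The spec of this stage is deliberately modest:
  classification accepts external beat markers (`beats_from_annotations`)
  bit-exactly, which is also how public-database protocols are run.
* Noise marking operates on the *raw* signal (the 45–100 Hz power-fraction
  rule is blind after band-limiting); 1 s windows, merged below 0.5 s
  gaps; beats inside noise are kept but flagged, and the trigger refuses
  candidates whose intervals touch noise.
* All times are seconds from record start; all amplitudes µV; WFDB
  physical units are converted on read.
* Problem sizes in the tests and acceptance script — 300–1200 s records,
  a 20-patient cohort at 600 s each, 1000 matching-oracle instances —
  were chosen to give stable statistics (hundreds of ectopic beats per
  estimate) while keeping a full run in tens of seconds.

## Known limitations

* Sensitivity and PPV on clean synthetic records approach 100% — real
  single-vector recordings will not.  The stressors (aberrant PACs,
  narrow projections, noise bursts) probe directions, not clinical
  magnitudes.
* The GEE implementation is intercept-only (marginal proportions with
  cluster-robust CIs), which is all the scoring suite needs; it is not a
  general regression fitter.
* Episode-level scoring of ventricular runs (VT/VF) is out of scope; runs
  of ≥ 4 candidates are logged and excluded from burden.
* Paced rhythms are not modelled or detected; validation studies in this
  device class exclude paced patients.
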