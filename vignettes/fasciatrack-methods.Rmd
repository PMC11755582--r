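---
title: "Measuring abdominal muscle activation from B-mode ultrasound video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring abdominal muscle activation from B-mode ultrasound video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Segmental stabilization exercises train patients to contract the
transversus abdominis (TrA) — the deepest lateral abdominal muscle —
selectively, without co-contracting the overlying internal (OI) and
external (OE) obliques. In a B-mode ultrasound image of the lateral
abdominal wall the three muscles appear as darker bands separated by
four bright fasciae, and a muscle's thickness is the distance between
its bounding fasciae. Whether a contraction was *selective* is
quantified by the preferential activation ratio

$$\mathrm{PAR} \;=\; \frac{TrA_C}{TrA_C+OI_C+OE_C} \;-\;
  \frac{TrA_R}{TrA_R+OI_R+OE_R},$$

the change in the TrA's share of the total three-muscle thickness from
rest ($R$) to contraction ($C$). PAR is dimensionless, lies in
$(-1, 1)$, is invariant to rescaling all six thicknesses (so it is
insensitive to calibration error), and is zero when all muscles thicken
proportionally. Positive values indicate preferential TrA activation.

`fasciatrack` implements the full measurement chain from a calibrated
frame stack to the PAR and the group statistics used in a two-arm
biofeedback comparison, plus a synthetic video generator so that every
stage can be validated end-to-end without clinical recordings.

## Pipeline

### Initial frame and fascia segmentation

One frame is segmented first: the frame with the highest mean Sobel
gradient magnitude, i.e. the frame on which the fascia interfaces are
sharpest. Ties break to the lowest index so that runs are reproducible.

The four fasciae are extracted by a Viterbi-style dynamic program that
finds, per fascia, the left-to-right path (one row per column,
$|\Delta\text{row}| \le$ `max_vertical_step` per column) maximizing

$$\sum_j I(r_j, j) \;-\; \texttt{step\_penalty}\cdot\sum_j |r_j - r_{j-1}|.$$

The source this stage follows describes only "brightest paths"; the
penalized max-sum objective is the minimal concrete reading, with the
step penalty (default 2 brightness units per pixel of vertical step)
discouraging jagged detours through speckle maxima. The image is
pre-smoothed with a small Gaussian ($\sigma$ = 1 px) before the DP.
Four paths are extracted sequentially by descending score; after each
acceptance a band of `exclusion_halfwidth` (default 6) pixels around
the path is masked, which both forces the next path onto a different
fascia and makes crossings impossible. The accepted paths are reordered
top to bottom and an order-preserving projection (sort per column,
minimum separation 1 px) guarantees the strict ordering invariant. All
tie-breaks are deterministic: smallest row, then smallest column, then
smallest frame index.

The automatic result can be replaced per boundary by an operator
correction file (JSON polylines); corrections are re-validated against
the ordering invariant and rejected with the offending columns named.
This mirrors the operator-review step of a semi-automated workflow
without requiring a GUI.

### Propagation and point tracking

The initial segmentation is carried to every other frame by optical
flow, and three measurement points per muscle — placed on the muscle's
upper fascia at 40 %, 50 % and 60 % of the segmented column range — are
tracked with a pyramidal Lucas–Kanade solver (default 21 px window,
3 levels).

For every frame the *reference* is the best-correlated
already-segmented frame (zero-normalized cross-correlation over the
segmentation's bounding region), not necessarily the direct
predecessor; with several keyframes each frame is matched to the one it
resembles most, which stabilizes recordings where the probe returns to
a previous pose. Additional keyframes can be supplied for difficult
videos, and per-video parameter overrides are echoed into the run
manifest for provenance.

Three named tracker parameters deserve definition, since the
parametrization they originate from is not fully specified:

* `sigma` (default 0.04) — the tracker's Gaussian pre-smoothing scale,
  expressed as a fraction of the window size (0.04 × 21 ≈ 0.84 px).
* `fgs_lambda` (default 5000) and `fgs_sigma` (default 3) — the
  regularization strength and edge sensitivity of a 1-D fast global
  smoother applied to the vertical displacement samples along each
  boundary before interpolation: it minimizes
  $\sum_i (x_i - y_i)^2 + \lambda \sum_i w_i (x_i - x_{i+1})^2$ with
  $w_i = \exp(-|\Delta I_i| / \texttt{fgs\_sigma})$, so smoothing
  relaxes across brightness edges.

Boundary propagation samples each polyline every 16 columns, tracks the
samples into the target frame, post-filters the vertical displacements
with the smoother above, applies the median lateral shift, and
re-imposes the ordering invariant. Implementation note: frames are
solved outward from their reference keyframe and each solve is
warm-started from the adjacent, already-solved frame. The template is
always the keyframe's, so the warm start is purely a solver
initialization and cannot accumulate drift; it is what keeps 100-frame
videos tractable in pure R. Points that diverge or leave the image are
flagged `lost`, never silently dropped.

### Thickness, contraction phase, summaries

Thickness is measured **vertically** — down the image column through
the tracked point on the muscle's upper fascia to the muscle's lower
boundary — times the pixel spacing (mm/px). The vertical convention is
the common choice in rehabilitative ultrasound and is well defined for
polyline boundaries; a perpendicular-to-fascia convention would differ
by $\cos\theta$ of the local fascia tilt, negligible for the nearly
horizontal fasciae of a properly positioned probe.

The contraction phase is detected on the 3-point mean TrA trace:
smooth with a 5-frame moving median; baseline = median of the first
15 % of frames; the contracted interval is the longest run that starts
where the smoothed trace reaches baseline + 0.5 × (peak − baseline) and
continues while it stays above baseline + 0.3 × (peak − baseline)
(hysteresis prevents chatter around the threshold). A flat trace yields
an empty interval with a warning, not an error. All four parameters are
exposed; no claim is made that this reproduces any particular published
detector, which is why it is configurable. Rest defaults to the frames
*before* the contraction (`rest_mode = "pre"`); pooling pre- and
post-contraction rest is available (`rest_mode = "all"`).

Per muscle, the three points are averaged per frame first, then the
per-frame means are averaged over each phase's frames — fixing an order
of operations that matters for ratios. A (frame, muscle) needs at least
one valid point and a phase at least 50 % valid frames; below that the
run errors rather than quietly degrading, making quality gating
explicit where a clinical workflow would rely on operator judgment.

### PAR aggregation and statistics

Per repetition, the six phase summaries give one PAR. Cohort tables
aggregate **means of PARs** (per participant, then across
participants), never the PAR of mean thicknesses — the two differ
because PAR is a nonlinear function of the thicknesses (with the
bundled default script the PAR of group-mean thicknesses is ≈ 0.014
while a cohort's mean PAR can be ≈ 0.025).

The statistics mirror a two-group repeated-measures design:

* `rm_anova()` — mixed-design ANOVA (within: repetition; between:
  group) by the classical sums-of-squares decomposition, reporting F,
  df, p and partial $\eta^2$ for the group, repetition and
  group × repetition effects. The group × repetition interaction is the
  "group-related" test whose df shape, $F(k-1,\ (n-g)(k-1))$, matches
  the reported form of such studies. Zero-variance effects return
  F = 0, p = 1 rather than 0/0.
* `mauchly_test()` — sphericity of the within-subject contrasts
  (pooled within-group covariance, df $n-g$), $\chi^2$ approximation,
  df $k(k-1)/2 - 1$; $k = 2$ is trivially spherical (W = 1, flagged).
  When Mauchly's p ≤ 0.05 the Greenhouse–Geisser correction is applied
  automatically to the within-subject tests (the branch exists and is
  exercised even though a well-behaved cohort will not trigger it).
* `paired_t()` — paired t with Cohen's $d = \bar{d}/s_d$; zero-variance
  differences are an error, not an infinite t.
* `mann_whitney_u()` — U reported as min(U₁, U₂); exact two-sided p by
  complete enumeration of rank assignments for small untied samples,
  otherwise the normal approximation with tie and continuity
  correction.
* Report tables use t-based 95 % CIs (the study's CI flavor is not
  stated; t-based is the conservative default for n ≈ 12 and is
  documented here). Single-observation cells flag SD/CI as undefined.
* A nonparametric path is an explicit caller choice, never
  auto-selected from a normality test, to keep reruns reproducible.

## The synthetic generator: what it emulates, what it does not

`generate_video()` renders a stated world: three piecewise-constant
tissue bands (intensities 40–50 on a background of 30) bounded by four
bright fasciae (Gaussian cross-profile, peak 200, width 3 px),
multiplicative exponential speckle (`speckle_scale` 0.3), a 1 px
Gaussian point-spread blur, and 8-bit quantization. The speckle field
is drawn **once per video in tissue coordinates** and translated with
the scripted drift, because real speckle arises from tissue-attached
scatterers and moves with the tissue; per-frame independent noise would
"twinkle" and bias any tracker. Contraction deformation does not warp
the noise field — an accepted approximation.

Scripted defaults are the rest/contracted group means of an abdominal
draw-in maneuver in older adults (TrA 4.61 → 5.44 mm, OI 9.34 →
10.57 mm, OE 5.22 → 5.40 mm), giving an analytic PAR of 0.0136.
Free choices neither the imaging hardware nor the exercise protocol
pins down, fixed once: 30 Hz frame rate and 100 frames (≈ 3.3 s: 1 s
rest, 0.5 s ramp up, 1 s hold, 0.5 s release — a plausible single
repetition), 256 × 384 px at 0.1 mm/px (a 26–38 mm field typical of a
linear probe at abdominal depth), and a 3 mm standoff to the first
fascia (thin subcutaneous layer; the 21.4 mm muscle stack must fit the
image). Ground-truth phase labels binarize the continuous activation at
its half-rise point — the standard onset convention, and the only
two-label truth consistent with a ramped profile.

The generator does **not** emulate: attenuation and depth-dependent
gain, acoustic shadowing, refraction, out-of-plane motion, fan-beam
geometry, or the image degradation of standing-posture scanning. A
green test on synthetic data therefore establishes that the algorithms
recover what they model — boundaries, displacement, thickness, PAR —
under speckle and drift; it does not establish clinical-grade
robustness to artifacts the generator omits.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inside R (native matrix indexing); every
  on-disk artifact (segmentation JSON, tracks/trace CSV) is 0-based
  with half-open column ranges. Conversion happens only at the I/O
  boundary.
* Determinism: a single integer seed fixes a video; the RNG state is
  restored after generation. Re-running the pipeline with the same
  config and seed is bit-identical, and the run manifest records an
  MD5 per output file.
* Degenerate inputs fail loudly and specifically: non-positive
  thickness or spacing, crossing corrections (with column indices),
  images too short for four separated paths, zero-variance frames in
  the correlation (undefined), all-points-lost frames, empty phases.
* LK windows are clamped at the image border; a point whose content
  leaves the field of view is only trustworthy until its window hits
  the border, and divergent points are flagged.

## Known limitations

Pure-R throughput is roughly 1 s of video per 10–15 s of compute at
default resolution; the warm-start scheme above is what keeps that
practical. The contraction detector assumes one dominant contraction
per recording (the longest super-threshold run); repetitions must be
split upstream. Thickness is vertical, not fascia-normal. The
Viterbi cost is a documented stand-in for an incompletely specified
published variant, as is the exact meaning of the tracker's named
parameters.
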