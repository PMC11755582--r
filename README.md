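# fasciatrack

Semi-automated muscle tracking and thickness measurement for B-mode
ultrasound video of the lateral abdominal wall.

Physiotherapy for chronic low back pain trains patients to contract the
transversus abdominis (TrA) selectively, without co-contracting the
overlying internal (OI) and external (OE) obliques. Rehabilitative
ultrasound imaging shows all three muscles as dark bands between four
bright fasciae, so exercise quality can be quantified by measuring each
muscle's thickness at rest and during contraction and computing the
preferential activation ratio

```
PAR = TrA_C / (TrA_C + OI_C + OE_C)  -  TrA_R / (TrA_R + OI_R + OE_R)
```

(the change in the TrA's share of the total three-muscle thickness;
positive = preferential TrA activation). `fasciatrack` is for motion
scientists and biomedical-imaging researchers who need this measurement
chain reproducible and testable end-to-end:

* **Segmentation** — initial-frame selection by Sobel edge energy, then
  Viterbi brightest-path extraction of the four fasciae, with a
  file-based operator-correction step.
* **Tracking** — optical-flow propagation of the segmentation to every
  frame and pyramidal Lucas–Kanade tracking of three measurement points
  per muscle, with correlation-based reference-frame selection.
* **Measurement** — calibrated thickness traces, automatic
  contraction-phase detection (baseline + relative threshold with
  hysteresis), rest/contracted summaries, PAR.
* **Statistics** — mixed-design repeated-measures ANOVA with Mauchly's
  sphericity test and an automatic Greenhouse–Geisser branch, paired
  t-tests with Cohen's d, Mann–Whitney U (exact for small samples), and
  study-style report tables.
* **Synthetic data** — a seeded generator of B-mode-like videos (bright
  fasciae, tissue-attached multiplicative speckle, scripted
  contraction, optional drift) with exact ground truth, so every stage
  above is validated without clinical data.

## Worked example

Simulate a draw-in maneuver scripted with realistic group-mean
thicknesses (TrA 4.61 → 5.44 mm, OI 9.34 → 10.57 mm, OE 5.22 →
5.40 mm), then run the full measurement chain:

```r
library(fasciatrack)

script <- contraction_script()          # the ADIM-like default
sim <- generate_video(script, seed = 42)
m <- measure_video(sim$video)

m$summary
#>   muscle  rest_mm contracted_mm n_rest_frames n_contracted_frames
#> 1     OE 5.248356      5.379888            36                  49
#> 2     OI 9.401298     10.412564            36                  49
#> 3    TrA 4.599772      5.327155            36                  49
sprintf("estimated PAR = %.4f (scripted PAR = %.4f)", m$par, sim$truth$par)
#> [1] "estimated PAR = 0.0133 (scripted PAR = 0.0136)"
```

The rest and contracted columns are the phase means of the three-point
muscle thicknesses in mm; the PAR estimated from video is within 0.001
of the script's analytic value. On a cohort table (one PAR per
participant × repetition) the statistics stage reproduces the usual
two-group workflow:

```r
set.seed(1)
cohort <- simulate_par_cohort(n_per_group = 12)   # no group effect
rm_anova(cohort)
#> mixed-design repeated-measures ANOVA
#>            effect df1 df2          F         p partial_eta_sq
#>             group   1  22 0.09352763 0.7626146    0.004233259
#>        repetition   2  44 0.55490180 0.5780938    0.024602271
#>  group:repetition   2  44 0.16140552 0.8514485    0.007283181
#> Mauchly W = 0.9161, chisq(2) = 1.839, p = 0.3987
```

A command-line front end (`inst/cli/fasciatrack`) exposes
`simulate | segment | track | measure | par | stats | run-all`, and
`run_pipeline()` writes every stage output plus a manifest with config
echo, seed and per-file MD5 hashes.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the installed package end-to-end — it simulates a default
scripted recording, measures it through segmentation, tracking, phase
detection and PAR, and runs the cohort statistics on a simulated
two-group study — then writes the JSON report to `--out`.
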