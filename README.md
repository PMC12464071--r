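# vplearn

Simulation and analysis of visual perceptual learning (VPL) experiments.

VPL studies train observers on a peripheral two-alternative forced-choice
task — here, judging whether a briefly flashed Gabor grating is tilted
clockwise or counterclockwise of a 45° reference — and ask how much
orientation-discrimination thresholds improve with practice and how far the
improvement transfers to untrained retinal locations. A key experimental
manipulation is trial-by-trial randomization of a task-irrelevant stimulus
dimension (spatial phase vs. Michelson contrast) during training; the two
kinds of variability produce different spatial generalization, which is the
effect this tool chain measures.

`vplearn` is aimed at psychophysicists who want a tested, scriptable
implementation of that measurement and analysis chain:

- **Stimulus model** — Gabor rendering
  `L = L_bg [1 + c·exp(-(x²+y²)/2σ²)·cos(2πf(x cosθ + y sinθ) + φ)]`,
  phase/contrast randomization schemes, Michelson contrast.
- **Adaptive staircases** — 3-down-1-up transformed up-down tracks with
  multiplicative `10^±0.05` steps (convergence point
  `P(correct) = 0.5^(1/3) ≈ 0.794`), two interleaved staircases per block,
  thresholds from the mean of reversals 5–10, invalid blocks flagged.
- **Learning statistics** — learning index `LI = (post − pre)/pre`,
  learner exclusions, power-law learning curves `T(b) = a·b^(−β) + c`,
  Welch t-tests with Cohen's d, Pearson correlation tests, one-sided Fisher
  r-to-z comparison of independent correlations
  `z = (atanh r₁ − atanh r₂)/√(1/(n₁−3) + 1/(n₂−3))` with Cohen's q, and
  partial η² = F·df₁/(F·df₁ + df₂).
- **ART mixed ANOVA** — aligned-rank-transform preparation of the
  `Threshold ~ Time*Randomization*Location*TrainingLocation + (1|Subject)`
  factorial, per-term F tests (exact split-plot ANOVA on balanced tables,
  lme4 Wald F with containment df otherwise), and ART-C post hoc contrasts.
- **Eye movements** — blink masking (−100/+150 ms), trial segmentation
  (−200/+350 ms), velocity-threshold microsaccade detection (5-sample
  velocity kernel, robust median-based λ = 6 threshold, ≥ 6 ms duration,
  10 ms merge, < 1 dva amplitude), microsaccade rate/percentage, fixation
  variability, amplitude–velocity main sequence.
- **Synthetic data** — Weibull 2AFC observers pinned to the staircase
  convergence point, full learning cohorts with group-specific transfer-LI
  correlation structure, and 1000-Hz gaze traces with drift, blinks, and
  minimum-jerk microsaccades with ground truth.

## Worked example

Simulate a cohort with the built-in "paper-like" preset (29 subjects in four
randomization × training-location groups, transfer-LI correlation 0.7 in the
phase group and 0 in the contrast group), then run the full report:

```r
library(vplearn)
set.seed(42)
sim    <- simulate_cohort(cohort_spec("paper-like"))
report <- vpl_report(sim$cohort)
report
```

```
== Cohort report ==
Subjects: 29 total, 21 retained (criterion LI <= -0.20)

Group mean learning indices:
 randomization li_training       li_C       li_F
      contrast  -0.3528770 -0.3206340 -0.2323566
         phase  -0.4120448 -0.4637439 -0.4095862

Transfer-LI correlations (C vs F):
  contrast: r = 0.067, t(9) = 0.200, p = 0.8459
  phase: r = 0.772, t(8) = 3.431, p = 0.0089
Fisher r-to-z: r1 = 0.772 (n = 10) vs r2 = 0.067 (n = 11)
  z = 1.8505, one-sided p = 0.0321, Cohen's q = 0.958

Aligned-rank-transform ANOVA (lmer; Wald F, between-within df)
                 term       F df1 df2        p eta2p
                 Time 782.458   1 337 7.29e-90 0.699
        Randomization   2.768   1  17 1.14e-01 0.140
   ...
   Time:Randomization:Location   2.892   2 337 5.69e-02 0.017
   ...
```

Reading the output: both groups learned (mean training-location LI ≈ −0.35
to −0.41, i.e. 35–41% threshold improvement); learning indices at the two
transfer locations correlate strongly in the phase-randomized group
(r = 0.77) but not in the contrast-randomized group (r = 0.07), and the
one-sided Fisher r-to-z test says that difference is itself significant
(p = 0.032) with a large effect (q = 0.96). The ANOVA table gives the
per-term aligned-rank F tests; `Time` is the (huge) overall learning
effect, and `Time:Randomization:Location` is the differential-transfer
interaction.

The eye-movement chain works the same way on gaze traces:

```r
set.seed(7)
s  <- simulate_trace(trace_spec())           # 1000-Hz trace + ground truth
ev <- detect_microsaccades(mask_blinks(s$trace))
main_sequence(ev)                            # amplitude-velocity correlation
```

A thin command-line wrapper over the same functions ships in
`inst/cli/vpl` (subcommands `simulate`, `threshold`, `li`, `art-anova`,
`detect-ms`, `report`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end pipeline from scratch at the given
seed: it simulates a paper-like cohort, extracts block and subject
thresholds, applies the exclusion rule, computes group learning indices,
the per-group transfer-LI correlations and their Fisher r-to-z comparison,
runs the full aligned-rank-transform ANOVA, and runs the microsaccade
detector over synthetic gaze traces, printing the combined report and
writing the JSON result file.

See `vignettes/vplearn-methods.Rmd` for the model, the stated synthetic
world and its rationale, numerical choices, and known limitations
(including an honest analysis of the detection power available at the
stated world).
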