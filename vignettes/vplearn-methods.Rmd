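---
title: "Measuring and analysing visual perceptual learning with vplearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and analysing visual perceptual learning with vplearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vplearn)
```

## The problem

Visual perceptual learning (VPL) experiments train observers on a
two-alternative forced-choice (2AFC) discrimination — here, whether a
briefly flashed peripheral Gabor grating is tilted clockwise or
counterclockwise of a 45° reference — and ask how much thresholds improve
with practice and how far that improvement *transfers* to untrained retinal
locations. A central experimental idea is to randomize a task-irrelevant
stimulus dimension (spatial phase, or Michelson contrast) from trial to
trial during training and compare the spatial generalization produced by the
two kinds of variability. `vplearn` implements that measurement and analysis
chain end to end, together with a synthetic observer/cohort/gaze generator
so every stage is testable without any experimental data.

## Stimulus model

A stimulus is a Gabor: a sinusoidal luminance carrier under an isotropic
Gaussian envelope on a uniform background,

$$L(x,y) = L_{bg}\left[1 + c\, e^{-(x^2+y^2)/2\sigma^2}
  \cos\!\big(2\pi f (x\cos\theta + y\sin\theta) + \phi\big)\right].$$

Defaults: 2 dva aperture, $f = 2.5$ cpd, $\sigma = 0.28$ dva,
$L_{bg} = 52.42$ cd/m², reference orientation 45°. Conventions fixed here:
0° is a vertical carrier, angles grow clockwise modulo 180°; phase is
measured at the envelope center and sampled on the half-open interval
[0°, 180°) in the phase-randomized condition (0° and 180° are sign flips of
each other, so the endpoint choice is immaterial but must be fixed);
contrast randomization draws uniformly from [0.33, 0.66] at fixed 0° phase.
Luminance is clipped at zero; no display gamma model is applied.

The nominal contrast $c$ is the *carrier* contrast. The Michelson contrast
measured on the rendered map is strictly smaller whenever the envelope is
narrow relative to the carrier period, because the nearest carrier trough
(0.2 dva off-center at 2.5 cpd) is attenuated by the envelope (factor 0.775
at $\sigma = 0.28$): for $c = 0.45$ the rendered map measures ≈ 0.376. The
tests pin this analytically derived value; the measured contrast equals the
nominal one only in the flat-envelope limit.

## Staircase and threshold extraction

Difficulty (the unsigned orientation offset from 45°) is driven by a
3-down-1-up transformed up-down rule with multiplicative steps of
$10^{\pm 0.05}$: three consecutive correct responses divide the offset by
$10^{0.05}$, any error multiplies it. The rule converges on the stimulus
level with $P(\text{correct}) = 0.5^{1/3} \approx 0.794$. Each block
interleaves two staircases (starting offsets 1° and 3°) by a per-trial
uniform random choice among unfinished staircases — "interleaved" is not
otherwise specified, and random interleaving avoids predictability while
remaining reproducible under a seed. A block ends when every staircase has
10 reversals or after 200 trials. Reversal levels are recorded at the trial
that triggers the direction change. Per staircase, the first 4 reversals are
discarded and the next 6 averaged; reversals beyond the 10th (over-collected
blocks) are ignored so the estimator is identical across blocks. The block
estimate averages the qualifying staircases; blocks where no staircase
reaches 10 reversals are flagged invalid and dropped. A
`pool_staircases` switch instead concatenates the two staircases' reversal
lists before the discard/average step, for sensitivity analyses.

Two properties of this estimator are worth knowing. First, the measurement
noise of a block estimate is roughly log-normal with a log-SD of about
0.12–0.17 for thresholds between 1° and 5°. Second, the estimator is biased
downward when the true threshold sits far above both starting offsets
(≈ −8% at 3°, ≈ −19% at 5° with starts at 1° and 3°), because the early
reversals collected on the way up are below the converged level and the
200-trial cap limits recovery. The bias is a property of the stated
procedure — a real experiment with these settings has it too — and it is
why the threshold-recovery tolerance is ±25%.

## Learning statistics

Learning is quantified by the learning index
$\mathrm{LI} = (T_{post} - T_{pre})/T_{pre}$ (negative = improvement),
computed on subject-level mean thresholds (mean over the valid blocks of a
location × session cell; block-level data are retained for the mixed model).
Subjects whose training-location LI is weaker than −0.20 (less than 20%
improvement) are excluded; −0.30 reproduces the usual robustness check. The
sign convention treats "an LI of 20% or worse" as *improvement weaker than
20%*, i.e. exclusion when $\mathrm{LI} > -0.20$.

Group comparisons use Welch's t-test with pooled-SD Cohen's d (the
conventional effect-size default; a Welch-denominator variant is
available). Transfer structure is summarized by the Pearson correlation
between C-transfer and F-transfer LIs within each randomization group, and
the two groups' correlations are compared with a one-sided Fisher r-to-z
test,

$$z = \frac{\operatorname{atanh} r_1 - \operatorname{atanh} r_2}
  {\sqrt{1/(n_1-3) + 1/(n_2-3)}},
  \qquad q = |\operatorname{atanh} r_1 - \operatorname{atanh} r_2|,$$

with Cohen's q as the effect size. Learning curves over training blocks are
fitted by $T(b) = a\,b^{-\beta} + c$ with $a \ge 0$, $\beta \ge 0$,
$c \ge 0$; the model is linear in $(a, c)$ at fixed $\beta$, so the fit
profiles $\beta$ (coarse grid plus golden-section refinement) with exact
linear least squares inside — this recovers noise-free parameters to
near machine precision and cannot diverge. A two-parameter variant pins
$c = 0$.

## Aligned rank transform ANOVA

The factorial analysis follows the aligned-rank-transform (ART) recipe on
the block-level table `threshold ~ Time * Randomization * Location *
TrainingLocation + (1 | Subject)`. For each of the 15 fixed terms the
response is *aligned* — the full-factorial cell mean is subtracted and the
target term's estimated effect (inclusion–exclusion over unweighted marginal
means of the cell means) is added back — then midranked, and the full model
is refitted to the ranks; only the target term is read from its own fit.
On data containing only non-target effects the aligned values are constant,
and with a single factor ART reduces exactly to ANOVA on plain ranks.

Alignment uses fixed-effect cell means of the raw response; the subject
intercept is handled by the model fitted to the ranks, not removed
beforehand. Subtracting subject means before alignment would annihilate the
purely between-subject terms (Randomization, TrainingLocation and their
interaction are constant within a subject), leaving those tests powerless,
and would break the one-factor equivalence above — so the package
deliberately aligns on the raw response.

Two engines produce the per-term F tests. On balanced split-plot tables
(equal cell counts, equal group sizes) the classical repeated-measures
ANOVA with an `Error(Subject)` stratum is exact and fast and is the
default. Otherwise a linear mixed model with a subject random intercept is
fitted (lme4), the term is tested by a Wald F on its sum-coded
coefficients, and the denominator degrees of freedom follow the classical
between–within (containment) rule: $n_{subj} - g$ for between-subject
terms, $N - \operatorname{rank}(X) - (n_{subj} - g)$ for within terms. The
Kenward–Roger correction used in the original analysis chain is not
available in this environment; the containment df are exact in the balanced
case and differ from Kenward–Roger only modestly at these sizes (e.g. 483
vs ≈ 469 denominator df for a 29-subject design), and the df method is
recorded in the output. No multiplicity correction is applied across the 15
terms, mirroring common reporting practice. Type-I error of the whole
procedure is verified by simulation from the model (subject intercepts plus
i.i.d. noise): all 15 terms reject at 0.05 ± 0.02 over 1000 replicates.

Post hoc contrasts use the concatenate-and-align variant (ART-C): the
response is aligned to the cells of the combined factor of interest,
midranked, and a cell-means mixed model `rank ~ 0 + cell + (1 | Subject)`
is fitted; the contrast (weights summing to zero over cells) is tested by a
t statistic with containment df, and Cohen's d is reported as
$2t/\sqrt{df}$ (the two-group equal-n conversion).

## Eye-movement analysis

Gaze traces are 1000-Hz samples in screen-centered degrees of visual angle
(x rightward, y upward, upper visual field = positive y). Blinks come from
the trace's validity channel; samples from 100 ms before to 150 ms after
each blink are masked, with the original blink runs kept in a separate
column so masking is idempotent. Trials are cut from 200 ms before
reference onset to 350 ms after test-grating offset; a trial containing any
blink is excluded from microsaccade-percentage denominators.

Microsaccades are detected by the velocity-threshold method: 2-D velocities
from a 5-sample centered difference, candidates as maximal runs above a
per-trial threshold lasting ≥ 6 ms, merging of candidates separated by
< 10 ms (merging, not discarding, preserves the event energy), and a 1-dva
amplitude cutoff. Amplitude is the componentwise range combined in
quadrature; peak velocity is the maximal speed in the event. The default
threshold is the robust median-based estimator of the classical algorithm,
$\eta_{x,y} = \lambda \sqrt{\operatorname{median}(v^2) -
\operatorname{median}(v)^2}$ with $\lambda = 6$ and an elliptic criterion.
A literal "mean + 6 SD of the trial's speed" variant is available but is
*not* the default: the saccades themselves inflate the trial's mean and SD,
which clips detected events (a 0.5-dva event measures ≈ 0.38 dva), lets
oversized events slip under the amplitude cutoff, and misses small events
outright; the robust estimator is what the cited detection algorithm
actually uses.

Summaries follow the definitions used in this literature: the
microsaccade *rate* is the average number of event onsets per 1-ms bin
across trials times the 1000-Hz sampling rate; the microsaccade
*percentage* divides the event count in a window (reference, test, or whole
trial) by the number of blink-free trials; *fixation variability* is the
across-trial SD of each trial's mean gaze-to-fixation distance during
stimulus presentation (union of the reference and test windows by default;
each window is selectable); and the amplitude–velocity *main sequence* is
the Pearson correlation between event amplitudes and peak velocities.

## The synthetic world

The generator states one world and the tests measure the pipeline against
it; none of its parameters were adjusted after seeing test outcomes.

**Observer.** A Weibull 2AFC observer,
$P(\text{correct} \mid x) = 0.5 + (0.5 - \lambda)\,
[1 - e^{-(x/s)^\beta}]$, sign-blind, with the scale $s$ solved so accuracy
at $x = \alpha$ is exactly $0.5^{1/3}$ — this pins $\alpha$ to the
staircase's convergence point, so staircase estimates are directly
comparable to $\alpha$. Defaults $\beta = 2$, lapse 0.02.

**Cohort.** Four groups (phase/contrast × UVF/LVF training) with a
realistic analysed-sample layout (6 + 7 phase, 8 + 8 contrast subjects).
Pre-training thresholds are log-normal with median 4.0°
at every location — the three locations are iso-eccentric at 6°, so their
expected difficulty is equal — decomposed into a subject ability factor
(log-SD 0.25) shared across locations plus a small location-specific
deviation (log-SD 0.10). A shared ability factor is what makes one
observer's thresholds correlate across nearby locations; making the
location deviations dominant would instead inject a large subject ×
location variance that the analysis model (subject intercept only) never
claims to absorb. Learning indices are normal with SD 0.15 around group ×
location mean improvements of, in degrees, 1.53 / 1.70 / 1.99 at
training / C / F for the phase group and 1.40 / 1.50 / 1.31 for the
contrast group (the C-transfer values interpolate between their
neighbours), and the (C, F) pair is drawn bivariate-normal with
correlation 0.7 in the phase group and 0 in the contrast group — the
differential transfer structure the preset exists to emulate. An LI SD of
0.15 is a typical between-subject spread for such studies and, after
staircase measurement noise attenuates the observed correlation
($\approx 0.85 \times$), keeps the phase group's *observed* transfer
correlation near 0.7. Post thresholds are
$T_{pre}(1 + \mathrm{LI})$, resampled (bounded retries) if nonpositive.
Block thresholds then come from actual staircase runs against the evolving
observer (learning is applied between sessions only; a training-session
mode decays the threshold along a power law across the 20 training blocks
for learning-curve fits). A `method = "direct"` shortcut replaces the
staircase runs by log-normal measurement error (log-SD 0.15, matching the
measured spread of staircase estimates) for fast calibration studies.

**Gaze traces.** Fixational drift is a random walk (step SD 0.002
dva/sample ≈ 1 dva/s drift speed) plus white measurement noise (SD 0.005
dva, a high-precision video tracker). Microsaccades arrive as a Poisson
process (1.5 Hz) with an 80-ms refractory gap; amplitudes are log-normal
(median 0.3 dva, log-SD 0.4) truncated to [0.05, 1) dva; displacement
follows a minimum-jerk profile whose peak velocity obeys the main sequence
$v_{peak} = 100\,A\,(1+\varepsilon)$ with 10% relative noise — the
minimum-jerk identity $v_{peak} = 1.875\,A/T$ then fixes each event's
duration. Blinks occur in 5% of trials and last 100–300 ms.

**What a green test does not establish.** The generator draws learning
indices directly from the assumed bivariate-normal structure; it contains
no attention, adaptation, or session-order effects, no response-time
structure, no fixation-break aborts, and its gaze noise is stationary.
Green tests certify that the pipeline recovers what the stated world put
in — not that the world is the one that produced any real dataset.

## Power at the stated world (an honest red)

The acceptance suite asks the built-in time × randomization × location
interaction to be detected (p < 0.05) in at least 80% of paper-like
replicates. At the stated world the measured power is ≈ 0.6 (0.59 over the
suite's 100 replicates), and the criterion is left red rather than met by
tuning. The arithmetic: the
interaction is carried almost entirely by the differential F-transfer
improvement (1.99° vs 1.31°, a 0.68° group difference), tested against
between-subject LI variability (SD 0.15 ≈ 0.6° on a 4° baseline) with 13
vs 16 subjects, plus staircase measurement noise. A subject-level t-test on
that difference has $d \approx 0.9$ and power ≈ 0.6 at $\alpha = 0.05$;
the rank-transformed block-level mixed model sits in the same range. An
experiment of this size observing the built-in effect would typically
report this interaction with a p-value in the few-percent range — single
observations compatible with power near one half. Reaching 80% would
require either shrinking the LI spread or inflating the group difference
well beyond the stated effect sizes, i.e. moving the generator away from
the world it is supposed to emulate. The correlation-recovery and calibration clauses of the same
criterion pass.

## Numerical and degenerate-input choices

Ranks use midranks for ties. Degenerate observers (always right/wrong)
produce zero reversals and invalid blocks, flagged rather than raised.
Welch tests refuse samples whose variances are both zero; correlation tests
refuse zero-variance inputs and flag $|r| = 1$ (infinite t) with a warning.
`partial_eta_sq` is the identity $F \cdot df_1/(F \cdot df_1 + df_2)$.
Power-law fits are flagged, not raised, on non-convergence. Gabor rendering
refuses grids below the Nyquist rate ($4 f$ pixels/deg). Microsaccade
detection returns an empty event table when fewer than 20 valid samples are
available, and velocity samples whose 5-sample kernel touches an invalid
sample are excluded. Transfer-location geometry is configured by polar
angles rather than hard-coded chord distances, because the printed
inter-location distances (5° adjacent, 11.5° training-to-F) are not jointly
realizable on a single 6°-eccentricity arc; distances should be recomputed
from the configured angles.

## Session info

```{r}
sessionInfo()
```
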