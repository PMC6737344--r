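---
title: "Correlation neurofeedback: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation neurofeedback: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfcoupling)
```

This vignette is the package's own account of the science it implements:
what is being modelled, which parameters matter and why they default as
they do, what the synthetic generator does and does not emulate, and where
the design was genuinely open.

## The feedback signal

The quantity fed back is not regional activation but *coupling*: the
Pearson correlation between the mean BOLD signals of two regions of
interest — the right anterior superior temporal lobe (ATL), which carries
conceptual representations of social behaviour, and the subgenual cingulate
cortex (SCC), a core node of depression pathophysiology. Reduced ATL–SCC
coupling while experiencing guilt (relative to indignation, an
other-blaming emotion matched for negative valence) is a proposed
vulnerability signature in remitted major depressive disorder, which makes
*raising* guilt-related coupling a plausible training target.

Per volume $t$ in an emotional block, each ROI sample is normalised against
the preceding baseline:

$$x_t = \bar{s}^{ROI}_t - \frac{1}{|B|}\sum_{u \in B} \bar{s}^{ROI}_u,$$

where $B$ is the entire preceding mental-subtraction block. This removes
local signal trends without any model of the drift. The engine then
maintains, per condition, the sliding-window correlation
$r_t = \mathrm{corr}(x_{t-9..t}^{ATL},\, x_{t-9..t}^{SCC})$ over the last
10 retained samples, updated every volume (TR = 2 s).

The reinforcement target is *moving*: $r_t$ is compared against the
recency-weighted mean $\bar{r}_w$ of the last 10 window correlations, with
a band of one running standard deviation $\sigma$ of the correlation
history accumulated so far in that run and condition:

* **INCREASE** (guilt blocks, active arm): thermometer steps up iff
  $r_t > \bar{r}_w + \sigma$, down otherwise.
* **STABILISE** (guilt blocks in the control arm; indignation blocks in
  both arms): up iff $|r_t - \bar{r}_w| \le k\,\sigma$ (default $k = 1$),
  down otherwise.

Because consecutive windows share 9 of 10 samples, $r_t$ hugs its own
recent mean; exceeding it *plus a standard deviation* is rare, while
staying inside the band is common. The asymmetry between the arms'
feedback success is therefore built into the rules, not into the data —
replaying identical series under both rules yields systematically lower
guilt-block levels under INCREASE (see the engine tests), reproducing the
direction of the large thermometer-position gap between arms reported for
this design. The absolute stabilise-arm level in our simulations
(~55–65 %) depends on how wide the $\pm 1\sigma$ band is relative to
window-to-window correlation noise; with real, autocorrelated BOLD the
band is relatively wider and success rates higher, which is why only the
direction of the gap is asserted anywhere in the package.

## Parameters and defaults

| Parameter | Default | Units | Why |
|---|---|---|---|
| `window_volumes` | 10 | volumes | the protocol's 10-volume sliding window |
| `discard_volumes` | 5 | volumes | first emotional-block volumes carry baseline carry-over correlations |
| `weighting` | linear | — | "weighted mean of the last 10" implies non-uniform; recency is the natural axis (uniform available) |
| `stabilise_band_sd` | 1 | running SDs | symmetric with the increase rule's +1 SD threshold |
| `sigmoid_midpoint`, `sigmoid_slope` | 0, 5 | r units | symmetric, near-linear mid-range logistic display map over $r \in [-1, 1]$ |
| `level_step` | 10 | % points | the protocol specifies direction of level changes only; magnitude is display policy |
| `neutral_level` | 50 | % | displayed during window warm-up |
| `motion_rms_threshold_*` | 1 mm / 1° | RMS | conventional fMRI gating magnitudes; inclusion is strict (`<`) |

Further numerical choices: a zero-variance window returns $r = 0$ with a
degenerate flag (a real-time loop must not halt); correlation histories
with fewer than two values give a band of zero; the very first correlation
of a run/condition has no reference and leaves the level unchanged;
buffers and the level reset at each emotional block (so windows never span
a subtraction block), while histories accumulate per condition over a run.
Gated volumes never enter buffers, histories or GLM inputs, and — unlike
the original real-time implementation, which could not log them — the
gated count is recorded per run.

## ROI machinery

Spheres are rasterised by including every voxel whose centre lies within
the radius (Euclidean, mm). Smoothing is separable Gaussian convolution
with zero padding; mass is conserved away from the boundary and
`fwhm = 0` is the identity. Warping to native space is backward resampling
through the inverse of the supplied 12-parameter affine (registration
estimation is out of scope: matrices are inputs) — nearest-neighbour for
binary masks, trilinear for weighted ones. Support for selection is
defined as weights above 5 % of the peak of the (smoothed, warped) mask;
"10 % most activated" uses `ceiling`, guaranteeing a non-empty selection,
with ties broken by ascending voxel index for reproducibility. Activation
is a per-voxel OLS t statistic on condition box-cars (unconvolved by
default, as real-time pipelines run; canonical-HRF convolution by option):
guilt vs. subtraction for the ATL, guilt vs. indignation for the SCC.
Whether the 10 % should be taken of the smoothed support or the unsmoothed
back-transformed sphere is ambiguous in the source protocol (ROI sizes
varied across subjects there too); the support threshold is therefore
explicit, configurable, and the support size is recorded in provenance.

## Offline statistics

Per subject, the two localizer runs contribute four condition-by-time
cells of retained emotional volumes (40 per cell at the defaults). Both
ROI series are z-scored *within cell* — standardised slopes per cell
require cell-wise standardisation — and a single OLS model with a separate
intercept and separate z(ATL) slope per cell (the full
ATL × condition × time interaction) yields per-cell $\beta$, $t$, the
model's residual df, and $d = 2t/\sqrt{df}$, which the code derives from
that one model rather than from four separate fits. The group analysis is
`aov` with `Error(subject/(condition*time))`; with two-level within
factors no sphericity correction exists to apply (asserted, not
corrected). The three-way interaction's p value is checked against the
pooled-variance t-test on per-subject difference-of-differences scores —
the two agree to numerical precision, and the group mean difference is
reported as CONTROL − ACTIVE with a pooled-SD (Bessel-corrected) Cohen's
d, the convention of the trial's summary tables. The ANCOVA confirmation
(`post ~ group + pre`) uses listwise deletion with the exclusion count
logged, since questionnaire-style outcomes arrive with missing entries.

Minimised randomisation assigns the first two subjects to the two arms in
random order, then each subsequent subject to the arm minimising
$|\Delta \bar{age}|/sd(age) + |\Delta n_{male}| + 0.25\,|\Delta n|$.
The small group-size term is this package's addition: with identical
covariates all candidate assignments tie, and pure random tie-breaking can
leave the arms arbitrarily unbalanced, which defeats the purpose of
minimisation. Weights are configurable; the allocation log is written to a
plain text file, mirroring concealed-allocation practice.

## The synthetic generator

Emotional-block samples are bivariate Gaussian with the cell's target
correlation (subtraction blocks are cross-ROI independent), scaled by
`noise_sd`; voxel-level fixtures add independent voxel noise around a
shared latent per ROI, so the ROI mean recovers the latent series on small
grids that keep tests fast. Motion traces are 6-parameter Gaussian noise
with occasional large translation spikes that cross the gating threshold.
Optional low-frequency sinusoidal drift and HRF/autocorrelation realism
are off by default: the engine's mathematics is correlation-level, the
baseline normalisation absorbs slow trends, and a drift-free default keeps
the generated target equal to the population correlation of the emitted
series — which is what the recovery tests quantify (Fisher-z convergence
at rate $1/\sqrt{n-3}$).

What passing tests therefore show: the pipeline's arithmetic, contracts
and statistical identities are correct, and effects of realistic size are
recoverable at trial-scale n. What they do not show: performance under
hemodynamic convolution, temporal autocorrelation, physiological noise or
realistic anatomy — real BOLD violates the i.i.d. sampling behind the
Fisher-z rate, and window correlations on real data are smoother and more
variable across subjects.

The cohort generator draws per-subject couplings on the Fisher-z scale
(subject intercept SD 0.1, per-cell jitter SD 0.1) around a base of
guilt ≈ 0.15, indignation ≈ 0.40 — magnitudes loosely mimicking the
published group means, labelled synthetic throughout. The
`active_effect` profile adds +0.5 (Fisher-z) to the active arm's
post-training guilt cell; the `null` profile adds nothing and is used for
type-I calibration.

## The responsive participant

The closed-loop test double models a participant who learns from
reinforcement. Under INCREASE-rule feedback the true coupling drifts
upward in proportion to the displayed level's excess over neutral
($\Delta r = \eta\,(L-50)/50$ for $L \ge 50$, default $\eta = 0.02$);
below-neutral feedback relaxes the coupling toward the participant's
baseline — punishment makes them fall back on their untrained strategy —
but never below it. Under STABILISE-rule feedback the coupling does not
drift: that rule reinforces *maintaining* the current strategy, and a
participant rewarded for stability has nothing to change. This rule-aware
asymmetry is deliberate: a signed level-proportional drift applied in both
arms would make the stabilise arm — which by design earns high levels —
drift strongly upward, the opposite of what a stabilisation intervention
reinforces. With these dynamics, active-arm sessions end with higher
guilt coupling than stabilise-arm sessions on the same seeds while
receiving markedly less positive feedback, matching the qualitative
pattern of the trial.

## Problem sizes

Defaults used by the tests and the acceptance script: full-length runs
(200/360 volumes), 100 volumes per cell for recovery checks, cohorts of
14 per arm (the trial's size) for calibration (200 null replicates),
20 paired seeds for closed-loop comparisons, and ~1,000-volume replays for
the exact engine-vs-oracle equivalence. These sizes were chosen so the
entire suite runs comfortably on a laptop while keeping every statistical
assertion at trial-relevant n.

## Known limitations

* No scanner transport, DICOM ingestion or display rendering; the engine
  consumes ROI series or arrays, not a real-time stream.
* Registration matrices are inputs, never estimated; no brain extraction,
  segmentation or nonlinear warping.
* The sigmoid display map's original parameters are not public; the
  logistic defaults are symmetric and configurable, and the step-based
  level dynamics encode only the documented directions of change.
* Between-group Cohen's d uses pooled SD of change scores with Bessel
  correction; the source convention's exact variant is not fully
  specified, so the variant is named in the output.
* The generator's i.i.d. Gaussian samples understate the difficulty of
  real-time correlation feedback on autocorrelated BOLD.
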