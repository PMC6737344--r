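# nfcoupling

Simulation and analysis toolkit for correlation-based real-time fMRI
neurofeedback, built around the blame-rebalance protocol for remitted major
depressive disorder: feeding back the coupling between the right anterior
superior temporal lobe (ATL) and the subgenual cingulate cortex (SCC) while
participants retrieve guilt- and indignation-related autobiographical
memories.

It is written for methods researchers who want to study, stress-test or
extend this class of closed-loop designs without scanner data: every stage —
paradigm, ROI definition and selection, the streaming feedback engine, and
the trial statistics — is implemented as ordinary R functions over plain
arrays and data frames, and a seed-deterministic synthetic BOLD generator
(including a closed-loop "responsive participant") makes the whole pipeline
verifiable end to end.

## The method

**Paradigm.** Each session has four runs on a block design alternating
mental-subtraction baseline blocks with guilt and indignation memory blocks.
Runs 1 and 4 are localizers (200 volumes at TR = 2 s: 4 guilt + 4
indignation blocks of 15 volumes, 8 subtraction blocks of 10); runs 2 and 3
deliver feedback (360 volumes: 4 + 4 emotional blocks of 30 volumes, 8
subtraction blocks of 15).

**ROI selection.** A-priori MNI spheres — ATL (58, 0, −12), r = 4 mm; SCC
(−4, 23, −5), r = 6 mm — are smoothed (6 mm FWHM), warped to native space
through the inverse of a supplied 12-parameter affine, and reduced to the
10 % most activated voxels under a per-voxel GLM contrast (guilt vs.
subtraction for the ATL, guilt vs. indignation for the SCC). The mean signal
over the selected voxels is the per-volume ROI signal.

**Feedback engine.** Emotional-block samples are normalised by subtracting
the mean ROI signal of the entire preceding subtraction block. After
discarding the first 5 volumes of each emotional block, the engine computes,
every volume, the Pearson correlation r over the last 10 retained samples
and compares it to a moving target: the recency-weighted mean of the last 10
window correlations, with a band of one running SD of the correlation
history so far. Under the **INCREASE** rule (guilt blocks, active arm) the
thermometer steps up only when r exceeds the weighted mean plus one SD;
under the **STABILISE** rule (guilt blocks in the control arm, indignation
blocks in both arms) it steps up while r stays inside the band and down
otherwise. Volumes whose translation or rotation RMS exceeds the motion
thresholds are excluded from all computation (and, unlike the original
real-time software, counted).

**Offline statistics.** Per subject, one OLS model over the four
condition-by-time cells of the two localizers regresses the z-scored SCC
series on the z-scored ATL series (full interaction with condition and
time), giving a standardised slope, t and df per cell and the within-subject
effect size d = 2t/√df. The primary trial analysis is the repeated-measures
ANOVA (condition × time within, group between) whose three-way interaction
is, by construction, equivalent to an independent t-test on the per-subject
difference-of-differences (guilt − indignation, post − pre) — the package
computes both and they agree to ~1e−16. ANCOVA confirmation, minimised
randomisation (age + gender balancing) and thermometer-position summaries
round out the trial toolkit.

## Worked example

```r
library(nfcoupling)

build_neurofeedback_run()
#> <nf_timeline> NEUROFEEDBACK run: 360 volumes, TR 2.0 s (720 s)
#>   volumes per condition: GUILT=120, INDIGNATION=120, SUBTRACTION=120
#>   16 blocks, opening with SUBTRACTION

# one synthetic subject whose guilt coupling rises from 0.15 to 0.45
subj  <- generate_subject(coupling_spec(0.15, 0.40, 0.45, 0.40),
                          group = "ACTIVE", seed = 42)
trace <- run_feedback_session(subj)
trace
#> <feedback_trace> 400 feedback volumes, 5 gated
#>   mean thermometer level: GUILT=30.2%, INDIGNATION=61.8%

subject_effects(subj)
#> <connectivity_effect> SUBJ0001 (ACTIVE), df = 150
#>      guilt_pre indig_pre guilt_post indig_post
#> beta     0.294     0.424      0.499      0.103
#> t        1.940     2.765      3.253      0.681
#> d        0.317     0.451      0.531      0.111

# a 14-per-arm cohort with an active-arm training effect
cohort <- generate_cohort(14, effect_profile("active_effect"), seed = 7)
group_compare(lapply(cohort, subject_effects))
#> <nf_group_result> repeated-measures ANOVA on per-subject beta effects
#>                 effect df      F        p
#> ...
#> 7 group:condition:time  1 18.095 2.41e-04
#> difference-score t-test (CONTROL - ACTIVE): diff = -0.530, se = 0.125,
#>   t(26) = -4.25, p = 0.000241, d = -1.61
```

The thermometer means illustrate the design's asymmetry: increasing
correlations beyond the moving target is much harder than keeping them
stable, so the active arm sees far less positive feedback during guilt
blocks (here 30 % vs. ~62 % under stabilisation) even while its coupling —
and the three-way interaction above — moves in the trained direction.

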