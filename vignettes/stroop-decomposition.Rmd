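---
title: "Decomposing the Stroop effect from mouse trajectories: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing the Stroop effect from mouse trajectories: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

strooptrace analyses mouse-tracking colour-word Stroop experiments in which
participants move a cursor from a start box to one of four colour response
boxes while ignoring the word they are reading. Because an initiation
deadline forces movement onset before response selection has finished,
conflict and facilitation leak into the movement itself: response times,
trajectory curvature, and outright excursions toward the incorrect response
box all carry Stroop effects. This vignette documents the statistical
procedure, the design decisions taken where more than one implementation was
defensible, and what the synthetic-data generator does and does not emulate.

## The design and the component algebra

Six stimulus types are crossed within participants: standard
colour-incongruent (a response-set colour word in its paired incongruent
ink), non-response-set incongruent (a colour word outside the response set),
colour-associated incongruent (e.g. "sky" in yellow), colour-neutral words
(the reference level), colour-associated congruent, and standard
colour-congruent. Ink colours come in two pairs (red-green, blue-yellow)
whose response boxes mirror each other about the vertical screen midline, so
every trial has a well-defined *incorrect-response side*.

Every Stroop component is a difference between two per-condition marginal
means. Writing SI, NRS, AI, N, AC, SC for the six condition means:

| component | contrast |
|---|---|
| total Stroop effect | SI − SC |
| interference | SI − N |
| facilitation | N − SC |
| response conflict | SI − NRS |
| semantic relevance | NRS − AI |
| semantic conflict | AI − N |
| response facilitation | AC − SC |
| semantic facilitation | N − AC |

The contrasts telescope: interference + facilitation = total; response
conflict + semantic relevance + semantic conflict = interference; response +
semantic facilitation = facilitation. `component_contrasts()` evaluates all
eight from one fitted model, so these identities hold to machine precision
for every fit — `additivity_residuals()` verifies this and the pipeline
writes the residuals alongside the estimates.

## Preprocessing

Exclusions follow the standard order: trials without a response (timeouts),
then incorrect responses, then — among the remaining correct trials —
response times more than 3 SDs from their own participant-by-condition cell
mean. The cell statistics are computed after the omission/error removal so
that error latencies cannot widen the cut; the rule is skipped (and logged)
in cells with fewer than two trials, and a zero-spread cell removes nothing.
The filter uses raw rather than log RTs.

Trajectories whose correct box lies left of the start box are mirrored about
the start-box x (remapped rightward), after which leftward excursion always
means "toward the incorrect response". Each trajectory is then translated
and scaled independently in x and y so its first sample lands exactly at
(0, 0) and its last at (1, 1.5). No rotation is applied: the signed x axis
is what gives the incorrect-response side its meaning, and rotating would
destroy that convention. A degenerate path whose endpoints coincide on an
axis raises an alignment error.

Time normalization linearly interpolates the aligned trajectory at 101
equally spaced times spanning click to response, *including* the
pre-initiation dwell, so step *s* sits at approximately (*s* − 1)% of total
response duration (step 11 ≈ 10%). Space normalization resamples 100 points
at equal arc-length increments along the polyline; dwell samples contribute
zero arc length and are dropped before resampling. Both normalizers use
linear interpolation — at 100 Hz the spacing between samples makes
higher-order schemes immaterial.

## Kinematic measures

The signed orthogonal deviation of a point from the direct path is the 2-D
cross product of the path direction with the point, divided by the path
length; positive values lie above the direct line, i.e. toward the
incorrect-response side after rightward remapping. `md_above` is the
*maximum* of the signed deviation over the full-resolution aligned path (not
the time-normalized subsample, which can only undershoot it). A path that
never rises above the direct line keeps its negative maximum rather than
being floored at zero — a consistently below-path trajectory is
distinguishable from a straight one. Initiation time is the first sample
whose displacement from the start exceeds a configurable threshold
(default 0: any movement); response time is the last sample time.

## Partial errors by clustering

Each space-normalized trajectory becomes a 200-dimensional vector (100 x
then 100 y values) and all kept trials are clustered jointly —
conditions and participants pooled — by agglomerative hierarchical
clustering with Euclidean distance and Ward linkage, cut at k = 8. Those are
the conventional defaults for this analysis style; both are arguments.
Rather than identifying partial-error clusters by eye, the package applies
an explicit rule: a cluster is a partial-error cluster when its pointwise
mean path crosses materially onto the incorrect side, min(x) < −0.05. The
threshold is exposed (`x_threshold`), and raising it can only shrink the
labelled set. A trial in a partial-error cluster counts as a partial error
even if its own path never crosses x < 0: the definition is cluster-level,
matching the data-driven character of the original analysis. Partial-error
rates are percentages per participant-by-condition cell; empty cells are
reported missing, not zero.

## Mixed models and marginal means

For each global measure (initiation time, response time, maximum deviation,
partial-error rate) the model is a REML linear mixed model with the six
conditions dummy-coded against the colour-neutral reference and a
by-participant random structure selected parsimoniously: start from a random
intercept plus uncorrelated slopes for all five non-reference conditions;
whenever the fit is singular or non-convergent, drop the slope with the
smallest variance; otherwise test the weakest slope by a likelihood-ratio
test and drop it unless supported at α = 0.20. The intercept is always
retained, and with one observation per cell (partial-error rates) only the
intercept is estimable, so selection short-circuits to it. Random effects
are by participant only — by-item structure is deliberately out of scope.
Partial-error rates are modelled as Gaussian responses on the percentage
scale rather than by a binomial model: fidelity to the original analysis was
preferred over distributional optimality, and the CI calibration tests below
apply to this choice as implemented.

Marginal means are intercept (neutral) or intercept plus the condition's
coefficient, with standard errors from the fixed-effect covariance and
Satterthwaite degrees of freedom. Component contrasts are evaluated directly
as contrasts of the fixed effects (the intercept cancels), each with its own
Satterthwaite df; with a single participant the model degenerates to
ordinary least squares and residual df are used, and if the mixed-model
machinery fails outright on degenerate input (for instance zero residual
variance) the same OLS fallback applies. The test suite cross-checks
marginal means, SEs and contrasts against the emmeans package route to
within 1e-9, and contrast SEs against a parametric bootstrap.

Global components are reported with 99% CIs: α = 0.01 is the Bonferroni
correction for the five lower-rank comparisons at α = 0.05, and intervals
that exclude zero may be read as statistically significant. Per-time-step
components use 95% CIs with the run-length rule below.

## Time courses across normalized time

For the deviation and x-coordinate profiles, one mixed model is fitted per
time step. The per-step random structure is simplified to the by-participant
intercept so that 101 fits stay fast and numerically stable; setting
`per_step_slope = TRUE` additionally retains a standard-incongruent slope
per step when a likelihood-ratio test supports it. Steps whose fit fails are
flagged and treated as non-significant — a conservative choice. Sustained
effects are maximal runs of at least `min_run` consecutive steps whose 95%
CI excludes zero; 10 steps (10% of movement duration) is the reporting
threshold and 5 the conventional display threshold, and no further
multiplicity correction is applied on top of the run-length rule. Peaks are
the largest estimate in the measure's expected direction (positive for
deviation, negative for x), ties resolved to the earliest step. Because the
anchored endpoints make step 1 and step 101 degenerate (all deviations
exactly zero), those fits are flagged rather than fitted.

## The synthetic-data generator

The generator exists so that every stage is testable with known ground
truth; it is a first-class module, not a fixture. Each trial draws an
initiation delay (truncated normal, mean 168 ms, SD 40, within the 500 ms
deadline) and a response time whose mean is `rt_base` (1070 ms) plus the
condition offset plus an additive participant effect (SD 110 ms), scaled by
a mean-one lognormal trial multiplier (CV 0.18). Keeping the participant
effect additive in milliseconds with a mean-one multiplier makes the
configured offsets *exactly* the marginal condition means, so
`ground_truth_components()` is exact contrast arithmetic on the
configuration. The default offsets (+119, +41, +5, 0, −25, −41 ms) are the
study-scale condition differences the pipeline is expected to resolve.

Movement follows a two-attractor co-activation rule in discrete
1/sample-rate steps: the cursor pursues a blended target
w(t)·incorrect + (1 − w(t))·correct, where w starts at the condition's pull
amplitude and decays geometrically, with isotropic Gaussian positional noise
(4 px) at every step except the last. The pursuit gain is modulated by a
late-peaked bell velocity profile (sin²(π u^1.8)): a slow start means the
high-pull early phase contributes little displacement, which places the
deviation peak near 60% of total response duration, where empirical
mouse-tracking deviation profiles peak. An endpoint-anchoring floor on the
step fraction guarantees the cursor lands exactly on its final target, and
the final target is the chosen box itself. Partial-error-regime trials are a
mixture component (probability `pull_prob` per condition) with a high
initial weight (0.92) and slow decay (0.992), so the cursor crosses well
onto the incorrect side before correcting; the regime label is stored per
trial, giving the clustering stage a ground truth to be scored against. The
mixture, rather than a continuum, is deliberate: classifier validation needs
labels. Timeouts and errors are independent Bernoulli draws (0.34% and
0.58%) — the pipeline only needs them present to exercise filtering.

The pull amplitudes (0.55, 0.39, 0.37, 0.34, 0.32, 0.29) were back-solved
once from the study-scale mean maximum deviations through the regime
mixture, and the regime probabilities are the study-scale partial-error
rates (36.7% down to 22.3%). These defaults are the generator's definition
of the study conditions and are not adjusted per analysis.

What the generator does *not* emulate: word-frequency and associative
priming gradients, trial-sequence effects, velocity profiles of real hands
beyond the bell shape, autocorrelated motor noise (noise is white), and
item-level variability. Passing tests therefore demonstrate that the
pipeline recovers effects from data with the study's coarse structure, not
that it is robust to every idiosyncrasy of real cursor data.

## Problem sizes and calibration results

The test suite uses a 10-participant calibrated simulation for structural
checks, 100 replicates at the full 80 × 32 × 6 size (metadata only) for RT
component recovery — each component's 99% CI covers its ground truth in well
over 90% of replicates — and 500 small null replicates for CI calibration,
where each component's 99% CI excludes zero at a rate statistically
consistent with 1%. The acceptance script runs the full trajectory pipeline
at 24 participants, a size at which the component estimates are stable but
the complete run stays in a few minutes on one CPU.

One calibration result deserves emphasis. Under a null simulation (no
condition differences, equal pull everywhere), the *per-step* false
exclusion rate of the 95% CIs is slightly conservative (≈3%), but runs of
ten or more consecutive falsely-significant steps occur in roughly 9% of
replicates (7/80 in held-out measurement). The reason is that trial-level
pull persistence — including the realistic ~25% partial-error mixture —
makes the step-wise test statistic nearly constant across normalized time,
so one exceedance stretches into a long run. The run-length heuristic is
therefore only an approximate familywise control under these conditions,
and time-course intervals near the 10-step threshold should be read with
that in mind.

## Known limitations

- Deviation-based facilitation estimates face a floor: the ideal trajectory
  bounds how much straighter a path can get, so facilitation is estimated
  with less sensitivity than interference.
- The Gaussian model for partial-error percentages ignores their bounded,
  discrete nature; a binomial model would be more efficient at low rates.
- Satterthwaite df come from the mixed-model machinery; the OLS fallback
  reports residual df, and which applies is recorded on the fit object.
- The automatic partial-error labelling rule depends on `x_threshold`;
  clusters of centre-directed movements with shallow crossings can flip in
  or out near the threshold.
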