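---
title: "Models and methods behind navrsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind navrsa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the generative model, the analysis statistics, the
numerical conventions, and the design decisions that were genuinely open.
It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The experiment being modelled

A participant is transported along a linear track to one of four test
locations spaced 4 m apart and must recall, from memory, which location
they occupy.  Two cue conditions isolate the two major sources of spatial
information: a *landmark* condition (a distal landmark beyond the far end
of the track) and a *self-motion* condition (optic flow anchored to a
start marker before the near end).  Track coordinates place
`Loc1`..`Loc4` at 0, 4, 8, 12 m with movement in the direction of
increasing coordinate; the landmark side is beyond `Loc4`, the
path-integration anchor before `Loc1`.  The paradigm comprises two
scanning days of eight runs each — every cue-by-environment combination
twice per day, never twice in a row — and each run presents a
second-order counterbalanced (de Bruijn) cycle of 20 location-occupation
events (5 per location) and 5 null events, preceded by a duplicated
lead-in event.

Counterbalancing is what makes the whole enterprise possible: because
every ordered pair of event types occurs exactly once per cycle, the
distance to the previously occupied location is balanced across current
locations, so repetition suppression (fMRI adaptation, fMRIa) and
multi-voxel pattern similarity can be estimated from the same runs.

### de Bruijn generation

Any order-2 de Bruijn cycle is an Eulerian circuit on the complete
directed graph (with self-loops) over the five event types;
`make_debruijn_sequence()` draws one by Hierholzer's algorithm with
randomized edge order.  The original study selected eight pre-existing
sequences optimized for detection power; the analyses here depend only on
the pair-coverage property, which every valid cycle has, so no attempt is
made to reproduce those specific sequences.  Each run's cycle is rotated
so that its final event is a location event; rotation preserves pair
coverage, and it guarantees that the duplicated lead-in supplies a defined
"previous location" for the first effective trial.

Null events occupy ordinary sequence slots.  Event onsets use a fixed
nominal spacing (12 s per slot by default); they exist only to support the
temporal-distance control predictor, since no stimulus-onset timing is
part of the analyses.

Session ordering is implemented as constrained random permutation (each
combination twice, no immediate repeats) rather than a literal Latin
square, because only those two constraints are testable properties of the
published design.

## The three-subpopulation generative model

The simulator realizes the hypothesized functional architecture of the
retrosplenial location code:

* two **adapting, cue-specific** populations, one recruited under each cue
  condition, tuned to the *true* location;
* one **non-adapting, shared** population, active under both cue
  conditions, tuned to the *reported* location.

Each neuron has a Gaussian tuning curve over the track coordinate with
width `tuning_sigma` (default 6 m; preferred positions uniform on
[−2, 14] m, one spacing beyond the track ends, so coverage is roughly
even).  Adaptation is implemented as neuron-level repetition suppression:
on a trial at location *x* preceded by location *p*, an adapting neuron
with tuning *f* fires

    a = f(x) * (1 − adaptation_gain * f(p))

so suppression is strongest when the previous location falls on the
neuron's own tuning curve — i.e. when the two locations are close.  A
population-level factor linear in |x − p| would have been simpler, but it
cannot produce the tuning-width behaviour the architecture is supposed to
explain: with arbitrarily broad tuning a planted linear slope survives,
whereas under repetition suppression broad tuning makes f(p) independent
of p and the adaptation effect vanishes, and very sharp tuning confines
suppression to exact repeats.  The neuron-level rule therefore makes both
qualitative mechanism claims emerge rather than being asserted: distance
coding (pattern-based and adaptation-based) peaks at tuning widths
comparable to the 4 m spacing, and is weak both for `tuning_sigma` much
smaller than the spacing and much larger than the track.

Populations are aggregated into voxels through loading matrices drawn in
two stages: a population-level voxel-propensity vector from a symmetric
Dirichlet whose concentration grows with `clustering_evenness`
(`0.05 + 400 * evenness^2`), then per-neuron loading rows from a Dirichlet
centred on that propensity.  Rows sum to one, so the total drive — and
hence the *mean* voxel adaptation slope — is conserved across evenness
levels, while lower evenness concentrates populations in fewer voxels and
strengthens pattern information.  This reproduces the second mechanism
claim: less even clustering raises RSA scores while leaving the mean
fMRIa slope nearly unchanged until the distribution is extremely uneven.
Voxels carry a long-axis coordinate in [0, 1]; configuration options
confine populations to axis sub-ranges (used to plant anatomical
separability and axis profiles).

### Behavioural model

Errors land on an adjacent location with probability
`adjacent_error_prob` (default 0.975; remaining errors go to a location
two or more steps away), and the error probability grows linearly with
distance from the cue's anchor: away from the landmark under landmark
navigation, away from the start marker under self-motion navigation.
Defaults (`error_base` 0.0815/0.1465, `error_gradient` 0.045 per
location step) were calibrated once so cohort mean accuracy falls near
0.85 (landmark) and 0.79 (self-motion), the reported behavioural means of
the paradigm; the mirrored accuracy gradients across the track follow
from the linear anchor-distance term.

### Noise scale

Voxel noise is i.i.d. Gaussian, `noise_sd = 3.5` by default.  This value
was fixed once so that the subject-level effect sizes of the
response-based spatial information scores in a 20-subject default cohort
land in the 0.6–1.0 range implied by the published group t statistics —
i.e. the simulator's default regime has the same statistical difficulty
as the real study, rather than being arbitrarily easy or hopeless.
Mechanism-demonstration experiments in the tests use cleaner settings
(noise 1.5–2, chosen for ~95% detection power of the planted effect)
because their purpose is to show a mechanism, not to mimic study power;
the calibration (null) experiments set all population gains to zero, where
the neuron count is irrelevant and is reduced for speed.

What the simulator deliberately omits: haemodynamics (patterns stand in
for first-level GLM beta estimates — all analyses consume betas),
physiological and motion artifacts, spatial autocorrelation of voxel
noise, anatomical realism beyond a 1-D long axis, and any dependence of
behaviour on trial history.  Passing tests therefore show that the
analysis chain recovers what the architecture plants at realistic
signal-to-noise, not that real BOLD data meet these assumptions.

## The analysis statistics

### Spatial information score

For each cue the 2 days x 4 runs are split chronologically into four
parts; within a part the two environment runs are averaged voxel-wise per
label (a label present in only one run falls back to that run's vector; a
label absent from both is marked missing).  Cross-validated similarity is
the Pearson correlation between label-mean vectors of *different* parts:
6 unordered pairings within a cue, 16 ordered pairings between cues.
Pairing matrices are averaged cell-wise; the score is
`−atanh(cor(atanh(S), D))` over the cells of the mean matrix, with
`D(i,j) = |i−j|·4`.

Numerical conventions: similarity cells are clipped to ±(1 − 1e−7) before
the Fisher transform; cells missing from every pairing are dropped by
pairwise deletion, and a score computed from fewer than 8 of the 16 cells
carries a low-confidence flag.  All 16 cells, including the 0 m diagonal,
enter the correlation by default: cross-validation makes the diagonal an
ordinary unbiased comparison, and the published trend analysis treats
0 m as a distance level.  `include_diagonal = FALSE` restricts the score
to distinct-location cells — this is the right measure of pure *distance*
coding (under very sharp tuning, an identity code still produces a
positive inclusive score through the diagonal), and the mechanism tests
use it.

### Unique contributions

Trial-level 20 x 20 similarity matrices per run pair are vectorized
(Fisher z, standardized) and regressed on standardized distance
predictors; coefficients are sign-reversed and averaged over the
relation's run pairs (within-cue: all 28 pairs of that cue's 8 runs, days
pooled; between-cue: all 64 cross pairs; "lumped": all 120).  The
intercept is retained (harmless under standardization).  A run pair whose
predictors correlate above 0.999 — location vs response under error-free
behaviour — is flagged degenerate and contributes no unique
coefficients.  Same-trial-index cells of cross-run matrices are kept:
they are ordinary cross-validated comparisons; a switch excludes them.
Temporal distance is defined from run-relative onsets for cross-run pairs
as well, recorded as a convention since no inter-run timing exists.

### Neural-space reconstruction

Distances are 1 − r, symmetrized, zero diagonal, then min-max normalized
over the *off-diagonal* entries (the manually zeroed diagonal does not
enter the minimum — otherwise the normalization formula would degenerate
to division by the maximum).  Classical MDS embeds the matrix in two
dimensions (the published configurations are planar; 1-D is available
since the physical layout is collinear); missing positive eigenvalues pad
zero axes.  Procrustes alignment to the physical layout allows
translation, uniform scaling, rotation and reflection — scaling is
included because the min-max normalization destroys absolute scale — and
reports the standardized Procrustes statistic
`1 − (Σσ)² / (ss_x · ss_target)`, zero iff the configurations match up to
those transforms.

The group test shuffles the 6 unique off-diagonal values over off-diagonal
positions (shuffling raw cells would break symmetry and the zero
diagonal), re-embeds, and takes the proportion of surrogate distances
strictly smaller than the actual one; ties therefore count in favour of
the null, and a perfectly recovered layout yields p = 0 exactly.  The
group matrix is the cell-wise mean of the subjects' raw (un-normalized)
distance matrices, normalized once.

Subject-level spaces for the adjacent-distance profile are aligned to the
physical layout first, then the three adjacent distances are measured and
submitted to a repeated-measures ANOVA; the cue x linear-trend interaction
is tested as a per-subject contrast difference.  These analyses use
location-defined labels: when the underlying code follows the reported
location, the confusions mix adjacent location-labelled patterns in
proportion to the behavioural error gradient, which is exactly how the
behavioural signature surfaces in the neural space.

### fMRIa estimation and the linkage analyses

The per-voxel adaptation effect is the OLS slope of trial activation on
distance-to-previous-location with current-location fixed effects
partialled out.  The location adjustment matters: end locations have a
larger mean distance to their predecessor, so a raw slope leaks each
voxel's location-activation profile into its adaptation estimate.  The
simulator stores an analytic ground truth per voxel — the same partial
slope computed on the noiseless expected activations over the balanced
(current, previous) design — against which recovery is tested.

Voxels are ranked by the signed unsmoothed effect and cut into equal
bins (earlier bins absorb remainders; ties keep original order); spatial
information scores are recomputed per bin, compared across bins by
repeated-measures ANOVA, and referenced to empirical chance levels
obtained by randomizing voxel order (per subject, then averaged — the
per-subject convention is a choice; the alternative of pooling first is
not distinguishable from the published description).  The axis profile
cuts voxels into deciles along the long-axis coordinate and tests the
linear trend (pooled-error contrast) plus the planned contrast of deciles
3–10 against 1–2.

### Group statistics

Directional one-sample t tests use the positive tail.  Bayes factors are
the default JZS kind — Cauchy(0, 0.707) prior on the standardized effect,
marginal likelihood by 1-D integration of the noncentral-t likelihood;
one-sided variants use the half-Cauchy (both variants are exposed, since
directional reports of this statistic vary).  Winsorization replaces
values beyond 3 interquartile ranges outside the quartiles (type-7
quantiles — fences depend on the convention, so it is recorded) with the
fence value.  The Max-T correction sign-flips whole subjects jointly
across the test family (10,000 permutations by default) and applies the
step-down maximum-statistic rule, the permutation analogue of
Holm–Bonferroni.  RM-ANOVA uses subject error strata with partial eta
squared; polynomial trends are tested against the pooled
subject-by-factor error, trend-by-condition interactions as per-subject
contrast differences — matching the two reporting styles such analyses
use.

## Problem sizes

The test suite and acceptance script run at desk scale, chosen to keep a
complete run in minutes while leaving every statistical conclusion
well-resolved: cohorts of 20 subjects with 60 voxels for
calibration and recovery studies (300 and 120 null cohorts in the suite
and script respectively; 100 cohorts for the neural-space recovery rate),
smaller cohorts (2–8 subjects) for arithmetic and oracle checks, and
reduced permutation counts (500 for Max-T inside calibration loops) where
only rates, not individual p-values, are consumed.  Defaults in the
package (`n_voxels = 120`, 5000 spatial permutations, 1000 voxel
randomizations, 10,000 Max-T permutations) reflect the published
procedure.

## Known limitations

* The simulator's voxel noise is white; spatially correlated noise would
  lower effective degrees of freedom in pattern correlations and is not
  modelled.
* The between-cue score's null distribution is very slightly asymmetric
  (correlated cells entering a correlation), which the calibration study
  bounds but does not remove; the effect is well inside the binomial CI at
  the study's scale.
* Real first-level GLM estimation (HRF convolution, nuisance regression)
  is out of scope; `read_real_dataset()` expects beta estimates.
* The clustering-evenness parameter is an abstraction; no empirical
  estimate of within- vs between-population voxel overlap exists to pin
  it, so only qualitative claims are made about it.
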