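# navrsa

Representational similarity analysis (RSA) for cue-dissociation spatial
navigation fMRI experiments — and a generative simulator of the neuronal
architecture such experiments probe.

## The scientific problem

In a cue-dissociation navigation paradigm, a participant is moved along a
linear track to one of four locations (`Loc1`..`Loc4`, 4 m apart) and must
recall which location they occupy, relying either on a distal **landmark**
or on optic-flow **self-motion** cues anchored to a start marker.  Previous
work on such data found *fMRI adaptation* (fMRIa) in retrosplenial cortex:
activation is suppressed when the current location is close to the
previously visited one, and the voxel-wise pattern of this suppression is
cue specific.  The complementary question is whether *multi-voxel pattern
similarity* carries location information too, and whether that code is
driven by the stimulus (the true location), or by behaviour (the reported
location), and whether it generalizes across cue types.

The central statistic is the **spatial information score**.  For a 4 × 4
cross-validated pattern-similarity matrix *S* (Pearson correlations of
label-mean activation vectors between independent data parts) and the
model representational dissimilarity matrix *D* with entries
*D(i,j) = |i − j| · 4 m*,

    score = −atanh( cor( atanh(S), D ) )

so a positive score means nearer locations evoke more similar patterns.
Around this score the package implements the full analysis chain:

* **Design generation** — order-2 de Bruijn event sequences (every ordered
  pair of the five event types occurs exactly once; 20 location events per
  run, 5 per location, plus null events and a duplicated lead-in event),
  session schedules (8 runs/day, each cue × environment combination twice,
  never consecutively), and per-trial kinematics (start ~ U(−18, −4) m,
  speed ~ U(2, 5) m/s).
* **Simulator** — trial-wise voxel patterns from three neuronal
  subpopulations: two cue-specific *adapting* populations tuned to the true
  location (Gaussian tuning over the track, neuron-level repetition
  suppression) and one shared *non-adapting* population tuned to the
  reported location; populations map to voxels through Dirichlet loading
  matrices whose concentration is set by a clustering-evenness parameter.
  Behavioural responses err mostly to adjacent locations, with mirrored
  accuracy gradients in the two cue conditions.
* **Condition-level RSA** — chronological part splitting with environment
  averaging, 6 within-cue and 16 between-cue part pairings, scores for
  location- and response-defined labels, environment- and day-relation
  variants, and directional group tests with JZS Bayes factors.
* **Trial-level decomposition** — 20 × 20 trial similarity matrices per run
  pair regressed jointly on competing standardized distance predictors
  (location, response, path length, temporal distance, traveled time); the
  sign-reversed coefficients are each predictor's *unique contribution*.
* **Neural-space reconstruction** — 1 − r distances, metric MDS, Procrustes
  alignment to the physical track, a 5000-permutation group resemblance
  test, and the adjacent-location distance profile whose cue × gradient
  interaction mirrors the behavioural confusion pattern.
* **fMRIa–RSA linkage** — per-voxel adaptation slopes, adaptation-ranked
  voxel quarters/deciles, partition-wise scores against empirical chance
  from 1000 voxel randomizations, and long-axis decile profiles.
* **Group statistics** — directional one-sample t tests, JZS Bayes factors,
  3-IQR winsorization, repeated-measures ANOVA with polynomial trend
  contrasts, and permutation Max-T familywise correction.

## Worked example

```r
library(navrsa)

cfg <- sim_config(n_subjects = 20, n_voxels = 60, seed = 1)
cohort <- simulate_cohort(cfg)

scores <- score_suite(cohort, label_mode = "response")
glance(scores)
#>   label_mode    relation     n mean_score    t df  p_value   bf10
#> 1   response between_cue    20      0.214 5.38 19 1.72e-05   1448
#> 2   response   within_lm    20      0.265 7.58 19 1.86e-07  88730
#> 3   response   within_sm    20      0.295 7.68 19 1.54e-07 105414
```

All three response-based relations are positive (within-landmark,
within-self-motion, and between-cue), the signature of a location code
that is tied to the reported location and generalizes across cue types.
Decomposing pattern similarity at the trial level shows the code follows
behaviour, not the stimulus:

```r
dec <- decompose_cohort(cohort, c("location", "response"), "within_sm")
subset(glance(dec), coefficient == "beta_unique")
#>    relation predictor coefficient  n    mean statistic df  p_value   bf10
#> 1 within_sm  location beta_unique 20 0.00164     0.464 19 0.324038  0.342
#> 2 within_sm  response beta_unique 20 0.01678     3.936 19 0.000444 81.066
```

The unique contribution of the reported location survives controlling for
the true location; the reverse does not.  `autoplot(scores)`,
`plot_neural_space()`, and `autoplot()` methods on the partition and axis
profiles produce the matching figures.

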