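---
title: "Classifying hemisphere chirality from functional connectomes: methods"
author: "hemiconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying hemisphere chirality from functional connectomes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The two hemispheres of the human cortex are grossly symmetric, yet the left
hemisphere (LH) dominates language while the right (RH) favours visuospatial
attention. `hemiconn` implements a supervised-learning probe of that
asymmetry: can a classifier told nothing but the *within-hemisphere*
functional connectivity pattern of an unseen hemisphere say whether it is a
left or a right one? And can the same machinery tell whether a hemisphere
belongs to a right-handed (dextral, Edinburgh Handedness Inventory EHI > 0)
or left-handed (sinistral, EHI ≤ 0) person?

The package runs three analyses end to end:

1. **Chirality in dextrals** — hemiconnectome (within-hemisphere connection
   vector) classification of LH vs RH, followed by a two-stage permutation
   *enrichment* analysis asking which resting-state network pairs carry the
   discriminative connections.
2. **Chirality in sinistrals** — the same on the (much smaller) sinistral
   group, with a size-matched dextral control: training sets subsampled to
   4/5 of the sinistral cohort size and compared fold-by-fold with a paired
   t-test.
3. **Handedness** — a four-way outcome (LH/RH × dextral/sinistral, labels
   like `rightyLH`) on hemiconnectomes, plus handedness-only classification
   on full-connectome and trans-connectome (interhemispheric) features, and
   the "hemisphere space" analyses of how far apart a subject's hemispheres
   sit in discriminant space.

## Feature sets and conventions

Connectivity is Pearson correlation between parcel timecourses, Fisher-Z
transformed (`atanh`, with |r| clipped to 1 − 10⁻⁷ so perfect correlations
stay finite; the clipping bound keeps features bounded without dropping
data). With P parcels per hemisphere:

* **HC** (hemiconnectome): the P(P−1)/2 within-hemisphere connections, upper
  triangle in row-major order by ascending parcel index. Both hemispheres
  use the same ordering, so homologous connections share a feature index —
  16,110 features at the full-scale P = 180.
* **TC** (transconnectome): all heterotopic LH×RH pairs, P² − P features.
  Homotopic (homologue–homologue) pairs are **excluded**: the full
  connectome then counts 2·16,110 + (180² − 180) = 64,440 connections,
  which fixes the convention.
* **FC**: HC-LH ‖ HC-RH ‖ TC.

Parcels belong to 12 resting-state networks; labels are symmetrized across
homologue pairs by adopting the LH member's label, the two visual networks
are merged and the three smallest networks dropped, leaving 8 networks and
therefore 8·9/2 = 36 enrichment groups. Parcels of dropped networks stay in
the classification features — dropping only removes them from enrichment
grouping.

## Classification and scoring

Folds are subject-level and handedness-stratified (default 5); both
hemisphere samples of a subject always share a fold, which prevents
identity leakage, and every run re-checks this. Three classifier families
are provided: LDA (`MASS::lda`; no feature scaling so the discriminant
scalings stay interpretable), a linear-kernel SVM (`e1071::svm`) and a
single-hidden-layer neural net (`nnet`), the latter two on per-feature
standardization fitted on the training folds. No hyperparameter search is
done; settings are exposed as arguments.

Performance is the Matthews correlation coefficient: accuracy is misleading
under the ~9:1 dextral:sinistral imbalance (an all-majority classifier
reaches 90% accuracy but MCC = 0, which the zero-denominator convention
makes exact). Each result gets a 95% bootstrap interval: (truth, prediction)
pairs resampled jointly, 1,000 replicates, distribution mean as the point
value and the 2.5th/97.5th percentiles as the interval; degenerate
replicates score 0 and are kept. `mccAccuracyCalibration()` reproduces the
simulation behind the MCC benchmarks of 0.4 ("good") and 0.6 ("excellent"):
for balanced binary classes MCC = 2a − 1 at per-class accuracy a, while
under heavy imbalance the same per-class accuracy maps to a lower MCC; the
simulation's class sizes and error-spreading rule are explicit parameters
because the original design is not fully specified.

The four-way outcome is scored after decomposition into its chirality and
handedness components (the exact inverse of label construction); a
generalized multiclass MCC is also available through `mcc()` on larger
matrices.

## Enrichment: two permutation stages

Stage one fits a maximal LDA on all samples and asks, per connection,
whether its scaling is extreme against "null models": LDA refits on data
whose hemisphere labels were shuffled *within subject pairs* (each
subject's LH/RH labels swapped with probability ½ — the shuffle unit is a
design choice; shuffling rows independently would break the
two-samples-per-subject structure). Each connection receives a two-sided
rank-proportion p, `min(1, 2·min(frac(null ≤ obs), frac(null ≥ obs)))`,
floored at 3/reps (the smallest resolvable simulated p; .0003 at the
full-scale 10,000 repetitions), and is flagged at p < .01.

Stage two keeps the number of flagged connections fixed and shuffles their
positions uniformly over the grouped upper-triangle features (mirrored back
onto the symmetric matrix, so matrix symmetry is preserved by
construction; features of dropped networks sit outside the shuffle space).
Each of the 36 groups gets a one-sided p — more flagged connections than
chance — with the same floor, then Benjamini–Hochberg correction across
groups.

Two repetition counts matter and they are deliberately decoupled. The
connection stage refits an LDA per repetition and is the expensive stage;
desk-scale runs reduce it to 500–1,000. The group stage is a cheap position
shuffle and stays at 10,000 by default even then: its p floor must stay
fine enough that BH over 36 groups can resolve p < .05 (a floor of
3/1,000 = .003 alone gives .003·36 = .108 when a single group is at floor).

Sign convention: LD1 is oriented so the LH class mean is negative; a
negative aligned scaling then marks a connection stronger in the LH,
positive stronger in the RH, and the (LH>RH, RH>LH) split is invariant to
the arbitrary global sign of the discriminant. Scalings are reported as
scalings — they are not per-feature "importance", since a connection with a
small hemispheric difference can carry a large weight.

### Conservatism of the group-level test

The group-level permutation test is one-sided on a *discrete* count
statistic, so its p-values are super-uniform: groups observing zero flagged
connections get p = 1, and P(p < α) can sit far below α. On null cohorts
the connection-level flagged fraction is calibrated at α (measured .010 at
α = .01 over 50 null cohorts), while the group-level fraction below .05 is
about .01 — valid type-I *control*, not exact calibration. The test suite
asserts exactly that: two-sided calibration at connection level, one-sided
control at group level.

## Hemisphere space

From the maximal LDA: per-hemisphere LD1 scores (LH negative by
convention), within-hemisphere standardized Z(LD1) using the sample (n−1)
SD, and the distance

> LD1_dist = |LD1_LH| + |LD1_RH|,

which is symmetric in the hemispheres and sign-flip invariant. Z(LD1) is
computed from the maximal model rather than pooled fold models (fold
models' discriminant axes are not comparable). LD1_dist is then modelled
against continuous EHI with four candidate forms — linear, quadratic,
continuous one- and two-breakpoint segmented regressions — compared by
nested F-tests and AIC. Breakpoints are estimated by a profiled grid search
(interior 5–95% EHI quantiles, 50 grid points) with Brent refinement, a
boundary flag when the optimum touches the search edge, and standard errors
from a 500-replicate nonparametric bootstrap; AIC counts breakpoints as
parameters so the segmented models are not flattered. The quadratic
reports its vertex together with a curvature check — "peak" language is
only warranted when the parabola opens downward.

## The synthetic cohort generator

The study's raw data are access-restricted, so the package ships a
generator whose defaults *are* the study conditions the analysis is
designed to detect; they are stand-ins chosen once, not fitted quantities:

* **EHI**: a two-component truncated-normal mixture — dextral mass 0.90
  (global right-handedness rate), dextral component N(80, 15) on (0, 100],
  sinistral/adextral component N(−30, 45) on [−100, 0] — reproducing the
  J-shaped population distribution with the expected dextral fraction
  exactly equal to the mass parameter.
* **Covariance**: each hemisphere's latent correlation matrix is a
  network-factor model, C = ΛΦΛᵀ + Ψ with loadings √w on network factors
  (baseline within-network correlation w = 0.35, between-network 0.10).
  Planted LH-minus-RH offsets (default +0.15 in correlation/Fisher-Z units
  on LN–DMN, LN–FPN and within-DMN blocks — the three groups the
  enrichment stage should recover) are applied to the factor-correlation
  matrix Φ, never to raw entries, so positive definiteness is structural
  and violations raise a construction error instead of producing an
  invalid matrix.
* **EHI link**: the offsets scale with a piecewise-linear function of EHI —
  slope 0.01 per EHI unit below a breakpoint at EHI = 75, slope 0 above,
  rescaled to [0, 1] over [−100, 100] — so more sinistral subjects get more
  similar hemispheres and the breakpoint is recoverable. Per-subject noise
  (SD 2 EHI units) jitters the effective EHI before the link.
* **Timeseries**: T i.i.d. multivariate-normal draws (default 300
  timepoints, a desk-scale stand-in for the ~2,400 volumes of a full
  resting-state session).

What the generator does *not* emulate: BOLD autocorrelation, motion and
physiological artefacts, surface geometry, parcel-coverage effects, or any
handedness signature beyond the asymmetry scale. Passing tests therefore
demonstrate that the pipeline detects what it is designed to detect under
clean conditions — not that real data contain such signal.

## Problem sizes used by the tests

Simulation tests run at deliberately reduced scale, chosen once:

* chirality/handedness reproductions: n = 200 subjects, P = 40, T = 300;
* enrichment recovery: P = 40, 40 dextral subjects, T = 300, 500
  connection permutations, 10,000 position shuffles, 8 seeds;
* enrichment type-I: 50 null cohorts at P = 20, n = 30, T = 100, 500
  permutations;
* breakpoint recovery: n = 900 EHI draws from the generator's own link,
  500 bootstrap replicates.

One caution from development: permutation enrichment depends on the
sample/feature regime. With roughly as many hemisphere samples as features
the within-class scatter is barely full rank and null scalings go
heavy-tailed (no connection ever looks extreme); with many more samples
than features the discriminant concentrates its weight on a few
non-redundant connections (the scalings-are-not-importance caveat made
concrete). The recovery test therefore runs in the study's own regime,
features ≫ samples, with planted blocks of at least ~15 connections.

## Known limitations

* LDA in the p ≫ n regime relies on `MASS::lda`'s rank truncation;
  scalings are reproducible but not unique in directions outside the
  retained rank.
* The generator's factor covariance gives block-constant correlations;
  real connectomes have richer within-block structure, which would lower
  enrichment power at equal offsets.
* Segmented fits assume a continuous mean function; breakpoints at the
  extreme 5% of the EHI range are flagged rather than estimated.
* Handedness classification on this generator can only fail for the right
  reason (the planted handedness signal is the asymmetry scale, which
  overlaps heavily between groups); it does not probe discrete
  dextral/sinistral connectivity signatures because none are planted.
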