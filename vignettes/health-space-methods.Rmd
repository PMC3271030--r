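---
title: "The health space model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The health space model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healthspace)
```

## The model

Unsupervised projections (PCA) place subjects on axes defined by variance,
which have no biological meaning; a single supervised projection (PLS-DA)
separates groups but still does not say *which process* moved.  The health
space instead fixes the axes up front: each axis is one predefined
biological process — in the demonstrator configuration oxidation,
inflammation and metabolism — parameterized by its own supervised
multivariate model built only from that process's significantly changed
plasma parameters.

For one axis the pipeline is:

1. **Feature assembly.**  Each complete subject contributes one row per
   treatment arm of the cross-over.  A parameter enters as its *baseline*
   value (first timepoint of that arm's period — each period has its own
   baseline, which the washout of a cross-over design justifies), its
   *mean over time* (arithmetic mean across the period's timepoints), or
   both.  The class code is `0` for the treated arm and `1` for control.
2. **Autoscaled PLS-DA with double cross-validation.**  Features are
   autoscaled (mean 0, unit sample sd) and a NIPALS PLS1 model regresses
   the class code on them.  The outer CV loop partitions *subjects* (both
   arms travel together, so autoscaling constants and weights for a
   held-out prediction never saw that subject); the inner loop picks the
   component count by inner-CV misclassification (score ≥ 0.5 predicts
   control; ties go to the fewest components).  Every sample receives one
   out-of-fold prediction score.
3. **Anchor scaling.**  All of an axis's scores are mapped by
   $s' = (s - \bar s_\mathrm{treated}) / (\bar s_\mathrm{control} -
   \bar s_\mathrm{treated})$, so the treated-group mean sits at 0 (the
   "healthy" origin — health here is *defined* as the average state after
   the intervention) and the control mean at 1.  The map also
   canonicalizes score orientation; an anti-separating axis is simply
   flipped.  Scores are comparable within an axis, deliberately *not*
   between axes, and no operation in the package computes cross-axis
   ratios.  The axes are statistically interdependent (parameters may be
   shared) yet are drawn orthogonal for display, exactly as the procedure
   prescribes; nothing is re-orthogonalized.

The per-subject **response vector** is the control-minus-treated score
difference per axis, so positive values mean the treatment moved the
subject toward the origin.  Response vectors are clustered as-is (no
rescaling) with Euclidean distance and average (UPGMA) linkage; the
default cut at `k = 2` reflects the two main responder groups the method
is meant to expose, and an automatic cut (largest relative merge-height
gap) is available but never overrides an explicit `k`.  Clusters are then
characterized parameter-by-parameter by a two-way ANOVA
(cluster × treatment arm) with interaction-first logic: a significant
interaction (a treatment effect present in one responder group only) is
the headline verdict; main effects are interpreted only where the
interaction is not significant.  Benjamini–Hochberg control at
$\alpha = 0.05$ is applied with the interaction p-values as one family
across parameters and each main effect as its own family over the
parameters without a significant interaction.

## Tunable parameters

| parameter | default | why |
|---|---|---|
| `outerFolds` / `innerFolds` | 7 / 5 | the procedure's source does not state fold counts; 7 outer folds keep ≥ 4 subjects per fold at n ≈ 33 while the inner 5-fold still has both classes everywhere |
| `maxComponents` | 10 | generous ceiling; the inner CV almost always selects 1–3 components on these designs |
| component selection | inner misclassification, ties → fewest | parsimony; RMSE selection would favor more components without classification benefit |
| `scoreType` | `"oof"` | plotted/clustered scores are the unbiased out-of-fold predictions; `"refit"` exists for projecting and for exact self-consistency checks |
| anchor source | oof scores | anchors stored with the refit model for projection; the refit-vs-oof offset is kept as a per-axis diagnostic |
| `alpha` | 0.05 | the stated rejection level |
| ANOVA SS | Type II | responder clusters are unbalanced; Type II matches the interaction-first reading (mains tested without assuming an interaction); Type III available |
| ANOVA unit | per-subject-arm means | one value per subject per arm, so repeated timepoints are never pseudo-replicated |
| missing values | drop parameter > 20 % missing, else arm-wise mean imputation | least-structured choice; every drop/imputation is warned about |
| outlier rule | top-split singleton with merge height > 3 × median pairwise distance, applied repeatedly | automates the manual exclusion of one aberrant subject; an explicit exclusion list overrides it and both paths are logged |
| response sign | control − treated | positive = moved toward the healthy origin; configurable |

## The synthetic-data generator

Real studies of this design are small and rarely deposited, so the
generator is a first-class module with known ground truth.  It emulates a
double-blind placebo-controlled cross-over study: ~33 subjects, parameter
blocks per process (7 oxidation / 18 inflammation / 115 metabolism by
default; 5 / 15 / 114 in the `"no-diet"` preset that mirrors rebuilding
the space without diet-derived parameters), a per-subject random intercept
shared across arms and timepoints (the within-subject pairing), residual
noise equicorrelated within a block (`withinBlockCorr = 0.3`), and an
additive standardized treatment effect (`effectSize`, Cohen's d scale,
default 1) acting on affected parameters at post-baseline timepoints of
the treated arm only.  Two planted responder subgroups (50 / 50) scale the
block effects by 1.5 / 1.5 / 0.3 and 0.3 / 0.3 / 1.5 — an
inflammation/oxidation responder group and a metabolic responder group.
All randomness flows from one seed; identical config + seed is
byte-identical.

What it does *not* emulate: metabolite identities, platform
characteristics (LC-MS/GC-MS/array noise), log-normal or heteroscedastic
scales, period or order effects (the demonstrator study found none), or
transcript-level data.  Passing recovery tests on this generator therefore
shows the pipeline recovers structure *of this kind*; it does not certify
performance on any particular real study.

A consequence worth stating plainly: under these default conditions the
planted subgroups are only weakly separated.  The equicorrelated block
noise does not average out across a block's parameters, the effect acts on
one of two timepoints (halving its trace in mean-over-time features), and
the subgroup multipliers differ by 1.2·d/2 per axis — a total
between-subgroup separation of roughly twice the response noise.  Even an
oracle clustering of the true block-mean responses misassigns ~15–20 % of
subjects, so perfect subgroup recovery is not attainable at `effectSize =
1`; the acceptance suite asserts the stated recovery targets anyway and
reports the honest result, and the recovery improves steadily with
`effectSize` (the monotonicity property tested in the suite).

## Numerical choices

* NIPALS PLS1 needs no inner iteration (the weight update is exact for a
  single response); a residual or weight norm below `1e-12` ends component
  extraction, capping the model with a warning.  Zero-variance features
  are centered, scaled by 1 and flagged — never dropped, so fold geometry
  is stable.
* With as many components as the design's rank, training predictions
  equal ordinary least squares; the suite asserts this to `1e-8` and the
  1-feature case against the closed form exactly.  Successive training
  score vectors are orthogonal to `1e-8`.
* Anchor scaling requires distinct group means; equality is a degenerate
  axis and construction fails with the axis named.  An axis whose
  out-of-fold misclassification is ≥ 0.45 warns that it may be
  uninformative.
* UPGMA merge heights are checked against a brute-force all-pairs-average
  oracle to `1e-10`; agglomeration ties are broken deterministically by
  the stock implementation given the package's sorted, deterministic
  subject order.
* Fold assignment derives from one master seed (child seeds per axis), so
  every build is reproducible; no global RNG state leaks (the caller's
  `.Random.seed` is restored).

## Problem sizes used in the checks

The unit suite runs reduced designs (8–20 subjects, 3–10 parameters per
block) chosen so each property is exercised in seconds.  The end-to-end
validation uses the full default study (33 subjects, 140 parameters):
50-seed recovery and planted-interaction runs and a 100-seed null-study
FDR calibration — a few minutes in total.

## Known limitations

* Two arms only; the contrast and the 0/1 anchors are inherently
  two-class.
* No weighting of axis parameters and no bootstrap feature selection
  (deliberate non-goals of this version).
* `projectSamples()` scores *new* subjects in an existing space — an
  enabling extension; the original procedure never specified cross-study
  projection, and no absolute "health" calibration across studies is
  implied.
* The univariate screen defaults to a paired t test on subject-matched arm
  means; the demonstrator study inherited its parameter selection from an
  earlier analysis, so curated axis definitions can be supplied directly
  and the screen skipped.
* Interactive 3-D output is not provided; figures are static PDF/PNG/SVG.
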