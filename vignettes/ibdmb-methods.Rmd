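---
title: "Models and design choices in ibdmb"
author: "ibdmb authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in ibdmb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the statistical machinery it
implements: the models and their assumptions, the tunable parameters and
why their defaults are what they are, what the synthetic cohort generator
does and does not emulate, and the design choices that were genuinely
open. Every empirical statement here is one the test suite or
`scripts/acceptance.R` computes; nothing is quoted from external data.

## The analysis problem

A baseline fecal sample from a newly diagnosed IBD patient yields a
genus-level count table from 16S amplicon sequencing. Counts are
*compositional*: the sequencer fixes each sample's total, so only relative
information survives, and any genus that truly expands displaces the
apparent abundance of every other genus. Analyses must additionally
contend with heterogeneous sequencing depth, batch (sequencing-library)
effects, and clinical covariates (age, sex, BMI, recent antibiotics,
sampling delay). The package's stages address, in order: diversity
(within- and between-sample), differential abundance between diagnosis
groups, a transferable log-ratio summary of the UC-CD axis, and
prediction of a severe first-year disease course.

## Core conventions

- **Orientation.** On disk, count tables are samples-as-rows with a header
  comment declaring the orientation; in memory the S4 container extends
  `SummarizedExperiment` and therefore stores taxa x samples. Accessors
  (`countMatrix`, `sampleData`, `sampleDepths`) insulate users from this.
- **Depth filter, then rarefaction.** Samples under 10 000 reads are
  removed (`filterSamples`), mirroring the sequencing QC convention that
  such samples go back for re-sequencing. Diversity works on data rarefied
  to 9 503 reads by without-replacement (multivariate hypergeometric)
  subsampling; the seed is a required argument, never hidden global state.
  Because 10 000 > 9 503, no conforming sample is dropped at rarefaction.
- **Calprotectin clamping.** Fecal calprotectin enters analyses clamped to
  the ELISA recording range 29-1801 µg/g at ingest, so downstream models
  see the values as a clinic would record them.
- **Genus-key normalization.** Cross-cohort joins match taxa on a
  canonical key: last non-empty lineage rank, rank prefixes and brackets
  stripped, SILVA "group" suffixes removed, punctuation collapsed. This
  is what lets an index built in one cohort score another cohort's table.

## Diversity

Shannon diversity is reported in nats; observed richness counts taxa with
at least one read after rarefaction. Group comparisons use a Gaussian GLM
with age, sex, BMI and antibiotics as default covariates; constant or
collinear covariates are dropped with a warning rather than silently
absorbed.

Between-sample structure uses Bray-Curtis dissimilarities on rarefied
counts. PERMANOVA partitions the distance matrix's sum of squares with
covariates entered before the group term (sequential, so the group effect
is covariate-adjusted), and tests the group pseudo-F by permuting sample
labels; p-values use the `(1 + b)/(1 + m)` convention and are therefore
never zero. With `nPermutations = "exact"` all label permutations are
enumerated, which the tests exploit to check the implementation against a
from-scratch brute-force oracle on n = 6 designs. PERMDISP compares
per-group distances to the group *spatial median* (more robust than
centroids — a deliberate choice) in principal-coordinate space. The
default 999 permutations trades Monte Carlo error (p resolution 0.001)
against runtime.

## The three-model consensus

Single differential-abundance methods disagree notoriously; the package
therefore reports a genus only when **all three** model families call it
at BH-adjusted q < 0.05 **and** their natural-log fold changes share a
sign. The families share one interface (group contrast + covariates +
library random intercept; taxa present in ≥10% of samples are tested) but
differ in how they confront compositionality:

1. **Bias-corrected log-linear** (ANCOM-BC family). Observed log counts
   equal true log abundances plus a sample-specific *sampling fraction*.
   The fraction is estimated as a per-sample intercept by alternating
   least squares and subtracted; the per-taxon linear model then yields a
   Wald test. Two refinements matter in practice: the offset is estimated
   from high-prevalence taxa only, because taxa with many zeros respond
   nonlinearly to a depth shift (log(c+1) compresses near zero) and would
   bias the row-mean estimate; and any residual common shift of the group
   coefficients is removed at the kernel-density mode of their
   distribution across taxa — the operating assumption, shared with the
   published method family, being that most taxa are not differential.
2. **CLR linear** (LinDA family). Ordinary regressions on centered
   log-ratio abundances (pseudocount 0.5); the compositional bias appears
   as a common offset of all coefficients and is removed at the mode, with
   t-tests on the corrected coefficients.
3. **TSS log-linear** (MaAsLin family). Regressions on
   log(relative abundance + half the smallest non-zero relative
   abundance). Faithful to its family, this model applies no
   compositional correction, which is exactly why it is only one vote of
   three.

These are re-implementations of the model *cores*, not ports: structural
zero detection, pseudocount sweeps and other sensitivity features of the
named packages are out of scope, and no numeric identity with them is
claimed — fidelity is established by simulation (null calibration,
parameter recovery, batch-confounding behaviour) instead.

**Random intercept.** The sequencing library enters as a variance
component (lme4) when at least three libraries are present, and as a fixed
term with two — with fewer levels a variance component is not estimable.
Mixed-model p-values use the Wald normal approximation; across 150 taxa
per method this is orders of magnitude cheaper than Satterthwaite degrees
of freedom and the difference is negligible at cohort sample sizes. The
test suite verifies that with library confounded into the group contrast,
the random intercept removes nearly all batch-attributable false
positives.

**What the consensus can and cannot do.** Under the global null each
method's type-I rate is calibrated (≤0.07 at nominal 0.05 in the
acceptance checks) and consensus hits are essentially absent. With 10
genuinely affected taxa among 150, however, BH at q < 0.05 admits about
`alpha * (R+1) * m0/m ≈ 0.5` borderline false positives *per method* by
design — that is what FDR control means — and because all three models are
near-linear in the same log-abundance noise, their borderline calls are
highly correlated and the intersection removes only about half of them.
The consensus hit set therefore recovers the planted set exactly in only
roughly three quarters of simulated cohorts, with zero misses and ~0.3
extra taxa on average; perfect set recovery is not a property this (or
any correlated-consensus) procedure can guarantee, though its empirical
FDR stays well under 0.10.

## The UC-CD index

From a UC-vs-CD consensus, taxa with positive lfc toward UC form the
`up` set and negative the `down` set, and a sample scores

\[ I = \ln\frac{\sum_{t \in up} x_t + \varepsilon}
               {\sum_{t \in down} x_t + \varepsilon} \]

on relative abundances with ε = 1e-6. Decisions worth recording: the
index is computed on *relative* abundances (sums of raw counts would make
it depth-dependent); ε guards both sums so the score is always finite and
is configurable; index taxa missing from a transfer cohort contribute
zero rather than triggering renormalization, with the matched fraction
reported as `coverage` so a user can judge how much of the signature a
cohort carries. The index is compositionally coherent (multiplying a
sample's counts by a constant leaves it unchanged) and exactly
anti-symmetric under swapping the two sets — both are tested identities.

The disease-location analysis fits covariate-adjusted linear models for
the pairwise contrasts along the colonic continuum (ileal vs colonic CD;
colonic CD vs UC) and adds an ordinal trend test across
L1 < L3 < L2 < E1 < E2 < E3. The trend test goes beyond pairwise
contrasts and is labelled `ordinal_trend` in the output to keep that
distinction visible.

## Severe disease course and prediction

The composite 1-year endpoint is severe iff any criterion fires:
IBD-related hospitalization, IBD surgery, stoma formation, **more than
two** corticosteroid courses (exactly two is not severe — the boundary is
strict and unit-tested), a second biologic started for failure of the
first, and — in CD only — new fistula/abscess/stricture findings. The
classifier is a pure function returning every trigger, and the synthetic
generator draws event records *consistent* with its drawn severe status,
so the rule can be verified end-to-end.

Prediction uses Monte Carlo cross-validation: 100 stratified random
80/20 train/test splits (both defaults configurable; the repeat count and
split ratio are artifact decisions, as is the signed-rank test used to
compare feature sets — none of the three is dictated by the underlying
clinical problem). Split membership depends only on the labels, seed,
repeat count and test fraction, so reports for different feature sets are
paired repeat-by-repeat and compared by a two-sided Wilcoxon signed-rank
test on per-repeat AUC differences. The learner is a gradient-boosted
tree classifier (shallow trees, depth 3, learning rate 0.1, early
stopping on an inner stratified validation fold) with the adjustment
covariates always appended and the library as an integer-coded feature;
a booster with a true random-effect term would be the closest published
analogue, and the categorical encoding is the documented fallback.
Attribution uses the tree-SHAP values native to the booster; the local
accuracy identity (contributions + base value = margin) is asserted in
the tests. Clinical disease-activity scores are a separate feature set
and are excluded from *diagnostic* models by a configuration flag, since
they are intertwined with the diagnostic labels themselves.

## The synthetic cohort generator

`generateCohort` draws, per sample, taxon log-intensities
`base + group + covariate·z + batch + severe + N(0, dispersion)`,
renormalizes, and samples counts multinomially at a log-normal library
size — a log-normal-multinomial model chosen (over Dirichlet-multinomial)
precisely so that group, covariate and batch effects compose additively
on the log scale, matching the assumptions of all three DA families.
Severe status is drawn *first* and its effects applied afterwards, so
outcome prediction has a recoverable signal by construction.

Defaults are the study conditions the package is exercised under: group
sizes 658 UC / 324 CD / 36 IBD-U / 26 + 41 suspected / 144 symptomatic /
72 healthy controls; 150 genera with a fixed long-tailed (exponential on
the log scale) baseline; dispersion 1 (log-scale sd of per-sample taxon
noise); library sizes log-normal(log 30 000, 0.35), placing >99.9% of
samples above the 10 000-read floor; eight sequencing libraries with
healthy controls confined to one (the single-library design real healthy
panels often have); severe-course probabilities 17% (CD) and 9% (UC).
Covariates are drawn from distributions loosely matched to published
cohort summary tables (age ~ log-normal around 39y, CD 60% female,
BMI ~ N(24.6, 4), antibiotics 8-19% by group, sampling delay log-normal
with symptomatic controls near zero, calprotectin log-normal with
group-specific medians, clamped). Biochemistry is drawn independently of
severe status, so it is uninformative for prognosis by construction —
the committed condition under which the microbiome-vs-biochemistry
comparison is evaluated.

Planted-effect scenarios place effects on *mid-abundance* genera
(baseline ranks ~40-85 of 150). Consensus-grade differential genera in
real cohorts are typical commensals, not the dominant taxa; planting
ln(4) effects on the ten most abundant genera would displace a quarter of
total abundance and manufacture an unrealistically large compositional
shock. Committed scenario scales: differential-abundance recovery uses
n = 200/group with |lfc| = ln 4; the location gradient uses shifts of
0.4·(rank − 3.5) on the index taxa; severe-course prediction uses 400 UC
samples at 25% severe with eight taxa at |lfc| = ln 3 (the acceptance
script additionally runs the full-size cohort at its default 9% severe
rate); null calibration uses 50-100 seeds at n = 100/group. These sizes
keep each property estimable with modest Monte Carlo error.

**What the generator does not emulate:** phylogenetic correlation between
genera, zero inflation beyond what the multinomial induces, longitudinal
within-subject dynamics, diet, or any attempt to fit the real cohort's
parameters (its data are not public). Passing tests therefore demonstrate
internal statistical validity — calibration, recovery, transfer under
taxon dropout — not that real cohorts will show effects of these sizes.

## Numerical choices and degenerate inputs

- Rarefaction maps sampled read indices to taxa through cumulative counts
  (exact multivariate hypergeometric; zero-count taxa handled by the tie
  behaviour of the interval search).
- OLS across taxa is a single QR decomposition shared by all taxa;
  rank-deficient designs drop aliased columns and error only if the
  contrast itself is aliased.
- A taxon with zero residual variance and zero effect (constant counts at
  equal depths) reports lfc 0 and p 1 rather than 0/0.
- `NA` p-values propagate through BH adjustment without entering `m`.
- AUC uses midranks, so ties count one half and an all-tied score vector
  scores exactly 0.5.
- All seeds are explicit arguments; the pipeline fans one master seed out
  through a fixed affine scheme so adding a stage never perturbs earlier
  stages' streams.

## Known limitations

- The consensus's exact-set recovery ceiling discussed above.
- Mixed-model DA p-values are Wald approximations; with very few
  libraries and tiny cohorts they can be liberal, which is one reason the
  fixed-term fallback exists below three libraries.
- The index's missing-taxon policy (contribute zero) deliberately shrinks
  transfer scores toward zero at low coverage instead of extrapolating;
  users should read `coverage` before interpreting a transferred score.
- The booster treats the library as an ordinary feature, not a variance
  component; with strong library-outcome confounding its AUCs can be
  optimistic relative to a true mixed-effects learner.
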