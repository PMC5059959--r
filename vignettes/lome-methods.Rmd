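---
title: "Constructing low-mass-ion discriminant equations: methods and design"
author: "lome package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing low-mass-ion discriminant equations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lome)
```

# The problem

Serum profiled by MALDI-TOF mass spectrometry yields, per measurement, a
centroided list of low-mass ions (LMIs): (m/z, intensity) pairs up to
m/z 2500, largely reflecting the metabolome. A low-mass-ion discriminant
equation (LOME) is a signed linear score over a small panel of such
ions,

$$\mathrm{DS}_j \;=\; \sum_{i \,\in\, \text{panel}} w_i \, x_{ij},$$

where $x_{ij}$ is the preprocessed (Pareto-scaled, weighted) intensity
of ion $i$ in sample $j$ and $w_i$ is a per-ion weighting factor derived
from PCA-based discriminant analysis. A sample screens positive when its
mean DS across replicate measurements exceeds a threshold (0 under the
sign rule). The scientific appeal is a single cheap serum measurement
that can, in principle, screen for several diseases at once; the
statistical challenge is selecting a handful of discriminative ions out
of roughly $10^4$ detected ones without overfitting.

This package implements the full construction pipeline: replicate-aware
alignment on a reference mass axis, normalization and Pareto scaling,
PCA-DA weighting factors, two combinatorial search algorithms that pick
the ion panel, and evaluation under a two-stage training scheme. Because
no instrument data are distributed, a synthetic-cohort generator with
known planted discriminative ions makes every stage testable end to end.

# The two-stage training scheme

Samples are trisected into Sets A1, A2 and B, stratified by class (and
by clinical stage when a `stage` column is present), with set sizes
within each stratum differing by at most one (`trisect()`). Sets
A = A1 ∪ A2 and B are the training and validation sets. Classes can be
held out of training entirely (`holdoutClasses`); their samples go to
Set B and are reported only through a per-group specificity, mirroring
how rare disease groups are handled in screening studies.

The stages are:

1. **Reference measurement selection** (`selectReferenceMeasurement()`).
   Each sample is measured several times (six by default). For each
   replicate index, the Set A1 spectra of that replicate are aligned on
   their own merged axis, preprocessed, and fitted with PCA-DA; the
   replicate whose discriminant score separates the classes best
   (largest sensitivity + specificity at threshold 0, ties by Fisher
   ratio then lower index) becomes the *reference mass spectrum*. Its
   axis anchors all further alignment, and its PCA-DA supplies the
   weighting factors.
2. **Preprocessing** (`alignToReference()`, `realign()`,
   `normalizeTotalArea()`, `paretoScale()`, `applyWeights()`,
   `averageReplicates()`). The remaining measurements of every sample
   are aligned on the reference axis at 300 ppm, normalized to a common
   total area, Pareto-scaled, multiplied by the weighting factors, and
   averaged per sample.
3. **Search Algorithm 1** (`searchPreliminary()`): ions whose weighted
   intensity magnitude exceeds 0.1 in more than half of the reference
   table's columns become the preliminary candidates.
4. **Search Algorithm 2** (`searchDiscriminative()`): a
   germination/growth combinatorial search over the candidates on the
   averaged Set A table returns the discriminative panel.
5. **Freezing and evaluation** (`buildLome()`): the model (axis, panel,
   weights, scaling statistics, threshold) is frozen and Sets A1, A2
   and B are evaluated separately; Set B never participates in any
   fitted quantity.

# PCA-based discriminant analysis

The original analysis used a proprietary implementation whose
internals are not published; we reconstruct the standard meaning of
PCA-DA. With Pareto-scaled columns as observations:

- PCA via singular value decomposition, with no re-centering (fitting
  columns already have zero per-ion mean after Pareto scaling);
- retain the smallest number of components explaining ≥ 95 % of the
  variance (`varianceRule`), capped at $n_\text{columns} - 2$ so the
  within-class covariance stays estimable, and optionally by
  `maxComponents`;
- a two-class Fisher discriminant on the component scores, with the
  pooled covariance regularized by adding $10^{-8}\,\mathrm{tr}(S)/k$
  to its diagonal;
- the discriminant direction back-projected to ion space and scaled to
  unit Euclidean norm, signed so the target class scores positive.

Back-projection makes the score an *exact* linear functional of the
ion intensities, which the rest of the pipeline requires: the DS of a
panel is simply the sum of the panel's weighted intensities, and the
DS of a union of ion sets is the sum of their DSs. The unit-norm
convention fixes the scale that the magnitude-0.1 candidate filter
acts on; with it, weighted intensities of non-discriminative ions
shrink as the axis grows, which is what makes the filter selective on
dense axes.

# The combinatorial search

**Search Algorithm 1** applies two strict cuts on the weighted
reference table: magnitude > 0.1 (strictly), in strictly more than
half of the columns. Both strictness choices are deliberate: they make
boundary cases deterministic (an ion at exactly 0.1, or passing in
exactly half the columns, is excluded).

**Search Algorithm 2** has two phases, both scored by the sum of
sensitivity and specificity of the combination's DS at threshold 0:

- *Germination.* If a single candidate already separates the training
  set perfectly it is returned at once. Otherwise all 2- and 3-subsets
  are scored; the best combination is set aside and the enumeration
  repeats on the remainder until at most one candidate is left. The
  set-aside combinations then become atomic units and the grouping
  repeats hierarchically. The hierarchy stops when one unit remains or
  when a full round fails to improve the best score seen so far — the
  stopping rule the original description leaves open; we chose the
  no-improvement rule because further grouping can only dilute a
  better unit once scores stop rising. The best unit formed at *any*
  level (singletons included) becomes the seed set.
- *Growth.* 1-, 2- and 3-subsets of the candidates outside the seed
  are added speculatively; the best enlargement replaces the seed only
  when it strictly improves the score, so the accepted sequence is
  strictly increasing and the phase terminates (the score is bounded
  by 2). Leftover single candidates from the first germination round
  are not grouped further but remain available to growth.

Ties at every decision follow two priorities: fewest ions, then
largest Fisher discriminant ratio
$(\bar d_\text{pos} - \bar d_\text{neg})^2 / (s^2_\text{pos} +
s^2_\text{neg})$ (sample variances; a zero denominator scores $+\infty$
when the means differ and 0 otherwise). Residual ties break toward the
lexicographically smallest ion-index set, making the whole search
deterministic. The test suite cross-checks the search against an
independently written trajectory oracle for candidate sets of up to 12
ions.

The number of candidates entering the search is capped (default 64,
with a warning) by keeping the best singleton scorers; scoring all
2-/3-subsets repeatedly is cubic in the candidate count and the cap
keeps desk-scale runs in seconds while leaving the algorithm itself
exact. Tests always run the uncapped algorithm on small candidate
sets.

# Numerical and boundary choices

- **ppm matching is inclusive**: a peak exactly 300 ppm from a
  reference ion matches. Each peak is assigned to its nearest
  reference ion in relative (ppm) distance, ties toward the lower m/z;
  peaks mapping to one ion are summed, conserving total ion current.
- **Import filters**: the minimum-response threshold (10.0) is
  inclusive; when the peak-count cap binds, equal intensities at the
  boundary keep the lower m/z. The filter is idempotent.
- **Normalization** targets the mean of the fitted columns' total
  areas, so the average column is unchanged; the target is frozen with
  the model. A column with non-positive total area is an error naming
  the column.
- **Pareto scaling** uses the sample (n−1) standard deviation, the
  metabolomics convention; zero-variance ions map to 0 everywhere.
  Statistics are fitted on the Set A columns and frozen; Set B and any
  later sample are transformed with the frozen statistics. The
  original software rescales per import, which would let validation
  data influence its own transform; freezing prevents that leakage.
- **Decisions**: screen-positive requires DS strictly greater than the
  threshold, so DS exactly 0 under the sign rule is negative —
  favoring specificity, which is the binding constraint in screening.
- **Trained thresholds** (`trainThreshold()`) scan all cut-points
  (midpoints of consecutive distinct scores plus one point outside
  each end), maximizing sensitivity + specificity, ties toward higher
  specificity, then the smaller threshold.
- **Reported percentages** are rounded half-up to two decimals, full
  precision retained internally; undefined ratios are reported as NA,
  never as 0.
- **Scoring new samples** (`scoreSamples()`) excludes measurements of
  the replicate that defined the reference spectrum, matching the
  training pipeline, which averages the *other* measurements of each
  sample; a switch restores all-replicate averaging.

# The synthetic cohort

`generateCohort()` emulates the structure the pipeline needs to be
tested against, not any particular instrument:

- per-ion baseline intensities are log-normal (`baseLogMean = log 500`,
  `baseLogSd = 1`), giving the heavy-tailed positive intensities of
  centroided MALDI spectra;
- planted discriminative ions are shifted additively on the log scale
  in every target-class sample (direction random per ion), i.e. a
  multiplicative fold change, the natural effect model for MS
  intensities;
- replicate noise is multiplicative with configurable CV, plus a
  per-measurement global intensity factor (log-sd 0.3) that total-area
  normalization is meant to remove;
- every observed m/z is jittered with a configurable ppm standard
  deviation (default 60 ppm, comfortably inside the 300 ppm matching
  window);
- nominal ion positions are uniform on m/z 50–2500 with a minimum
  spacing of 600 ppm so that 300 ppm matching is unambiguous by
  construction (a switch disables the spacing to stress-test
  alignment);
- one RNG stream is seeded per cohort and per-sample sub-seeds are
  drawn from it, so identical configurations reproduce byte-identical
  cohorts.

What the generator does **not** simulate: isotope envelopes, adducts,
matrix clusters, detector saturation, baseline drift, or correlated
biological covariation between ions. Passing tests therefore
demonstrate that the pipeline's algorithms behave as specified on data
with known ground truth — not that the pipeline would reach any
particular performance on real serum spectra.

The default noise structure is a modeling choice, not an empirical
claim: the original study does not characterize its noise, and the
log-normal model is the field's standard stand-in.

# Problem sizes used in the tests

The shipped tests run the full pipeline at desk scale: cohorts of
2–3 classes × 8–30 samples × 2–4 replicates on axes of 40–200 ions,
and search-oracle comparisons on 12 candidate ions; the acceptance
script uses the generator's full defaults (2000 ions, six replicates,
30 samples per class across five classes, one held out of training).
These sizes were chosen so each property is exercised on hundreds of
samples of randomness while the whole suite stays interactive.

# Known limitations

- The PCA-DA reconstruction is the standard published meaning of the
  method; the proprietary implementation's component count and exact
  preprocessing are unrecoverable, so both are exposed as
  configuration (`varianceRule`, `maxComponents`).
- The germination hierarchy's nesting depth and stopping rule are
  under-specified in the original description; the implemented reading
  is recorded in the search trace rather than asserted as the authors'
  intent.
- The reference axis is built by greedy single-pass clustering of
  pooled peaks, a deterministic stand-in for the import behavior of
  the original peak-table software.
- Only two-class (target vs. rest) discrimination is supported;
  multi-disease screening is done by building one LOME per target.
- No "indeterminate" band around the threshold and no panel-shrinkage
  post-processing are implemented.
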