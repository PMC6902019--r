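---
title: "Calling stimulation-induced protein translocation from fractionated TMT proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling stimulation-induced protein translocation from fractionated TMT proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transloc)
```

## The experimental design the pipeline assumes

Each donor contributes one TMT 10-plex set holding that donor's nine
samples — cytosolic (C), membrane/organelle (M) and nuclear (N)
fractions at rest and after 15 and 60 min of stimulation — plus a
pooled internal standard in channel 131. Because the internal standard
is the *same* pool in every set, per-channel ratios to channel 131 put
all donors on one scale; sample-median normalization then removes
residual per-sample loading differences. Two properties of this design
drive every modeling choice downstream:

* **Fractionation enriches, it does not isolate.** A protein that is
  80% nuclear still leaves measurable signal in the C and M fractions.
  Translocation therefore manifests as *partial, opposite-direction*
  fold changes in two fractions, not as appearance/disappearance.
* **Three donors give one degree of freedom... almost.** A paired
  analysis (within-donor differences) leaves n − 1 = 2 residual df per
  gene. Per-gene variance estimates at df = 2 are useless on their
  own; borrowing strength across genes is not optional here, it is the
  analysis.

## Quantification and picked protein FDR

PSM-level log2 ratios to the internal standard are computed per set,
each sample column is centered on its median (idempotent by
construction; tolerance 1e-9), and gene-level values are medians over
the PSMs of peptides *unique* to a gene symbol — a peptide observed
with two gene symbols in the input contributes to neither. Uniqueness
is decided from the PSM table's own annotations; no external protein
database is consulted.

Protein-level error control uses the picked target–decoy strategy on
gene-symbol groups: for each gene only the better-scoring of the
target/decoy pair survives, the picked list is sorted by descending
score, and the FDR estimate at rank k is (decoys so far)/(targets so
far); targets are kept up to the deepest rank at or below the 1%
threshold. Which score is "the" protein score is not fixed by the
method; this implementation takes a per-gene best-PSM score column,
which is the common choice when PSMs are pre-filtered to 1% PSM-level
FDR upstream. Ties are resolved target-before-decoy and then
lexicographically by symbol, so results are reproducible to the byte.

The quantification funnel is deliberately two-staged: rollup leaves
missing values in place (a gene absent from one set keeps NA columns),
and only `filter_full_quantitation()` removes genes, so the run report
can audit the counts *identified → overlapping across sets → fully
quantified* separately.

## The moderated paired model

For gene g in fraction f, within-donor differences
Δ_d = x(treatment, d) − x(baseline, d) give the paired fold change
log2FC = mean(Δ), residual variance s² = var(Δ) and df = n − 1.
Moderation follows the scaled-F empirical-Bayes model with a
spectra-count covariate: the prior variance s₀² is a smooth function of
the gene's median PSM count across sets, because a gene quantified by
ten PSMs is averaging away per-spectrum noise that a one-PSM gene keeps
in full. Concretely:

* log s² is regressed on log count with a degree-1 loess (span 0.75);
  with fewer than 20 genes, fewer than two distinct counts, or a
  degenerate local fit, the trend falls back to monotone binned means
  and finally to a constant.
* The prior df d₀ comes from method of moments on the residuals
  z = log(s²/s₀²): under the model var(z) = trigamma(df/2) +
  trigamma(d₀/2), solved with a Newton trigamma inverse. d₀ is capped
  at 1e6, which represents "effectively infinite" — at that point the
  posterior variance is the trend value and the reference distribution
  is indistinguishable from normal (within 1e-6 in P).
* Because E[log s²] = log σ² + digamma(df/2) − log(df/2) under scaled
  χ², the fitted log-trend is a *biased* estimate of log s₀² — at
  df = 2 the raw geometric mean underestimates the prior variance by a
  factor of about e^0.58. The trend is therefore corrected by the
  expectation of log F(df, d₀) before use. Skipping this correction
  makes every moderated test anticonservative, which is visible as a
  failed uniformity check on null simulations; the test suite verifies
  the corrected estimator recovers the true (s₀², d₀) of data generated
  from the scaled-F model, and agrees with an independent
  empirical-Bayes implementation in the constant-trend case.
* Zero sample variances (possible with medians over few PSMs) are
  floored at the smallest positive observed variance times 1e-3 before
  taking logs.

The moderated statistic is t = log2FC/(s̃/√n) with
s̃² = (d₀·s₀²(count) + df·s²)/(d₀ + df) on d₀ + df degrees of freedom.
P values are two-sided and deliberately *not* corrected for multiple
testing: in this design P acts as a variability filter and the fold
change as the effect-size filter, and the final opposite-direction
requirement is itself a stringent compound criterion.

By default the trend is fitted pooling genes across all three fractions
within a contrast (`per_fraction = FALSE`): the variance-versus-count
relationship is a property of the measurement process, not of the
compartment, and pooling triples the genes informing d₀. A per-fraction
option exists for designs where fractions differ strongly in technical
quality.

## The decision tree

A gene is called translocating at a contrast if some fraction has
log2FC > 0.201 and another has log2FC < −0.201, with P < 0.05 in both.
All inequalities are strict, so genes sitting exactly on a threshold
are excluded reproducibly. Both thresholds are configurable;
0.201 log2 units (≈ 15% change) and P < 0.05 are the defaults. The
opposite-direction requirement is evaluated on signs only — the gained
and lost amounts need not match, because fraction purities and the
compression inherent to MS2 reporter quantification make exact mass
balance unobservable. The 1 h contrast is the default for calling; the
15 min contrast is fitted and reported but only used for calls on
request. Every qualifying fraction pair is recorded, and the summary
counts a gene once per fraction it touches, so "share of calls
involving the membrane fraction" is well defined even for three-way
qualifiers.

Two containment properties are tested as invariants: the passing set
is monotone in both thresholds, and is always a subset of the
candidate set (P < 0.05 in ≥ 2 fractions) at the same P threshold.

## Compartment classification

Fully quantified genes are z-scored per row and clustered with k-means
(k = 3) under 1 − Pearson distance, implemented through the identity
‖x̃ − ỹ‖² = 2(1 − cor(x, y)) for rows centered and scaled to unit
norm — so a standard Euclidean k-means on the rescaled rows minimizes
total correlation distance. 25 random restarts are used and the seed is
fixed, making assignments reproducible. Clusters are labeled with the
fraction whose columns have the highest cluster mean, ties broken in
the fixed order C, M, N; a per-gene silhouette-like confidence
(1 − own-centroid distance / nearest-other-centroid distance) is an
addition of this implementation, for downstream filtering, and is
marked as such in the output. Row z-scoring before clustering is an
assumption — heat-map tools differ in their row scaling — but any
location/scale row transform leaves 1 − Pearson unchanged, so only the
exclusion of constant rows is consequential.

PCA of the sample columns (genes centered) plus a mean silhouette over
fraction groups gives the fractionation QC; average-linkage clustering
of the columns under 1 − Pearson (deterministic, columns pre-sorted by
name so ties cannot reorder leaves) reproduces the usual heat-map
column dendrogram.

## Imaging statistics

Per-cell nuclear and cytosolic intensities (from upstream
segmentation; this package never touches pixels) are normalized by the
*median total intensity of the unstimulated population*, preserving
changes in total expression. Condition-level localization is the pair
of median nuclear and median cytosolic intensities rescaled to sum to
1. Group comparisons use a Mann–Whitney test with midrank ties: exact
(null U distribution, or full enumeration when ties are present and
the arrangement count permits) for groups under 20, tie- and
continuity-corrected normal approximation otherwise; a group of 100 or
fewer cells triggers a warning, since the comparison is intended for
populations of >100 cells. Medians of normalized intensities are used
for the shares; using raw intensities instead would only change the
shares when stimulation changes total expression, which is exactly what
the normalization is meant to keep visible.

## What the synthetic data emulates — and what it does not

`simulate_experiment()` generates the full design: 3 donors × one TMT
set each, 9 sample channels plus the shared internal standard (the
grand mean of all 27 expected sample intensities, as a common pool
would be). Per gene: a log-normal baseline abundance
(meanlog = log(1e5), sdlog = 1.5, a realistic reporter-intensity
dynamic range), a compartment profile placing 0.70–0.95 of its mass in
a primary compartment, mixing through a purity matrix (default 0.80
on-diagonal, 0.10 off — enrichment, not isolation), per-gene donor
offsets (sd 0.1 log2 units, removed by pairing), and independent
per-channel PSM noise (sd 0.2 log2 units, ≈ 15% reporter CV). PSM
counts per gene and set follow 1 + Poisson(3); count-dependent
protein-level variance is *not* imposed — it emerges from averaging
per-PSM noise, which is precisely what the moderation model assumes.
Translocators (default 5% of genes) move mass from their primary
compartment to a random other one; the moved mass is set so the source
loses `effect_size` log2 units at 60 min (default 0.6), attenuated to
30% of that at 15 min — a partial early response. Target and decoy
scores are Normal(3, 1) and Normal(0, 1). Within- versus
between-donor variance magnitudes are not constrained by the design
itself; the defaults above are fixed once as plausible for primary
human cells and are not tuned per analysis.

Deliberately absent: co-isolation ratio compression (MS2 interference
systematically shrinks TMT ratios toward 1 — real sensitivity at a
given true effect will be lower than simulated), retention-time or
spectral structure, peptide-level missingness mechanisms, shared
peptides (rollup exclusion is exercised by constructed unit fixtures
instead), and isotopic impurity. Passing recovery tests on this
generator therefore demonstrates that the statistical machinery is
correct and calibrated for the assumed noise model — not that any
particular real dataset will yield a particular number of calls.

## Problem sizes and numerical conventions

The test suite runs the calibration and recovery studies at 2,000
genes, 3 donors: 100 replicate simulations for null uniformity
(Kolmogorov–Smirnov at α = 0.01 per fraction) and call-rate checks, 20
for spike-in sensitivity/FDP, and 10 per effect size for the
dose-response monotonicity check — sizes chosen to keep Monte-Carlo
error on the reported means well below the margins being asserted.
All simulation, clustering and pipeline functions take explicit integer
seeds and restore the caller's RNG state; identical seeds give
byte-identical outputs. Degenerate inputs are handled by rule, not by
chance: empty call sets produce zero involvement percentages without
division errors, constant rows are excluded from clustering and
reported, genes with fewer than two complete donor pairs are marked
untestable and can never satisfy the decision tree in that fraction.

## Known limitations

* The picked-FDR score semantics (best-PSM score per gene) is one of
  several defensible choices; with aggregate protein scores the
  retained set can differ near the threshold.
* With 3 donors the d₀ estimate dominates inference; on very small
  gene sets (tens of genes) the trend falls back to a constant and
  moderation is correspondingly cruder.
* The decision tree cannot see translocation between compartments that
  co-purify, and same-direction abundance changes (synthesis,
  degradation) are invisible to it by design.
* Calling operates per contrast; no attempt is made to model the
  15 min and 60 min responses jointly as a trajectory.
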