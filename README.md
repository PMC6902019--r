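# transloc

Detection of stimulation-induced protein translocation between
subcellular compartments from fractionated, TMT-labeled quantitative
proteomics.

## The problem

Cells redistribute proteins between compartments within minutes of a
stimulus — in T cells, receptor engagement sends transcription factors
to the nucleus and reorganizes membrane signaling within the first hour.
Subcellular fractionation followed by isobaric (TMT 10-plex) mass
spectrometry can measure this proteome-wide: each donor's cytosolic (C),
membrane/organelle (M) and nuclear (N) fractions at rest and after 15
and 60 min of stimulation are labeled into one TMT set (9 samples),
with a pooled internal standard shared across sets in channel 131 to
make donors comparable. Fractionation is an *enrichment*, not an
isolation, and with 3 donors the per-protein statistics are starved for
degrees of freedom — the two issues this package's pipeline is built
around.

`transloc` takes identified, quantified peptide-spectrum matches (PSMs)
and produces translocation calls:

1. **Quantification** — per-PSM log2 reporter ratios to the internal
   standard, sample-median normalization, gene-level rollup as the
   median ratio over peptides unique to a gene symbol, and
   protein-level **picked target–decoy FDR** on gene-symbol groups
   (keep the better of each target/decoy pair, walk the ranked list,
   FDR = decoys/targets).
2. **Differential statistics** — per fraction, donor-paired log2 fold
   changes Δ̄ with empirical-Bayes variance moderation along a
   spectra-count trend: per gene, s² (df = n−1) is shrunk toward a
   prior s₀²(PSM count) fitted on the log–log scale, with prior df d₀
   estimated by method of moments under the scaled-F model
   s² ~ s₀²·F(df, d₀). The moderated statistic is
   t = Δ̄ / (s̃/√n), s̃² = (d₀·s₀² + df·s²)/(d₀ + df), on d₀ + df
   degrees of freedom; P values are two-sided and uncorrected.
3. **Translocation calling** — the opposite-direction decision tree: a
   gene is called if |log2FC| > 0.201 in one direction in one fraction
   and > 0.201 in the opposite direction in another, with P < 0.05 in
   both (strict inequalities).
4. **Classification & QC** — k-means (k = 3) under 1 − Pearson
   correlation assigns each fully quantified gene a compartment; PCA
   and average-linkage column clustering check that samples separate by
   fraction.
5. **Integration & imaging** — Venn overlaps with externally supplied
   regulated-phosphoprotein/PTM gene lists, and per-cell
   nuclear/cytosol intensity statistics (normalization to the
   unstimulated population, shares summing to 1, Mann–Whitney tests).

A synthetic-data generator with known ground truth (compartment
profiles mixed through a configurable purity matrix, donor offsets,
per-channel PSM noise, spiked translocators, target/decoy scores)
supports calibration and recovery benchmarking of the whole pipeline.

## Worked example

```r
library(transloc)

run <- run_pipeline(list(simulation = list(seed = 7), seed = 7))
print(run)
#> transloc_run
#>   identified (picked FDR): 2000
#>   overlapping across sets: 2000
#>   fully quantified:        2000
#>   candidates (P<0.05, >=2 fractions): 119
#>   translocation calls:     108
#>   fraction involvement (%): C 72.2, M 71.3, N 63.9
#>   recovery vs ground truth: sensitivity 1.000, FDP 0.074
```

The funnel reads top to bottom: 2,000 simulated genes pass the 1%
picked protein FDR, all are seen in all 3 donors' sets and fully
quantified (the generator produced no missing channels here); 119 genes
change with P < 0.05 in at least two fractions at 1 h, and 108 of those
change in *opposite* directions with |log2FC| > 0.201 in two fractions
— the translocation calls. Since the simulation spiked 100 true
translocators (5%), the calls recover all of them (sensitivity 1.000)
with 7.4% false discoveries. `summary(run$fit)` gives the same funnel
for other thresholds; `coef(run$fit)` returns the gene × fraction
fold-change matrix; `plot(run$fit)` draws the opposite-direction
scatter with calls highlighted.

For real data, point the pipeline at TSV exports instead:

```r
run <- run_pipeline(list(psm_file = "psms.tsv", design_file = "design.tsv",
                         out_dir = "results"))
```

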