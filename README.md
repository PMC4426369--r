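# memorychrom

Some targets of the essential budding-yeast general regulatory factor Abf1
keep transcribing even after Abf1 dissociates from their promoters — a
"memory effect" — while other targets shut down once the factor leaves.
`memorychrom` implements the computational machinery for dissecting that
distinction: it asks whether the two classes of target promoter differ in
intrinsic, sequence-encoded propensity to re-form nucleosomes after factor
eviction, and whether that difference travels with the expected functional
correlates (conserved motifs, low expression noise).

The package is aimed at regulatory genomicists working with ChIP-seq,
promoter sequence analysis, and per-gene expression statistics in yeast-like
genomes.

## What it computes

**ChIP-seq normalization.** Single-end tags are extended 3′-ward to 120 bp,
coverage is summed per base pair, divided by the genomic average
`120 · N_tags / G`, log2-transformed, and standardized genome-wide:

```
z(x) = ( log2( c(x) / (120 · N / G) ) − μ ) / σ
```

with `μ`, `σ` the genome-wide moments of the log2 ratios; zero-coverage
positions are masked rather than pseudocounted.

**Meta-profiles.** Z-scores are averaged across genes after aligning each
promoter on its motif center (10-bp bins) or on the TSS (100-bp sliding
windows in 10-bp steps), oriented so negative offsets are upstream in gene
orientation.

**Nucleosome-disfavoring sequence statistic.** A 7-mer is a poly(dA:dT)
tract if it contains ≥ 6 A or ≥ 6 T. The per-position statistic is the
fraction of tract 7-mers among the 144 7-mer starts inside a sliding 150-bp
window, computed on the coding strand, profiled around motif centers, and
averaged per promoter class — with an A-tract/T-tract decomposition and
independent application to orthologous promoters of related species.

**Conservation calling.** Sites are scored with a PWM as
`Σ_i log2(p_i[b_i] / q[b_i])`; a site is conserved if every ortholog scores
within two standard deviations below the reference-species motif average.

**Classification and class comparison.** Targets are responsive if their
mRNA drops ≥ 1.5-fold (`log2fc ≤ −log2 1.5`), memory if `|log2fc| < 0.2`,
intermediate otherwise; per-gene metrics (expression noise, mRNA half-life)
are centered and compared between classes with 95% percentile-bootstrap
error bars.

**Synthetic data.** A generator plants all of these contrasts in a toy
genome (identical motifs, class-dependent upstream T-tract density,
condition-dependent ChIP enrichment, class-shifted expression and noise) so
the entire pipeline is testable without external data.

## Worked example

```r
library(memorychrom)

sim <- simulate_dataset(sim_config(seed = 42))   # 2 x 250 kb, 60 genes/class

# ChIP: Z-scored coverage, motif-centered profile
z  <- normalize_zscore(coverage_track(sim$tags$wt, sim$genome))
p  <- motif_centered_profile(z, sim$sites)
profile_at(p, 0)
#> [1] 3.8725

# sequence propensity: upstream dA/dT contrast between classes
ap <- class_average_at_profile(sim$genome, sim$sites)
up <- ap$offset >= -200 & ap$offset < -20
tapply(ap$mean[up], ap$class_label[up], mean)
#>     memory responsive
#>    0.24905    0.05836

# classification and noise comparison
cls <- classify_table(sim$expression)
#> classified 120 genes: memory=60, responsive=60, intermediate=0
rec <- merge(cls, sim$metrics, by = "gene_id")
rec$noise <- center_metric(rec$noise)
s <- class_metric_summary(rec, "noise", seed = 42)
compare_classes(s, "memory", "responsive")$diff_mean
#> [1] -0.4619
```

The wild-type profile peaks at the motif (Z ≈ 3.9 at offset 0, vs ≈ 2.1 in
the ts condition); memory promoters carry a four-fold higher upstream
dA/dT tract frequency than responsive ones with no downstream difference;
every gene is assigned its planted class; and memory genes sit ~0.46
centered-noise units below responsive genes with a bootstrap CI that
excludes zero.

The same analysis, written as a narrated workflow, lives in `analysis/`
(`01_simulate.R` → `04_classes_noise.R`); each driver prints what it found
and writes compact tables under `results/`.

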