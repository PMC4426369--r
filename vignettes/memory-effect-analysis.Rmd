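---
title: "Distinguishing memory-effect from transcriptionally responsive promoters: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing memory-effect from transcriptionally responsive promoters: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

General regulatory factors such as Abf1 keep their binding sites
nucleosome-free while bound. When a temperature-sensitive allele evicts the
factor, some target genes lose transcription (≥ 1.5-fold mRNA decrease:
*transcriptionally responsive*) while others keep transcribing essentially
unchanged (|log2 change| < 0.2: *memory effect*). The hypothesis this
package operationalizes is chromatin-mediated: memory promoters carry
nucleosome-disfavoring poly(dA:dT) tracts upstream of the factor's motif,
so after eviction their chromatin stays open without help, whereas
responsive promoters re-assemble a nucleosome and lose access for the
transcription machinery. The analyses here quantify (i) factor eviction
(ChIP-seq meta-profiles), (ii) the sequence propensity itself, (iii) its
conservation in related species, and (iv) its correlate in expression
noise.

## ChIP coverage and Z-scores

Single-end tags are extended from their 5′ end to a total of 120 bp
(bridging the forward/reverse read gap) and coverage is summed per base
pair. Coverage is ratioed against the genomic average `120 · N / G`, log2
transformed, and standardized to N(0,1) using genome-wide moments.

Numerical choices:

* **Zero-coverage positions are masked**, excluded from the moments, and
  propagate as `NA` downstream. log2(0) is undefined and no pseudocount
  convention is part of the method; masking avoids inventing one. At the
  default simulated depth (50,000 tags on 500 kb, mean coverage 12×) well
  under 1% of positions are masked.
* **The log2 ratio is coverage over the genomic-average expectation**, not
  an IP/input ratio — the normalization needs no second library.
* **Degenerate tracks** (constant coverage, sd = 0) yield all-zero Z-scores
  with a warning instead of an error, so pathological inputs fail soft.
* Mass conservation is exact by construction: total coverage equals
  120 bp × tags minus bases clipped at chromosome ends, and the test suite
  asserts the integer identity.

## Meta-profiles

Signal is extracted on `[center − flank, center + flank)` around each motif
center (`center = start + ⌊L/2⌋`, deterministic for the even 14-bp motif),
oriented by gene strand, averaged within 10-bp bins `[10k, 10k + 10)`, then
averaged unweighted across genes (one gene, one vote). TSS profiles use a
100-bp sliding window advancing 10 bp, the convention used for polymerase
signal over gene bodies.

* **Minus-strand mirroring** maps gene-frame offset `d` to genomic offset
  `−d` about the center base, so an impulse k bp 5′ of the motif lands in
  the same bin for either strand; the leftover `+flank` cell of the
  mirrored grid is dropped to keep all profiles on one grid.
* **Edge handling:** sites closer than `flank` to a chromosome end
  contribute only their defined offsets — no padding, no fabricated signal.
  Bins where no gene contributes are `NA` with `n_contributing = 0`.
* Orientation by *gene* strand (not motif strand) is the default; the two
  coincide in the simulator, and the extraction function takes whatever
  strand column the caller supplies, so either convention is available.

## The poly(dA:dT) propensity statistic

A 7-mer is a nucleosome-disfavoring tract iff it contains at least six A's
or at least six T's (`N` counts as neither; the two events are disjoint, so
the A-tract and T-tract components add exactly). The per-position statistic
is the tract fraction among the `150 − 6 = 144` valid 7-mer starts in a
150-bp window centered on the position, sliding 1 bp — centered sliding
windows give smooth profiles and a denominator that makes the value a
[0, 1] proportion comparable across window sizes.

Sequences are taken on the **coding strand** (minus-strand promoters are
reverse-complemented before scanning), so "upstream" and T-vs-A tract
identity are gene-relative. This is the biologically meaningful frame —
nucleosome-depleted regions are canonically T-tracts-then-A-tracts read
along the gene — and a strand-symmetry test pins the convention down.
Positions whose window would leave the chromosome are `NA`, not
zero-filled.

Cross-species profiles are computed independently per species on that
species' own genome and site coordinates; orthology (shared gene ids) is
established upstream and genes missing in a species are skipped there.

## PWM scoring and the conservation criterion

Sites are scored `Σ_i log2(p_i[b_i]/q[b_i])` after 1e-3 pseudo-probability
smoothing (finite log-odds). The conservation call takes the
reference-species score set, computes its mean μ and sd σ, and calls a site
conserved iff **every** ortholog scores ≥ μ − 2σ. μ and σ come from the
full scored reference site set — "the motif average" is read as the average
over motif instances, which is the only self-contained reading.

The synthetic ortholog generator pairs with this criterion: reference sites
are the consensus with zero or one substitution (probabilities 0.6/0.4),
under a PWM whose non-consensus bases share one probability so every
single-substitution penalty is the same value d. Reference scores then take
two lattice values, and the worst site (−d) lies within μ − 2σ whenever at
least 20% of sites carry a mismatch — a binomial tail below 1e−4 at 80
sites. That makes "zero mutation rate ⇒ conserved fraction exactly 1" a
designed property of the generator rather than a lucky draw, while σ > 0
keeps the criterion well defined. Species orthologs then mutate each base
independently at a configurable rate, which drives the conserved fraction
monotonically toward zero.

## Classification

`responsive` iff `log2fc ≤ −log2(1.5)`; `memory` iff `|log2fc| < 0.2`;
`intermediate` otherwise. The two defining thresholds leave boundary
semantics open; they are fixed here as: the 1.5-fold edge is responsive
(the defining condition is "at least 1.5-fold"), and `|log2fc| = 0.2`
is intermediate (the memory condition is a strict "less than"). Both
thresholds are arguments with these defaults.

## Bootstrap class comparison

Per-gene metrics are centered by subtracting the global mean over all
supplied genes. Each class's mean gets a 95% **percentile** bootstrap CI
(genes resampled with replacement within class; default 10,000 resamples) —
the simplest method consistent with generic bootstrap error bars; the
bootstrap SE is also reported for readers who prefer SE bars. Class
differences reuse the stored replicate streams pairwise (replicate i of
class a against replicate i of class b), so the difference CI is
deterministic given the summary's seed. Classes with fewer than two genes
are omitted with a warning; missing metric values are dropped per gene, not
imputed. Percentile intervals at n = 50 undercover slightly (~93–94%
empirically), which the calibration test brackets explicitly.

## The synthetic-data generator

The generator emulates exactly the contrasts the analysis must detect, at
the study's stated conditions:

* **Genome:** i.i.d. uniform background over {A,C,G,T} (a neutral null for
  the dA/dT statistic: background tract frequency ≈ 0.0027), default
  2 × 250 kb; one 14-bp consensus motif per gene on a random strand; gene
  anchors spaced 1300 bp with a 650-bp margin so ±500-bp flanks plus the
  75-bp window reach never overlap — exceeding the density is a sizing
  error, not a silent overlap.
* **T-tracts:** memory promoters start a run of 5–8 T (coding strand) at
  rate 0.08 per bp over gene-frame offsets [−200, −20); responsive
  promoters at 0.02. Runs replace background bases in place (no indels, so
  coordinates stay fixed) and are clipped at the region edge, never
  touching the motif.
* **ChIP tags:** a mixture of uniform background and a motif component (+
  tags at center − 60, − tags at center + 60, Normal(0, 20 bp) jitter,
  integer-rounded, clipped at chromosome ends). The mixture weight is
  solved in closed form so expected extended-tag coverage at motif centers
  over the genomic mean equals the requested enrichment: 5-fold in the
  wild-type condition, 2-fold in the ts condition, 50,000 tags each.
* **Expression and noise:** responsive log2 fold changes center at −1,
  memory at 0, sd 0.1; noise centers at −0.5 (memory) vs 0 (responsive),
  sd 0.2. Because the classes are *defined* by the expression thresholds, a
  draw outside its class-defining region is resampled (truncated normal): a
  nominal memory gene at |log2fc| ≥ 0.2 would simply not be a memory gene,
  so untruncated draws would contradict the labels the generator asserts.
* **Occupancy stand-in:** per-bp `plogis(2 − 8 f)` of the local windowed
  tract frequency f — a monotone sequence-to-occupancy map that reproduces
  the qualitative structure (tract-rich ⇒ depleted) without pretending to
  be a nucleosome model.
* **Determinism:** each output object draws from its own stream derived
  from the master seed by a fixed offset, so adding one simulated object
  never perturbs the others, and identical configs give bitwise-identical
  output including written files.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: mappability and GC biases, fragment-length
dispersion and paired ends, sequencing error, realistic promoter base
composition and phased nucleosome arrays, a genuine thermodynamic occupancy
model, real ortholog divergence (indels, alignment error), and the
continuum of intermediate targets (classes are planted as clean bimodal
contrasts).

## Analysis bands and problem sizes

The upstream contrast is evaluated over gene-frame offsets [−200, −20), the
planted tract region. The "no downstream signal" control uses [100, 280):
the 150-bp window reaches 75 bp sideways, so offsets closer than ~+95 still
average over upstream tract sequence and genuinely carry class signal — a
downstream band must start beyond the window's reach to be a null region.

Default problem sizes throughout the tests and drivers — 500-kb genomes,
60 genes per class, 50,000 tags, 10,000 bootstrap resamples (1,000–5,000 in
replicated calibration loops), 500 calibration replications — are the
package's chosen study conditions: large enough that every planted contrast
is detected with wide margins, small enough that the full suite runs in
well under a minute per stage on one CPU.

## Known limitations

* Z-score masking means deeply undersampled libraries propagate many `NA`s
  into profiles; the method is meant for libraries with near-full coverage.
* The per-sample Z-score normalization supports within-sample comparisons
  and profile shapes; cross-sample ratios of raw enrichment are left to the
  caller, as between-sample standardization is exactly what the Z-scoring
  removes.
* Peak calling is out of scope: peak intervals are consumed (BED), never
  produced.
* The conservation criterion presumes aligned, full-length orthologous
  sites; it does not handle missing or partially aligned orthologs beyond
  skipping them.
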