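---
title: "Predicting heterosis from heterozygous PEUS SNPs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting heterosis from heterozygous PEUS SNPs: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heteropeus)
```

## The scientific question

A maize F1 hybrid typically outyields the average of its two inbred
parents (mid-parent heterosis, MPH) and often the better parent too (BPH).
Predicting which crosses will show strong heterosis *before* field testing
saves a breeding programme most of its trial capacity. The classical
genomic predictor is parental genetic distance, `GD = 1 − IBS`, computed
over all SNPs. The predictor at the core of this package is more
mechanistic: count, over the gene-proximal regions most likely to affect
expression — promoters (1 kb upstream of the start codon), exons, UTRs and
stop codons, collectively *PEUS* regions — the SNPs at which the two
homozygous parents carry different alleles. The F1 is heterozygous at
exactly those loci, and under directional dominance each heterozygous
functional locus contributes positively to hybrid performance. The count is
therefore, under a dominance model of heterosis, proportional to the
expected dominance deviation of the cross, while GD dilutes the same signal
across the whole genome.

## The analysis pipeline

### Genotype filtering

Variant data enter as a multi-sample VCF of the inbred parents. Only
biallelic SNPs are used. Filters follow standard resequencing practice for
inbred panels, in two stages with defaults:

| parameter | default | action |
|---|---|---|
| per-call depth | ≥ 3 | failing call masked to missing |
| per-call genotype quality | ≥ 5 | failing call masked to missing |
| site QUAL | ≥ 30 | failing site removed |
| missing rate (after masking) | ≤ 0.2 | failing site removed |

Masking before the missing-rate test matters: a site whose low-depth calls
would individually be unreliable is kept if enough samples remain well
genotyped. "Site quality" is the VCF QUAL field — per-base qualities do not
survive variant calling, so the read-level base-quality filter of a calling
pipeline is represented by its site-level descendant. Filtering is
idempotent and the missing-rate denominator is the number of samples in the
(possibly subset) matrix.

### PEUS classification

The region index is built from GFF3 gene models, strand-aware:

* **promoter** — `promoter_len` (default 1000) bases 5′ of the start codon,
  i.e. of the CDS start in transcript orientation, truncated at the
  chromosome start. The anchor is deliberately the start codon, not the
  transcription start site, so the promoter of a transcript with a 5′UTR
  overlaps that UTR; both categories are then recorded. Anchoring at the
  start codon keeps the definition usable on annotations with unreliable
  TSS calls.
* **exon** — all exon intervals;
* **UTR** — 5′ and 3′ UTR intervals;
* **stop codon** — the final 3 coding bases in transcript orientation,
  split across two CDS intervals when the stop codon spans an intron.

Categories are unioned over transcripts and genes: a site is a PEUS SNP if
*any* transcript places it in any category (the most inclusive reading,
matching gene-level annotation tools). Category counts increment once per
category a site carries, while the PEUS total counts each site once.
Transcripts without CDS contribute exon/UTR intervals only. Interval lookup
is delegated to `GenomicRanges`; the tests check it against a brute-force
linear scan.

### Cross scoring

For a cross between homozygous parents, over PEUS sites genotyped in both:
equal dosages → homozygous F1 locus; different homozygous dosages →
heterozygous F1 locus. A locus where either parent is missing *or carries a
residual heterozygous call* is excluded from both counts: an inbred's
heterozygous call leaves the F1's zygosity ambiguous, so the locus is
uninformative. The three counts always sum to the PEUS site total.

`GD = 1 − IBS` uses all filtered sites (not only PEUS), with
pairwise-complete missing handling; per site the shared-allele fraction is
`(2 − |d_a − d_b|)/2` for dosages `d`. For fully homozygous, fully observed
parents restricted to PEUS sites, GD reduces to the heterozygous fraction —
an identity the tests assert.

### Heterosis and the line × tester ANOVA

`MPH = 100(F1 − MP)/MP` and `BPH = 100(F1 − BP)/BP`, with parent and F1
means taken over replications and (for the across-location scope) over
locations. Both scopes are provided because aggregated (across-location)
heterosis and per-location heterosis answer different questions — overall
ranking versus stability of the predictor across environments — and the
per-location values feed the predictor comparison below. A cross with a
non-positive parent mean has undefined heterosis and is flagged `NA`, never
imputed.

The grain-yield ANOVA is the fixed-effects decomposition

```
Y_ijkl = μ + loc_l + rep(loc)_kl + line_i + tester_j + (line:tester)_ij
       + (line:loc)_il + (tester:loc)_jl + (line:tester:loc)_ijl + e_ijkl
```

fitted to F1 plots only (parents and checks are excluded; the model indexes
crosses). Lines and testers are deliberately chosen germplasm, not random
samples, so *every* F statistic is tested against the pooled error mean
square rather than against interaction terms. Sums of squares are
sequential; on the balanced, orthogonal designs the function accepts they
equal marginal sums of squares, and unbalanced data are rejected with an
explicit error rather than silently approximated. For the reference
19 lines × 5 testers × 3 locations × 3 replications layout the df column is
(2, 6, 18, 4, 72, 36, 8, 144, 564). Fisher's LSD is
`t(1 − α/2, df_error) · sqrt(2·MS_error / n)`. Kempthorne combining
abilities are the means-based decomposition: a parent's GCA is its marginal
cross-mean deviation from the grand mean and the SCA is the cell residual,
so `grand + GCA_line + GCA_tester + SCA` reconstructs every cell mean
exactly.

### Associating predictors with heterosis

Pearson correlations (p from the t transform on n − 2 df, two-sided) and
least-squares regressions relate each predictor (`n_het_peus`, `gd`) to
each response (MPH, BPH), either per cross, or on parent means (crosses
aggregated by line, tester or heterotic group — the small-n analyses a
breeder actually uses for parent selection). To ask whether one predictor
is *systematically* stronger, the per-location × per-response correlation
coefficients form paired strata (3 locations × 2 responses = 6 pairs);
after Fisher's z transform (`atanh`), a paired t-test compares the two
predictors. The z transform is variance-stabilising; the untransformed
option is kept for sensitivity analysis. No multiplicity adjustment is
applied — the comparison is a single pre-specified test. Finally, the top-k
summary ranks crosses by yield (or heterosis) and counts each parent's
membership among the top k, the practical check that parents with high
heterozygous PEUS means dominate the best crosses.

## The synthetic-data generator

The generator reproduces the statistical structure the analysis assumes,
with known ground truth, so that the pipeline's claims can be tested
end-to-end.

**Population structure.** 24 fully homozygous inbreds in three heterotic
groups (nonReid 13, Reid 8, Suwan1 3); the five testers come from the Reid
group, crossed to the remaining 19 lines → 95 crosses. Group allele
frequencies follow a Balding–Nichols beta model around uniform ancestral
frequencies (p ∈ [0.05, 0.95]) with divergence Fst = 0.15, a typical
differentiation among maize heterotic groups. Every call carries depth 10
and GQ 99, so default filtering is a no-op on clean simulated data (tests
that exercise the filters build dirty data explicitly).

**Genome.** Two chromosomes of 2 Mb carry 24,000 SNPs and a sparse panel
of 20 two-exon genes (5′/3′ UTRs, an intron, promoter space reserved on the
correct strand side). The PEUS compartment is thus a small slice (~1–2%) of
the genome-wide panel, which mirrors the essential geometry of a real
genome, where PEUS regions are a few percent of all SNPs: the genetic
distance panel must be dominated by non-PEUS sites for the comparison of
the two predictors to mean anything. Real gene density is *not* emulated —
at desk scale the panel's geometry (relative compartment sizes), not its
absolute size, is what carries over.

**Trait architecture.** A fraction (default 0.6) of PEUS SNPs is causal.
Additive effects are small (`a ~ N(0.02, 0.01)` t/ha); dominance effects
are `d ~ Gamma(shape 6, mean 0.057)` t/ha — positive and mildly dispersed.
The low dispersion is a modelling statement: an *unweighted* count of
heterozygous loci is close to the optimal linear predictor only when
per-locus effects are roughly exchangeable, which is the premise implicit
in using the count at all. The F1 dosage at a locus is the parental mean
(no recombination is needed because F1s are not selfed), heterozygous
exactly where the homozygous parents differ.

**Phenotypes.** `gy = 6 + loc + rep(loc) + genetic value + entry×loc +
plot noise`, truncated at zero (rare; logged when it happens). Variance
components (location SD 1.5, rep SD 0.3, G×E SD 0.6, plot SD 1.6 t/ha) are
sized so the simulated error mean square (~2.5) and location/F ratios are
of the magnitude a multi-location maize yield trial reports. Under these
defaults mean MPH is ≈ 35% and the per-cross correlation between the
heterozygous PEUS count and MPH is ≈ 0.3–0.45 — the order of magnitude
line × tester studies report for significant per-cross predictors at
n = 95. Random streams are split per component (annotation, genotypes,
effects, field noise) via sub-seeds of the master seed, so changing the
noise leaves genotypes fixed.

**What passing tests do and do not show.** The generator builds in the
dominance-at-PEUS architecture, group structure and balanced trial design;
it omits linkage and recombination maps, epistasis, ascertainment bias in
SNP discovery, genotyping error correlated with divergence, and unbalanced
field data. Recovery results therefore demonstrate that the pipeline
*detects the signal when the generating model holds* — they are a
correctness check of the machinery, not evidence about real maize panels.

**Recovery behaviour.** Two properties are tested over 50 replicate seeds
at the default configuration: (A) with the causal architecture inside PEUS
regions, `r(n_het_peus, MPH) > r(GD, MPH)` in ≥ 80% of seeds — the
PEUS count's advantage comes from its direct overlap with the causal loci,
which GD shares only diluted by `sqrt(n_causal / n_total)`; (B) relocating
all causal loci off-PEUS abolishes the advantage: the win indicator is
tested against a fair coin with a two-sided exact binomial test at
α = 0.01. In B a slight GD lean is expected at desk scale (GD's panel
still contains the causal loci; the PEUS panel no longer does), which is
why B is framed as "not distinguishable from 50/50" rather than "exactly
50%".

## Numerical and design notes

* Coordinates are 1-based inclusive externally (VCF/GFF3); conversions are
  confined to readers/writers (BED output is 0-based half-open).
* Multiallelic records are dropped, not split: the het/hom classification
  of a cross is only defined for biallelic comparisons, and inbred panels
  lose little this way.
* VCF reading uses `vcfR`; writing is a small in-package formatter so that
  outputs are plain text.
* Top-k ties at the boundary are broken by stable table order, with a
  warning — deterministic output was preferred over randomised
  tie-breaking.
* ANOVA p-values are the conventional upper-tail F probabilities.
* The paired predictor comparison needs ≥ 2 strata; with the default 3
  locations it runs on 6, so its df are small — it is a coarse test by
  construction, reported unadjusted.
* Problem sizes in the test-suite (matrices up to a few thousand sites,
  oracle checks on ≤ 100-site matrices and ≤ 3×3×2×2 ANOVA designs, 50
  recovery seeds) were chosen so the whole suite exercises every claim in a
  few minutes on a single core.

## Known limitations

* Only balanced trials are analysed; unbalanced or incomplete field data
  need a mixed-model treatment that is out of scope here.
* The promoter definition ignores enhancers and distal regulation; the
  classifier does not call codon-level consequences (synonymous versus
  nonsynonymous).
* GD is plain IBS distance; kinship-corrected or LD-pruned distances are
  not implemented.
* The simulator's dominance-only heterosis is the minimal generative model
  under which the PEUS count is predictive by construction; real heterosis
  includes epistatic and pseudo-overdominance components the generator
  does not emulate.
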