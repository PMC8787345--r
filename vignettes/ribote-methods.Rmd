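---
title: "ribote: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ribote: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribote)
```

## The quantity being estimated

Ribosome-profiling experiments without an internal spike-in standard can
only compare a gene's translation to the rest of the same sample's mRNA
population. ribote therefore estimates **relative translational
efficiency**, TE_rel: normalized footprint count over normalized mRNA
count, and its mutant-vs-wild-type change ΔTE_rel. A decrease means the
mRNA depends *more than average* on the disrupted initiation factor; it
says nothing about absolute translation rates, which in these experiments
fall globally.

## Counting rules

Three rules are applied before any statistics, because they *are* the
analysis contract:

* **Codon exclusion.** Footprints on the first 15 and the final 5 codons of
  each CDS are ignored (`cds_counting_window()`), removing
  cycloheximide-induced pile-ups near start and stop. A CDS of ≤20 codons
  has an empty window and the gene is dropped (reported in the run
  manifest). The codon index of a footprint at nucleotide *p* is
  `floor((p − cds_start)/3)`; P-site offsetting is upstream of this package
  and out of scope.
* **Full-length uORF counting.** uORFs are too short for the exclusion
  window, so they are summed over their whole length. Their ΔTE_rel is
  computed with the *host gene's* RNA counts as denominator — the source
  analysis does not state its denominator, and this choice keeps the uORF
  and gene universes aligned. uORF records inherit the host gene's
  expression-filter status for the same reason.
* **The 128-read filter.** A gene is excluded when its four mRNA libraries
  (two replicates each of WT and mutant) total fewer than 128 reads.
  "Fewer than" is taken literally: a total of exactly 128 is kept. The
  filter demands exactly the four samples of one strain pair unless
  explicitly overridden.

## The ΔTE_rel model

Per gene, counts from the eight libraries are modelled as negative
binomial (`Var = μ + α μ²`) with log-linear mean

```
log μ = log s_j + β₀ + β₁·assay + β₂·condition + β₃·assay·condition
```

so `β₃/ln 2` is log2 ΔTE_rel. Choices, and why:

* **Interaction design, not ratio-of-ratios contrast.** The source
  analysis used the DESeq2 machinery for TE without stating the design;
  the interaction GLM is the standard formulation and is what the tests
  calibrate. This is a reimplementation of the analysis *design* — exact
  numerical parity with DESeq2 internals (dispersion shrinkage details,
  Cook's outlier handling, independent filtering) is a declared non-goal.
* **Size factors** are median-of-ratios, computed separately for RP and
  RNA libraries because the two assay types have different composition.
  With no all-positive gene the estimator falls back to total-count ratios
  with a warning.
* **Dispersion** is estimated per gene and assay by method of moments on
  normalized counts within each condition, floored at 1e-8, then shrunk
  halfway (weight 0.5, configurable) toward a trend `α(μ) = a₀ + a₁/μ`
  fitted across genes. Degenerate (zero-variance) genes take the trend
  value. With two replicates per condition the per-gene estimate is noisy
  (2 residual df); the trend borrows strength across genes, which is what
  makes the Wald test calibrate (verified by the null-simulation test:
  raw p < 0.05 fraction within 0.05 ± 0.02 at 1,000 genes).
* **Wald test, normal reference**, matching the default of the package the
  source analysis used; BH step-up adjustment across all tested genes.
  Genes with an empty design cell (all-zero counts in some
  assay × condition) are reported `NA` rather than forced to converge.
* **Fold-change categories.** Significant genes (padj < 0.05) are binned
  at ratio ≥1.5 / ≥2 (up) and ≤1/1.5 / ≤1/2 (down); significant genes
  below the 50% band are labelled `sig_small` rather than silently
  promoted or dropped.

A note on scale invariance: multiplying one library's counts by *c* scales
its median-of-ratios factor by exactly *c* relative to the other
libraries, and leaves the plug-in TE_rel ratios exactly unchanged. The NB
*MLE* is only asymptotically invariant — scaled counts are genuinely
different data and the NB score reweights them — so the estimate
invariance is exact in the Poisson limit and approximate (observed < 0.02
in log2 units) at moderate dispersion.

## Feature definitions

* **5'-UTR length** comes from the dominant-isoform rule: after
  renormalizing a gene's isoform abundances to sum to 1 (the rule is
  stated in fractions of all transcripts), the top isoform must hold ≥40%
  and be ≥2× the runner-up; ties at exactly 40% or 2× pass ("at least").
  Genes without a dominant isoform get a missing TL length and drop out of
  length-based analyses only.
* **PARS windows** (per-nt scores, higher = more double-stranded):
  `utr_all` = mean over the TL; `first30` = first 30 nt of the TL;
  `start30` = the 30 nt centred on the AUG, interpreted as
  `[cds_start−15, cds_start+15)` (the source text says only "centered
  around the AUG"; the offset is configurable for sensitivity checks);
  `plus30` = the next 30 nt; `max30` = the maximum mean over every 30-nt
  window fully inside the TL, sliding by 1 nt. TLs shorter than 30 nt
  yield missing `first30`/`max30` rather than a truncated window —
  truncated windows would not be comparable statistics. Any missing PARS
  value inside a window makes that window's statistic missing; `max30`
  maximizes over the complete windows and is missing only when none
  exists.
* **Kozak context score.** The source analysis cites prior work without
  defining the computation, so ribote adopts a pseudocount-1 position
  probability matrix over the −6..+4 windows of the analysis universe
  itself, converted to log2 odds against the pooled base composition of
  the −6..−1 positions, with the invariant AUG core forced to zero
  contribution. Only rank-based statistics are used downstream, limiting
  sensitivity to this choice; the PWM source set is a parameter.
* **Sequence logos** report per-position information content
  `2 + Σ p log2 p` bits with no small-sample correction (0 ≤ IC ≤ 2).
* **uORF cap distance** is the 0-based offset of the uORF start from the
  transcript 5' end.

## Association layer

Spearman correlations are Pearson on average ranks with a t-approximation
p (n − 2 df); an exact-rank permutation alternative matters only at very
small n, where the package's exact Wilcoxon and hypergeometric branches
are the tools actually used. Set overlaps use the exact hypergeometric
survival function; the universe is the genes passing the expression filter
in *both* compared datasets (the source does not state its universe; this
is the conservative choice and a parameter). Two-group contrasts use the
Wilcoxon rank-sum test (exact when the smaller group has ≤8 observations
and there are no ties, else normal approximation with continuity
correction); multi-group contrasts use one-way ANOVA with Tukey HSD,
adjusted within each Tukey family only — the figure-level family in the
source is unstated. ΔTE profile clustering uses Euclidean distance with
Ward linkage (`ward.D2`), chosen for determinism and common practice;
genes missing from one dataset are imputed as 0 ("no change") and
flagged, with dropping available as the alternative.

## What the simulator emulates — and what it does not

`generate_transcriptome()`/`generate_counts()` produce a yeast-like stated
world: log-normal TL lengths (median ≈ 75 nt, range clamped to
12–1500 nt), log-normal CDS lengths (median ≈ 380 codons, min 25),
log-normal mean expression, a DESeq2-style dispersion trend
`α(μ) = 0.01 + 1.5/μ` with log-normal gene-level jitter, Beta-distributed
Kozak-context strength (consensus `AAAAAA|AUG|G`), Poisson-distributed
uORF counts placed inside the TL, Gaussian PARS tracks with optional
planted 30-nt structured windows, and per-sample size factors log-uniform
in [0.5, 2]. True log2 ΔTE_rel is a linear function of centred TL length,
Max30 and context strength plus Gaussian noise, zeroed for the configured
null fraction. Footprints are generated as gene-level NB totals spread
multinomially across codons; the optional cycloheximide-like 5' ramp adds
*extra* occupancy to the first 15 codons from an independent RNG stream,
so the codon-exclusion rule removes it exactly by construction.

Not emulated: read-level artefacts (alignment, mapping bias, rRNA
contamination), positional pausing beyond the ramp, RNA-level differential
expression between conditions, and isoform-level quantification beyond the
dominance rule. A green simulation test therefore establishes that the
*statistical machinery* is correct and calibrated under the stated model —
not that the biological conclusions of any particular dataset are right.

The dominant-isoform fraction is exact by construction: dominant genes get
a top abundance in [0.7, 0.95] (which guarantees both clauses of the
rule analytically), non-dominant genes a three-isoform pattern whose
runner-up exceeds 60% of the top (which violates the 2× clause whichever
minor ranks second). The generator never calls the selector it is tested
against.

## Numerical choices and degenerate inputs

* NB IRLS: log-link, working weights `μ/(1+αμ)`, initialization from a
  log-linear least-squares fit, step tolerance 1e-10, 50 iterations max,
  linear predictor clamped to ±30; Wald SEs from the observed information
  at convergence. Genes with any empty design cell are not fitted.
* Dispersion floor 1e-8; trend fitted by least squares on the raw
  estimates with non-negativity clamps, falling back to the median raw
  dispersion when the fit is singular or under-determined.
* BH: NA p-values are excluded from the effective number of tests and
  propagate as NA.
* Correlations: zero-variance input or fewer than 3 complete pairs is
  reported missing with a reason, never silently 0.
* All generator and pipeline randomness derives from a single user seed
  through per-stage stream seeds (kept below 2^31), making end-to-end runs
  byte-reproducible.

## Monte-Carlo sizes in the test suite

Calibration and recovery tests use 800–1,000 genes with 2+2 replicates —
small enough to keep the whole suite within a few minutes on one CPU, and
large enough that the asserted bands (e.g. type-I fraction 0.05 ± 0.02,
size factors within 5%, sensitivity ≥ 0.8 at |log2 ΔTE| = 1 under
realistic yeast sequencing depth of several hundred RNA reads per
expressed gene) hold with comfortable margin. The deposited data behind
the source study's headline gene counts are deliberately not downloaded;
those numbers are not reproducible at desk scale, which is why acceptance
is property-based throughout.

## Known limitations

* The NB stage is not a DESeq2 clone; on real data the gene lists will
  differ in detail from a DESeq2 run (no outlier replacement, simpler
  dispersion shrinkage).
* TE_rel inference assumes RNA counts are comparable across conditions
  after size-factor normalization; a global RNA-level shift would be
  absorbed into the condition main effect, not the interaction.
* The Kozak score depends on the PWM source set; absolute scores are not
  comparable across universes, only ranks within one. Because the
  background is the pooled −6..−1 composition of the same universe, a
  position-invariant consensus (as the simulator plants upstream of the
  AUG) leaves upstream log-odds nearly flat — in the simulation the
  planted context strength is expressed mostly through the +4 position,
  whose consensus G stands out against the A-rich upstream background.
* With two replicates per condition, per-gene dispersion estimates lean
  heavily on the trend; strongly gene-specific overdispersion is
  under-captured, which the shrinkage weight parameter exposes.
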