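# ribote

Differential **relative translational efficiency** (TE_rel) analysis for
ribosome-profiling experiments, with the transcript-leader feature scoring
needed to ask *why* translation of particular mRNAs changes.

## The problem

Ribosome profiling pairs deep sequencing of ribosome-protected mRNA
fragments (RP) with RNA-seq of the same cells. For a gene *g* in library
*j*, the translational efficiency is footprint density over mRNA abundance;
after within-library normalization it is only interpretable *relative to
the rest of that sample's transcriptome*:

```
TE_rel(g) = (RP_gj / s_j^RP) / (RNA_gj / s_j^RNA)
```

When a translation-initiation factor is disrupted (here: the eIF3 complex
or its mRNA-entry-channel arm, contrasted against isogenic wild type in two
biological replicates each), the question is which mRNAs are *more or less
sensitive than average*, and whether sensitivity tracks features of the
transcript leader (5'-UTR): its length, secondary structure (PARS scores),
start-codon (Kozak) context, uORFs, and closed-loop-forming potential.

## What the package does

- **Quantification with the field's exclusion rules** — footprints on the
  first 15 and last 5 codons of each CDS are ignored (cycloheximide
  artifacts); uORFs are counted full-length; genes with fewer than 128
  total mRNA reads across the four libraries of a strain pair are excluded.
- **The ΔTE_rel test** — per gene, a negative-binomial log-linear model
  over the eight libraries with design
  `~ assay + condition + assay:condition` and offsets `log(size factor)`
  (median-of-ratios, per assay). The interaction coefficient is
  `log2 ΔTE_rel`; inference is a Wald test with Benjamini–Hochberg
  adjustment, and significant genes are binned by fold change
  (≥50% / ≥100%, up or down). NB parameterization:
  `Var = μ + α μ²`, per-gene α estimated by method of moments and shrunk
  toward a `α(μ) = a₀ + a₁/μ` trend.
- **Feature scoring** — 5'-UTR length via the dominant-isoform rule (top
  isoform ≥40% of transcripts and ≥2× the runner-up); PARS window
  statistics (mean over the UTR, First30, Start30, Plus30, and the Max30
  sliding-window maximum); Kozak −6..+4 context scores from a pseudocounted
  log₂-odds PWM; sequence-logo matrices; uORF cap distances.
- **Association statistics** — Spearman/Pearson correlations,
  hypergeometric set overlaps, Wilcoxon and ANOVA+Tukey group contrasts,
  Ward hierarchical clustering of ΔTE profiles, cross-dataset comparison
  against published ΔTE tables for other initiation-factor mutants.
- **A synthetic-data generator** — annotation (GFF3), sequences (FASTA),
  PARS tracks (bedGraph), isoform/closed-loop/count tables (TSV) with known
  ground truth (planted effects, dispersions, size factors), so the entire
  pipeline is testable at desk scale without the deposited sequencing data.

## Worked example

```r
library(ribote)

cfg <- sim_config(
  400, seed = 1, frac_null = 0.5,
  effect_model = list(intercept = 0, utr_length = -0.002, max30 = -0.3,
                      context_score = 0, sd = 0.25),
  mean_expression_dist = list(meanlog = log(300), sdlog = 0.8),
  pars_model = list(baseline_mean = -0.5, noise_sd = 1,
                    structured_rate = 0.5, structured_effect = 2.5,
                    window = 30, missing_rate = 0))
run <- run_full(cfg, "demo_out")

run$manifest$n_genes_tested
#> [1] 397
table(run$te$category)
#>
#> down100  down50      ns   up100    up50
#>       4      11     370       3       9
run$assoc$correlations$tl_length
#> spearman rho = -0.1335 (n = 277, p = 0.0263)
run$assoc$group_tests$tl_length_wilcoxon$down_vs_ns
#> Wilcoxon down vs ns: W = 1834.5, p = 0.0038 (normal approx.)
run$evaluation$empirical_fdr
#> [1] 0
```

The simulation plants a negative effect of 5'-UTR length (−0.002 per nt)
and of structured Max30 windows on true log2 ΔTE_rel; the run recovers a
significantly negative Spearman correlation with UTR length and
significantly longer leaders among ΔTE-decreased genes — the analysis
pattern the method is built to detect — with zero false discoveries among
the 27 significant calls in this run. `demo_out/` contains `te_results.tsv`, `features.tsv`,
`assoc.json`, `evaluation.json` and a reproducibility `manifest.json`
(plus `sim/` with every generated input file).

## Command line

```sh
Rscript inst/cli/ribote.R simulate --n-genes 500 --seed 1 --outdir sim/
Rscript inst/cli/ribote.R run --sim-genes 500 --seed 1 --outdir out/
Rscript inst/cli/ribote.R run --config run.yaml --outdir out/
```

Exit codes: 0 ok, 1 input error, 2 internal error.

## Scope

Upstream read processing (alignment, P-site offsetting, rRNA subtraction)
and GO enrichment are out of scope; inputs are transcript-coordinate
annotation, counts and tracks. The NB stage is a reimplementation of the
analysis design, not a numerical clone of DESeq2 (no Cook's filtering, no
independent filtering beyond the 128-read rule).
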