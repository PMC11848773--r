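# fibrosig

Identification of **etiology-specific pro-fibrogenic gene signatures** from
bulk liver transcriptomes, and their attribution to cell types with a
single-cell reference.

Liver fibrosis in primary sclerosing cholangitis (PSC), primary biliary
cholangitis (PBC) and metabolic dysfunction-associated steatotic liver
disease (MASLD) is staged histologically (Desmet/Scheuer 0–4 or Ishak 0–6),
but the transcriptional programs driving the scarring differ by etiology.
`fibrosig` implements the full analysis cascade needed to isolate such a
disease-specific program and ask *which cells express it, and when*:

1. **Differential expression** per disease, advanced vs. early fibrosis:
   per-gene negative-binomial GLM with log size-factor offset
   (median-of-ratios), a sex covariate, Cox–Reid dispersion estimation with
   parametric-trend MAP shrinkage, Wald test
   (z = log2FC / se), Benjamini–Hochberg correction, and the inclusive DEG
   rule padj ≤ 0.05 ∧ |log₂FC| ≥ 1.
2. **Set algebra**: exact Venn partition of the per-disease DEG sets, the
   focus-disease-specific set, intersection with an external validation
   cohort, and hypergeometric over-representation testing.
3. **Cell-type specificity**: against a labeled single-cell reference, a
   gene belongs to a cell type iff the type passes a 0.5% detection-fraction
   floor and its mean expression is ≥ 1.5× the next-highest eligible type
   ("50% higher"); otherwise it is *unspecific*.
4. **Trajectory deconvolution**: the bulk fibrosis axis (a
   sign-oriented principal component, positive = more fibrosis) is projected
   onto the reference; per cell type, the density of PC gene weights of its
   assigned genes shows *when* along fibrosis that type's program is active.
5. **qPCR validation**: ΔΔCt quantification against a housekeeping gene
   (fold change 2^(−ΔΔCt)) with exact unpaired two-sided Wilcoxon tests.
6. A **synthetic-data module** generates bulk cohorts, single-cell
   references and qPCR plates with planted, machine-readable ground truth —
   every stage of the cascade is testable end-to-end without any download.

The differential-expression core follows the classic R modelling idiom:
`nb_fit()` returns a classed object with `print()`, `summary()`, `coef()`,
`results()` and `plot()` (dispersion diagnostics) methods.

## Worked example

A complete synthetic run — three diseases with Table-style cohort
composition, an Ishak-staged external PSC cohort sharing 60% of the planted
program, and a single-cell reference in which planted trajectory genes are
markers of their cell type:

```r
library(fibrosig)

cfg <- pipeline_config(seed = 42)
run <- run_pipeline(cfg)
run
#> Pipeline run (seed 42 )
#>   DEGs per disease: PSC=197, PBC=53, MASLD=135
#>   PSC-specific: 181; validated externally: 72
#>   cell-type attributed: 3 of 72 mapped genes
```

The per-disease DEG counts mirror the planted programs (120 PSC-specific +
shared + trajectory genes, 40 PBC, 120 MASLD); 181 genes are exclusive to
the PSC comparison, of which 72 replicate in the external cohort — the
planted sharing is 60%, the shortfall being power, exactly as in real
validation cohorts. The trajectory stage then shows *when* each cell type's
genes are active along the oriented fibrosis axis:

```r
run$trajectories$PSC
#> Trajectory scores along component 1 (sign 1 ): 2000 genes used, 0 dropped
#>       cell_type n_genes   median_coef median_cell_score
#> 1 cholangiocyte      30  0.0650391858        3.15072327
#> 2    fibroblast      10 -0.0023660538       -0.10054297
#> 3    hepatocyte      10 -0.0037763486        0.07579337
#> 4    macrophage      31 -0.0674136069       -3.43139561
#> 5         tcell      11 -0.0008049872        0.10140596
```

The planted macrophage-early program sits on the negative (early-fibrosis)
side of the axis and the cholangiocyte-late program on the positive side;
the three uninvolved types stay near zero. `plot(run$trajectories$PSC)`
draws the density curves.

Individual stages are plain functions on plain containers:

```r
f   <- filter_low_counts(run$bulk$counts)      # summed-count >= 10 filter
fit <- nb_fit(f, run$bulk$meta, disease = "PSC", covariates = "sex")
head(results(fit)[order(results(fit)$padj), ], 3)
#>        gene base_mean   log2FC        se     stat            p         padj is_deg
#> 1497 g01497 1077.5561 2.045133 0.1384674 14.76978 2.294578e-49 4.589157e-46   TRUE
#> 23   g00023  444.1447 2.332184 0.1641123 14.21091 7.840503e-46 7.840503e-43   TRUE
#> 993  g00993 1784.0335 2.192568 0.1559816 14.05658 7.019269e-45 4.679513e-42   TRUE
```

The top genes recover the planted |log₂FC| = 2 step effects. Setting
`outdir =` in `pipeline_config()` writes every stage as plain text (TSV/CSV/
MatrixMarket) plus a `manifest.json` with thresholds, seeds, per-stage gene
counts and an MD5 hash per file; reruns with the same seed are
byte-identical.

## Package layout

| Path | Contents |
| --- | --- |
| `R/simulate-*.R` | synthetic bulk / single-cell / qPCR generators with ground truth |
| `R/preprocess.R` | count filter, size factors, log transform, oriented PCA |
| `R/diffexp.R` | NB Wald GLM (`nb_fit`), BH adjustment, DEG calling |
| `R/genesets.R` | Venn partition, specific sets, external validation, ORA |
| `R/celltype.R` | detection fractions, specificity rule, trajectory scoring |
| `R/qpcr.R` | ΔΔCt quantification and rank-sum comparison |
| `R/pipeline.R` | `run_pipeline()` orchestration with manifest |
| `vignettes/fibrosig-methods.Rmd` | model, assumptions, design choices, limitations |
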