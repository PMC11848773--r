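---
title: "Methods: etiology-specific pro-fibrogenic signatures and their cell-type attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: etiology-specific pro-fibrogenic signatures and their cell-type attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Chronic cholestatic and metabolic liver diseases — primary sclerosing
cholangitis (PSC), primary biliary cholangitis (PBC) and metabolic
dysfunction-associated steatotic liver disease (MASLD) — all progress through
histologically staged fibrosis, but the transcriptional programs that drive
scarring differ by etiology. `fibrosig` implements the computational cascade
used to isolate an etiology-specific pro-fibrogenic gene set from bulk liver
transcriptomes and to attribute it to cell types with a single-cell
reference:

1. per-disease differential expression between advanced and early fibrosis
   (negative-binomial Wald test with a sex covariate),
2. Venn partition of the per-disease DEG sets and extraction of the
   focus-disease-specific set,
3. validation of that set against an independent external cohort,
4. cell-type specificity assignment of the validated genes against a labeled
   single-cell reference, and
5. projection of the fibrosis-axis principal component onto the reference to
   score cell types along the fibrosis trajectory.

Every stage can be exercised on synthetic cohorts with planted,
machine-readable ground truth, which is how the package tests itself.

# Differential expression model

For gene $g$ and sample $j$ with size factor $s_j$, counts are modeled as

$$y_{gj} \sim \mathrm{NB}(\mu_{gj}, \alpha_g), \qquad
  \log \mu_{gj} = \log s_j + x_j^\top \beta_g,$$

with $\mathrm{Var}(y) = \mu + \alpha\mu^2$. The design contains an intercept,
the sex covariate and the fibrosis category (early = reference; Desmet/Scheuer
stages 0–2 vs. 3–4, or Ishak 0–3 vs. 4–6 for externally staged cohorts).
Size factors are median-of-ratios estimates; note they are identified only up
to a multiplicative constant, which cancels in all downstream contrasts.

Dispersion estimation follows the DESeq2 family but deliberately simplified:

* per-gene Cox–Reid adjusted maximum likelihood on $\log\alpha \in
  [\log 10^{-8}, \log 10]$, with fitted means held fixed from an initial
  method-of-moments fit;
* a parametric mean–dispersion trend $\alpha(\mu) = a_1/\mu + a_0$ fitted by
  iterated gamma-weighted least squares over well-behaved genes (trend
  coefficients clamped non-negative; a constant median fallback if fewer than
  ten usable genes);
* maximum a posteriori shrinkage of $\log\alpha$ towards the trend with a
  log-normal prior whose variance is
  $\max(\mathrm{MAD}^2(\log\alpha_{gw} - \log\alpha_{tr}) -
  \psi_1((m-p)/2),\ 0.25)$, the trigamma term approximating the sampling
  variance of the gene-wise estimate.

What is intentionally *not* implemented: dispersion-outlier refitting,
independent filtering of low-mean genes, count-outlier replacement, and
log2FC shrinkage (apeglm/ashr). The thresholding convention
(padj $\le$ 0.05, $|\log_2\mathrm{FC}| \ge 1$, both inclusive) operates on
unshrunk fold changes, so shrinkage would change the meaning of the cut-off.
The Wald statistic $\beta/\mathrm{se}$ is referred to the standard normal;
genes with an undefined standard error propagate `NA` and are excluded from
the Benjamini–Hochberg denominator. A weak ridge ($10^{-6}$) on the IRLS
normal equations keeps coefficients finite when one category has all-zero
counts. The suite cross-checks log2FC estimates and DEG calls against DESeq2
on a shared simulated cohort; agreement is high but not exact, the residual
difference being the empirical-Bayes details listed above.

The count filter retains genes with a *summed* count of at least 10 across
samples. The alternative strict reading — at least 10 in every sample — is
available via `filter_low_counts(mode = "each")` but would discard most genes
in cohorts of ~50 samples, so the summed interpretation (standard DESeq2
practice) is the default.

# PCA and the fibrosis axis

PCA operates on $\log_2(y/s + 1)$-transformed counts, genes centered but not
scaled (scaling is available by flag). This transform replaces heavier
regularized-log/variance-stabilizing transforms: their empirical-Bayes
shrinkage is internal to DESeq2 and under-determined from the outside, while
the simple transform preserves the sample-clustering structure that the
fibrosis axis is extracted from. All filtered genes enter the PCA (no
high-variance pre-selection).

Each component is *oriented*: if the Spearman correlation between its scores
and the fibrosis stage is negative, the component (scores and loadings) is
flipped and the sign recorded, so positive scores always point towards higher
fibrosis. Undefined or zero correlations keep the $+1$ convention. The
trajectory component per disease defaults to the one with the largest
absolute Spearman correlation with stage — in practice PC1 for cholestatic
cohorts and a later component when a disease's dominant variance axis is not
fibrosis — with a manual override in the pipeline configuration.

# Cell-type specificity rule

Against a labeled single-cell reference, a gene is mapped as follows:

* cell types in which the gene is detected in fewer than 0.5% of cells
  (boundary inclusive) are ineligible; if no type remains the gene is
  `"undetected"`;
* among eligible types, the gene is assigned to the type with the highest
  mean expression **iff** that mean is at least 1.5 times the next-highest
  eligible mean (boundary inclusive, i.e. "50% higher"); a single eligible
  type counts as specific; otherwise the gene is `"unspecific"`.

The rule is invariant to cell permutations and to global rescaling of the
expression matrix. Enrichment log fold changes (natural log of type mean over
the mean of all other cells, with an $\epsilon = 10^{-9}$ of the global mean
guarding zeros) are reported alongside for dot-plot-style displays but do not
enter the assignment.

# Trajectory projection

The single-cell matrix is library-size normalized (counts per $10^4$),
`log1p`-transformed, and each gene standardized to zero mean and unit
variance (zero-variance genes are zeroed and flagged). Two linked views of
"cell types along the fibrosis axis" are computed:

* **gene-level (default density)**: every shared gene carries its oriented PC
  loading ("gene weight") as a coordinate on the fibrosis axis; per cell type
  the density of these coordinates is estimated over the genes *assigned* to
  that type by the specificity rule (equal weights, Gaussian KDE, weighted
  Scott bandwidth $1.06\,\sigma n_{\mathrm{eff}}^{-1/5}$);
* **cell-level (secondary)**: each cell's score $\sum_g w_g z_{cg}$, giving a
  per-type score distribution.

A detection-share weighting over *all* genes
($f_{t,g}/\sum_{t'} f_{t',g}$, `density_weights = "share"`) is also
implemented. It is not the default because, in any realistic gene universe,
the overwhelming majority of genes are background with near-uniform shares
across types: every type's density then collapses onto the same background
distribution of loadings and the per-type median becomes an artifact of the
background rather than of the planted (or real) biology. Restricting each
type's density to its assigned genes reflects the procedure of determining
per-gene cell-type specificity and ranking genes by their PC coefficient, and
empirically recovers planted trajectory polarity in essentially every
simulation seed, whereas the share weighting recovers it in a minority.

Genes absent from the reference are dropped from the projection and counted,
mirroring the partial attributability always observed with real references.

# qPCR quantification

$\Delta Ct = Ct_{\mathrm{target}} - Ct_{\mathrm{HK}}$ per sample (technical
replicates averaged on the Ct scale first), $\Delta\Delta Ct$ against the
arithmetic mean of the control group's $\Delta Ct$ (median optional), and
relative expression $2^{-\Delta\Delta Ct}$. Group comparison is the unpaired
two-sided Wilcoxon rank-sum test: exact for groups of at most 12 without
ties, normal approximation with tie correction otherwise; all-tied inputs
return $p = 1$ by convention. Amplification-efficiency correction (Pfaffl) is
out of scope.

# The synthetic-data generator

The generator defines the study conditions the package is tested under.

**Bulk cohorts.** Counts are negative binomial with a gene-shared dispersion
$\alpha$ (default 0.05, typical of well-powered bulk liver RNA-seq after
trend shrinkage), log-normal baseline means
($\mathrm{meanlog} = \log 100$, $\mathrm{sdlog} = 1.5$, spanning filtered-out
to highly expressed genes), and uniform per-sample size factors in
$[0.5, 2]$. The default cohort composition copies the three-disease design
the cascade targets: 16 PSC (12 early / 4 advanced), 15 PBC (12/3) and 16
MASLD (10/6) samples on the Desmet scale, with an Ishak-staged, PSC-only
cohort of 74 samples as the external validation set. Disease DEG programs
are step effects of $\pm 2$ log2 units (70% up-regulated, as fibrosis
signatures are predominantly inductions) applied in the advanced category,
with configurable 2- and 3-disease overlaps; trajectory programs are instead
log-linear in stage ($\pm 0.8$ log2 per stage around the mid-stage), keeping
the category-level and trajectory-level analyses distinguishable. A
designated gene subset carries a sex effect, and sexes alternate within each
disease so sex is never confounded with the fibrosis category. The external
cohort shares 60% of the focus-disease program by construction, so the
validation overlap has a planted expectation.

**Single-cell reference.** Sparse Poisson counts: baseline rate
$\lambda_0 = -\log(1-d)$ so that the expected detection fraction of a
background gene is exactly $d$ (default 0.25); each cell type carries
disjoint planted markers at $10\times\lambda_0$ (floored so markers stay
detectable even at $d = 0$). The default $d$ is chosen so that, at a few
hundred cells per type, the Poisson standard error of a per-type mean is
several-fold smaller than the 1.5× specificity margin — the regime in which
the rule is meaningful; at substantially lower detection rates the rule
degenerates into coin-flipping on baseline genes, which is a property of the
rule, not of its implementation. In end-to-end runs the bulk trajectory
genes are co-planted as the markers of their cell type, tying the two
modalities together the way a real signature ties to its producing cells.

What the generator does *not* emulate: doublets, ambient RNA, batch effects
beyond size factors and sex, gene–gene correlation, and read-level artifacts.
Passing tests therefore demonstrate the correctness and calibration of the
cascade's statistics under its own model family, not robustness to every
failure mode of real tissue data.

**qPCR plates.** Housekeeping Ct around 20 cycles, per-gene baseline
$\Delta Ct$ uniform in $[2, 8]$, cases shifted by $-\log_2 \mathrm{FC}$, and
Gaussian Ct noise (default sd 0.3 cycles, a typical technical-replicate
spread), so the expected recovered fold change equals the planted one.

# Numerical choices and degenerate inputs

* IRLS: linear predictor clamped to $[-30, 30]$; convergence at
  $10^{-8}$ on coefficients, 50 iterations maximum.
* Dispersion optimization: golden-section (`optimize`) with tolerance
  $10^{-4}$ on $\log\alpha$ — well below any downstream sensitivity.
* Specificity boundaries are compared inclusively with ordinary
  floating-point comparison; exact-boundary constructions (mean ratio exactly
  1.5, detection exactly 0.5%) resolve inclusively by design and are pinned
  by tests.
* All-zero genes are rejected by the GLM with a pointer to
  `filter_low_counts`; zero-count cells are dropped with a warning before
  projection; an empty gene intersection between loadings and reference is an
  error.
* Orientation ties (zero-variance scores or stages) default to $+1$.
* All generators accept a seed and restore the caller's RNG state; the
  pipeline derives per-stage seeds from its master seed by fixed offsets, so
  identical configurations are byte-identical across runs.

# Problem sizes used by the test suite

The suite and the acceptance script exercise the cascade at the scale the
statistics stabilize at while staying desk-sized: 2,000-gene universes for
calibration/power/trajectory checks (16-sample discovery-style cohorts;
20 seeds for power and covariate leakage, 40 for trajectory polarity), a
5-type × 200-cell reference with 10 planted markers per type for the
specificity rule, 1,000 random vectors for the BH oracle, 500 random
instances for the Venn oracle, and a reduced 400-gene two-disease
configuration for the byte-identity determinism check of the full pipeline.

# Known limitations

* The dispersion machinery is a documented approximation of the DESeq2
  empirical-Bayes pipeline; per-gene results can differ near the
  significance boundary.
* The headline gene counts of the motivating study (431/367/150 etc.) derive
  from patient data that the package does not ship; nothing in the package
  asserts them, and the synthetic defaults only mirror the cohort *shapes*.
* The specificity rule assigns at most one cell type per gene; genuinely
  multi-lineage genes are "unspecific" by construction.
* The gene-level trajectory densities inherit the specificity rule's
  assignments; genes not assigned to any type contribute to no density.
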