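---
title: "Zonal multi-omics of the liver lobule: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zonal multi-omics of the liver lobule: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zonemap)
```

## The problem

Hepatocytes are functionally heterogeneous along the porto-central axis of
the liver lobule: metabolic programs, morphogen signalling and even
mitochondrial content vary systematically between the pericentral (CV),
intermediate (IZ) and periportal (PV) zones. `zonemap` analyses paired
multi-omics measurements from micro-dissected zones — read counts for
expression, strand-merged bisulfite CpG calls for DNA methylation — and
integrates them into a picture of *epigenetically marked driver genes*:
genes whose zonal upregulation coincides with zonal hypomethylation of
nearby regulatory DNA.

Because each donor contributes one sample per zone, every zonal contrast
is paired within donors. The design carries donor-level covariates
(phenotype group, sex, age, BMI, diabetes) which are constant within a
donor; they are therefore collinear with a donor factor, and the package
resolves that collinearity explicitly (see *Covariates versus donor
blocking* below).

## Differential expression model

For gene $g$ and sample $s$ (donor $d(s)$, zone $z(s) \in \{CV, PV\}$),
counts are modelled as negative binomial,

$$y_{gs} \sim \mathrm{NB}(\mu_{gs}, \phi_g), \qquad
\log \mu_{gs} = \log(N_s f_s) + \delta_{d(s)} + \beta_g \cdot
\mathbf{1}[z(s) = PV],$$

with $N_s$ the raw library size and $f_s$ a median-of-ratios
normalization factor rescaled to geometric mean one. $\beta_g / \log 2$
is the reported $\log_2$ fold change, oriented PV over CV: positive
values mean periportally higher expression. The model is fitted by
iteratively reweighted least squares with a log link.

Dispersion is estimated in two passes. A Poisson fit (donor + zone, so
residuals are donor-adjusted) provides fitted means $\hat\mu$; the
per-gene dispersion $\hat\phi_g$ solves the Pearson moment equation
$\sum_s (y_{gs}-\hat\mu_{gs})^2 / (\hat\mu_{gs}(1+\phi\hat\mu_{gs})) =
n - p$. Raw moment estimates are noisy at this sample size, so they are
shrunk 50% toward a lowess trend of $\hat\phi$ on mean $\log_2$ CPM —
the simplest defensible stabilization in the family of trended-dispersion
estimators used throughout count-based DE tools. The Wald statistic on
$\beta_g$ is referred to a $t$ distribution with the residual degrees of
freedom (38 samples − 20 design columns = 18 at the default cohort),
which empirically keeps the type-I error of the test inside
[0.03, 0.07] at $p<0.05$ on null simulations; a normal reference is
anticonservative at this design size.

Genes are called zonated at BH $q < 0.01$ and $|\log_2 \mathrm{FC}| > 1$;
the CPM filter (`min_cpm = 0.5` in at least `min_samples = 5` samples,
computed on raw library sizes) runs first. Intermediate-zone samples are
excluded from the PV-vs-CV test and used only for three-point profile
classification, where the intermediate zone of a gene is called a peak or
trough only if it exceeds (falls below) both flanking zones by more than
`flat_tol = 0.1` on a max-normalized scale.

## Differential methylation model

CpG calls are strand-merged (a CpG is keyed by the position of the C on
the plus strand) and filtered to sites with coverage $\ge 10$ per sample.
Sites are aggregated into 500 bp tiles on a fixed grid anchored at
coordinate 0 of each chromosome — step size equals tile size, so the grid
is deterministic and non-overlapping. Aggregation uses *missing-as-zero*
semantics: a sample that does not cover a CpG contributes (0, 0) at that
site, while the site still counts toward the tile's union CpG set. Tiles
with fewer than 3 union CpGs are discarded (a strict per-sample mode is
available via `per_sample_cpgs`), as are mitochondrial and sex
chromosomes.

Per tile, $(\text{methylated}, \text{total})$ counts are analysed by
logistic regression on zone with donor blocking. Count overdispersion
relative to the binomial (from cell-to-cell heterogeneity and local
correlation of CpGs) is absorbed by inflating the Wald variance with the
Pearson scale $\max(1, X^2/\mathrm{df})$ — the quasi-binomial correction
family — and the statistic is again referred to a $t$ with residual
degrees of freedom. The effect size `dmeth` is the coverage-weighted mean
methylation percentage of PV minus CV, in percentage points; with this
orientation a gene upregulated pericentrally that is hypomethylated
pericentrally has negative $\log_2$FC and positive `dmeth`. A tile is a
DMR at $q<0.01$ and $|\mathrm{dmeth}| \ge 5$ points. Tiles whose
intermediate-zone mean escapes the CV–PV range by more than
`gradient_tol = 5` points are flagged `IZ_extreme`; everything else is a
monotone porto-central gradient.

Degenerate tiles (all 0% or all 100% in both zones) are reported with
`dmeth = 0`, $p = 1$; tiles lacking nonzero coverage in at least 3 donors
per zone are untestable and carry `NA` statistics.

## Integration and driver genes

DMRs are annotated to the gene with the nearest TSS (tile midpoint to
TSS; ties broken by the lexicographically smaller gene id for
determinism) and to a genomic feature with fixed precedence
promoter > exon > intron > intergenic, where the promoter is a
strand-aware TSS −1500/+500 bp window. The window is a conventional
asymmetric choice and is config-exposed.

A differentially expressed gene is associated with every DMR whose
nearest gene it is. Across gene–DMR pairs, the Pearson correlation of
$\log_2$FC with `dmeth` quantifies the expression–methylation
anti-correlation (with the shared PV-vs-CV orientation, repression shows
as $r < 0$). A gene is an *epigenetically marked driver* of zonation if
it is upregulated in a zone and at least one associated DMR is
hypomethylated in that same zone; genes with DMRs in both directions
remain drivers when one concordant DMR exists and are flagged `mixed`.

## Binding-site methylation zonation

For each transcription factor, the tested tile universe is
cross-tabulated by DMR status and binding-site overlap (at least one
base of one site), and enrichment is tested two-sided by Fisher's exact
test with Bonferroni correction across included TFs ($p < \alpha/n$,
strict). The zonated methylation difference of a TF, `delta_txf`, is the
mean `dmeth` over DMR tiles overlapping its sites; because the DMR
population as a whole carries a mild porto-central demethylation
gradient, `delta_txf` is centred by subtracting the across-TF mean
(`delta_txf_norm`, mean-zero by construction). An alternative mode
subtracts the mean `dmeth` of all DMR tiles instead. TFs with fewer than
10 DMR-overlapping tiles are excluded before normalization and
correction; the cut-off is a package convention (config-exposed), chosen
because the mean over fewer tiles is dominated by single-tile noise.

## Cross-species comparison

A nine-layer mouse zonation reference is collapsed to three zones by
fixed averaging (layers 1–2 pericentral, 4–5 intermediate, 8–9
periportal; layers 3, 6, 7 unused), background-subtracted, and matched
to human genes through a one-to-one orthologue map. Per zone, Spearman
rank correlation of $\log(\mathrm{CPM}+1)$ quantifies global
comparability. A human-zonated gene is *conserved* when the mouse
porto-central fold change $\log_2((PV+\varepsilon)/(CV+\varepsilon))$
(with $\varepsilon = 0.01$ CPM) matches the human direction with
magnitude $\ge$ `mouse_lfc_min = 0.5`; below that magnitude the mouse
profile is *flat*, otherwise *discordant*. No quantitative conservation
criterion is standard in the field, so the threshold rule is a package
convention reported in the output metadata.

## Mitochondrial read ratio

The per-sample fraction of reads on the mitochondrial chromosome is a
proxy for mtDNA copy number. Zone contrasts are tested with the paired
two-sided Wilcoxon signed-rank test, exact for up to 25 donors (robust
to donor-level scale differences; a paired t-test is available), either
pairwise over the three contrasts or pooled (CV against each donor's
IZ/PV mean). Asterisk markers in the report use $p < 0.001$.

## What the synthetic lobule emulates

The generator produces a fully labelled dataset under the default study
design: 19 donors × 3 zones; phenotype groups NC/HO/STEA/EARLY with
4/5/5/5 donors and group-typical sex, age and BMI ranges (no phenotype
effect on expression by default; an effect knob exists to exercise
covariate adjustment).

* **Expression** — 2,000 genes; 5% pericentrally and 5% periportally
  upregulated at $|\log_2\mathrm{FC}| = 2$, intermediate zone at the
  geometric midpoint (profiles are monotone along the axis; IZ-peaked
  genes exist only via a negative-control knob). Counts are negative
  binomial (dispersion 0.05) around zone means scaled by uniform library
  sizes (0.8–1.2 M) and a log-normal, gene-independent donor effect
  (SD 0.15) — the structure that makes donor blocking matter.
* **Methylome** — 2,000 autosomal 500 bp tiles (plus chrX territory that
  the tiling stage must discard; the mitochondrial chromosome carries no
  CpG tiles), ~8 CpGs per tile, negative-binomial coverage (mean 30),
  beta-binomial site methylation (precision 30). 200 tiles are planted
  DMRs at 20 percentage points; half are coupled to zonated genes (1–3
  DMRs per driver gene placed in its promoter, first intron or an exon)
  and hypomethylated in the gene's upregulated zone. Uncoupled DMRs
  anchor at flat genes so the planted couplings are the only
  expression–methylation structure and truth labels suffice to score the
  driver caller.
* **TFBS** — 20 TFs; 3 zonated TFs alternate CV/PV preference (binding
  factors occur on both sides of the porto-central axis) and place sites
  in DMR tiles hypomethylated in their preferred zone with odds 5,
  deepening those tiles' differences by 10 points; the rest place sites
  uniformly.
* **Mitochondrial reads** — binomial split of $10^6$ reads per sample at
  zone fractions 0.005 / 0.008 / 0.010 (CV / IZ / PV).
* **Mouse reference** — a noisy monotone transform of the human zonal
  truth with a configurable concordant fraction (default 0.6), reversed
  or flattened profiles for the rest, and 100 additional flat
  orthologues (300 orthologue pairs in total).

All randomness flows from one integer seed through R's RNG; a fixed seed
reproduces every file bit-identically. The generator does **not**
emulate raw reads, bisulfite conversion error, SNPs, non-parenchymal
contamination, spatially correlated methylation beyond the tile level, or
realistic between-gene dispersion trends — so passing recovery tests
demonstrate correctness of the estimators under the stated model, not
performance on real tissue.

## Problem sizes used in validation

Parameter-recovery tests run at the default design above. The
binding-site statistic is validated on a tile universe proportioned like
a genome-wide analysis — 20,000 tiles with 2,000 DMRs (a 10% DMR
fraction) and 10,000 sites per TF — because the statistic consumes
tile-level DM results and its discriminating power depends on the number
of DMR tiles a TF's sites sample: at a few hundred tiles the binary
tile-marking saturates and per-TF means are single-tile-noise dominated.
For these runs the tile-level truth (planted difference + estimation
noise matching the caller's observed recovery error) stands in for the
DM caller, whose own recovery is validated separately; this isolates the
statistic from the caller. End-to-end determinism is checked on a small
8-donor configuration.

## Numerical choices

* IRLS: log-link with linear predictor clamped to ±30, deviance
  convergence at relative 1e-8, 50-iteration cap; information matrix
  inverted by Cholesky with an SVD pseudo-inverse fallback.
* Moment dispersion solved by monotone root-finding on $[0, 10^4]$;
  trend floored at $10^{-4}$, final dispersion at $10^{-6}$.
* Contrasts are fitted in a canonical orientation (higher zone ordinal
  versus lower) and sign-flipped for reversed requests, so relabeling
  CV↔PV negates effect sizes bit-exactly and preserves p-values.
* Fisher's two-sided p sums hypergeometric probabilities
  $\le p_{\mathrm{obs}} (1 + 10^{-7})$ — the standard relative tolerance
  for floating-point ties.
* Nearest-TSS ties and BED sorting are resolved lexicographically for
  determinism.

## Known limitations

* The DE engine targets the paired two-zone contrast; it does not fit
  arbitrary designs or contrasts of more than two zones.
* Overdispersion handling in the DM test is a scale correction, not a
  full beta-binomial likelihood; for very low-coverage tiles the Wald
  approximation is crude (such tiles are largely removed by the coverage
  and CpG filters).
* DMR-to-gene assignment is nearest-TSS only; enhancer–gene contact maps
  are out of scope.
* The conserved-zonation rule is direction + magnitude in the mouse
  summary profiles; it uses no mouse significance estimate.
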