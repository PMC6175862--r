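# zonemap

Zonal transcriptome and methylome analysis of the liver lobule.

Hepatocytes change their transcriptional and epigenetic program along the
porto-central axis — from the pericentral zone (CV, around the central
vein) through the intermediate zone (IZ) to the periportal zone (PV).
`zonemap` analyses paired multi-omics data from micro-dissected zones of
multiple donors and integrates them:

* **Zonal differential expression** — per-gene negative-binomial GLM of
  counts on zone with donor blocking (each donor contributes one sample
  per zone), Wald *t* test on the zone coefficient, BH-FDR across genes.
  Calls at `q < 0.01`, `|log2FC| > 1`, with log2FC oriented PV over CV.
* **Tiled differential methylation** — strand-merged CpG calls filtered
  at ≥10× coverage, aggregated into 500 bp tiles (≥3 union CpGs,
  missing-as-zero; chrM/X/Y excluded), tested by overdispersion-corrected
  logistic regression with donor blocking. DMRs at `q < 0.01` and
  |Δmeth| ≥ 5 percentage points (Δmeth = %meth(PV) − %meth(CV)).
* **Epigenetically marked driver genes** — DMRs annotated to the nearest
  TSS (promoter/exon/intron/intergenic by fixed precedence); a zonally
  upregulated gene with ≥1 DMR hypomethylated in the same zone is a
  driver; the gene–DMR log2FC/Δmeth anti-correlation is quantified by
  Pearson *r*.
* **Binding-site methylation zonation** — per TF, a 2×2 table
  (DMR status × site overlap) tested by Fisher's exact test with
  Bonferroni correction, plus the zonated methylation difference
  `Delta.TXF` (mean Δmeth over DMR tiles carrying the TF's sites) and
  its across-TF-centred `Delta.TXF.Norm`.
* **Cross-species comparison** — a 9-layer mouse zonation reference
  merged to three zones (layers 1–2 / 4–5 / 8–9), per-zone Spearman
  correlation of log(CPM+1) over one-to-one orthologues, and a
  conserved / discordant / mouse-flat classification of human-zonated
  genes.
* **Mitochondrial gradient** — per-sample mitochondrial read fraction
  tested across zones by exact paired Wilcoxon signed-rank tests.
* **Synthetic lobule generator** — a fully labelled simulation of the
  whole design (counts, CpG calls, gene models, TFBS BED, sample sheet,
  mitochondrial reads, mouse reference) so every stage can be validated
  by parameter recovery without access to protected data.

## Worked example

Simulate the default study design (19 donors × 3 zones, 2,000 genes with
10% zonated at |log2FC| = 2, 2,000 CpG tiles with 200 planted DMRs) and
run every stage:

```r
library(zonemap)
res <- run_zonemap("zonemap_out", sim_cfg = sim_config(seed = 3))
writeLines(res$summary)
```

```
zonemap pipeline summary
========================
DE: 2000 genes tested; 100 CV_high, 100 PV_high
DM: 2000 tiles tested; 200 DMRs (200 monotone, 0 IZ_extreme)
Drivers: 48 epigenetically marked driver genes (24 CV, 24 PV)
DEG-DMR anti-correlation: r = -0.996 (p = 2.47e-104, 100 pairs)
TFBS: 3/20 TFs significant at Bonferroni threshold 0.0025
Mito CV_vs_IZ: median diff 0.003, p = 0.000143 (*)
Mito CV_vs_PV: median diff 0.005, p = 3.81e-06 (*)
Mito IZ_vs_PV: median diff 0.002, p = 0.000143 (*)
```

Reading the report: all 200 planted zonated genes are recovered (100 per
zone) and all 200 planted DMRs are found with monotone porto-central
gradients; 48 of the planted driver genes carry at least one concordant
hypomethylated DMR; expression and methylation gradients are strongly
anti-correlated (*r* = −0.996 across the 100 gene–DMR pairs); exactly
the 3 planted zonated TFs pass the Bonferroni threshold; and the
mitochondrial read fraction rises monotonically from CV to PV, with the
CV-vs-PV contrast at the minimal attainable exact p for 19 donors
(2 × 2⁻¹⁹ ≈ 3.8 × 10⁻⁶). Every number is written as a TSV under
`zonemap_out/` along with a JSON manifest of content hashes; re-running
with the same seed reproduces the directory bit-identically.

A thin command-line front-end over the same functions ships at
`inst/cli/zonemap.R`:

```sh
Rscript inst/cli/zonemap.R all --simulate --seed 3 --out zonemap_out
Rscript inst/cli/zonemap.R de --counts counts.tsv --samples samples.tsv --out de.tsv
```

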