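#' Annotate tiles to the nearest gene and genomic feature
#'
#' Each tile is assigned the gene whose transcriptional start site is
#' closest to the tile midpoint (ties broken by the lexicographically
#' smaller gene id, for determinism), and a genomic feature evaluated
#' against that gene's model with fixed precedence
#' promoter > exon > intron > intergenic. The promoter is a strand-aware
#' window around the TSS (`promoter_up` bp upstream, `promoter_down` bp
#' downstream; defaults 1500/500). The reported distance is from the tile
#' interval to the TSS, 0 when the TSS falls inside the tile.
#'
#' Tiles on chromosomes absent from the gene models are flagged intergenic
#' with no gene.
#'
#' @param tiles Data frame with `tile_id`, `chrom`, `start`, `end`
#'   (0-based half-open), e.g. a [zonal_dm()] result.
#' @param models Gene models as read by [read_gene_models()].
#' @param promoter_up,promoter_down Promoter window around the TSS in bp.
#' @return Data frame with `tile_id`, `nearest_gene`, `distance`, `feature`.
#' @export
annotate_dmrs <- function(tiles, models, promoter_up = 1500L,
                          promoter_down = 500L) {
  if (nrow(models) == 0L) stop("empty gene models")
  n <- nrow(tiles)
  gene <- rep(NA_character_, n)
  distance <- rep(NA_real_, n)
  feature <- rep("intergenic", n)
  by_chrom <- split(seq_len(nrow(models)), models$chrom)
  mid <- (tiles$start + tiles$end) / 2
  for (i in seq_len(n)) {
    cand <- by_chrom[[tiles$chrom[i]]]
    if (is.null(cand)) next
    tss0 <- models$tss[cand] - 1          # 0-based TSS position
    d_mid <- abs(mid[i] - (tss0 + 0.5))
    best <- cand[d_mid == min(d_mid)]
    if (length(best) > 1L) best <- best[order(models$gene_id[best])][1L]
    gene[i] <- models$gene_id[best]
    bt <- models$tss[best] - 1
    distance[i] <- if (tiles$start[i] <= bt && bt < tiles$end[i]) 0 else
      if (bt < tiles$start[i]) tiles$start[i] - bt else bt - (tiles$end[i] - 1L)
    feature[i] <- tile_feature(tiles$start[i], tiles$end[i], models[best, ],
                               promoter_up, promoter_down)
  }
  data.frame(tile_id = tiles$tile_id, nearest_gene = gene,
             distance = distance, feature = feature,
             stringsAsFactors = FALSE)
}

# Feature of one tile relative to one gene model, fixed precedence.
tile_feature <- function(start, end, gene, promoter_up, promoter_down) {
  tss0 <- gene$tss - 1
  if (gene$strand == "+") {
    p_lo <- tss0 - promoter_up
    p_hi <- tss0 + promoter_down + 1
  } else {
    p_lo <- tss0 - promoter_down
    p_hi <- tss0 + promoter_up + 1
  }
  overlaps <- function(a_lo, a_hi) start < a_hi && a_lo < end
  if (overlaps(p_lo, p_hi)) return("promoter")
  es <- gene$exon_start_list[[1L]]
  ee <- gene$exon_end_list[[1L]]
  for (k in seq_along(es)) if (overlaps(es[k], ee[k])) return("exon")
  if (overlaps(min(es), max(ee))) return("intron")
  "intergenic"
}

#' Link differentially expressed genes with DMRs
#'
#' A differentially expressed gene is associated with every flagged DMR
#' whose nearest gene it is; a gene may carry multiple DMRs while each DMR
#' maps to exactly one gene.
#'
#' @param de `zonemap_de` result (PV-vs-CV contrast).
#' @param dm `zonemap_dm` result from the same contrast.
#' @param annotations Output of [annotate_dmrs()] covering the `dm` tiles.
#' @return Data frame of gene-DMR pairs with `gene_id`, `tile_id`,
#'   `log2fc`, `zonation_call`, `dmeth`, `feature`.
#' @export
link_deg_dmr <- function(de, dm, annotations) {
  degs <- de[de$zonation_call != "none", , drop = FALSE]
  dmrs <- dm[dm$dmr_flag %in% TRUE, , drop = FALSE]
  ann <- annotations[match(dmrs$tile_id, annotations$tile_id), , drop = FALSE]
  hit <- !is.na(ann$nearest_gene) & ann$nearest_gene %in% degs$gene_id
  if (!any(hit)) {
    return(data.frame(gene_id = character(), tile_id = character(),
                      log2fc = numeric(), zonation_call = character(),
                      dmeth = numeric(), feature = character(),
                      stringsAsFactors = FALSE))
  }
  g <- ann$nearest_gene[hit]
  gi <- match(g, degs$gene_id)
  out <- data.frame(gene_id = g,
                    tile_id = dmrs$tile_id[hit],
                    log2fc = degs$log2fc[gi],
                    zonation_call = degs$zonation_call[gi],
                    dmeth = dmrs$dmeth[hit],
                    feature = ann$feature[hit],
                    stringsAsFactors = FALSE)
  out[order(out$gene_id, out$tile_id), , drop = FALSE]
}

#' Anti-correlation between expression and methylation gradients
#'
#' Pearson correlation between the per-pair log2 fold change and the
#' methylation difference, one observation per gene-DMR pair. With the
#' shared sign convention (both oriented PV over/minus CV), epigenetic
#' repression shows as a negative correlation.
#'
#' @param pairs Gene-DMR association table from [link_deg_dmr()].
#' @return List with `r`, `p`, and `n_pairs`.
#' @export
anticorrelation <- function(pairs) {
  if (nrow(pairs) < 3L) stop("need at least 3 gene-DMR pairs")
  if (stats::sd(pairs$log2fc) == 0 || stats::sd(pairs$dmeth) == 0) {
    stop("zero variance in log2fc or dmeth")
  }
  ct <- stats::cor.test(pairs$log2fc, pairs$dmeth, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_pairs = nrow(pairs))
}

#' Classify epigenetically marked driver genes
#'
#' A gene is a driver of zonation when it is upregulated in a zone and at
#' least one associated DMR is hypomethylated in that same zone. With the
#' fixed sign conventions (log2fc and dmeth both oriented PV vs CV):
#' a CV-upregulated gene (`zonation_call == "CV_high"`, log2fc < 0) needs a
#' DMR with `dmeth > 0` (lower methylation pericentrally), a PV-upregulated
#' gene needs `dmeth < 0`. Genes whose DMRs point in both directions remain
#' drivers if at least one concordant DMR exists and carry `mixed = TRUE`.
#'
#' @param pairs Gene-DMR association table from [link_deg_dmr()].
#' @return Data frame with one row per driver gene: `gene_id`, `zone`,
#'   `n_dmrs` (concordant), `n_discordant`, `mixed`, `dmeth_range`.
#' @export
classify_drivers <- function(pairs) {
  if (nrow(pairs) == 0L) {
    return(data.frame(gene_id = character(), zone = character(),
                      n_dmrs = integer(), n_discordant = integer(),
                      mixed = logical(), dmeth_range = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(split(pairs, pairs$gene_id), function(pg) {
    call <- pg$zonation_call[1L]
    zone <- sub("_high$", "", call)
    concordant <- if (zone == "CV") pg$dmeth > 0 else pg$dmeth < 0
    if (!any(concordant)) return(NULL)
    dd <- pg$dmeth[concordant]
    data.frame(gene_id = pg$gene_id[1L], zone = zone,
               n_dmrs = sum(concordant),
               n_discordant = sum(!concordant),
               mixed = any(!concordant),
               dmeth_range = paste0(round(min(abs(dd)), 1), "-",
                                    round(max(abs(dd)), 1)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    return(data.frame(gene_id = character(), zone = character(),
                      n_dmrs = integer(), n_discordant = integer(),
                      mixed = logical(), dmeth_range = character(),
                      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

#' Distribution of tiles over genomic features
#'
#' @param annotations Output of [annotate_dmrs()].
#' @param subset Optional logical or index vector selecting rows.
#' @return Named numeric vector of fractions over promoter, exon, intron,
#'   intergenic, summing to 1.
#' @export
feature_distribution <- function(annotations, subset = NULL) {
  feats <- c("promoter", "exon", "intron", "intergenic")
  f <- annotations$feature
  if (!is.null(subset)) f <- f[subset]
  if (length(f) == 0L) stop("empty subset")
  tab <- table(factor(f, levels = feats))
  stats::setNames(as.vector(tab) / length(f), feats)
}
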