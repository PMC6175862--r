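#' Merge a nine-zone mouse zonation matrix into three zones
#'
#' The reconstructed mouse layers are collapsed to match the three
#' micro-dissected human zones: layers 1-2 averaged as pericentral, 4-5 as
#' intermediate, 8-9 as periportal; layers 3, 6 and 7 are not used.
#'
#' @param mouse Genes x 9 numeric matrix, columns ordered layer 1
#'   (pericentral) to layer 9 (periportal).
#' @return Genes x 3 matrix with columns `CV`, `IZ`, `PV`.
#' @export
merge_mouse_zones <- function(mouse) {
  if (ncol(mouse) != 9L) stop("expected 9 mouse zone columns, got ", ncol(mouse))
  out <- cbind(CV = rowMeans(mouse[, 1:2, drop = FALSE]),
               IZ = rowMeans(mouse[, 4:5, drop = FALSE]),
               PV = rowMeans(mouse[, 8:9, drop = FALSE]))
  rownames(out) <- rownames(mouse)
  out
}

#' High-confidence expression filter after background subtraction
#'
#' Subtracts a per-gene (or global) background level from the merged
#' expression values, clamps at zero, and keeps genes with positive
#' background-subtracted expression in at least one merged zone.
#'
#' @param merged Genes x 3 merged zone matrix.
#' @param background Per-gene numeric vector (recycled scalar allowed) of
#'   background expression levels; must be non-negative.
#' @return List with `expr` (background-subtracted matrix) and `keep`
#'   (logical vector of retained genes).
#' @export
background_filter <- function(merged, background = 0) {
  if (any(background < 0)) stop("negative background")
  expr <- pmax(merged - background, 0)
  keep <- rowSums(expr > 0) >= 1L
  list(expr = expr, keep = keep)
}

#' Cross-species zonal expression correlation
#'
#' Spearman rank correlation, per zone, of `log(CPM + 1)` expression of
#' one-to-one orthologues between the human zonal means and the merged
#' mouse matrix.
#'
#' @param human Genes x 3 matrix of human per-zone mean CPM (rows = human
#'   gene ids).
#' @param mouse Genes x 3 merged mouse matrix (rows = mouse gene ids),
#'   in CPM-like units.
#' @param orthologues Data frame with `human_gene`, `mouse_gene`.
#' @param zone Zone label (`CV`, `IZ`, or `PV`).
#' @return List with `rho`, `p`, `n_pairs`.
#' @export
cross_species_correlation <- function(human, mouse, orthologues, zone) {
  zone <- match.arg(zone, ZONE_LEVELS)
  hi <- match(orthologues$human_gene, rownames(human))
  mi <- match(orthologues$mouse_gene, rownames(mouse))
  ok <- !is.na(hi) & !is.na(mi)
  if (sum(ok) < 5L) stop("fewer than 5 shared orthologue pairs")
  x <- log(human[hi[ok], zone] + 1)
  y <- log(mouse[mi[ok], zone] + 1)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n_pairs = sum(ok))
}

#' Conserved zonation classification
#'
#' For every human-zonated gene with an orthologue in the merged mouse
#' matrix, the mouse porto-central fold change is
#' `log2((PV + eps) / (CV + eps))`. The gene is `conserved` when the sign
#' matches the human log2 fold change and the magnitude reaches
#' `mouse_lfc_min`; `mouse_flat` when the magnitude is below threshold;
#' `discordant` otherwise. Genes missing from the orthologue map (or
#' filtered out in mouse) are `skipped`.
#'
#' @param de `zonemap_de` result (PV vs CV); only called genes
#'   (`zonation_call != "none"`) are classified.
#' @param mouse Genes x 3 merged mouse matrix (after
#'   [background_filter()]).
#' @param orthologues One-to-one orthologue map.
#' @param mouse_lfc_min Minimum |mouse log2FC| for a zonated mouse profile
#'   (default 0.5).
#' @param eps Pseudo-value added to both zone means (default 0.01 CPM).
#' @return List with `classes` (data frame `gene_id`, `class`,
#'   `mouse_log2fc`) and `counts` (named vector over conserved /
#'   discordant / mouse_flat / skipped).
#' @export
conserved_zonation <- function(de, mouse, orthologues, mouse_lfc_min = 0.5,
                               eps = 0.01) {
  zonated <- de[de$zonation_call != "none", , drop = FALSE]
  mi <- match(orthologues$mouse_gene[match(zonated$gene_id,
                                           orthologues$human_gene)],
              rownames(mouse))
  cls <- rep("skipped", nrow(zonated))
  mlfc <- rep(NA_real_, nrow(zonated))
  ok <- !is.na(mi)
  if (any(ok)) {
    m <- mouse[mi[ok], , drop = FALSE]
    mlfc[ok] <- log2((m[, "PV"] + eps) / (m[, "CV"] + eps))
    flat <- abs(mlfc[ok]) < mouse_lfc_min
    same_sign <- sign(mlfc[ok]) == sign(zonated$log2fc[ok])
    cls[ok] <- ifelse(flat, "mouse_flat",
                      ifelse(same_sign, "conserved", "discordant"))
  }
  classes <- data.frame(gene_id = zonated$gene_id, class = cls,
                        mouse_log2fc = mlfc, stringsAsFactors = FALSE)
  counts <- table(factor(cls, levels = c("conserved", "discordant",
                                         "mouse_flat", "skipped")))
  list(classes = classes,
       counts = stats::setNames(as.integer(counts), names(counts)),
       mouse_lfc_min = mouse_lfc_min, eps = eps)
}
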