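#' PCA-based zonation QC of an expression matrix
#'
#' Ranks genes by variance of `log2(CPM + 1)`, runs a centered PCA of the
#' samples on the `n_top` most variable genes and correlates each principal
#' component with the zone ordinal (CV = 1, IZ = 2, PV = 3). A large |r| on
#' a leading component indicates zonation as a major axis of variation.
#'
#' @param counts Gene-by-sample count matrix.
#' @param samples Sample sheet (used for the zone of each column).
#' @param n_top Number of most variable genes to use (default 1000).
#' @return List with `scores` (samples x PCs), `var_explained`, and
#'   `zone_cor` (Pearson r of each PC with the zone ordinal).
#' @export
pca_zonation_qc <- function(counts, samples, n_top = 1000L) {
  if (ncol(counts) < 3L) stop("need at least 3 samples for PCA")
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  lc <- log2(cpm(counts) + 1)
  v <- apply(lc, 1L, stats::var)
  if (all(v == 0)) stop("no variance: constant expression matrix")
  n_top <- min(n_top, sum(v > 0))
  top <- order(v, decreasing = TRUE)[seq_len(n_top)]
  pca_with_zone_cor(t(lc[top, , drop = FALSE]), zone_ordinal(samples$zone))
}

#' PCA-based zonation QC of the methylome
#'
#' Selects CpG sites with coverage strictly above `min_cov` in every sample,
#' ranks them by variance of the methylation ratio, and runs a centered PCA
#' of the samples on the `n_top` most variable sites, reporting the Pearson
#' correlation of each component with the zone ordinal.
#'
#' @param calls Named list of per-sample CpG call data frames
#'   (strand-merged, as read by [read_cpg_calls()]).
#' @param samples Sample sheet; names of `calls` must be sample ids.
#' @param n_top Number of most variable CpGs (default 5000). If fewer sites
#'   are eligible, all are used with a warning.
#' @param min_cov Coverage threshold (strict `>`, default 5) applied in all
#'   samples.
#' @return As [pca_zonation_qc()], plus `n_sites` used.
#' @export
top_variable_cpg_pca <- function(calls, samples, n_top = 5000L, min_cov = 5L) {
  if (length(calls) < 3L) stop("need at least 3 samples for PCA")
  samples <- samples[match(names(calls), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id)) stop("call list names missing from sample sheet")
  mats <- cpg_matrices(calls)
  eligible <- rowSums(mats$total > min_cov) == ncol(mats$total)
  if (!any(eligible)) stop("no CpG passes the coverage filter in all samples")
  ratio <- mats$meth[eligible, , drop = FALSE] / mats$total[eligible, , drop = FALSE]
  v <- apply(ratio, 1L, stats::var)
  if (all(v == 0)) stop("no variance: constant methylation ratios")
  if (sum(v > 0) < n_top) {
    warning("only ", sum(v > 0), " variable CpGs eligible; using all")
  }
  n_use <- min(n_top, sum(v > 0))
  top <- order(v, decreasing = TRUE)[seq_len(n_use)]
  out <- pca_with_zone_cor(t(ratio[top, , drop = FALSE]),
                           zone_ordinal(samples$zone))
  out$n_sites <- n_use
  out
}

# Site-by-sample meth/total matrices over the union of covered positions
# (absent site = 0 coverage).
cpg_matrices <- function(calls) {
  keys <- lapply(calls, function(df) paste(df$chrom, df$pos, sep = ":"))
  univ <- sort(unique(unlist(keys, use.names = FALSE)))
  meth <- total <- matrix(0L, nrow = length(univ), ncol = length(calls),
                          dimnames = list(univ, names(calls)))
  for (s in seq_along(calls)) {
    idx <- match(keys[[s]], univ)
    meth[idx, s] <- calls[[s]]$meth_count
    total[idx, s] <- calls[[s]]$total_count
  }
  list(meth = meth, total = total)
}

pca_with_zone_cor <- function(mat, zone_ord) {
  if (nrow(unique(mat)) < 2L) stop("degenerate PCA: duplicated samples only")
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  scores <- pc$x
  list(scores = scores,
       var_explained = pc$sdev^2 / sum(pc$sdev^2),
       zone_cor = cor_with_covariate(scores, zone_ord))
}
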