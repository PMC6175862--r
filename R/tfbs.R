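#' Mark tiles overlapping transcription-factor binding sites
#'
#' A tile is marked for a TF when at least one base of one of that TF's
#' sites overlaps the tile. Because the tile universe lies on a fixed grid
#' anchored at 0, the tiles touched by a site `[start, end)` are exactly
#' the grid indices `floor(start/size) .. floor((end-1)/size)`; sites
#' falling outside the tested tile universe are ignored.
#'
#' @param tiles Data frame with `tile_id`, `chrom`, `start`, `end` on the
#'   fixed grid (e.g. a [zonal_dm()] result).
#' @param tfbs BED data frame with `chrom`, `start`, `end`, `name`
#'   (TF symbol).
#' @param tile_size Grid width in bp (default 500).
#' @return Logical matrix, tiles x TFs.
#' @export
overlap_tiles_tfbs <- function(tiles, tfbs, tile_size = 500L) {
  if (!"name" %in% names(tfbs)) stop("TFBS BED needs a name column (TF symbol)")
  tfs <- sort(unique(tfbs$name))
  marks <- matrix(FALSE, nrow = nrow(tiles), ncol = length(tfs),
                  dimnames = list(tiles$tile_id, tfs))
  first_tile <- tfbs$start %/% as.integer(tile_size)
  last_tile <- (tfbs$end - 1L) %/% as.integer(tile_size)
  span <- last_tile - first_tile
  # expand multi-tile sites (rare: sites are short relative to the grid)
  site <- rep.int(seq_len(nrow(tfbs)), span + 1L)
  tidx <- unlist(lapply(seq_len(nrow(tfbs)),
                        function(i) first_tile[i]:last_tile[i]),
                 use.names = FALSE)
  row <- match(paste0(tfbs$chrom[site], ":", tidx), tiles$tile_id)
  ok <- !is.na(row)
  marks[cbind(row[ok], match(tfbs$name[site], tfs)[ok])] <- TRUE
  marks
}

#' Per-TF 2x2 contingency table of DMR status versus binding
#'
#' The tested tile universe is partitioned into the four categories
#' noDMR.noTFBS, noDMR.TFBS, DMR.noTFBS and DMR.TFBS.
#'
#' @param marked Logical vector: tile overlaps a site of the TF.
#' @param dmr Logical vector: tile is a flagged DMR.
#' @return Integer vector `(noDMR.noTFBS, noDMR.TFBS, DMR.noTFBS,
#'   DMR.TFBS)`.
#' @export
tf_contingency <- function(marked, dmr) {
  if (length(marked) == 0L) stop("empty tile universe")
  stopifnot(length(marked) == length(dmr))
  c(noDMR.noTFBS = sum(!dmr & !marked),
    noDMR.TFBS = sum(!dmr & marked),
    DMR.noTFBS = sum(dmr & !marked),
    DMR.TFBS = sum(dmr & marked))
}

#' Zonated binding-site methylation analysis
#'
#' For each transcription factor, tests whether DMRs are enriched among the
#' tiles carrying its binding sites (two-sided Fisher's exact test on the
#' 2x2 table, Bonferroni-corrected across TFs) and summarizes the
#' porto-central methylation gradient at its sites as
#' `delta_txf`: the mean methylation difference (PV − CV, percentage
#' points) over DMR tiles overlapping the TF's sites. Because the DMR set
#' as a whole carries a mild global demethylation gradient, `delta_txf` is
#' centred into `delta_txf_norm` by subtracting the across-TF mean
#' (`norm_mode = "tf_mean"`, default) or the mean `dmeth` of all DMR tiles
#' (`norm_mode = "dmr_mean"`).
#'
#' TFs with fewer than `min_dmr_tfbs_tiles` DMR tiles at their sites are
#' excluded before normalization and multiple-testing correction.
#'
#' @param dm `zonemap_dm` result (the tile universe; only tested tiles with
#'   a non-`NA` q-value enter the universe).
#' @param tfbs TFBS BED data frame (name = TF symbol).
#' @param alpha Family-wise error level for the Bonferroni threshold
#'   (default 0.05).
#' @param min_dmr_tfbs_tiles Minimum DMR-overlapping tiles per included TF
#'   (default 10).
#' @param tile_size Grid width (default 500).
#' @param norm_mode `"tf_mean"` or `"dmr_mean"`, see above.
#' @return Data frame of class `zonemap_tf` with one row per included TF:
#'   the four 2x2 counts, `fisher_p`, `odds_ratio`, `log10_enrichment`,
#'   `delta_txf`, `delta_txf_norm`, `significant`. Excluded TFs are listed
#'   in `attr(, "excluded")`; the Bonferroni threshold in
#'   `attr(, "threshold")`.
#' @export
tf_zonation <- function(dm, tfbs, alpha = 0.05, min_dmr_tfbs_tiles = 10L,
                        tile_size = 500L, norm_mode = c("tf_mean", "dmr_mean")) {
  norm_mode <- match.arg(norm_mode)
  universe <- dm[!is.na(dm$q), , drop = FALSE]
  if (nrow(universe) == 0L) stop("empty tile universe")
  marks <- overlap_tiles_tfbs(universe, tfbs, tile_size = tile_size)
  dmr <- universe$dmr_flag %in% TRUE
  global_dmr_frac <- mean(dmr)
  rows <- lapply(colnames(marks), function(tf) {
    m <- marks[, tf]
    n_dmr_tfbs <- sum(m & dmr)
    if (n_dmr_tfbs < min_dmr_tfbs_tiles) return(NULL)
    tab <- tf_contingency(m, dmr)
    fe <- fisher_exact_2x2(matrix(tab, nrow = 2L, byrow = TRUE))
    tfbs_dmr_frac <- n_dmr_tfbs / sum(m)
    data.frame(tf = tf,
               noDMR.noTFBS = tab[1L], noDMR.TFBS = tab[2L],
               DMR.noTFBS = tab[3L], DMR.TFBS = tab[4L],
               fisher_p = fe$p, odds_ratio = fe$odds_ratio,
               log10_enrichment = log10(tfbs_dmr_frac / global_dmr_frac),
               delta_txf = mean(universe$dmeth[m & dmr]),
               stringsAsFactors = FALSE)
  })
  excluded <- colnames(marks)[vapply(rows, is.null, logical(1L))]
  if (length(excluded) > 0L) {
    message("excluding ", length(excluded), " TF(s) below the ",
            min_dmr_tfbs_tiles, "-DMR-tile minimum: ",
            paste(excluded, collapse = ", "))
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no TF passes the inclusion filter")
  rownames(res) <- NULL
  baseline <- switch(norm_mode,
                     tf_mean = mean(res$delta_txf),
                     dmr_mean = mean(universe$dmeth[dmr]))
  res$delta_txf_norm <- normalize_delta_txf(res$delta_txf, baseline)
  threshold <- alpha / nrow(res)
  res$significant <- tf_significance(res$fisher_p, n_tests = nrow(res),
                                     alpha = alpha)
  class(res) <- c("zonemap_tf", class(res))
  attr(res, "excluded") <- excluded
  attr(res, "threshold") <- threshold
  attr(res, "norm_baseline") <- baseline
  res
}

#' Centre per-TF methylation gradients
#'
#' Subtracts a baseline (by default the across-TF mean of `delta_txf`) so
#' the normalized values are mean-zero over the included TFs.
#'
#' @param delta_txf Numeric vector of per-TF gradients.
#' @param baseline Value to subtract; defaults to `mean(delta_txf)`.
#' @return Centred vector. With a single TF the input is returned
#'   unchanged with a warning.
#' @export
normalize_delta_txf <- function(delta_txf, baseline = mean(delta_txf)) {
  if (length(delta_txf) < 2L) {
    warning("fewer than 2 TFs; skipping normalization")
    return(delta_txf)
  }
  delta_txf - baseline
}

#' Bonferroni significance flags for the per-TF Fisher tests
#'
#' @param fisher_p Vector of Fisher p-values.
#' @param n_tests Number of tests in the family.
#' @param alpha Family-wise error level (default 0.05).
#' @return Logical vector: `p < alpha / n_tests` (strict).
#' @export
tf_significance <- function(fisher_p, n_tests, alpha = 0.05) {
  fisher_p < alpha / n_tests
}
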