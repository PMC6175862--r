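#' Filter CpG sites by coverage
#'
#' Per sample, keeps only strand-merged CpG sites with total coverage of at
#' least `min_cov` reads.
#'
#' @param calls Named list of per-sample CpG call data frames.
#' @param min_cov Minimum coverage (default 10; `>=`).
#' @return The filtered list (possibly with empty data frames).
#' @export
filter_sites <- function(calls, min_cov = 10L) {
  lapply(calls, function(df) {
    out <- df[df$total_count >= min_cov, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Aggregate CpG calls into fixed 500 bp tiles
#'
#' Tiles lie on a fixed grid anchored at coordinate 0 of each chromosome
#' (`[0,500)`, `[500,1000)`, ...; 0-based half-open), so a 1-based CpG
#' position `pos` belongs to tile `floor((pos-1)/tile_size)`. Aggregation
#' treats a sample that misses a covered CpG as contributing zero coverage
#' at that site (missing-as-zero): the site still counts toward the tile's
#' union CpG set, and the sample's sums are simply the sums over the sites
#' it does cover. Tiles whose union CpG count falls below `min_cpgs` are
#' discarded, as are all tiles on mitochondrial and sex chromosomes.
#'
#' @param calls Named list of per-sample coverage-filtered CpG call data
#'   frames.
#' @param tile_size Tile width in bp (default 500; step size equals width).
#' @param min_cpgs Minimum CpG positions per retained tile (default 3),
#'   counted over the union of samples unless `per_sample = TRUE`, in which
#'   case every sample must itself cover at least `min_cpgs` sites.
#' @param per_sample Strict per-sample CpG counting mode (default `FALSE`).
#' @return Object of class `zonemap_tiles`: list with `tiles` (data frame:
#'   `tile_id`, `chrom`, `start`, `end`, `n_cpgs`), and tile-by-sample
#'   integer matrices `meth` and `total`.
#' @export
tile_methylome <- function(calls, tile_size = 500L, min_cpgs = 3L,
                           per_sample = FALSE) {
  if (length(calls) == 0L) stop("no samples")
  if (is.null(names(calls))) stop("calls must be a named list (sample ids)")
  all_df <- do.call(rbind, lapply(names(calls), function(s) {
    df <- calls[[s]]
    if (nrow(df) == 0L) return(NULL)
    data.frame(sample = s, chrom = df$chrom, pos = df$pos,
               meth = df$meth_count, total = df$total_count,
               stringsAsFactors = FALSE)
  }))
  if (is.null(all_df) || nrow(all_df) == 0L) stop("no CpG calls after filtering")
  all_df <- all_df[!(all_df$chrom %in% excluded_chroms()), , drop = FALSE]
  if (nrow(all_df) == 0L) stop("no autosomal CpG calls")

  tile_idx <- (all_df$pos - 1L) %/% as.integer(tile_size)
  tile_key <- paste0(all_df$chrom, ":", tile_idx)
  tile_ids <- sort(unique(tile_key))
  sample_ids <- names(calls)
  ti <- match(tile_key, tile_ids)
  si <- match(all_df$sample, sample_ids)

  meth <- total <- matrix(0L, nrow = length(tile_ids), ncol = length(sample_ids),
                          dimnames = list(tile_ids, sample_ids))
  flat <- (si - 1L) * length(tile_ids) + ti
  agg_m <- rowsum(all_df$meth, flat)
  agg_t <- rowsum(all_df$total, flat)
  idx <- as.integer(rownames(agg_m))
  meth[idx] <- as.integer(agg_m)
  total[idx] <- as.integer(agg_t)

  # union CpG count per tile across samples
  site_key <- paste0(tile_key, "\r", all_df$pos)
  first <- !duplicated(site_key)
  n_cpgs <- as.vector(table(factor(tile_key[first], levels = tile_ids)))

  chrom <- sub(":[0-9]+$", "", tile_ids)
  start <- as.integer(sub("^.*:", "", tile_ids)) * as.integer(tile_size)
  tiles <- data.frame(tile_id = tile_ids, chrom = chrom, start = start,
                      end = start + as.integer(tile_size), n_cpgs = n_cpgs,
                      stringsAsFactors = FALSE)

  if (per_sample) {
    per_key <- paste0(tile_key, "\r", all_df$sample)
    cnt <- table(per_key)
    # a tile passes only if every sample covers >= min_cpgs sites in it
    ok_tile <- vapply(tile_ids, function(tid) {
      v <- cnt[paste0(tid, "\r", sample_ids)]
      v[is.na(v)] <- 0L
      all(v >= min_cpgs)
    }, logical(1L))
    keep <- which(ok_tile)
  } else {
    keep <- which(n_cpgs >= min_cpgs)
  }
  out <- list(tiles = tiles[keep, , drop = FALSE],
              meth = meth[keep, , drop = FALSE],
              total = total[keep, , drop = FALSE],
              tile_size = as.integer(tile_size))
  rownames(out$tiles) <- NULL
  attr(out, "n_tiles_prefilter") <- length(tile_ids)
  class(out) <- "zonemap_tiles"
  out
}

#' @export
print.zonemap_tiles <- function(x, ...) {
  cat("zonemap_tiles:", nrow(x$tiles), "tiles x", ncol(x$meth),
      "samples (", x$tile_size, "bp grid )\n")
  invisible(x)
}

# Overdispersion-corrected logistic Wald test for one tile.
# X: design for the included samples; zone_col: index of the zone column.
tile_wald <- function(meth, total, X, zone_col) {
  y <- meth / total
  fit <- suppressWarnings(
    stats::glm.fit(X, y, weights = total, family = stats::binomial())
  )
  cf <- fit$coefficients
  if (anyNA(cf)) return(list(b = NA_real_, p = 1))
  mu <- fit$fitted.values
  df_res <- fit$df.residual
  if (df_res <= 0) return(list(b = cf[zone_col], p = 1))
  pearson <- sum(total * (y - mu)^2 / pmax(mu * (1 - mu), 1e-10))
  scale <- max(1, pearson / df_res)
  # unscaled covariance from the weighted QR of the final IRLS step
  R <- qr.R(fit$qr)
  pivot <- fit$qr$pivot
  cov_un <- tryCatch({
    ci <- chol2inv(R)
    ci[order(pivot), order(pivot), drop = FALSE]
  }, error = function(e) NULL)
  if (is.null(cov_un)) return(list(b = cf[zone_col], p = 1))
  se <- sqrt(max(cov_un[zone_col, zone_col], 0) * scale)
  b <- cf[zone_col]
  if (!is.finite(se) || se <= 0) return(list(b = b, p = 1))
  list(b = b, p = 2 * stats::pt(-abs(b / se), df = df_res))
}

#' Differential methylation test for a single tile
#'
#' Logistic regression of per-sample (methylated, total) counts on zone
#' with donor blocking; overdispersion relative to the binomial is absorbed
#' by inflating the Wald statistic's variance with the Pearson chi-square
#' scale `max(1, X^2/df)` (quasi-binomial style). The methylation
#' difference `dmeth` is the coverage-weighted mean methylation percentage
#' of `contrast[1]` minus that of `contrast[2]` (default PV − CV), in
#' percentage points.
#'
#' @param meth,total Named per-sample methylated and total counts for the
#'   tile.
#' @param samples Sample sheet.
#' @param contrast Two zones, numerator of the difference first.
#' @param donor_blocking Block on donor (default) instead of donor-level
#'   covariates.
#' @param min_donors Minimum donors per zone with nonzero coverage
#'   (default 3).
#' @return List with `dmeth` (percentage points) and `p`.
#' @export
test_dm <- function(meth, total, samples, contrast = c("PV", "CV"),
                    donor_blocking = TRUE, min_donors = 3L) {
  samples <- samples[match(names(total), samples$sample_id), , drop = FALSE]
  keep <- as.character(samples$zone) %in% contrast & total > 0
  sub <- samples[keep, , drop = FALSE]
  tabd <- table(sub$donor_id, as.character(sub$zone))
  complete <- rownames(tabd)[rowSums(tabd[, contrast, drop = FALSE] > 0) == 2L]
  per_zone <- colSums(tabd[, contrast, drop = FALSE] > 0)
  if (any(per_zone < min_donors) || length(complete) < min_donors) {
    return(list(dmeth = NA_real_, p = NA_real_))
  }
  sub <- sub[sub$donor_id %in% complete, , drop = FALSE]
  m <- meth[sub$sample_id]; t_ <- total[sub$sample_id]
  z <- as.character(sub$zone)
  m1 <- sum(m[z == contrast[1L]]); t1 <- sum(t_[z == contrast[1L]])
  m2 <- sum(m[z == contrast[2L]]); t2 <- sum(t_[z == contrast[2L]])
  dmeth <- 100 * (m1 / t1 - m2 / t2)
  r <- m / t_
  if (all(r == 0) || all(r == 1)) return(list(dmeth = 0, p = 1))
  X <- zonal_design(sub, contrast, donor_blocking)
  zone_col <- grep("^zone", colnames(X))
  w <- tile_wald(m, t_, X, zone_col)
  list(dmeth = dmeth, p = w$p)
}

#' Tile-wise zonal differential methylation
#'
#' Runs [test_dm()] over every tile of a [tile_methylome()] object, adds
#' coverage-weighted per-zone mean methylation, BH-adjusted q-values, DMR
#' flags (`q < fdr` and `|dmeth| >= min_diff`), and the porto-central
#' gradient class from [classify_dmr_gradient()].
#'
#' @param tiles `zonemap_tiles` object.
#' @param samples Sample sheet.
#' @param contrast Two zones, numerator first (default PV vs CV).
#' @param fdr DMR q-value threshold (default 0.01).
#' @param min_diff Minimum absolute methylation difference in percentage
#'   points (default 5).
#' @param gradient_tol Tolerance for the IZ gradient class, percentage
#'   points (default 5).
#' @param donor_blocking Block on donor (default).
#' @return A `data.frame` of class `zonemap_dm` with per-tile results;
#'   tiles failing the testability precondition carry `NA` statistics and
#'   `dmr_flag = FALSE`.
#' @export
zonal_dm <- function(tiles, samples, contrast = c("PV", "CV"), fdr = 0.01,
                     min_diff = 5, gradient_tol = 5, donor_blocking = TRUE) {
  stopifnot(inherits(tiles, "zonemap_tiles"))
  samples <- samples[match(colnames(tiles$total), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id)) stop("tile sample columns missing from sample sheet")
  n <- nrow(tiles$tiles)
  dmeth <- p <- rep(NA_real_, n)
  design_cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    res <- test_dm_cached(tiles$meth[i, ], tiles$total[i, ], samples,
                          contrast, donor_blocking, design_cache)
    dmeth[i] <- res$dmeth
    p[i] <- res$p
  }
  q <- rep(NA_real_, n)
  tested <- !is.na(p)
  q[tested] <- bh_adjust(p[tested])
  zone_means <- sapply(ZONE_LEVELS, function(z) {
    idx <- which(as.character(samples$zone) == z)
    if (length(idx) == 0L) return(rep(NA_real_, n))
    tt <- tiles$total[, idx, drop = FALSE]
    100 * rowSums(tiles$meth[, idx, drop = FALSE]) / ifelse(rowSums(tt) > 0, rowSums(tt), NA)
  })
  if (n == 1L) zone_means <- matrix(zone_means, nrow = 1L,
                                    dimnames = list(NULL, ZONE_LEVELS))
  dmr <- tested & q < fdr & abs(dmeth) >= min_diff
  grad <- vapply(seq_len(n), function(i) {
    classify_dmr_gradient(zone_means[i, "CV"], zone_means[i, "IZ"],
                          zone_means[i, "PV"], tol = gradient_tol)
  }, character(1L))
  out <- data.frame(tiles$tiles,
                    meth_CV = zone_means[, "CV"],
                    meth_IZ = zone_means[, "IZ"],
                    meth_PV = zone_means[, "PV"],
                    dmeth = dmeth, p = p, q = q,
                    dmr_flag = dmr, gradient_class = grad,
                    stringsAsFactors = FALSE)
  class(out) <- c("zonemap_dm", class(out))
  attr(out, "contrast") <- contrast
  out
}

# test_dm with memoized design matrices keyed by the included sample set
# (most tiles share the full set, so the design is built once).
test_dm_cached <- function(meth, total, samples, contrast, donor_blocking,
                           cache) {
  keep <- as.character(samples$zone) %in% contrast & total > 0
  key <- paste(which(keep), collapse = ",")
  entry <- cache[[key]]
  if (is.null(entry)) {
    sub <- samples[keep, , drop = FALSE]
    tabd <- table(sub$donor_id, as.character(sub$zone))
    complete <- rownames(tabd)[rowSums(tabd[, contrast, drop = FALSE] > 0) == 2L]
    per_zone <- colSums(tabd[, contrast, drop = FALSE] > 0)
    if (any(per_zone < 3L) || length(complete) < 3L) {
      entry <- list(ok = FALSE)
    } else {
      sub <- sub[sub$donor_id %in% complete, , drop = FALSE]
      X <- zonal_design(sub, contrast, donor_blocking)
      entry <- list(ok = TRUE, ids = sub$sample_id,
                    zone = as.character(sub$zone), X = X,
                    zone_col = grep("^zone", colnames(X)))
    }
    cache[[key]] <- entry
  }
  if (!entry$ok) return(list(dmeth = NA_real_, p = NA_real_))
  m <- meth[entry$ids]; t_ <- total[entry$ids]
  z <- entry$zone
  m1 <- sum(m[z == contrast[1L]]); t1 <- sum(t_[z == contrast[1L]])
  m2 <- sum(m[z == contrast[2L]]); t2 <- sum(t_[z == contrast[2L]])
  dmeth <- 100 * (m1 / t1 - m2 / t2)
  r <- m / t_
  if (all(r == 0) || all(r == 1)) return(list(dmeth = 0, p = 1))
  w <- tile_wald(m, t_, entry$X, entry$zone_col)
  list(dmeth = dmeth, p = w$p)
}

#' Classify the porto-central gradient shape of a tile
#'
#' A tile is `IZ_extreme` when the intermediate-zone mean lies outside the
#' range spanned by the pericentral and periportal means, widened by `tol`
#' percentage points on both sides; otherwise `monotone`. Tiles without
#' intermediate-zone coverage are `undetermined`.
#'
#' @param cv,iz,pv Coverage-weighted mean methylation per zone, percent.
#' @param tol Tolerance in percentage points (default 5).
#' @return `"monotone"`, `"IZ_extreme"`, or `"undetermined"`.
#' @export
classify_dmr_gradient <- function(cv, iz, pv, tol = 5) {
  if (is.na(iz) || is.na(cv) || is.na(pv)) return("undetermined")
  lo <- min(cv, pv) - tol
  hi <- max(cv, pv) + tol
  if (iz < lo || iz > hi) "IZ_extreme" else "monotone"
}

#' Export DMRs as BED intervals
#'
#' Writes flagged DMRs as a BED file with the absolute methylation
#' difference as score.
#'
#' @param dm `zonemap_dm` result.
#' @param path Output path.
#' @export
write_dmr_bed <- function(dm, path) {
  d <- dm[dm$dmr_flag %in% TRUE, , drop = FALSE]
  write_bed(data.frame(d$chrom, d$start, d$end, d$tile_id,
                       round(abs(d$dmeth), 2)), path)
}
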