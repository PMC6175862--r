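grid_tiles <- function(n = 10L, chrom = "chr1", size = 500L) {
  data.frame(tile_id = paste0(chrom, ":", 0:(n - 1)), chrom = chrom,
             start = (0:(n - 1)) * size, end = (1:n) * size,
             stringsAsFactors = FALSE)
}

test_that("site-tile overlap respects half-open boundaries", {
  tiles <- grid_tiles(4L)
  bed <- data.frame(chrom = "chr1",
                    start = c(100L, 500L, 499L, 998L),
                    end = c(120L, 520L, 501L, 1004L),
                    name = c("A", "A", "B", "B"),
                    stringsAsFactors = FALSE)
  marks <- overlap_tiles_tfbs(tiles, bed)
  # [100,120) marks tile [0,500); [500,520) does not (half-open)
  expect_true(marks["chr1:0", "A"])
  expect_identical(unname(marks[, "A"]), c(TRUE, TRUE, FALSE, FALSE))
  # [499,501) spans the boundary: marks both tiles
  expect_identical(unname(marks[, "B"]), c(TRUE, TRUE, TRUE, FALSE))
})

test_that("overlap marks equal a brute-force all-pairs computation", {
  sim <- small_sim()
  dm <- sim$truth$tiles[!(sim$truth$tiles$chrom %in% c("chrX", "chrM")), ]
  marks <- overlap_tiles_tfbs(dm, sim$tfbs)
  set.seed(8)
  check <- sample.int(nrow(dm), 40)
  for (i in check) {
    for (tf in colnames(marks)) {
      sites <- sim$tfbs[sim$tfbs$name == tf, ]
      hit <- any(sites$chrom == dm$chrom[i] &
                   sites$start < dm$end[i] & dm$start[i] < sites$end)
      expect_identical(unname(marks[i, tf]), hit)
    }
  }
})

test_that("contingency tables partition the tile universe", {
  set.seed(9)
  marked <- runif(500) < 0.3
  dmr <- runif(500) < 0.1
  tab <- tf_contingency(marked, dmr)
  expect_equal(sum(tab), 500L)
  # brute-force cross-tabulation
  expect_equal(unname(tab["DMR.TFBS"]), sum(dmr & marked))
  expect_equal(unname(tab["noDMR.noTFBS"]), sum(!dmr & !marked))
  expect_error(tf_contingency(logical(0), logical(0)), "empty tile universe")
})

test_that("Fisher test matches enumeration and handles degenerate margins", {
  expect_equal(fisher_exact_2x2(matrix(c(10, 10, 10, 10), 2)),
               list(p = 1, odds_ratio = 1))
  r <- fisher_exact_2x2(matrix(c(12, 3, 5, 10), 2, byrow = TRUE))
  expect_equal(r$p, oracle_fisher_p(12, 3, 5, 10), tolerance = 1e-12)
  expect_equal(r$p, stats::fisher.test(matrix(c(12, 3, 5, 10), 2,
                                              byrow = TRUE))$p.value,
               tolerance = 1e-9)
  # one margin zero
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 5, 10), 2))$p, 1)
  expect_equal(fisher_exact_2x2(matrix(c(0, 5, 0, 10), 2))$p, 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "negative")

  # random tables against stats::fisher.test
  set.seed(10)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 8), 2)
    expect_equal(fisher_exact_2x2(tab)$p, stats::fisher.test(tab)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("delta_txf is the mean gradient over bound DMR tiles", {
  tiles <- grid_tiles(40L)
  dm <- data.frame(tiles, dmeth = rep(c(7, -7, 20, 3), 10),
                   q = rep(c(1e-5, 1e-5, 0.5, 1e-5), 10),
                   dmr_flag = rep(c(TRUE, TRUE, FALSE, TRUE), 10),
                   stringsAsFactors = FALSE)
  # one TF bound on every tile: delta_txf = brute-force mean over DMR tiles
  bed <- data.frame(chrom = "chr1", start = tiles$start + 10L,
                    end = tiles$start + 30L, name = "TFX",
                    stringsAsFactors = FALSE)
  res <- suppressWarnings(tf_zonation(dm, bed, min_dmr_tfbs_tiles = 5L))
  expect_equal(res$delta_txf, mean(dm$dmeth[dm$dmr_flag]))

  # all bound DMR tiles at +7: delta_txf = +7 (pericentral hypomethylation)
  dm7 <- dm; dm7$dmeth[dm7$dmr_flag] <- 7
  res7 <- suppressWarnings(tf_zonation(dm7, bed, min_dmr_tfbs_tiles = 5L))
  expect_equal(res7$delta_txf, 7)

  # symmetric +/- values cancel
  dms <- dm
  dms$dmeth[dms$dmr_flag] <- rep(c(5, -5), 15)
  ress <- suppressWarnings(tf_zonation(dms, bed, min_dmr_tfbs_tiles = 5L))
  expect_equal(ress$delta_txf, 0)

  # below the DMR-tile minimum the TF is excluded
  expect_error(suppressMessages(tf_zonation(dm, bed, min_dmr_tfbs_tiles = 50L)),
               "no TF passes")
})

test_that("normalization centres the per-TF gradients", {
  expect_equal(normalize_delta_txf(c(-2, -1, 0)), c(-1, 0, 1))
  expect_equal(normalize_delta_txf(c(3, 3, 3)), c(0, 0, 0))
  expect_warning(out <- normalize_delta_txf(5), "fewer than 2")
  expect_equal(out, 5)
})

test_that("Bonferroni flags use a strict threshold", {
  expect_equal(0.05 / 59, 8.474576e-4, tolerance = 1e-6)
  expect_true(tf_significance(1e-5, n_tests = 59))
  expect_false(tf_significance(0.05 / 59, n_tests = 59))  # exactly at threshold
})

test_that("relabeling zones negates delta_txf and preserves Fisher p", {
  sim <- small_sim()
  dm <- zonal_dm(tile_methylome(filter_sites(sim$calls)), sim$samples)
  res <- suppressMessages(tf_zonation(dm, sim$tfbs, min_dmr_tfbs_tiles = 3L))
  dm_flip <- dm
  dm_flip$dmeth <- -dm$dmeth
  res_f <- suppressMessages(tf_zonation(dm_flip, sim$tfbs,
                                        min_dmr_tfbs_tiles = 3L))
  expect_identical(res$fisher_p, res_f$fisher_p)
  expect_identical(res$delta_txf, -res_f$delta_txf)
  expect_identical(res$delta_txf_norm, -res_f$delta_txf_norm)
  # enrichment is 0 exactly when the DMR fraction matches the global one
  bal <- res$log10_enrichment[abs(res$DMR.TFBS / (res$DMR.TFBS + res$noDMR.TFBS) -
                                    mean(dm$dmr_flag, na.rm = TRUE)) < 1e-12]
  expect_true(all(bal == 0))
})
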