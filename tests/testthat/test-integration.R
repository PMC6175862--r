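make_models <- function() {
  df <- data.frame(
    gene_id = c("GA", "GB"), chrom = "chr1", strand = c("+", "-"),
    tss = c(10001L, 32300L),
    exon_starts = c("10000,11000,12000", "30000,31000,32000"),
    exon_ends = c("10300,11300,12300", "30300,31300,32300"),
    stringsAsFactors = FALSE)
  df$exon_start_list <- lapply(strsplit(df$exon_starts, ","), as.integer)
  df$exon_end_list <- lapply(strsplit(df$exon_ends, ","), as.integer)
  df
}

test_that("tiles annotate to the nearest TSS with fixed feature precedence", {
  models <- make_models()
  tiles <- data.frame(
    tile_id = c("t_prom", "t_intron", "t_exon", "t_inter", "t_chr9"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr9"),
    start = c(9500L, 10600L, 11000L, 20000L, 100L),
    end = c(10000L, 11000L, 11500L, 20500L, 600L),
    stringsAsFactors = FALSE)
  ann <- annotate_dmrs(tiles, models)
  expect_equal(ann$feature,
               c("promoter", "intron", "exon", "intergenic", "intergenic"))
  expect_equal(ann$nearest_gene, c("GA", "GA", "GA", "GA", NA))
  # TSS inside the tile gives distance 0; otherwise interval distance
  tss_tile <- data.frame(tile_id = "t0", chrom = "chr1",
                         start = 10000L, end = 10500L)
  expect_equal(annotate_dmrs(tss_tile, models)$distance, 0)
  # tile covers 9500..9999, TSS at 0-based 10000: one base away
  expect_equal(ann$distance[ann$tile_id == "t_prom"], 1)

  # pure function: repeated calls identical
  expect_identical(ann, annotate_dmrs(tiles, models))
})

test_that("nearest-gene assignment matches a brute-force all-pairs scan", {
  sim <- small_sim()
  models <- sim$gene_models
  tiles <- sim$truth$tiles[sim$truth$tiles$chrom %in% models$chrom, ][1:120, ]
  ann <- annotate_dmrs(tiles, models)
  for (i in seq_len(nrow(tiles))) {
    mid <- (tiles$start[i] + tiles$end[i]) / 2
    on_chrom <- models[models$chrom == tiles$chrom[i], ]
    d <- abs(mid - (on_chrom$tss - 0.5))
    best <- on_chrom$gene_id[d == min(d)]
    expect_equal(ann$nearest_gene[i], sort(best)[1])
  }
})

test_that("DEG-DMR linking equals a brute-force join", {
  sim <- small_sim()
  de <- fit_zonal_de(filter_expressed(sim$counts), sim$samples)
  dm <- zonal_dm(tile_methylome(filter_sites(sim$calls)), sim$samples)
  ann <- annotate_dmrs(dm, sim$gene_models)
  pairs <- link_deg_dmr(de, dm, ann)

  degs <- de$gene_id[de$zonation_call != "none"]
  dmr_rows <- which(dm$dmr_flag %in% TRUE)
  n_oracle <- 0L
  for (i in dmr_rows) {
    g <- ann$nearest_gene[ann$tile_id == dm$tile_id[i]]
    if (!is.na(g) && g %in% degs) n_oracle <- n_oracle + 1L
  }
  expect_equal(nrow(pairs), n_oracle)
  # referential integrity
  expect_true(all(pairs$gene_id %in% degs))
  expect_true(all(pairs$tile_id %in% dm$tile_id[dmr_rows]))

  # a DEG with no nearby DMR has no associations
  lonely <- setdiff(degs, pairs$gene_id)
  if (length(lonely) > 0) {
    expect_equal(sum(pairs$gene_id %in% lonely), 0L)
  }
})

test_that("anti-correlation behaves on exact and permuted pairings", {
  pairs <- data.frame(gene_id = paste0("g", 1:20), tile_id = paste0("t", 1:20),
                      log2fc = seq(-2, 2, length.out = 20),
                      zonation_call = "PV_high",
                      dmeth = -3 * seq(-2, 2, length.out = 20),
                      stringsAsFactors = FALSE)
  expect_equal(anticorrelation(pairs)$r, -1)

  set.seed(6)
  null_r <- replicate(200, {
    perm <- pairs
    perm$dmeth <- sample(perm$dmeth)
    anticorrelation(perm)$r
  })
  expect_lt(stats::quantile(abs(null_r), 0.95), 0.6)

  flat <- pairs; flat$dmeth <- 1
  expect_error(anticorrelation(flat), "zero variance")
  expect_error(anticorrelation(pairs[1:2, ]), "at least 3")
})

test_that("driver classification follows the fixed sign conventions", {
  pairs <- data.frame(
    gene_id = c("g1", "g2", "g3", "g3"),
    tile_id = c("t1", "t2", "t3", "t4"),
    log2fc = c(-3, -2, 2, 2),
    zonation_call = c("CV_high", "CV_high", "PV_high", "PV_high"),
    dmeth = c(20, -15, -8, 12),
    stringsAsFactors = FALSE)
  drv <- classify_drivers(pairs)
  # g1: CV-up with CV-hypomethylated DMR (dmeth > 0) -> CV driver
  # g2: CV-up but only a CV-hypermethylated DMR -> not a driver
  # g3: PV-up with one concordant and one discordant DMR -> mixed driver
  expect_equal(drv$gene_id, c("g1", "g3"))
  expect_equal(drv$zone, c("CV", "PV"))
  expect_equal(drv$mixed, c(FALSE, TRUE))
  expect_equal(drv$n_dmrs, c(1L, 1L))

  # invariance under CV<->PV relabeling with negated signs
  flipped <- pairs
  flipped$log2fc <- -pairs$log2fc
  flipped$dmeth <- -pairs$dmeth
  swap <- c(CV_high = "PV_high", PV_high = "CV_high")
  flipped$zonation_call <- unname(swap[pairs$zonation_call])
  drv_f <- classify_drivers(flipped)
  expect_equal(drv_f$gene_id, drv$gene_id)
  expect_equal(drv_f$zone, unname(c(CV = "PV", PV = "CV")[drv$zone]))
  expect_equal(drv_f$mixed, drv$mixed)

  expect_equal(nrow(classify_drivers(pairs[0, ])), 0L)
})

test_that("feature distribution is a normalized tally", {
  ann <- data.frame(tile_id = paste0("t", 1:8),
                    nearest_gene = "g", distance = 0,
                    feature = c(rep("promoter", 2), rep("exon", 1),
                                rep("intron", 4), "intergenic"),
                    stringsAsFactors = FALSE)
  fr <- feature_distribution(ann)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_equal(unname(fr), c(2, 1, 4, 1) / 8)

  all_prom <- ann; all_prom$feature <- "promoter"
  expect_equal(unname(feature_distribution(all_prom)), c(1, 0, 0, 0))
  expect_error(feature_distribution(ann, subset = logical(8)), "empty subset")
})
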