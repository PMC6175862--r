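test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_dataset(small_sim_config(seed = 11))
  b <- simulate_dataset(small_sim_config(seed = 11))
  expect_identical(a$counts, b$counts)
  expect_identical(a$calls, b$calls)
  expect_identical(a$tfbs, b$tfbs)
  expect_identical(a$truth, b$truth)
  expect_identical(a$chrom_counts, b$chrom_counts)
  c_ <- simulate_dataset(small_sim_config(seed = 12))
  expect_false(identical(a$counts, c_$counts))
})

test_that("planted class bookkeeping matches the configured fractions", {
  cfg <- sim_config(seed = 3, genes = list(n_genes = 2000L, frac_cv_high = 0.1))
  # only the gene layer is needed; keep the methylome small
  cfg$methylome$n_tiles <- 300L
  cfg$methylome$n_dmrs <- 30L
  sim <- simulate_dataset(cfg)
  expect_equal(sum(sim$truth$genes$class == "CV_high"), 200L)
  expect_equal(sum(sim$truth$genes$class == "PV_high"), 100L)
  expect_equal(sum(sim$truth$tiles$dmr_flag), 30L)
  expect_equal(nrow(sim$samples), 19L * 3L)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(methylome = list(n_tiles = 100L, n_dmrs = 200L)),
               "more planted DMRs than tiles")
  expect_error(sim_config(genes = list(frac_cv_high = 1.5)), "fractions")
  expect_error(sim_config(n_donors = 10L), "phenotype counts")
})

test_that("per-tile methylation simulator hits its zonal means", {
  set.seed(42)
  zones <- stats::setNames(rep(c("CV", "IZ", "PV"), each = 2),
                           paste0("s", 1:6))
  out <- simulate_methylation_for_tile(
    c(CV = 0.2, IZ = 0.35, PV = 0.5), cpg_positions = seq_len(1000),
    zones = zones, coverage_mean = 60, coverage_size = 10, precision = 50)
  ratio <- colSums(out$meth) / colSums(out$total)
  expect_true(all(abs(ratio[1:2] - 0.2) < 0.03))
  expect_true(all(abs(ratio[3:4] - 0.35) < 0.03))
  expect_true(all(abs(ratio[5:6] - 0.5) < 0.03))

  # high-precision, high-coverage limit: per-CpG ratios approach the means
  lim <- simulate_methylation_for_tile(
    c(CV = 0.3, IZ = 0.3, PV = 0.3), cpg_positions = 1:200,
    zones = zones, coverage_mean = 5000, coverage_size = 1e6,
    precision = 1e7)
  expect_true(max(abs(lim$meth / lim$total - 0.3)) < 0.05)

  expect_error(simulate_methylation_for_tile(c(CV = .1, IZ = .1, PV = .1),
                                             integer(0), zones),
               "empty cpg_positions")
})

test_that("TFBS planting realizes the configured placement odds", {
  cfg <- sim_config(seed = 5,
                    methylome = list(n_tiles = 2000L, n_dmrs = 400L),
                    tfbs = list(n_tfs = 2L, sites_per_tf = 4000L,
                                frac_zonated = 0.5, placement_odds = 5))
  u <- simulate_tf_universe(cfg)
  auto <- u$tile_truth[!(u$tile_truth$chrom %in% c("chrX", "chrY", "chrM")), ]
  # per-site placement odds ratio from site counts (not distinct tiles)
  zon_tf <- u$tf_truth$tf[u$tf_truth$zonated][1]
  dirn <- u$tf_truth$direction[u$tf_truth$zonated][1]
  target_ids <- auto$tile_id[auto$dmr_flag &
                               (if (dirn == "CV") auto$true_dmeth > 0
                                else auto$true_dmeth < 0)]
  site_tile <- paste0(u$bed$chrom, ":", u$bed$start %/% 500L)
  n_target <- length(target_ids)
  n_other <- nrow(auto) - n_target
  in_target <- site_tile %in% target_ids
  by_tf <- split(in_target, u$bed$name)
  odds <- function(x) (mean(x) / (1 - mean(x))) / (n_target / n_other)
  expect_equal(odds(by_tf[[zon_tf]]), 5, tolerance = 0.15)

  # non-zonated TF: placement odds for DMR tiles are 1
  null_tf <- u$tf_truth$tf[!u$tf_truth$zonated][1]
  dmr_ids <- auto$tile_id[auto$dmr_flag]
  in_dmr <- site_tile[u$bed$name == null_tf] %in% dmr_ids
  odds_null <- (mean(in_dmr) / (1 - mean(in_dmr))) /
    (length(dmr_ids) / (nrow(auto) - length(dmr_ids)))
  expect_equal(odds_null, 1, tolerance = 0.25)

  # zero sites: empty track
  cfg0 <- sim_config(seed = 5, methylome = list(n_tiles = 300L, n_dmrs = 30L),
                     tfbs = list(n_tfs = 2L, sites_per_tf = 0L))
  u0 <- simulate_tf_universe(cfg0)
  expect_equal(nrow(u0$bed), 0L)
})

test_that("library sizes and coverage match configured means within 5%", {
  sim <- small_sim()
  cfg <- sim$config
  lib <- colSums(sim$counts)
  expect_lt(abs(mean(lib) - mean(cfg$genes$lib_size_range)) /
              mean(cfg$genes$lib_size_range), 0.05)
  cov <- unlist(lapply(sim$calls, function(df) df$total_count))
  # coverage is reported conditional on being > 0 (zero-covered sites are
  # absent from the call tables)
  mu <- cfg$methylome$coverage_mean
  p0 <- stats::dnbinom(0, mu = mu, size = cfg$methylome$coverage_size)
  expect_lt(abs(mean(cov) - mu / (1 - p0)) / mu, 0.05)
})

test_that("truth labels are self-consistent for downstream scoring", {
  sim <- small_sim()
  cp <- sim$truth$couplings
  gt <- sim$truth$genes[match(cp$gene_id, sim$truth$genes$gene_id), ]
  # coupled DMRs are hypomethylated in the zone where the gene is up:
  # CV_high gene (log2fc < 0) <-> positive dmeth (PV - CV), and vice versa
  expect_true(all(cp$true_dmeth > 0 | gt$class != "CV_high"))
  expect_true(all(cp$true_dmeth < 0 | gt$class != "PV_high"))
  # every planted DMR lies within simulated CpG territory
  expect_true(all(cp$tile_id %in% sim$truth$tiles$tile_id))
  # sample sheet composition
  expect_equal(unname(table(sim$samples$phenotype)[PHENOTYPE_LEVELS]),
               unname(sim$config$phenotype$counts) * 3L,
               ignore_attr = TRUE)
})

test_that("simulated mitochondrial fractions track the zone truth", {
  sim <- small_sim()
  mr <- mito_ratio(sim$chrom_counts)
  samples <- sim$samples[match(mr$sample_id, sim$samples$sample_id), ]
  fr <- sim$config$mito$fractions
  for (z in ZONE_LEVELS) {
    obs <- mr$ratio[as.character(samples$zone) == z]
    sd3 <- 3 * sqrt(fr[[z]] * (1 - fr[[z]]) / sim$config$mito$total_reads)
    expect_true(all(abs(obs - fr[[z]]) < sd3 + 1e-6))
  }
})
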