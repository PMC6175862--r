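test_that("expression filter implements the CPM rule", {
  # gene with CPM just above 0.5 in exactly 5 samples is retained
  n_s <- 8L
  lib <- rep(1e6, n_s)
  counts <- matrix(50L, nrow = 3, ncol = n_s,
                   dimnames = list(c("keep", "edge", "zero"), paste0("s", 1:n_s)))
  counts["edge", ] <- c(rep(1L, 5), rep(0L, 3))   # CPM 1 in 5 samples
  counts["zero", ] <- 0L
  # pad library sizes so CPM of 'edge' is 0.6 in its 5 covered samples
  pad <- matrix(as.integer(lib / 3), nrow = 1,
                dimnames = list("pad", colnames(counts)))
  counts["edge", 1:5] <- 200L
  m <- rbind(counts, pad)
  cpm_edge <- cpm(m)["edge", ]
  expect_true(sum(cpm_edge > 0.5) == 5L)
  kept <- filter_expressed(m, min_cpm = 0.5, min_samples = 5L)
  expect_true("edge" %in% rownames(kept))
  expect_false("zero" %in% rownames(kept))

  # brute-force double loop oracle on a random matrix
  set.seed(1)
  rm_ <- matrix(rpois(600, 3), nrow = 60,
                dimnames = list(sprintf("g%02d", 1:60), paste0("s", 1:10)))
  rm_ <- rm_ + 1L  # avoid all-zero library edge
  keep_oracle <- logical(60)
  cpm_all <- cpm(rm_)
  for (g in 1:60) {
    n_above <- 0L
    for (s in 1:10) if (cpm_all[g, s] > 0.5) n_above <- n_above + 1L
    keep_oracle[g] <- n_above >= 5L
  }
  kept2 <- filter_expressed(rm_, 0.5, 5L)
  expect_identical(rownames(kept2), rownames(rm_)[keep_oracle])

  # requiring more qualifying samples than exist removes every gene
  expect_error(filter_expressed(rm_, 0.5, 11L), "all genes filtered")
})

test_that("normalization factors are composition-corrected with geometric mean 1", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(normalization_factors(m)), c(1, 1))

  m2 <- cbind(a = c(10, 20, 30), b = 2 * c(10, 20, 30))
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(unname(normalization_factors(m2)), c(1, 1))

  set.seed(2)
  sim_eq <- matrix(rnbinom(2000 * 8, mu = rep(rexp(2000, 1 / 200), 8),
                           size = 10), ncol = 8)
  rownames(sim_eq) <- paste0("g", 1:2000)
  colnames(sim_eq) <- paste0("s", 1:8)
  f <- normalization_factors(sim_eq + 1L)
  expect_true(all(abs(f - 1) < 0.05))
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)

  bad <- m; bad[, 1] <- 0
  expect_error(normalization_factors(bad), "zero total count")
})

test_that("zonal DE handles null genes and enforces the paired design", {
  samples <- make_samples(5L)
  sub <- samples[samples$zone != "IZ", ]
  n_g <- 30L
  set.seed(3)
  counts <- matrix(rnbinom(n_g * nrow(sub), mu = 100, size = 20),
                   nrow = n_g,
                   dimnames = list(sprintf("g%02d", 1:n_g), sub$sample_id))
  counts[1, ] <- 100L   # identical counts, equal library size handling below
  # equalize library sizes so the null gene is exactly flat
  counts <- counts[, order(colnames(counts))]
  de <- fit_zonal_de(counts, samples, norm_factors = stats::setNames(
    rep(1, ncol(counts)), colnames(counts)))
  expect_s3_class(de, "zonemap_de")
  # q >= p within the result set (BH construction)
  expect_true(all(de$q >= de$p - 1e-12))
  # calls respect both thresholds
  called <- de$zonation_call != "none"
  expect_true(all(de$q[called] < 0.01 & abs(de$log2fc[called]) > 1))

  # a gene with identical counts everywhere, with equal offsets
  eq <- matrix(50L, nrow = 4, ncol = nrow(sub),
               dimnames = list(paste0("g", 1:4), sub$sample_id))
  de_eq <- fit_zonal_de(eq, samples, norm_factors = stats::setNames(
    rep(1, ncol(eq)), colnames(eq)))
  expect_equal(de_eq$log2fc, rep(0, 4), tolerance = 1e-8)
  expect_equal(de_eq$p, rep(1, 4), tolerance = 1e-6)
  expect_true(all(de_eq$zonation_call == "none"))

  # fewer than 3 complete donor pairs
  expect_error(fit_zonal_de(counts[, 1:4], samples), "fewer than 3 complete")
})

test_that("relabeling the contrast negates every log2 fold change exactly", {
  sim <- small_sim()
  kept <- filter_expressed(sim$counts)[1:80, ]
  de_pv <- fit_zonal_de(kept, sim$samples, contrast = c("PV", "CV"))
  de_cv <- fit_zonal_de(kept, sim$samples, contrast = c("CV", "PV"))
  expect_identical(de_pv$log2fc, -de_cv$log2fc)
  expect_identical(de_pv$p, de_cv$p)
  # calls name the favoured zone, so they are orientation-independent
  expect_identical(de_pv$zonation_call, de_cv$zonation_call)
})

test_that("DE estimates agree with an independent NB GLM implementation", {
  sim <- small_sim()
  kept <- filter_expressed(sim$counts)
  set.seed(9)
  idx <- sort(sample.int(nrow(kept), 60))
  de <- fit_zonal_de(kept[idx, ], sim$samples)

  sub <- sim$samples[sim$samples$zone != "IZ", ]
  y <- kept[idx, sub$sample_id]
  zone <- factor(as.character(sub$zone), levels = c("CV", "PV"))
  design <- stats::model.matrix(~ factor(sub$donor_id) + zone)
  dge <- edgeR::DGEList(y)
  dge <- edgeR::calcNormFactors(dge)
  dge <- edgeR::estimateDisp(dge, design)
  fit <- edgeR::glmFit(dge, design)
  lrt <- edgeR::glmLRT(fit)
  expect_gt(cor(de$log2fc, lrt$table$logFC), 0.98)
  expect_lt(mean(abs(de$log2fc - lrt$table$logFC)), 0.2)
})

test_that("profile classification separates gradients, peaks and flats", {
  expect_equal(classify_profile(c(CV = 1.0, IZ = 0.6, PV = 0.2)), "CV_high")
  expect_equal(classify_profile(c(CV = 0.3, IZ = 1.0, PV = 0.3)), "IZ_peak")
  expect_equal(classify_profile(c(CV = 1.0, IZ = 0.2, PV = 0.9)), "IZ_trough")
  expect_equal(classify_profile(c(CV = 1.0, IZ = 0.97, PV = 0.95)), "flat")
  expect_equal(classify_profile(c(CV = 0.2, IZ = 0.6, PV = 1.0)), "PV_high")
  expect_error(classify_profile(c(1, NA, 0.5)), "three zone means")

  # generator default: no IZ peaks among truth-zonated genes
  sim <- small_sim()
  prof <- zonation_profiles(sim$counts, sim$samples)
  zon <- sim$truth$genes$class %in% c("CV_high", "PV_high")
  expect_equal(sum(prof$profile_class[zon] == "IZ_peak"), 0L)
})

test_that("expression PCA recovers zonation as a leading component", {
  sim <- small_sim()
  qc <- pca_zonation_qc(sim$counts, sim$samples, n_top = 200L)
  expect_gte(max(abs(qc$zone_cor[1:2])), 0.8)

  # permuted zone labels kill the correlation
  set.seed(4)
  perm <- sim$samples
  null_cor <- replicate(20, {
    perm$zone <- sample(perm$zone)
    max(abs(pca_zonation_qc(sim$counts, perm, n_top = 200L)$zone_cor[1:2]))
  })
  expect_lt(stats::quantile(null_cor, 0.95), max(abs(qc$zone_cor[1:2])))

  const <- matrix(5L, nrow = 10, ncol = ncol(sim$counts),
                  dimnames = list(paste0("g", 1:10), colnames(sim$counts)))
  expect_error(pca_zonation_qc(const, sim$samples), "no variance")
})
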