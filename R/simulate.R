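#' Configuration for the synthetic lobule generator
#'
#' Builds the nested parameter list consumed by [simulate_dataset()]. The
#' defaults describe the study design the pipeline targets: 19 donors each
#' contributing one sample per zone (CV, IZ, PV), a transcriptome in which
#' 10\% of genes are zonated with |log2FC| = 2 between the periportal and
#' pericentral zones and the intermediate zone at the geometric midpoint
#' (profiles are monotone along the porto-central axis), a tiled RRBS-like
#' methylome with planted differentially methylated tiles anti-correlated
#' with the zonated genes, TF binding-site tracks in which a subset of TFs
#' concentrates its sites in pericentrally hypomethylated tiles, and a
#' porto-central gradient of the mitochondrial read fraction.
#'
#' @param n_donors Number of donors (default 19).
#' @param seed Integer seed; fully determines the generated dataset.
#' @param genes,methylome,tfbs,mito,phenotype Named lists overriding
#'   individual defaults within each group (partial lists allowed).
#' @return Nested configuration list of class `sim_config`.
#' @export
sim_config <- function(n_donors = 19L, seed = 1L, genes = list(),
                       methylome = list(), tfbs = list(), mito = list(),
                       phenotype = list()) {
  cfg <- list(
    n_donors = as.integer(n_donors),
    seed = as.integer(seed),
    genes = list(
      n_genes = 2000L,
      frac_cv_high = 0.05,
      frac_pv_high = 0.05,
      n_iz_peak = 0L,           # negative-control planting of IZ-peaked genes
      lfc = 2,                  # |log2FC| PV vs CV for zonated genes
      dispersion = 0.05,        # NB dispersion (var = mu + phi mu^2)
      donor_sd = 0.15,          # log-normal donor random effect SD
      lib_size_range = c(8e5, 1.2e6),
      abundance_sdlog = 1.5     # spread of baseline relative abundances
    ),
    methylome = list(
      n_chroms = 4L,
      gene_spacing = 6000L,     # bp between gene starts on a chromosome
      gene_offset = 5000L,
      n_tiles = 2000L,          # autosomal tiles carrying CpGs
      n_sex_tiles = 20L,        # chrX tiles, exercised by the exclusion rule
      tile_size = 500L,
      cpg_per_tile_mean = 8,
      coverage_mean = 30,
      coverage_size = 5,        # NB size of per-CpG coverage
      bb_precision = 30,        # beta-binomial precision (alpha + beta)
      n_dmrs = 200L,
      dmeth = 20,               # planted |methylation difference|, points
      frac_cv_hypo = 0.5,       # fraction of DMRs hypomethylated in CV
      coupled_frac = 0.5,       # fraction of DMRs coupled to zonated genes
      max_dmrs_per_gene = 3L,
      placement = c(promoter = 0.4, intron = 0.4, exon = 0.2)
    ),
    tfbs = list(
      n_tfs = 20L,
      sites_per_tf = 1000L,
      frac_zonated = 0.15,
      placement_odds = 5,       # odds of a zonated TF site landing in a
                                # CV-hypomethylated DMR tile
      dmeth_boost = 10,         # extra points of zonal difference at bound tiles
      site_width = 15L
    ),
    mito = list(
      fractions = c(CV = 0.005, IZ = 0.008, PV = 0.010),
      total_reads = 1e6
    ),
    phenotype = list(
      counts = c(NC = 4L, HO = 5L, STEA = 5L, EARLY = 5L),
      male_prob = c(NC = 0.25, HO = 0.20, STEA = 0.40, EARLY = 0.40),
      age_range = list(NC = c(54, 62), HO = c(29, 68),
                       STEA = c(34, 67), EARLY = c(41, 58)),
      bmi_range = list(NC = c(22, 27), HO = c(32, 47),
                       STEA = c(32, 62), EARLY = c(40, 60)),
      diabetes_prob = 0.2,
      effect = 0                # optional log2 expression shift in STEA/EARLY
    )
  )
  cfg$genes <- modify_list_deep(cfg$genes, genes)
  cfg$methylome <- modify_list_deep(cfg$methylome, methylome)
  cfg$tfbs <- modify_list_deep(cfg$tfbs, tfbs)
  cfg$mito <- modify_list_deep(cfg$mito, mito)
  cfg$phenotype <- modify_list_deep(cfg$phenotype, phenotype)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  g <- cfg$genes; m <- cfg$methylome
  fracs <- c(g$frac_cv_high, g$frac_pv_high, m$frac_cv_hypo, m$coupled_frac,
             cfg$tfbs$frac_zonated, cfg$mito$fractions)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (g$n_genes < 1L || m$n_tiles < 1L || cfg$n_donors < 1L) {
    stop("counts must be positive")
  }
  if (m$n_dmrs > m$n_tiles) stop("infeasible config: more planted DMRs than tiles")
  if (sum(cfg$phenotype$counts) != cfg$n_donors) {
    stop("phenotype counts must sum to n_donors")
  }
  invisible(cfg)
}

#' Simulate a complete labelled lobule dataset
#'
#' Generates, deterministically for a given seed, every input the pipeline
#' consumes together with the ground truth needed to score it:
#' a gene-by-sample count matrix (negative binomial around zone-specific
#' means with a log-normal donor effect and uniform library sizes),
#' per-sample strand-merged CpG call tables (beta-binomial around
#' tile-level zonal means, negative-binomial coverage), reduced gene
#' models, a TFBS BED track, the sample sheet, per-chromosome read counts
#' for the mitochondrial ratio, and a `truth` object with all planted
#' labels and effect sizes.
#'
#' Zonated genes follow monotone three-point profiles: the intermediate
#' zone sits at the geometric midpoint of the pericentral and periportal
#' means (IZ-peaked genes exist only via the `n_iz_peak` negative-control
#' knob). Coupled DMR tiles are placed in the promoter, first intron or an
#' exon of their driver gene and are hypomethylated in the zone where the
#' gene is upregulated. The mitochondrial chromosome carries no CpG tiles.
#'
#' @param config A [sim_config()] object.
#' @return Object of class `zonemap_sim`: list with `counts`, `samples`,
#'   `calls`, `gene_models`, `tfbs`, `chrom_counts`, `truth`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  samples <- simulate_sample_sheet(config)
  geno <- simulate_gene_layout(config)
  gene_truth <- simulate_gene_truth(config, geno$models)
  counts <- simulate_counts(config, samples, gene_truth)
  tiles <- simulate_tile_layout(config, geno, gene_truth)
  tf <- plant_tfbs(tiles$truth, config)
  tiles$truth <- tf$tile_truth      # dmeth boosts applied at bound tiles
  calls <- simulate_methylome(config, samples, tiles$truth)
  chrom_counts <- simulate_mito(config, samples, geno$chrom_lengths)
  truth <- list(genes = gene_truth,
                tiles = tiles$truth,
                couplings = tiles$couplings,
                tfs = tf$tf_truth,
                mito = data.frame(zone = names(config$mito$fractions),
                                  fraction = as.numeric(config$mito$fractions),
                                  stringsAsFactors = FALSE))
  out <- list(counts = counts, samples = samples, calls = calls,
              gene_models = geno$models, tfbs = tf$bed,
              chrom_counts = chrom_counts, truth = truth, config = config)
  class(out) <- "zonemap_sim"
  out
}

#' @export
print.zonemap_sim <- function(x, ...) {
  cat("zonemap_sim:", nrow(x$counts), "genes x", ncol(x$counts), "samples;",
      nrow(x$truth$tiles), "CpG tiles (", sum(x$truth$tiles$dmr_flag),
      "planted DMRs );", nrow(x$truth$tfs), "TFs; seed",
      x$config$seed, "\n")
  invisible(x)
}

simulate_sample_sheet <- function(config) {
  ph <- config$phenotype
  donors <- sprintf("D%02d", seq_len(config$n_donors))
  pheno <- rep(names(ph$counts), ph$counts)
  sex <- vapply(pheno, function(p) {
    if (stats::runif(1) < ph$male_prob[[p]]) "M" else "F"
  }, character(1L))
  age <- vapply(pheno, function(p) {
    round(stats::runif(1, ph$age_range[[p]][1L], ph$age_range[[p]][2L]))
  }, numeric(1L))
  bmi <- vapply(pheno, function(p) {
    round(stats::runif(1, ph$bmi_range[[p]][1L], ph$bmi_range[[p]][2L]), 1)
  }, numeric(1L))
  diabetes <- stats::runif(config$n_donors) < ph$diabetes_prob
  df <- do.call(rbind, lapply(seq_along(donors), function(i) {
    data.frame(sample_id = paste(donors[i], ZONE_LEVELS, sep = "_"),
               donor_id = donors[i], zone = ZONE_LEVELS,
               phenotype = pheno[i], sex = sex[i], age = age[i],
               bmi = bmi[i], diabetes = diabetes[i],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  validate_sample_sheet(df)
}

# Deterministic gene geometry: genes evenly spaced along autosomes, three
# 300 bp exons separated by 700 bp introns, random strand.
simulate_gene_layout <- function(config) {
  g <- config$genes; m <- config$methylome
  n <- g$n_genes
  per_chrom <- ceiling(n / m$n_chroms)
  idx <- seq_len(n) - 1L
  chrom <- paste0("chr", idx %/% per_chrom + 1L)
  slot <- idx %% per_chrom
  gstart <- m$gene_offset + slot * m$gene_spacing
  strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
  exon_starts <- paste(gstart, gstart + 1000L, gstart + 2000L, sep = ",")
  exon_ends <- paste(gstart + 300L, gstart + 1300L, gstart + 2300L, sep = ",")
  tss <- ifelse(strand == "+", gstart + 1L, gstart + 2300L)
  models <- data.frame(gene_id = sprintf("G%05d", seq_len(n)),
                       chrom = chrom, strand = strand, tss = tss,
                       exon_starts = exon_starts, exon_ends = exon_ends,
                       stringsAsFactors = FALSE)
  models$exon_start_list <- lapply(strsplit(exon_starts, ","), as.integer)
  models$exon_end_list <- lapply(strsplit(exon_ends, ","), as.integer)
  models$gstart <- gstart
  chrom_lengths <- stats::setNames(
    rep(m$gene_offset + per_chrom * m$gene_spacing + m$gene_offset,
        m$n_chroms),
    paste0("chr", seq_len(m$n_chroms)))
  list(models = models, chrom_lengths = chrom_lengths, per_chrom = per_chrom)
}

simulate_gene_truth <- function(config, models) {
  g <- config$genes
  n <- g$n_genes
  n_cv <- round(g$frac_cv_high * n)
  n_pv <- round(g$frac_pv_high * n)
  n_iz <- g$n_iz_peak
  if (n_cv + n_pv + n_iz > n) stop("zonated fractions exceed gene count")
  class <- rep("flat", n)
  picks <- sample.int(n, n_cv + n_pv + n_iz)
  class[picks[seq_len(n_cv)]] <- "CV_high"
  class[picks[n_cv + seq_len(n_pv)]] <- "PV_high"
  if (n_iz > 0L) class[picks[n_cv + n_pv + seq_len(n_iz)]] <- "IZ_peak"
  lfc <- ifelse(class == "PV_high", g$lfc, ifelse(class == "CV_high", -g$lfc, 0))
  data.frame(gene_id = models$gene_id, class = class, true_log2fc = lfc,
             stringsAsFactors = FALSE)
}

simulate_counts <- function(config, samples, gene_truth) {
  g <- config$genes
  n <- nrow(gene_truth)
  w <- stats::rlnorm(n, meanlog = 0, sdlog = g$abundance_sdlog)
  half <- 2^(gene_truth$true_log2fc / 2)
  zone_mean <- cbind(CV = w / half, IZ = w, PV = w * half)
  iz_peak <- gene_truth$class == "IZ_peak"
  zone_mean[iz_peak, "IZ"] <- w[iz_peak] * 2^g$lfc
  donors <- unique(samples$donor_id)
  donor_eff <- stats::setNames(
    stats::rlnorm(length(donors), 0, g$donor_sd), donors)
  lib <- stats::runif(nrow(samples), g$lib_size_range[1L], g$lib_size_range[2L])
  pheno_shift <- if (config$phenotype$effect != 0) {
    affected <- stats::runif(n) < 0.1
    ifelse(affected, 2^config$phenotype$effect, 1)
  } else rep(1, n)
  counts <- matrix(0L, nrow = n, ncol = nrow(samples),
                   dimnames = list(gene_truth$gene_id, samples$sample_id))
  for (s in seq_len(nrow(samples))) {
    z <- as.character(samples$zone[s])
    p <- zone_mean[, z]
    if (samples$phenotype[s] %in% c("STEA", "EARLY")) p <- p * pheno_shift
    p <- p / sum(p)
    mu <- lib[s] * donor_eff[samples$donor_id[s]] * p
    counts[, s] <- as.integer(stats::rnbinom(n, mu = mu, size = 1 / g$dispersion))
  }
  counts
}

# Lay out CpG tiles: coupled DMR tiles in the promoter/intron/exon of their
# driver gene, remaining DMRs and null tiles sampled from a per-gene
# candidate grid plus intergenic space, plus chrX tiles that the pipeline
# must exclude.
simulate_tile_layout <- function(config, geno, gene_truth) {
  m <- config$methylome
  models <- geno$models
  tsize <- m$tile_size
  gidx <- models$gstart %/% tsize     # gene-anchored grid index (gstart % 500 == 0)

  n_coupled <- round(m$n_dmrs * m$coupled_frac)
  zonated <- which(gene_truth$class %in% c("CV_high", "PV_high"))
  # distribute coupled DMRs over driver genes, 1..max per gene
  driver_rows <- integer(0); per_gene <- integer(0)
  pool <- sample(zonated)
  while (sum(per_gene) < n_coupled && length(pool) > 0L) {
    k <- min(sample.int(m$max_dmrs_per_gene, 1L), n_coupled - sum(per_gene))
    driver_rows <- c(driver_rows, pool[1L]); per_gene <- c(per_gene, k)
    pool <- pool[-1L]
  }
  if (sum(per_gene) < n_coupled) stop("not enough zonated genes for coupling")

  feature_offset <- function(feature, strand) {
    # grid offsets relative to the gene anchor tile, by placement feature
    switch(feature,
           promoter = if (strand == "+") -2L else 5L,
           intron = 1L,
           exon = 2L)
  }
  coupled <- do.call(rbind, lapply(seq_along(driver_rows), function(i) {
    row <- driver_rows[i]
    feats <- sample(names(m$placement), per_gene[i], replace = FALSE,
                    prob = m$placement)
    off <- vapply(feats, feature_offset, integer(1L),
                  strand = models$strand[row])
    data.frame(chrom = models$chrom[row], tidx = gidx[row] + off,
               coupled_gene = models$gene_id[row],
               sign = if (gene_truth$class[row] == "CV_high") 1 else -1,
               stringsAsFactors = FALSE)
  }))
  if (is.null(coupled)) {
    coupled <- data.frame(chrom = character(), tidx = integer(),
                          coupled_gene = character(), sign = numeric(),
                          stringsAsFactors = FALSE)
  }

  # candidate pool for uncoupled DMRs and null tiles. Uncoupled DMRs anchor
  # at flat genes only, so the planted couplings are the sole DEG-DMR
  # structure and the truth labels suffice to score the driver caller.
  flat_gene <- gene_truth$class == "flat"
  cand <- data.frame(
    chrom = rep(models$chrom, times = 4L),
    tidx = c(gidx, gidx + 1L, gidx + 2L, gidx + 7L),
    near_flat = c(rep(flat_gene, 3L), rep(FALSE, length(gidx))),
    stringsAsFactors = FALSE)
  cand_key <- paste0(cand$chrom, ":", cand$tidx)
  used <- paste0(coupled$chrom, ":", coupled$tidx)
  cand <- cand[!(cand_key %in% used), , drop = FALSE]
  n_rest <- m$n_tiles - nrow(coupled)
  n_uncoupled <- m$n_dmrs - nrow(coupled)
  if (n_rest > nrow(cand) || n_uncoupled > sum(cand$near_flat)) {
    stop("tile candidate pool exhausted")
  }
  dmr_pick <- sample(which(cand$near_flat), n_uncoupled)
  null_pick <- sample(setdiff(seq_len(nrow(cand)), dmr_pick),
                      n_rest - n_uncoupled)
  rest <- cand[c(dmr_pick, null_pick), c("chrom", "tidx"), drop = FALSE]
  rest$coupled_gene <- NA_character_
  rest$sign <- 0
  if (n_uncoupled > 0L) {
    rest$sign[seq_len(n_uncoupled)] <-
      ifelse(stats::runif(n_uncoupled) < m$frac_cv_hypo, 1, -1)
  }
  tiles <- rbind(coupled, rest)
  is_dmr <- tiles$sign != 0
  # chrX tiles: simulated CpG territory that tiling must discard
  if (m$n_sex_tiles > 0L) {
    sex <- data.frame(chrom = "chrX",
                      tidx = sample.int(2000L, m$n_sex_tiles),
                      coupled_gene = NA_character_, sign = 0,
                      stringsAsFactors = FALSE)
    tiles <- rbind(tiles, sex)
    is_dmr <- c(is_dmr, rep(FALSE, m$n_sex_tiles))
  }
  base <- ifelse(is_dmr, stats::runif(nrow(tiles), 0.3, 0.6),
                 stats::rbeta(nrow(tiles), 2, 2))
  true_dmeth <- tiles$sign * m$dmeth
  truth <- data.frame(
    tile_id = paste0(tiles$chrom, ":", tiles$tidx),
    chrom = tiles$chrom,
    start = tiles$tidx * tsize,
    end = (tiles$tidx + 1L) * tsize,
    dmr_flag = is_dmr,
    true_dmeth = true_dmeth,
    base_meth = base,
    coupled_gene = tiles$coupled_gene,
    stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  couplings <- truth[!is.na(truth$coupled_gene),
                     c("coupled_gene", "tile_id", "true_dmeth")]
  names(couplings)[1L] <- "gene_id"
  rownames(couplings) <- NULL
  list(truth = truth, couplings = couplings)
}

#' Plant transcription-factor binding sites over the tile territory
#'
#' Non-zonated TFs place their sites uniformly over all CpG tiles. Zonated
#' TFs are assigned a zone preference (alternating CV and PV, as binding
#' factors enriched on either side of the porto-central axis) and place
#' each site in a DMR tile hypomethylated in their preferred zone with the
#' configured odds (a tile-level weight of `placement_odds` against 1).
#' Tiles that receive a zonated TF's site and are DMRs get their planted
#' zonal difference deepened by `dmeth_boost` percentage points in the
#' direction of the existing difference.
#'
#' @param tile_truth Tile truth table from the generator (`tile_id`,
#'   `chrom`, `start`, `end`, `dmr_flag`, `true_dmeth`, ...).
#' @param config A [sim_config()] object.
#' @return List with `bed` (TFBS BED data frame), `tf_truth` (per-TF
#'   zonated flag) and the updated `tile_truth`.
#' @export
plant_tfbs <- function(tile_truth, config) {
  tf <- config$tfbs
  if (tf$n_tfs == 0L) {
    return(list(bed = data.frame(chrom = character(), start = integer(),
                                 end = integer(), name = character()),
                tf_truth = data.frame(tf = character(), zonated = logical()),
                tile_truth = tile_truth))
  }
  auto <- which(!(tile_truth$chrom %in% excluded_chroms()))
  if (tf$sites_per_tf > 0L && length(auto) == 0L) {
    stop("requested sites exceed available tiles")
  }
  n_zon <- round(tf$frac_zonated * tf$n_tfs)
  tf_names <- sprintf("TF%02d", seq_len(tf$n_tfs))
  zonated <- c(rep(TRUE, n_zon), rep(FALSE, tf$n_tfs - n_zon))
  direction <- rep(NA_character_, tf$n_tfs)
  direction[zonated] <- rep_len(c("CV", "PV"), n_zon)
  # dmeth > 0 (PV - CV) means the tile is hypomethylated pericentrally
  target_cv <- tile_truth$dmr_flag[auto] & tile_truth$true_dmeth[auto] > 0
  target_pv <- tile_truth$dmr_flag[auto] & tile_truth$true_dmeth[auto] < 0
  bed <- NULL
  boosted <- logical(nrow(tile_truth))
  for (k in seq_len(tf$n_tfs)) {
    if (tf$sites_per_tf == 0L) next
    wgt <- if (zonated[k]) {
      target <- if (direction[k] == "CV") target_cv else target_pv
      ifelse(target, tf$placement_odds, 1)
    } else rep(1, length(auto))
    rows <- auto[sample.int(length(auto), tf$sites_per_tf, replace = TRUE,
                            prob = wgt)]
    offs <- sample.int(config$methylome$tile_size - tf$site_width,
                       tf$sites_per_tf, replace = TRUE) - 1L
    bed <- rbind(bed, data.frame(
      chrom = tile_truth$chrom[rows],
      start = tile_truth$start[rows] + offs,
      end = tile_truth$start[rows] + offs + tf$site_width,
      name = tf_names[k], stringsAsFactors = FALSE))
    if (zonated[k]) boosted <- boosted | (seq_len(nrow(tile_truth)) %in% rows &
                                            tile_truth$dmr_flag)
  }
  tile_truth$true_dmeth[boosted] <- tile_truth$true_dmeth[boosted] +
    sign(tile_truth$true_dmeth[boosted]) * tf$dmeth_boost
  if (is.null(bed)) {
    bed <- data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      stringsAsFactors = FALSE)
  }
  bed <- bed[order(bed$chrom, bed$start, bed$end), , drop = FALSE]
  rownames(bed) <- NULL
  list(bed = bed,
       tf_truth = data.frame(tf = tf_names, zonated = zonated,
                             direction = direction,
                             stringsAsFactors = FALSE),
       tile_truth = tile_truth)
}

#' Simulate beta-binomial methylation calls for one tile
#'
#' Per sample and CpG: coverage is negative binomial, the site methylation
#' level is beta-distributed around the sample's zonal mean with the given
#' precision (alpha + beta), and the methylated count is binomial. The
#' expected per-sample mean methylation equals the sample's zonal mean.
#'
#' @param zonal_means Named numeric vector (`CV`, `IZ`, `PV`) of
#'   methylation levels between 0 and 1.
#' @param cpg_positions 1-based CpG positions within the tile.
#' @param zones Character vector of the sample zones (one entry per
#'   sample).
#' @param coverage_mean,coverage_size Negative-binomial coverage model.
#' @param precision Beta-binomial precision (alpha + beta).
#' @return List with integer matrices `meth` and `total`
#'   (positions x samples).
#' @export
simulate_methylation_for_tile <- function(zonal_means, cpg_positions, zones,
                                          coverage_mean = 30,
                                          coverage_size = 5,
                                          precision = 30) {
  if (length(cpg_positions) == 0L) stop("empty cpg_positions")
  if (any(zonal_means < 0 | zonal_means > 1)) stop("zonal means must be in [0, 1]")
  n_site <- length(cpg_positions)
  n_samp <- length(zones)
  m <- rep(zonal_means[zones], each = n_site)
  m <- pmin(pmax(m, 1e-6), 1 - 1e-6)
  total <- stats::rnbinom(n_site * n_samp, mu = coverage_mean,
                          size = coverage_size)
  p <- stats::rbeta(n_site * n_samp, m * precision, (1 - m) * precision)
  meth <- stats::rbinom(n_site * n_samp, total, p)
  list(meth = matrix(as.integer(meth), n_site, n_samp,
                     dimnames = list(cpg_positions, names(zones))),
       total = matrix(as.integer(total), n_site, n_samp,
                      dimnames = list(cpg_positions, names(zones))))
}

# Bulk methylome simulation over all tiles; same model as
# simulate_methylation_for_tile, vectorized across tiles.
simulate_methylome <- function(config, samples, tile_truth) {
  m <- config$methylome
  n_tiles <- nrow(tile_truth)
  n_cpg <- 3L + stats::rpois(n_tiles, max(m$cpg_per_tile_mean - 3, 0))
  pos_list <- lapply(seq_len(n_tiles), function(i) {
    sort(sample.int(m$tile_size, n_cpg[i])) + tile_truth$start[i]
  })
  delta <- tile_truth$true_dmeth / 100
  zm <- cbind(CV = tile_truth$base_meth - delta / 2,
              IZ = tile_truth$base_meth,
              PV = tile_truth$base_meth + delta / 2)
  zm <- pmin(pmax(zm, 0.02), 0.98)
  # long vectors over (site, sample)
  site_tile <- rep.int(seq_len(n_tiles), n_cpg)
  pos <- unlist(pos_list, use.names = FALSE)
  chrom_site <- tile_truth$chrom[site_tile]
  n_site <- length(pos)
  zones <- as.character(samples$zone)
  N <- n_site * length(zones)
  mu <- numeric(N)
  for (s in seq_along(zones)) {
    mu[(s - 1L) * n_site + seq_len(n_site)] <- zm[cbind(site_tile,
                                                        match(zones[s], ZONE_LEVELS))]
  }
  total <- stats::rnbinom(N, mu = m$coverage_mean, size = m$coverage_size)
  p <- stats::rbeta(N, mu * m$bb_precision, (1 - mu) * m$bb_precision)
  meth <- stats::rbinom(N, total, p)
  calls <- vector("list", length(zones))
  names(calls) <- samples$sample_id
  for (s in seq_along(zones)) {
    idx <- (s - 1L) * n_site + seq_len(n_site)
    covered <- total[idx] > 0L
    df <- data.frame(chrom = chrom_site[covered], pos = as.integer(pos[covered]),
                     meth_count = as.integer(meth[idx][covered]),
                     total_count = as.integer(total[idx][covered]),
                     stringsAsFactors = FALSE)
    calls[[s]] <- validate_cpg_calls(df)
  }
  calls
}

simulate_mito <- function(config, samples, chrom_lengths) {
  fr <- config$mito$fractions
  total <- config$mito$total_reads
  do.call(rbind, lapply(seq_len(nrow(samples)), function(s) {
    z <- as.character(samples$zone[s])
    mito <- stats::rbinom(1L, total, fr[[z]])
    rest <- stats::rmultinom(1L, total - mito,
                             prob = chrom_lengths / sum(chrom_lengths))[, 1L]
    data.frame(sample_id = samples$sample_id[s],
               chrom = c(names(chrom_lengths), "chrM"),
               reads = as.integer(c(rest, mito)), stringsAsFactors = FALSE)
  }))
}

#' Simulate a tile universe with planted TFBS tracks only
#'
#' Generates the gene layout, tile truth (planted DMRs) and TF binding-site
#' track of [simulate_dataset()] without simulating read counts or CpG
#' calls. Used to validate the binding-site zonation statistic at the scale
#' of a genome-wide tile universe, where simulating every CpG call would
#' dominate runtime without informing the statistic (which consumes
#' tile-level DM results).
#'
#' @param config A [sim_config()] object.
#' @return List with `tile_truth`, `bed`, `tf_truth`, `couplings`.
#' @export
simulate_tf_universe <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  geno <- simulate_gene_layout(config)
  gene_truth <- simulate_gene_truth(config, geno$models)
  tiles <- simulate_tile_layout(config, geno, gene_truth)
  tf <- plant_tfbs(tiles$truth, config)
  list(tile_truth = tf$tile_truth, bed = tf$bed, tf_truth = tf$tf_truth,
       couplings = tiles$couplings)
}

#' Convert planted tile truth into a DM-result frame
#'
#' Builds the tile-level differential-methylation frame the downstream
#' statistics consume directly from generator truth: planted DMRs carry
#' their true methylation difference plus Gaussian estimation noise and a
#' significant q-value, null tiles carry noise-only differences and
#' non-significant q-values. This isolates statistic-level validation
#' (binding-site enrichment, Delta.TXF) from the tile caller, whose own
#' recovery is validated separately.
#'
#' @param tile_truth Tile truth table from the generator.
#' @param noise_sd SD of the estimation noise on `dmeth`, percentage
#'   points (default 1, matching the caller's observed recovery error).
#' @return Data frame with the [zonal_dm()] columns used downstream
#'   (`tile_id`, `chrom`, `start`, `end`, `dmeth`, `q`, `dmr_flag`);
#'   excluded (sex/mito) chromosomes are dropped as the tiling stage
#'   would.
#' @export
truth_tiles_as_dm <- function(tile_truth, noise_sd = 1) {
  t_ <- tile_truth[!(tile_truth$chrom %in% excluded_chroms()), , drop = FALSE]
  n <- nrow(t_)
  dmeth <- t_$true_dmeth + stats::rnorm(n, 0, noise_sd)
  q <- ifelse(t_$dmr_flag, 1e-8, stats::runif(n, 0.05, 1))
  data.frame(tile_id = t_$tile_id, chrom = t_$chrom, start = t_$start,
             end = t_$end, dmeth = dmeth, q = q, dmr_flag = t_$dmr_flag,
             stringsAsFactors = FALSE)
}

#' Simulate a nine-zone mouse zonation reference with orthologue map
#'
#' Builds the interspecies comparison inputs from a simulated human
#' dataset: a one-to-one orthologue map covering every zonated human gene
#' plus `n_flat_orthologues` flat genes, and a genes x 9 mouse layer
#' matrix derived as a noisy monotone transform of the human zonal truth.
#' Of the zonated orthologues, a configured fraction is concordant (same
#' porto-central direction in mouse); the remainder is split between flat
#' mouse profiles and reversed (discordant) ones.
#'
#' Layers 1-2, 4-5 and 8-9 carry the pericentral, intermediate and
#' periportal targets respectively (matching the three-zone merge rule);
#' layers 3, 6 and 7 are interpolated. Per gene and layer a log-normal
#' noise factor is applied.
#'
#' @param sim A `zonemap_sim` object.
#' @param concordance Fraction of zonated orthologues conserved in mouse
#'   (default 0.6).
#' @param n_flat_orthologues Additional non-zonated human genes given
#'   orthologues (default 100).
#' @param noise_sd Log-normal noise SD per gene and layer (default 0.3).
#' @param discordant_frac Among non-concordant zonated orthologues, the
#'   fraction with a reversed (rather than flat) mouse gradient
#'   (default 0.5).
#' @param seed Seed for this generator (default: dataset seed + 1000).
#' @return List with `mouse` (genes x 9 matrix, CPM-like), `orthologues`
#'   (data frame `human_gene`, `mouse_gene`) and `truth` (per-orthologue
#'   planted class: concordant / discordant / flat).
#' @export
simulate_mouse_reference <- function(sim, concordance = 0.6,
                                     n_flat_orthologues = 100L,
                                     noise_sd = 0.3, discordant_frac = 0.5,
                                     seed = sim$config$seed + 1000L) {
  set.seed(seed)
  gt <- sim$truth$genes
  zonated <- gt$gene_id[gt$class %in% c("CV_high", "PV_high")]
  flat <- sample(gt$gene_id[gt$class == "flat"],
                 min(n_flat_orthologues, sum(gt$class == "flat")))
  human_genes <- c(zonated, flat)
  # planted mouse behaviour per zonated orthologue
  n_con <- round(concordance * length(zonated))
  n_rest <- length(zonated) - n_con
  n_dis <- round(discordant_frac * n_rest)
  cls <- c(rep("concordant", n_con), rep("discordant", n_dis),
           rep("flat", n_rest - n_dis))
  cls <- sample(cls)
  cls <- c(cls, rep("flat", length(flat)))
  # human true zone means on a CPM-like scale
  hm <- zone_mean_cpm(sim$counts, sim$samples)[human_genes, , drop = FALSE]
  target <- hm
  rev_rows <- cls == "discordant"
  target[rev_rows, ] <- hm[rev_rows, c("PV", "IZ", "CV")]
  flat_rows <- cls == "flat" & human_genes %in% zonated
  target[flat_rows, ] <- exp(rowMeans(log(hm[flat_rows, , drop = FALSE] + 0.01)))
  # expand three zone targets into nine layers with interpolation
  l3 <- sqrt(target[, "CV"] * target[, "IZ"])
  l67 <- sqrt(target[, "IZ"] * target[, "PV"])
  nine <- cbind(target[, "CV"], target[, "CV"], l3,
                target[, "IZ"], target[, "IZ"], l67, l67,
                target[, "PV"], target[, "PV"])
  noise <- matrix(stats::rlnorm(length(nine), 0, noise_sd), nrow = nrow(nine))
  nine <- nine * noise
  mouse_genes <- paste0("Mm_", human_genes)
  rownames(nine) <- mouse_genes
  colnames(nine) <- paste0("zone", 1:9)
  list(mouse = nine,
       orthologues = data.frame(human_gene = human_genes,
                                mouse_gene = mouse_genes,
                                stringsAsFactors = FALSE),
       truth = data.frame(human_gene = human_genes, planted = cls,
                          stringsAsFactors = FALSE))
}

#' Write a simulated dataset to disk
#'
#' Emits every pipeline input format plus truth tables and a JSON run
#' manifest (config, seed, content hashes).
#'
#' @param sim A `zonemap_sim` object.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cpg_dir <- file.path(dir, "cpg")
  dir.create(cpg_dir, showWarnings = FALSE)
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  write_sample_sheet(sim$samples, file.path(dir, "samples.tsv"))
  write_gene_models(sim$gene_models, file.path(dir, "genes.tsv"))
  write_bed(sim$tfbs, file.path(dir, "tfbs.bed"))
  utils::write.table(sim$chrom_counts, file.path(dir, "chromcounts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (s in names(sim$calls)) {
    write_cpg_calls(sim$calls[[s]], file.path(cpg_dir, paste0(s, ".tsv")))
  }
  for (nm in c("genes", "tiles", "couplings", "tfs", "mito")) {
    utils::write.table(sim$truth[[nm]],
                       file.path(dir, paste0("truth_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_manifest(dir, config = unclass(sim$config), seed = sim$config$seed)
  invisible(dir)
}
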