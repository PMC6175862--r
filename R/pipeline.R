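# Stage-tagged error helper: failures abort with the stage name so a
# pipeline run can be resumed from intact earlier outputs.
stage_error <- function(stage, e) {
  stop("[stage:", stage, "] ", conditionMessage(e), call. = FALSE)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) stage_error(stage, e))
}

#' Run the full zonal analysis pipeline
#'
#' Executes all stages in dependency order — simulate (optional), de, dm,
#' integrate, tfbs, xspecies (optional), mito, report — writing one TSV per
#' stage plus a JSON manifest and a plain-text summary to `out_dir`. All
#' randomness flows from the single `seed`; re-running with the same seed
#' and config reproduces identical outputs.
#'
#' @param out_dir Output directory (created; existing stage files are
#'   overwritten within a run but runs never mutate other directories).
#' @param config Analysis configuration from [default_config()] /
#'   [read_config()].
#' @param sim_cfg A [sim_config()]; when supplied (or `simulate = TRUE`)
#'   inputs are generated rather than read.
#' @param inputs Named list of input paths (`counts`, `samples`, `cpg_dir`,
#'   `genes`, `tfbs`, `chromcounts`, optionally `mouse` and `orthologues`)
#'   used when not simulating.
#' @param simulate Generate inputs with `sim_cfg` defaults (default
#'   `FALSE` unless `sim_cfg` is given).
#' @param seed Seed for the simulation (overrides `sim_cfg$seed`).
#' @return Invisible list of stage results (`sim`, `de`, `dm`,
#'   `annotations`, `pairs`, `drivers`, `tf`, `mito`, `summary`).
#' @export
run_zonemap <- function(out_dir, config = default_config(), sim_cfg = NULL,
                        inputs = NULL, simulate = !is.null(sim_cfg),
                        seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()

  if (simulate) {
    if (is.null(sim_cfg)) sim_cfg <- sim_config()
    if (!is.null(seed)) sim_cfg$seed <- as.integer(seed)
    sim <- run_stage("simulate", simulate_dataset(sim_cfg))
    counts <- sim$counts
    samples <- sim$samples
    calls <- sim$calls
    gene_models <- sim$gene_models
    tfbs_bed <- sim$tfbs
    chrom_counts <- sim$chrom_counts
    results$sim <- sim
  } else {
    if (is.null(inputs)) stop("[stage:input] neither inputs nor simulation requested")
    need <- c("counts", "samples", "cpg_dir", "genes", "tfbs", "chromcounts")
    miss <- need[!vapply(need, function(k) !is.null(inputs[[k]]) &&
                           file.exists(inputs[[k]]), logical(1L))]
    if (length(miss) > 0L) {
      stop("[stage:input] missing input(s): ", paste(miss, collapse = ", "))
    }
    counts <- run_stage("input", read_counts(inputs$counts))
    samples <- run_stage("input", read_sample_sheet(inputs$samples))
    files <- list.files(inputs$cpg_dir, pattern = "\\.tsv$", full.names = TRUE)
    calls <- run_stage("input", lapply(files, read_cpg_calls))
    names(calls) <- sub("\\.tsv$", "", basename(files))
    gene_models <- run_stage("input", read_gene_models(inputs$genes))
    tfbs_bed <- run_stage("input", read_bed(inputs$tfbs))
    chrom_counts <- run_stage("input", utils::read.delim(inputs$chromcounts,
                                                         stringsAsFactors = FALSE))
  }

  ecf <- config$expression
  mcf <- config$methylation
  de <- run_stage("de", {
    kept <- filter_expressed(counts, ecf$min_cpm, ecf$min_samples)
    fit_zonal_de(kept, samples, fdr = ecf$fdr, min_lfc = ecf$min_lfc,
                 donor_blocking = ecf$donor_blocking)
  })
  write_stage_tsv(de, file.path(out_dir, "de.tsv"))
  results$de <- de

  dm <- run_stage("dm", {
    filtered <- filter_sites(calls, mcf$min_cov)
    tiles <- tile_methylome(filtered, tile_size = mcf$tile_size,
                            min_cpgs = mcf$min_cpgs,
                            per_sample = mcf$per_sample_cpgs)
    zonal_dm(tiles, samples, fdr = mcf$fdr, min_diff = mcf$min_diff,
             gradient_tol = mcf$gradient_tol,
             donor_blocking = mcf$donor_blocking)
  })
  write_stage_tsv(dm, file.path(out_dir, "dm.tsv"))
  results$dm <- dm

  integ <- run_stage("integrate", {
    ann <- annotate_dmrs(dm, gene_models,
                         promoter_up = config$integration$promoter_up,
                         promoter_down = config$integration$promoter_down)
    pairs <- link_deg_dmr(de, dm, ann)
    drivers <- classify_drivers(pairs)
    anti <- if (nrow(pairs) >= 3L) anticorrelation(pairs) else NULL
    list(annotations = ann, pairs = pairs, drivers = drivers, anti = anti)
  })
  write_stage_tsv(integ$annotations, file.path(out_dir, "annotations.tsv"))
  write_stage_tsv(integ$pairs, file.path(out_dir, "deg_dmr_pairs.tsv"))
  write_stage_tsv(integ$drivers, file.path(out_dir, "drivers.tsv"))
  results <- c(results, integ[c("annotations", "pairs", "drivers", "anti")])

  tf <- run_stage("tfbs", {
    tf_zonation(dm, tfbs_bed, alpha = config$tfbs$alpha,
                min_dmr_tfbs_tiles = config$tfbs$min_dmr_tfbs_tiles,
                tile_size = mcf$tile_size, norm_mode = config$tfbs$norm_mode)
  })
  write_stage_tsv(tf, file.path(out_dir, "tf_zonation.tsv"))
  results$tf <- tf

  if (!is.null(inputs$mouse) && !is.null(inputs$orthologues)) {
    xs <- run_stage("xspecies", {
      mouse <- read_matrix_tsv(inputs$mouse)
      orth <- read_orthologues(inputs$orthologues)
      merged <- merge_mouse_zones(mouse)
      bg <- background_filter(merged)
      human_means <- zone_mean_cpm(counts, samples)
      cons <- conserved_zonation(de, bg$expr[bg$keep, , drop = FALSE], orth,
                                 mouse_lfc_min = config$xspecies$mouse_lfc_min,
                                 eps = config$xspecies$epsilon)
      cors <- lapply(ZONE_LEVELS, function(z) {
        cross_species_correlation(human_means, bg$expr[bg$keep, , drop = FALSE],
                                  orth, z)
      })
      names(cors) <- ZONE_LEVELS
      list(conserved = cons, correlations = cors)
    })
    write_stage_tsv(xs$conserved$classes, file.path(out_dir, "xspecies.tsv"))
    results$xspecies <- xs
  }

  mito <- run_stage("mito", {
    ratios <- mito_ratio(chrom_counts, mito_chrom = config$mito$mito_chrom)
    tests <- zonal_ratio_test(ratios, samples, test = config$mito$test,
                              pooled = config$mito$pooled)
    list(ratios = ratios, tests = tests)
  })
  write_stage_tsv(mito$ratios, file.path(out_dir, "mito.tsv"))
  write_stage_tsv(mito$tests, file.path(out_dir, "mito_tests.tsv"))
  results$mito <- mito

  results$summary <- run_stage("report", summary_report(results))
  writeLines(results$summary, file.path(out_dir, "summary.txt"))
  write_manifest(out_dir, config = config,
                 seed = if (simulate) sim_cfg$seed else NA)
  invisible(results)
}

write_stage_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

zone_mean_cpm <- function(counts, samples) {
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  cpm_mat <- cpm(counts)
  sapply(ZONE_LEVELS, function(z) {
    rowMeans(cpm_mat[, as.character(samples$zone) == z, drop = FALSE])
  })
}

#' Human-readable pipeline summary
#'
#' Tallies every stage output into a short plain-text report: differentially
#' expressed genes per zone, DMR and gradient-class counts, driver genes per
#' zone, significant TFs, anti-correlation, mitochondrial gradient p-values.
#' Every number is recomputed from the stage tables passed in.
#'
#' @param results Stage result list as produced by [run_zonemap()].
#' @return Character vector of report lines.
#' @export
summary_report <- function(results) {
  lines <- c("zonemap pipeline summary", "========================")
  if (!is.null(results$de)) {
    tab <- table(factor(results$de$zonation_call,
                        levels = c("CV_high", "PV_high", "none")))
    lines <- c(lines,
               sprintf("DE: %d genes tested; %d CV_high, %d PV_high",
                       nrow(results$de), tab[["CV_high"]], tab[["PV_high"]]))
  }
  if (!is.null(results$dm)) {
    n_dmr <- sum(results$dm$dmr_flag %in% TRUE)
    gr <- table(factor(results$dm$gradient_class[results$dm$dmr_flag %in% TRUE],
                       levels = c("monotone", "IZ_extreme", "undetermined")))
    lines <- c(lines,
               sprintf("DM: %d tiles tested; %d DMRs (%d monotone, %d IZ_extreme)",
                       sum(!is.na(results$dm$p)), n_dmr,
                       gr[["monotone"]], gr[["IZ_extreme"]]))
  }
  if (!is.null(results$drivers)) {
    dz <- table(factor(results$drivers$zone, levels = c("CV", "PV")))
    lines <- c(lines,
               sprintf("Drivers: %d epigenetically marked driver genes (%d CV, %d PV)",
                       nrow(results$drivers), dz[["CV"]], dz[["PV"]]))
  }
  if (!is.null(results$anti)) {
    lines <- c(lines,
               sprintf("DEG-DMR anti-correlation: r = %.3f (p = %.3g, %d pairs)",
                       results$anti$r, results$anti$p, results$anti$n_pairs))
  }
  if (!is.null(results$tf)) {
    lines <- c(lines,
               sprintf("TFBS: %d/%d TFs significant at Bonferroni threshold %.3g",
                       sum(results$tf$significant), nrow(results$tf),
                       attr(results$tf, "threshold")))
  }
  if (!is.null(results$xspecies)) {
    rho <- vapply(results$xspecies$correlations, function(x) x$rho, numeric(1L))
    cnt <- results$xspecies$conserved$counts
    lines <- c(lines,
               sprintf("Cross-species: rho CV/IZ/PV = %.2f/%.2f/%.2f; %d conserved, %d discordant, %d mouse-flat",
                       rho[["CV"]], rho[["IZ"]], rho[["PV"]],
                       cnt[["conserved"]], cnt[["discordant"]],
                       cnt[["mouse_flat"]]))
  }
  if (!is.null(results$mito)) {
    for (i in seq_len(nrow(results$mito$tests))) {
      t_ <- results$mito$tests[i, ]
      lines <- c(lines,
                 sprintf("Mito %s: median diff %.2g, p = %.3g%s", t_$contrast,
                         t_$median_diff, t_$p,
                         if (t_$p < 0.001) " (*)" else ""))
    }
  }
  lines
}

#' Write a machine-readable run manifest
#'
#' JSON file with the configuration snapshot, seed, package version and
#' md5 content hashes of every file in the output directory; identical
#' inputs and seed reproduce an identical manifest (modulo the manifest
#' itself).
#'
#' @param dir Run directory.
#' @param config Configuration list to snapshot.
#' @param seed Seed used (NA when inputs were read, not simulated).
#' @return Path of the manifest, invisibly.
#' @export
write_manifest <- function(dir, config, seed = NA) {
  files <- setdiff(list.files(dir, recursive = TRUE), "manifest.json")
  hashes <- as.list(tools::md5sum(file.path(dir, files)))
  names(hashes) <- files
  manifest <- list(
    package = "zonemap",
    version = as.character(utils::packageVersion("zonemap")),
    seed = seed,
    config = config,
    files = hashes
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
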