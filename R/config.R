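#' Default analysis configuration
#'
#' One nested list holding every tunable threshold of the pipeline, each at
#' its published default. A YAML file with the same structure can override
#' any subset of keys via [read_config()].
#'
#' Key groups:
#' \describe{
#'   \item{expression}{CPM filter (`min_cpm` 0.5 in `min_samples` 5), DE
#'     thresholds (`fdr` 0.01, `min_lfc` 1), `donor_blocking` (drop
#'     donor-level covariates in favour of the donor factor),
#'     `flat_tol` 0.1 for profile classification, `pca_n_top` 1000.}
#'   \item{methylation}{`min_cov` 10 per-sample site filter, `tile_size`
#'     500, `min_cpgs` 3 (union semantics across samples; set
#'     `per_sample_cpgs = TRUE` for the strict mode), `fdr` 0.01,
#'     `min_diff` 5 percentage points, `gradient_tol` 5,
#'     `pca_n_top` 5000 with `pca_min_cov` 5.}
#'   \item{integration}{promoter window `promoter_up` 1500 / `promoter_down`
#'     500 bp around the TSS, strand-aware.}
#'   \item{tfbs}{`alpha` 0.05 Bonferroni family level, `min_dmr_tfbs_tiles`
#'     10 inclusion filter, `norm_mode` "tf_mean" (subtract the across-TF
#'     mean of Delta.TXF; "dmr_mean" subtracts the mean dmeth of all DMR
#'     tiles instead).}
#'   \item{xspecies}{`epsilon` 0.01 CPM pseudo-value, `mouse_lfc_min` 0.5.}
#'   \item{mito}{`mito_chrom` "chrM", `test` "wilcoxon" (or "t"),
#'     `pooled` FALSE (pairwise zone contrasts; TRUE tests CV against the
#'     donor mean of IZ and PV).}
#' }
#'
#' @return Nested list of configuration values.
#' @export
default_config <- function() {
  list(
    expression = list(
      min_cpm = 0.5,
      min_samples = 5L,
      fdr = 0.01,
      min_lfc = 1,
      donor_blocking = TRUE,
      flat_tol = 0.1,
      pca_n_top = 1000L
    ),
    methylation = list(
      min_cov = 10L,
      tile_size = 500L,
      min_cpgs = 3L,
      per_sample_cpgs = FALSE,
      fdr = 0.01,
      min_diff = 5,
      gradient_tol = 5,
      donor_blocking = TRUE,
      pca_n_top = 5000L,
      pca_min_cov = 5L
    ),
    integration = list(
      promoter_up = 1500L,
      promoter_down = 500L
    ),
    tfbs = list(
      alpha = 0.05,
      min_dmr_tfbs_tiles = 10L,
      norm_mode = "tf_mean"
    ),
    xspecies = list(
      epsilon = 0.01,
      mouse_lfc_min = 0.5
    ),
    mito = list(
      mito_chrom = "chrM",
      test = "wilcoxon",
      pooled = FALSE
    )
  )
}

#' Read a configuration file
#'
#' Reads a YAML configuration and merges it over [default_config()]:
#' any key absent from the file keeps its default.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  modify_list_deep(cfg, user)
}

modify_list_deep <- function(base, override) {
  for (k in names(override)) {
    if (is.list(override[[k]]) && is.list(base[[k]])) {
      base[[k]] <- modify_list_deep(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}
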