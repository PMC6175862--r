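#' Read a sample sheet
#'
#' The sample sheet is the single source of donor-level covariates for every
#' stage of the pipeline. It is a TSV with one row per sample and (at least)
#' the columns `sample_id`, `donor_id`, `zone`, `phenotype`, `sex`, `age`,
#' `bmi`, `diabetes`.
#'
#' Validation enforces the design invariants: each donor contributes at most
#' one sample per zone, zone and phenotype labels are canonical, and the
#' donor-level covariates (phenotype, sex, age, bmi, diabetes) are constant
#' within a donor.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with one row per sample; `zone` and `phenotype`
#'   are factors with canonical level order.
#' @seealso [write_sample_sheet()]
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no samples in sample sheet: ", path)
  validate_sample_sheet(df)
}

#' Validate a sample-sheet data frame
#'
#' @param df Data frame with the eight sample-sheet columns.
#' @return The validated data frame with canonical factor levels.
#' @export
validate_sample_sheet <- function(df) {
  required <- c("sample_id", "donor_id", "zone", "phenotype",
                "sex", "age", "bmi", "diabetes")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("sample sheet missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("no samples")
  bad_zone <- setdiff(unique(as.character(df$zone)), ZONE_LEVELS)
  if (length(bad_zone) > 0L) {
    stop("unknown zone label(s): ", paste(bad_zone, collapse = ", "))
  }
  bad_ph <- setdiff(unique(as.character(df$phenotype)), PHENOTYPE_LEVELS)
  if (length(bad_ph) > 0L) {
    stop("unknown phenotype label(s): ", paste(bad_ph, collapse = ", "))
  }
  if (!is.numeric(df$age) || !is.numeric(df$bmi) || anyNA(df$age) || anyNA(df$bmi)) {
    stop("age and bmi must be numeric and complete")
  }
  key <- paste(df$donor_id, df$zone, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate (donor, zone) combination: ", gsub("\r", "/", dup, fixed = TRUE))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id")
  # donor-level covariates must not vary within donor
  for (col in c("phenotype", "sex", "age", "bmi", "diabetes")) {
    n_per_donor <- tapply(df[[col]], df$donor_id, function(x) length(unique(x)))
    if (any(n_per_donor > 1L)) {
      stop("covariate '", col, "' varies within donor(s): ",
           paste(names(n_per_donor)[n_per_donor > 1L], collapse = ", "))
    }
  }
  df$zone <- factor(as.character(df$zone), levels = ZONE_LEVELS)
  df$phenotype <- factor(as.character(df$phenotype), levels = PHENOTYPE_LEVELS)
  df$diabetes <- as.logical(df$diabetes)
  rownames(df) <- df$sample_id
  df
}

#' @rdname read_sample_sheet
#' @param samples Validated sample-sheet data frame.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-by-sample count matrix
#'
#' TSV with gene ids in the first column and one column of non-negative
#' integer read counts per sample.
#'
#' @param path Path to the TSV file.
#' @return Integer matrix, genes in rows, samples in columns.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1L]]
  if (anyNA(m)) stop("count matrix contains missing entries")
  if (any(m < 0L)) stop("count matrix contains negative entries")
  m
}

#' @rdname read_counts
#' @param counts Integer count matrix with gene row names and sample column
#'   names.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read strand-merged CpG methylation calls for one sample
#'
#' One TSV per sample with columns `chrom`, `pos` (1-based position of the C
#' on the plus strand after strand merging), `meth_count`, `total_count`.
#'
#' @param path Path to the TSV file.
#' @return Data frame sorted by (chrom, pos) with the four call columns.
#' @export
read_cpg_calls <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "meth_count", "total_count")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("CpG call table missing column(s): ", paste(missing, collapse = ", "))
  }
  validate_cpg_calls(df[required])
}

validate_cpg_calls <- function(df) {
  if (any(df$meth_count < 0L) || any(df$total_count < 0L)) {
    stop("negative CpG counts")
  }
  if (any(df$meth_count > df$total_count)) {
    i <- which(df$meth_count > df$total_count)[1L]
    stop("meth_count exceeds total_count at ", df$chrom[i], ":", df$pos[i])
  }
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_cpg_calls
#' @param calls CpG call data frame (`chrom`, `pos`, `meth_count`,
#'   `total_count`).
#' @export
write_cpg_calls <- function(calls, path) {
  utils::write.table(calls[, c("chrom", "pos", "meth_count", "total_count")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export CpG calls as bedGraph tracks
#'
#' Writes two bedGraph files: methylation ratio (0-1) and coverage. Intervals
#' are 0-based half-open single-base records for the strand-merged CpG.
#'
#' @param calls CpG call data frame.
#' @param ratio_path,coverage_path Output paths.
#' @export
write_cpg_bedgraph <- function(calls, ratio_path, coverage_path) {
  start0 <- calls$pos - 1L
  ratio <- ifelse(calls$total_count > 0L, calls$meth_count / calls$total_count, 0)
  utils::write.table(
    data.frame(calls$chrom, start0, calls$pos, signif(ratio, 6)),
    ratio_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(calls$chrom, start0, calls$pos, calls$total_count),
    coverage_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(ratio_path)
}

#' Read a BED file of named genomic intervals
#'
#' Three or more whitespace-separated columns: chrom, start (0-based
#' inclusive), end (exclusive), and optionally a name (here: the TF symbol).
#' Overlapping intervals are preserved as-is; no merging.
#'
#' @param path Path to the BED file.
#' @return Data frame with `chrom`, `start`, `end` and (if present) `name`,
#'   sorted by (chrom, start, end).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name", "score", "strand")[1:max(3L, count_bed_cols(path))],
                          fill = TRUE)
  if (!is.numeric(df$start) || !is.numeric(df$end)) {
    stop("malformed BED coordinates in ", path)
  }
  if (any(df$start >= df$end)) {
    i <- which(df$start >= df$end)[1L]
    stop("BED interval with start >= end: ", df$chrom[i], ":", df$start[i], "-", df$end[i])
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

count_bed_cols <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty BED file: ", path)
  length(strsplit(first, "[ \t]+")[[1L]])
}

#' @rdname read_bed
#' @param bed BED data frame (`chrom`, `start`, `end`, optional `name`).
#' @export
write_bed <- function(bed, path) {
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read reduced gene models
#'
#' TSV with columns `gene_id`, `chrom`, `strand`, `tss` (1-based),
#' `exon_starts`, `exon_ends` (comma-separated 0-based half-open intervals,
#' sorted and non-overlapping).
#'
#' @param path Path to the TSV file.
#' @return Data frame with one row per gene; exon coordinates kept as comma
#'   lists plus parsed list-columns `exon_start_list` / `exon_end_list`.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene_id", "chrom", "strand", "tss", "exon_starts", "exon_ends")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("gene model table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df$exon_start_list <- lapply(strsplit(as.character(df$exon_starts), ","), as.integer)
  df$exon_end_list <- lapply(strsplit(as.character(df$exon_ends), ","), as.integer)
  for (i in seq_len(nrow(df))) {
    s <- df$exon_start_list[[i]]; e <- df$exon_end_list[[i]]
    if (length(s) != length(e) || any(s >= e)) {
      stop("malformed exons for gene ", df$gene_id[i])
    }
    if (is.unsorted(s, strictly = TRUE) || any(e[-length(e)] > s[-1L])) {
      stop("exons not sorted/non-overlapping for gene ", df$gene_id[i])
    }
  }
  df
}

#' @rdname read_gene_models
#' @param models Gene-model data frame.
#' @export
write_gene_models <- function(models, path) {
  cols <- c("gene_id", "chrom", "strand", "tss", "exon_starts", "exon_ends")
  utils::write.table(models[cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain numeric TSV matrix (first column = row ids)
#'
#' Used for the mouse 9-zone expression reference and similar summary
#' matrices.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with row names from the first column.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  m
}

#' @rdname read_matrix_tsv
#' @param m Numeric matrix; row names become the first column.
#' @param id_col Name of the id column written first.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a one-to-one orthologue map
#'
#' TSV with columns `human_gene`, `mouse_gene`. Each id may appear at most
#' once on its side of the map.
#'
#' @param path Path to the TSV file.
#' @return Data frame with the two id columns.
#' @export
read_orthologues <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("human_gene", "mouse_gene") %in% names(df))) {
    stop("orthologue map needs columns human_gene, mouse_gene")
  }
  if (anyDuplicated(df$human_gene) || anyDuplicated(df$mouse_gene)) {
    stop("orthologue map is not one-to-one")
  }
  df
}
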