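#' Zone levels of the liver lobule
#'
#' The porto-central axis is discretized into three micro-dissected zones:
#' pericentral (`CV`, around the central vein), intermediate (`IZ`) and
#' periportal (`PV`, around the portal triad). The ordinal encoding
#' CV = 1 < IZ = 2 < PV = 3 is used whenever a zone enters a correlation or
#' gradient computation.
#'
#' @format Character vector of the three canonical zone labels, in ordinal
#'   order.
#' @export
ZONE_LEVELS <- c("CV", "IZ", "PV")

#' Phenotype groups of the donor cohort
#'
#' Histology-defined groups: normal controls (`NC`), healthy obese (`HO`),
#' bland steatosis (`STEA`) and early NASH (`EARLY`).
#'
#' @format Character vector of the four phenotype labels.
#' @export
PHENOTYPE_LEVELS <- c("NC", "HO", "STEA", "EARLY")

#' Convert zone labels to their ordinal encoding
#'
#' @param zone Character vector of zone labels (`CV`, `IZ`, `PV`).
#' @return Integer vector with CV = 1, IZ = 2, PV = 3.
#' @examples
#' zone_ordinal(c("CV", "PV", "IZ"))
#' @export
zone_ordinal <- function(zone) {
  ord <- match(as.character(zone), ZONE_LEVELS)
  if (anyNA(ord)) {
    stop("unknown zone label(s): ",
         paste(unique(setdiff(as.character(zone), ZONE_LEVELS)), collapse = ", "))
  }
  ord
}

# Chromosome names excluded from tiled methylation analysis (mitochondrial
# and sex chromosomes), in common naming variants.
excluded_chroms <- function() {
  c("chrM", "chrMT", "MT", "M", "chrX", "X", "chrY", "Y")
}

is_mito_chrom <- function(chrom) {
  chrom %in% c("chrM", "chrMT", "MT", "M")
}
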