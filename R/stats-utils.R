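#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional on both margins, the count in the top-left cell follows a
#' hypergeometric distribution. The two-sided p-value is the sum of the
#' probabilities of all tables (with the same margins) whose probability does
#' not exceed that of the observed table, with a small relative tolerance for
#' floating-point ties — the standard two-sided convention. The odds ratio
#' reported is the sample odds ratio `ad/bc`; a zero cell yields `Inf` or 0.
#'
#' @param tab 2x2 matrix or length-4 vector `(a, b, c, d)` read row-wise:
#'   `a` = noDMR & noTFBS, `b` = noDMR & TFBS, `c` = DMR & noTFBS,
#'   `d` = DMR & TFBS (any 2x2 cross-tabulation works).
#' @return List with `p` (two-sided p-value) and `odds_ratio`.
#' @examples
#' fisher_exact_2x2(matrix(c(10, 10, 10, 10), 2))  # p = 1, OR = 1
#' @export
fisher_exact_2x2 <- function(tab) {
  x <- as.vector(t(as.matrix(tab)))
  if (length(x) != 4L) stop("need a 2x2 table")
  if (any(x < 0)) stop("negative entries in 2x2 table")
  if (any(x != round(x))) stop("non-integer entries in 2x2 table")
  a <- x[1L]; b <- x[2L]; cc <- x[3L]; d <- x[4L]
  r1 <- a + b
  c1 <- a + cc
  n <- a + b + cc + d
  or <- (a * d) / (b * cc)   # 0/0 -> NaN, x/0 -> Inf
  if (r1 == 0 || c1 == n || c1 == 0 || r1 == n || n == 0) {
    return(list(p = 1, odds_ratio = or))
  }
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  dens <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  list(p = min(1, p), odds_ratio = or)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, kept as a named
#' operation so every stage shares one FDR implementation.
#'
#' @param p Numeric vector of p-values.
#' @return Vector of q-values (monotone step-up adjustment).
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Counts-per-million normalization
#'
#' @param counts Gene-by-sample count matrix.
#' @param lib_sizes Optional library sizes; defaults to column sums of
#'   `counts` (raw library sizes).
#' @return Matrix of CPM values with the dimensions of `counts`.
#' @export
cpm <- function(counts, lib_sizes = colSums(counts)) {
  if (any(lib_sizes <= 0)) stop("sample with non-positive total count")
  sweep(counts, 2L, lib_sizes, "/") * 1e6
}

# Pearson correlation of each column of `scores` with a numeric covariate.
cor_with_covariate <- function(scores, covariate) {
  apply(scores, 2L, function(s) {
    if (stats::sd(s) == 0) return(NA_real_)
    stats::cor(s, covariate)
  })
}
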