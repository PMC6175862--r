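#' Filter genes by expression level
#'
#' Discards genes for which fewer than `min_samples` samples have a
#' counts-per-million value above `min_cpm`. CPM is computed on raw library
#' sizes (total counts per sample before filtering).
#'
#' @param counts Gene-by-sample integer count matrix.
#' @param min_cpm CPM threshold (strict `>`). Default 0.5.
#' @param min_samples Minimum number of samples above the threshold.
#'   Default 5.
#' @return The filtered count matrix.
#' @export
filter_expressed <- function(counts, min_cpm = 0.5, min_samples = 5L) {
  if (nrow(counts) == 0L || ncol(counts) == 0L) stop("empty count matrix")
  keep <- rowSums(cpm(counts) > min_cpm) >= min_samples
  if (!any(keep)) stop("all genes filtered out")
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios normalization factors
#'
#' Composition-correcting scale factors in the style of count-based DE
#' tools: per-sample counts are scaled to their library size, a per-gene
#' pseudo-reference is formed as the geometric mean across samples (over
#' genes positive in all samples), and each sample's factor is the median
#' ratio to that reference, rescaled so the factors have geometric mean 1.
#' The effective library size of a sample is raw library size times its
#' factor.
#'
#' @param counts Filtered gene-by-sample count matrix.
#' @return Named numeric vector of factors, geometric mean 1.
#' @export
normalization_factors <- function(counts) {
  lib <- colSums(counts)
  if (any(lib <= 0)) {
    stop("sample with zero total count: ",
         paste(colnames(counts)[lib <= 0], collapse = ", "))
  }
  rate <- sweep(counts, 2L, lib, "/")
  pos <- rowSums(rate > 0) == ncol(rate)
  if (!any(pos)) stop("no gene expressed in all samples; cannot normalize")
  lgr <- log(rate[pos, , drop = FALSE])
  ref <- rowMeans(lgr)
  f <- exp(apply(lgr - ref, 2L, stats::median))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

# ---- negative binomial GLM engine -----------------------------------------

# IRLS fit of a NB GLM with log link, fixed dispersion phi (var = mu + phi
# mu^2; phi = 0 is Poisson), offset, dense design matrix.
nb_glm_fit <- function(y, X, offset, phi, max_iter = 50L, tol = 1e-8) {
  n <- length(y)
  eta <- log(pmax(y, 0.5)) # includes offset implicitly at start
  beta <- NULL
  dev_old <- Inf
  for (iter in seq_len(max_iter)) {
    mu <- exp(pmin(eta, 30))
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    beta <- fit$coefficients
    if (anyNA(beta)) stop("rank-deficient design in NB GLM")
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    dev <- nb_deviance(y, mu, phi)
    if (abs(dev - dev_old) < tol * (abs(dev) + 0.1)) break
    dev_old <- dev
  }
  mu <- exp(eta)
  w <- mu / (1 + phi * mu)
  XtWX <- crossprod(X * sqrt(w))
  cov_un <- tryCatch(chol2inv(chol(XtWX)), error = function(e) {
    MASS_ginv(XtWX)
  })
  list(beta = beta, se = sqrt(pmax(diag(cov_un), 0)), mu = mu,
       df_residual = n - qr(X)$rank)
}

nb_deviance <- function(y, mu, phi) {
  if (phi <= 0) {
    2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  } else {
    a <- 1 / phi
    2 * sum(ifelse(y > 0, y * log(y / mu), 0) -
              (y + a) * log((y + a) / (mu + a)))
  }
}

# Moore-Penrose fallback for near-singular information matrices.
MASS_ginv <- function(m) {
  s <- svd(m)
  pos <- s$d > max(s$d) * 1e-10
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# Method-of-moments dispersion given fitted means from a donor-adjusted
# Poisson fit: solves sum((y-mu)^2 / (mu(1+phi*mu))) = n - p in phi >= 0.
moment_dispersion <- function(y, mu, df_residual) {
  if (df_residual <= 0) return(0)
  f <- function(phi) sum((y - mu)^2 / (mu * (1 + phi * mu))) - df_residual
  if (f(0) <= 0) return(0)
  upper <- 0.1
  while (f(upper) > 0 && upper < 1e4) upper <- upper * 10
  if (f(upper) > 0) return(upper)
  stats::uniroot(f, c(0, upper), tol = 1e-8)$root
}

# Build the per-gene design matrix for a zonal contrast. Donor blocking
# supersedes donor-level covariates (they are collinear with the donor
# factor); when blocking is off the covariates enter as fixed effects.
# The fit orientation is canonical (higher zone ordinal vs lower) so that
# reversing the user contrast negates the coefficient exactly; the sign to
# apply for the requested orientation is attached as attr "sign".
zonal_design <- function(samples, contrast, donor_blocking = TRUE) {
  canonical <- contrast[order(zone_ordinal(contrast))]
  sign_flip <- if (identical(contrast[1L], canonical[2L])) 1 else -1
  contrast <- canonical
  zone <- factor(as.character(samples$zone), levels = c(contrast[1L], contrast[2L]))
  if (donor_blocking) {
    donor <- factor(samples$donor_id)
    X <- stats::model.matrix(~ donor + zone)
  } else {
    covars <- data.frame(
      phenotype = factor(as.character(samples$phenotype)),
      sex = factor(samples$sex),
      age = samples$age,
      bmi = samples$bmi,
      diabetes = samples$diabetes,
      zone = zone
    )
    # drop constant covariates (e.g. single phenotype group) to keep full rank
    keep <- vapply(covars, function(v) length(unique(v)) > 1L, logical(1L))
    keep["zone"] <- TRUE
    X <- stats::model.matrix(~ ., covars[, keep, drop = FALSE])
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- qrX$pivot[-seq_len(qrX$rank)]
    zone_col <- grep("^zone", colnames(X))
    if (zone_col %in% drop_cols) stop("rank-deficient design: zone aliased")
    message("dropping aliased design column(s): ",
            paste(colnames(X)[drop_cols], collapse = ", "))
    X <- X[, -drop_cols, drop = FALSE]
  }
  attr(X, "sign") <- sign_flip
  X
}

#' Paired zonal differential expression
#'
#' Per-gene negative-binomial log-linear model of counts on zone with donor
#' blocking (default) or donor-level covariates, tested by a Wald test on
#' the zone coefficient. The model is fit by iteratively reweighted least
#' squares with a log link and per-sample offsets equal to the log effective
#' library size (raw size times normalization factor). Dispersion is
#' estimated per gene by method of moments on the residuals of a
#' donor-adjusted Poisson fit, then shrunk 50\% toward a lowess
#' mean-dispersion trend across genes. P-values use a t reference with the
#' residual degrees of freedom and are BH-adjusted across genes.
#'
#' The log2 fold change is oriented `contrast[1]` over `contrast[2]`; with
#' the default `c("PV", "CV")` a positive value means higher periportal
#' expression. A gene is called `PV_high` when `q < fdr` and
#' `log2fc > min_lfc`, `CV_high` when `q < fdr` and `log2fc < -min_lfc`,
#' otherwise `none`.
#'
#' Only samples from the two contrast zones enter the fit, and only donors
#' contributing both zones are kept (the paired design). Intermediate-zone
#' samples are used downstream for profile classification, not here.
#'
#' @param counts Filtered gene-by-sample count matrix.
#' @param samples Sample sheet covering (at least) the count columns.
#' @param contrast Character vector of two zones, numerator first.
#' @param fdr,min_lfc Call thresholds (defaults 0.01 and 1).
#' @param donor_blocking Block on donor (default) instead of donor-level
#'   covariates.
#' @param norm_factors Optional precomputed normalization factors.
#' @return A `data.frame` of class `zonemap_de` with columns `gene_id`,
#'   `log2fc`, `logcpm`, `dispersion`, `p`, `q`, `zonation_call`.
#' @export
fit_zonal_de <- function(counts, samples, contrast = c("PV", "CV"),
                         fdr = 0.01, min_lfc = 1, donor_blocking = TRUE,
                         norm_factors = NULL) {
  stopifnot(length(contrast) == 2L, all(contrast %in% ZONE_LEVELS))
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id)) stop("count columns missing from sample sheet")
  in_contrast <- as.character(samples$zone) %in% contrast
  sub <- samples[in_contrast, , drop = FALSE]
  # paired design: keep donors contributing both contrast zones
  tab <- table(sub$donor_id, as.character(sub$zone))
  complete <- rownames(tab)[rowSums(tab[, contrast, drop = FALSE] > 0) == 2L]
  if (length(complete) < 3L) stop("fewer than 3 complete donor pairs")
  sub <- sub[sub$donor_id %in% complete, , drop = FALSE]
  y_mat <- counts[, sub$sample_id, drop = FALSE]

  if (is.null(norm_factors)) norm_factors <- normalization_factors(y_mat)
  offset <- log(colSums(y_mat) * norm_factors[colnames(y_mat)])
  X <- zonal_design(sub, contrast, donor_blocking)
  zone_col <- grep("^zone", colnames(X))
  fit_sign <- attr(X, "sign")
  n_genes <- nrow(y_mat)

  # pass 1: Poisson fits for means, moment dispersion per gene
  phi_raw <- numeric(n_genes)
  mean_cpm <- rowMeans(cpm(y_mat, colSums(y_mat) * norm_factors[colnames(y_mat)]))
  for (g in seq_len(n_genes)) {
    y <- y_mat[g, ]
    if (all(y == 0)) { phi_raw[g] <- 0; next }
    fit0 <- nb_glm_fit(y, X, offset, phi = 0)
    phi_raw[g] <- moment_dispersion(y, fit0$mu, fit0$df_residual)
  }
  phi_shrunk <- shrink_dispersion(phi_raw, mean_cpm)

  # pass 2: NB fit at the shrunk dispersion, Wald t on the zone coefficient
  log2fc <- p <- numeric(n_genes)
  for (g in seq_len(n_genes)) {
    y <- y_mat[g, ]
    if (all(y == 0)) { log2fc[g] <- 0; p[g] <- 1; next }
    fit <- nb_glm_fit(y, X, offset, phi = phi_shrunk[g])
    b <- fit$beta[zone_col]
    se <- fit$se[zone_col]
    log2fc[g] <- fit_sign * b / log(2)
    p[g] <- if (se <= 0 || !is.finite(se)) 1 else
      2 * stats::pt(-abs(b / se), df = fit$df_residual)
  }
  q <- bh_adjust(p)
  call <- rep("none", n_genes)
  call[q < fdr & log2fc > min_lfc] <- paste0(contrast[1L], "_high")
  call[q < fdr & log2fc < -min_lfc] <- paste0(contrast[2L], "_high")
  res <- data.frame(
    gene_id = rownames(y_mat),
    log2fc = log2fc,
    logcpm = log2(mean_cpm + 0.5),
    dispersion = phi_shrunk,
    p = p,
    q = q,
    zonation_call = call,
    stringsAsFactors = FALSE
  )
  class(res) <- c("zonemap_de", class(res))
  attr(res, "contrast") <- contrast
  attr(res, "n_donors") <- length(complete)
  res
}

# 50% shrinkage of raw moment dispersions toward a lowess trend on mean
# log2 CPM; the trend is floored at a small positive value.
shrink_dispersion <- function(phi_raw, mean_cpm, weight = 0.5) {
  x <- log2(mean_cpm + 0.5)
  if (length(phi_raw) >= 10L && stats::sd(x) > 0) {
    lo <- stats::lowess(x, phi_raw, f = 0.5)
    trend <- stats::approx(lo$x, lo$y, xout = x, rule = 2)$y
  } else {
    trend <- rep(mean(phi_raw), length(phi_raw))
  }
  trend <- pmax(trend, 1e-4)
  pmax(weight * trend + (1 - weight) * phi_raw, 1e-6)
}

#' Per-zone normalized expression profiles
#'
#' Mean CPM per zone for each gene, normalized to the zone with the highest
#' expression (so the maximum is 1 for expressed genes), plus a profile
#' class from [classify_profile()].
#'
#' @param counts Count matrix (all three zones).
#' @param samples Sample sheet.
#' @param flat_tol Flatness tolerance on the max-normalized scale
#'   (default 0.1).
#' @return Data frame with `gene_id`, the normalized zone means `CV`, `IZ`,
#'   `PV`, and `profile_class`.
#' @export
zonation_profiles <- function(counts, samples, flat_tol = 0.1) {
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  cpm_mat <- cpm(counts)
  zmeans <- sapply(ZONE_LEVELS, function(z) {
    idx <- which(as.character(samples$zone) == z)
    if (length(idx) == 0L) stop("missing zone: ", z)
    rowMeans(cpm_mat[, idx, drop = FALSE])
  })
  mx <- apply(zmeans, 1L, max)
  norm <- zmeans / ifelse(mx > 0, mx, 1)
  cls <- apply(norm, 1L, function(m) classify_profile(m, flat_tol = flat_tol))
  data.frame(gene_id = rownames(counts),
             CV = norm[, "CV"], IZ = norm[, "IZ"], PV = norm[, "PV"],
             profile_class = cls,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify a three-zone expression profile
#'
#' Works on max-normalized zone means (CV, IZ, PV). The intermediate zone is
#' a peak (`IZ_peak`) if it exceeds both flanking zones by more than
#' `flat_tol`, a trough (`IZ_trough`) symmetrically; otherwise the profile
#' is a monotone gradient (`CV_high` / `PV_high`) or `flat` when the ends
#' differ by at most `flat_tol`.
#'
#' @param means Numeric vector of three zone means, named or ordered
#'   CV, IZ, PV.
#' @param flat_tol Tolerance on the max-normalized scale (default 0.1).
#' @return One of `"CV_high"`, `"PV_high"`, `"IZ_peak"`, `"IZ_trough"`,
#'   `"flat"`.
#' @examples
#' classify_profile(c(CV = 1.0, IZ = 0.6, PV = 0.2))  # CV_high
#' classify_profile(c(CV = 0.3, IZ = 1.0, PV = 0.3))  # IZ_peak
#' @export
classify_profile <- function(means, flat_tol = 0.1) {
  if (!is.null(names(means))) means <- means[ZONE_LEVELS]
  if (length(means) != 3L || anyNA(means)) stop("need three zone means")
  cv <- means[1L]; iz <- means[2L]; pv <- means[3L]
  if (iz > cv + flat_tol && iz > pv + flat_tol) return("IZ_peak")
  if (iz < cv - flat_tol && iz < pv - flat_tol) return("IZ_trough")
  if (abs(cv - pv) <= flat_tol) return("flat")
  if (cv > pv) "CV_high" else "PV_high"
}
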