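# Shared fixture builders. Everything is generated in code; heavyweight
# default-scale simulations live only in test-acceptance.R.

# A minimal valid sample sheet: n_donors donors x three zones.
make_samples <- function(n_donors = 6L) {
  donors <- sprintf("D%02d", seq_len(n_donors))
  df <- expand.grid(zone = ZONE_LEVELS, donor_id = donors,
                    stringsAsFactors = FALSE)[, c("donor_id", "zone")]
  df$sample_id <- paste(df$donor_id, df$zone, sep = "_")
  df$phenotype <- rep(rep_len(PHENOTYPE_LEVELS, n_donors), each = 3L)
  df$sex <- rep(rep_len(c("F", "M"), n_donors), each = 3L)
  df$age <- rep(seq(35, by = 2, length.out = n_donors), each = 3L)
  df$bmi <- rep(seq(24, by = 1.5, length.out = n_donors), each = 3L)
  df$diabetes <- rep(rep_len(c(FALSE, TRUE), n_donors), each = 3L)
  validate_sample_sheet(df)
}

# A small but feasible simulation configuration (fast; used by most tests).
small_sim_config <- function(seed = 7L, ...) {
  sim_config(seed = seed,
             genes = list(n_genes = 400L),
             methylome = list(n_tiles = 300L, n_dmrs = 30L),
             tfbs = list(n_tfs = 6L, sites_per_tf = 150L, frac_zonated = 0.5),
             ...)
}

# Memoised small simulated dataset shared across test files.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(small_sim_config())
    cache
  }
})

# Independent two-sided Fisher oracle: log-binomial-coefficient
# enumeration over the conditional support (no dhyper).
oracle_fisher_p <- function(a, b, c_, d) {
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n || n == 0) return(1)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  logp <- lchoose(c1, support) + lchoose(n - c1, r1 - support) - lchoose(n, r1)
  p <- exp(logp)
  p_obs <- exp(lchoose(c1, a) + lchoose(n - c1, r1 - a) - lchoose(n, r1))
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Brute-force BH: sort descending, cummin of (n / rank) * p.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  pmin(1, cummin((n / (n:1)) * p[o]))[order(o)]
}

# Exact paired Wilcoxon signed-rank two-sided p by enumerating all sign
# assignments (requires no ties among |d| and no zero differences).
oracle_wilcoxon_exact <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  t_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(t_all <= v), mean(t_all >= v)))
}
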