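# Independent oracles used to cross-check the package implementations.
# These deliberately use a different route than the implementation
# (direct binomial-coefficient enumeration, literal step-up definitions,
# causal-configuration enumeration) so agreement is informative.

# Two-sided Fisher exact p by full enumeration of the hypergeometric
# support from binomial coefficients.
oracle_fisher <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; k <- a + c_; n <- r1 + r2
  support <- max(0, k - r2):min(r1, k)
  prob <- choose(r1, support) * choose(r2, k - support) / choose(n, k)
  p_obs <- choose(r1, a) * choose(r2, c_) / choose(n, k)
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Literal Benjamini-Hochberg step-up: adj_(i) = min_{j >= i} m p_(j) / j,
# capped at 1, mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m * p[ord[j]] / j, 0)
    adj_sorted[i] <- min(1, min(vals))
  }
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

# Colocalization posteriors by explicit enumeration over the causal
# configuration space: no causal variant, one per single trait, ordered
# pairs of distinct variants, and shared variants. All configuration
# weights are divided by exp(c1 + c2), c = max log ABF per trait, so the
# enumeration stays finite for strong signals; the normalisation cancels
# the constant.
oracle_coloc <- function(l1, l2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-4) {
  m <- length(l1)
  c1 <- max(l1); c2 <- max(l2)
  e1 <- exp(l1 - c1); e2 <- exp(l2 - c2)
  w0 <- exp(-c1 - c2)
  w1 <- sum(p1 * e1) * exp(-c2)
  w2 <- sum(p2 * e2) * exp(-c1)
  w3 <- 0
  for (i in seq_len(m)) for (j in seq_len(m))
    if (i != j) w3 <- w3 + p1 * p2 * e1[i] * e2[j]
  w4 <- sum(p12 * e1 * e2)
  w <- c(h0 = w0, h1 = w1, h2 = w2, h3 = w3, h4 = w4)
  w / sum(w)
}

# Fixed-effect IVW as weighted least squares through the origin, solved
# from the normal equations.
oracle_ivw_fixed <- function(pairs) {
  w <- 1 / pairs$se_y^2
  x <- pairs$beta_x; y <- pairs$beta_y
  theta <- sum(w * x * y) / sum(w * x^2)
  list(theta = theta, se = sqrt(1 / sum(w * x^2)))
}

# Greedy maximum-significance independent set, written as a direct filter
# over the p-value order (used against ld_prune).
oracle_prune <- function(records, r2, r2_max) {
  ord <- order(records$pval, records$snp_id)
  kept <- character()
  for (id in records$snp_id[ord]) {
    ok <- TRUE
    for (kid in kept) if (r2[id, kid] >= r2_max) ok <- FALSE
    if (ok) kept <- c(kept, id)
  }
  kept
}

# Small canonical GWAS table builder for IO/harmonization tests.
make_gwas <- function(snp_id, ea, oa, beta, se = 0.02, eaf = 0.3,
                      chrom = "1", pos = seq_along(snp_id) * 1000,
                      pval = 1e-4, n = 10000) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
             effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, pval = pval, n = n,
             stringsAsFactors = FALSE)
}

# Harmonized-pair builder for estimator tests.
make_pairs <- function(beta_x, beta_y, se_x = 0.01, se_y = 0.02,
                       snp_id = sprintf("s%03d", seq_along(beta_x))) {
  data.frame(snp_id = snp_id, beta_x = beta_x, se_x = se_x,
             beta_y = beta_y, se_y = se_y, eaf_x = 0.3, eaf_y = 0.3,
             flipped = FALSE, stringsAsFactors = FALSE)
}

# Harmonized pairs straight from a simulated two-sample study.
sim_pairs <- function(...) {
  s <- simulate_two_sample_gwas(...)
  suppressMessages(harmonize(s$exposure, s$outcome))
}
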