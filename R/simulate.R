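# Synthetic summary-statistics generators with known ground truth, emulating
# every input the pipeline consumes: a SNP universe with matching covariates
# and block LD, a traits x SNPs p-value phenome with planted enriched
# traits, paired exposure/outcome GWAS under a linear causal model with
# optional pleiotropy/heterogeneity, and LD-structured regional statistics
# for colocalization scenarios. All generators are pure functions of their
# parameters and seed; each draws from an independent substream derived from
# the root seed and a label, so adding a generator never perturbs another.

#' Simulate a SNP universe with matching covariates and block LD
#'
#' Covariates follow MAF ~ Uniform(0.01, 0.5), gene density ~ Poisson(8),
#' distance to nearest gene ~ Exponential(mean 20 kb) rounded, LD buddies ~
#' negative binomial (mean 30). LD is block diagonal: consecutive blocks of
#' 5 SNPs with within-block `r^2 = 0.3`. Risk SNPs occupy distinct blocks,
#' and each is guaranteed at least `k_guarantee` matchable candidates by
#' cloning its covariates (with jitter inside the matching tolerances) onto
#' SNPs in otherwise-unused blocks, so the matched-control stage is always
#' feasible by construction.
#'
#' @param n_snps Universe size; must be at least `50 * n_risk`.
#' @param n_risk Number of risk SNPs.
#' @param k_guarantee Matchable candidates guaranteed per risk SNP.
#' @param seed Root seed.
#' @return List with `annotations` (see [read_annotation_table()]), `ld`
#'   (correlation matrix), `risk_ids`, and `guaranteed` (the clone ids per
#'   risk SNP).
#' @export
simulate_snp_universe <- function(n_snps = 50 * n_risk, n_risk = 35,
                                  k_guarantee = 4, seed = 1L) {
  stopifnot(n_snps >= 50 * n_risk)
  n_blocks <- n_snps %/% 5
  if (n_blocks < n_risk * (1 + k_guarantee))
    stop("cannot guarantee ", k_guarantee, " unlinked clones per risk SNP",
         call. = FALSE)
  with_seed(derive_seed(seed, "universe"), {
    ids <- sprintf("snp%05d", seq_len(n_snps))
    ann <- data.frame(
      snp_id = ids,
      maf = stats::runif(n_snps, 0.01, 0.5),
      gene_density = stats::rpois(n_snps, 8),
      dist_nearest_gene = round(stats::rexp(n_snps, 1 / 20000)),
      ld_buddies = stats::rnbinom(n_snps, size = 5, mu = 30),
      stringsAsFactors = FALSE
    )
    block <- (seq_len(n_snps) - 1) %/% 5
    # first SNP of blocks 0..n_risk-1 are the risk SNPs
    risk_idx <- which(block < n_risk & seq_len(n_snps) %% 5 == 1)[seq_len(n_risk)]
    risk_ids <- ids[risk_idx]
    # Risk SNPs take disjoint log-spaced MAF slots so no risk SNP's +/-5%
    # matching window overlaps another's: a guaranteed clone can then never
    # be consumed as a control for a different risk SNP.
    slots <- exp(seq(log(0.012), log(0.49), length.out = n_risk))
    ann$maf[risk_idx] <- sample(slots) * stats::runif(n_risk, 0.999, 1.001)
    guaranteed <- vector("list", n_risk)
    for (i in seq_len(n_risk)) {
      ri <- risk_idx[i]
      clone_blocks <- n_risk + (i - 1) * k_guarantee + seq_len(k_guarantee) - 1
      clone_idx <- clone_blocks * 5 + 1
      # block-mates of a clone are made unmatchable to any risk SNP, so a
      # selected control can never sit in LD with a guaranteed clone
      filler_idx <- setdiff(clone_blocks[1] * 5 + 1:5 +
                              rep((seq_len(k_guarantee) - 1) * 5, each = 5),
                            clone_idx)
      ann$dist_nearest_gene[filler_idx] <- round(stats::runif(
        length(filler_idx), 5e6, 9e6))
      # jitter within the base windows: MAF +/-4% relative, counts/distance
      # +/-30% relative (inside the +/-50% windows)
      for (j in clone_idx) {
        ann$maf[j] <- min(0.5, ann$maf[ri] * stats::runif(1, 0.96, 1.04))
        ann$gene_density[j] <- round(ann$gene_density[ri] *
                                       stats::runif(1, 0.8, 1.2))
        d <- ann$dist_nearest_gene[ri]
        ann$dist_nearest_gene[j] <-
          if (d == 0) round(stats::runif(1, 0, 10000))
          else round(d * stats::runif(1, 0.75, 1.25))
        ann$ld_buddies[j] <- round(ann$ld_buddies[ri] *
                                     stats::runif(1, 0.8, 1.2))
      }
      guaranteed[[i]] <- ids[clone_idx]
    }
    r_within <- sqrt(0.3)
    ld <- matrix(0, n_snps, n_snps, dimnames = list(ids, ids))
    for (b in unique(block)) {
      members <- which(block == b)
      ld[members, members] <- r_within
    }
    diag(ld) <- 1
    list(annotations = ann, ld = ld, risk_ids = risk_ids,
         guaranteed = stats::setNames(guaranteed, risk_ids))
  })
}

#' Simulate a phenome p-value matrix with planted enriched traits
#'
#' For an unplanted trait every SNP is "associated" (p drawn uniformly
#' below `alpha`) independently with probability `base_rate`, otherwise
#' p ~ Uniform(alpha, 1) — an exchangeable null across SNPs. Planted traits
#' use association rate `q1` for risk SNPs and `q0` for all other SNPs.
#'
#' @param snp_ids SNPs to cover (typically risk plus matched controls).
#' @param risk_ids Subset of `snp_ids` the planted rates `q1` apply to.
#' @param n_traits Number of traits.
#' @param planted Data frame with columns `trait` (index in
#'   `1..n_traits` or trait id), `q1`, `q0`; may be empty.
#' @param base_rate Null association rate per SNP-trait pair.
#' @param alpha Nominal threshold the rates refer to (default 0.01).
#' @param seed Root seed.
#' @param n_range Range to draw per-trait sample sizes from.
#' @return A [phenome()] object with attribute `truth` (the planted table).
#' @export
simulate_phenome <- function(snp_ids, risk_ids, n_traits = 2514,
                             planted = data.frame(), base_rate = 0.01,
                             alpha = 0.01, seed = 1L,
                             n_range = c(1000, 461000)) {
  stopifnot(all(risk_ids %in% snp_ids))
  with_seed(derive_seed(seed, "phenome"), {
    traits <- sprintf("trait%04d", seq_len(n_traits))
    S <- length(snp_ids)
    rate <- matrix(base_rate, n_traits, S, dimnames = list(traits, snp_ids))
    if (nrow(planted)) {
      pl_idx <- if (is.numeric(planted$trait)) planted$trait
                else match(planted$trait, traits)
      stopifnot(!anyNA(pl_idx))
      for (r in seq_len(nrow(planted))) {
        rate[pl_idx[r], ] <- planted$q0[r]
        rate[pl_idx[r], risk_ids] <- planted$q1[r]
      }
    }
    assoc <- matrix(stats::runif(n_traits * S), n_traits, S) < rate
    p <- matrix(stats::runif(n_traits * S), n_traits, S,
                dimnames = list(traits, snp_ids))
    p <- ifelse(assoc, p * alpha, alpha + p * (1 - alpha))
    p[p == 0] <- .Machine$double.xmin
    trait_n <- stats::setNames(
      round(stats::runif(n_traits, n_range[1], n_range[2])), traits)
    ph <- phenome(p, trait_n)
    attr(ph, "truth") <- planted
    ph
  })
}

.strand_pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                       c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))

#' Simulate paired exposure/outcome GWAS under a linear causal model
#'
#' True instrument effects `b_j ~ N(0, 0.05^2)` are rejection-sampled until
#' genome-wide detectable at the exposure sample size (|b|/se_x past the
#' normal quantile for `p_sig`). Standard errors follow
#' `1/sqrt(2*maf*(1-maf)*n)` (standardised-trait approximation). The true
#' outcome effect is `theta*b_j + alpha_j`, with pleiotropy
#' `alpha_j ~ N(pleiotropy_mean, pleiotropy_sd^2)` plus heterogeneity
#' `N(0, heterogeneity_sd^2)`; a fraction `prop_invalid` of instruments
#' additionally receives `invalid_effect`. Observed effects are drawn with
#' their standard errors. Some outcome rows are stored with swapped and/or
#' strand-complemented alleles to exercise harmonization; alleles are
#' non-palindromic by construction.
#'
#' @param J Number of instruments.
#' @param theta True causal effect.
#' @param pleiotropy_mean,pleiotropy_sd Directional/balanced pleiotropy.
#' @param heterogeneity_sd Extra per-instrument effect noise.
#' @param n_x,n_y Exposure/outcome GWAS sample sizes.
#' @param prop_invalid Fraction of instruments given `invalid_effect`.
#' @param invalid_effect Pleiotropic offset for invalid instruments.
#' @param p_sig Detection threshold used in the rejection step.
#' @param seed Root seed.
#' @return List with `exposure` and `outcome` canonical record tables and
#'   `truth` (`theta`, per-instrument `b`, `alpha`, `invalid`).
#' @export
simulate_two_sample_gwas <- function(J, theta, pleiotropy_mean = 0,
                                     pleiotropy_sd = 0,
                                     heterogeneity_sd = 0,
                                     n_x = 50000, n_y = 50000,
                                     prop_invalid = 0, invalid_effect = 0,
                                     p_sig = 5e-8, seed = 1L) {
  stopifnot(J >= 1)
  with_seed(derive_seed(seed, "two_sample"), {
    ids <- sprintf("iv%04d", seq_len(J))
    maf <- stats::runif(J, 0.05, 0.5)
    se_x <- 1 / sqrt(2 * maf * (1 - maf) * n_x)
    se_y <- 1 / sqrt(2 * maf * (1 - maf) * n_y)
    zcrit <- stats::qnorm(1 - p_sig / 2)
    # instruments are coded to the exposure-increasing allele (b > 0), the
    # convention under which directional pleiotropy has a common sign
    b <- numeric(J)
    for (j in seq_len(J)) {
      repeat {
        cand <- abs(stats::rnorm(1, 0, 0.05))
        if (cand / se_x[j] > zcrit) { b[j] <- cand; break }
      }
    }
    alpha <- stats::rnorm(J, pleiotropy_mean, pleiotropy_sd) +
      stats::rnorm(J, 0, heterogeneity_sd)
    # invalid instruments are the weakest fraction (smallest true effects):
    # pleiotropy tends to dominate weak instruments, and the valid set then
    # retains the majority of IVW weight — the regime where the weighted
    # median's breakdown property applies
    invalid <- rank(b, ties.method = "first") <= round(prop_invalid * J)
    alpha[invalid] <- alpha[invalid] + invalid_effect
    beta_x <- stats::rnorm(J, b, se_x)
    beta_y <- stats::rnorm(J, theta * b + alpha, se_y)
    al <- .strand_pairs[sample.int(nrow(.strand_pairs), J, replace = TRUE), ,
                        drop = FALSE]
    exposure <- data.frame(
      snp_id = ids, chrom = as.character(sample.int(22, J, replace = TRUE)),
      pos = sample.int(2e8, J), effect_allele = al[, 1],
      other_allele = al[, 2], eaf = maf, beta = beta_x, se = se_x,
      pval = 2 * stats::pnorm(-abs(beta_x / se_x)), n = n_x,
      stringsAsFactors = FALSE
    )
    outcome <- exposure
    outcome$beta <- beta_y
    outcome$se <- se_y
    outcome$pval <- 2 * stats::pnorm(-abs(beta_y / se_y))
    outcome$n <- n_y
    # exercise harmonization: ~30% swapped, ~20% (independently) strand
    # complemented; both are no-ops after harmonize()
    comp <- c(A = "T", T = "A", C = "G", G = "C")
    swap <- stats::runif(J) < 0.3
    flip <- stats::runif(J) < 0.2
    ea <- outcome$effect_allele; oa <- outcome$other_allele
    outcome$effect_allele <- ifelse(swap, oa, ea)
    outcome$other_allele <- ifelse(swap, ea, oa)
    outcome$beta <- ifelse(swap, -outcome$beta, outcome$beta)
    outcome$eaf <- ifelse(swap, 1 - outcome$eaf, outcome$eaf)
    outcome$effect_allele <- ifelse(flip, comp[outcome$effect_allele],
                                    outcome$effect_allele)
    outcome$other_allele <- ifelse(flip, comp[outcome$other_allele],
                                   outcome$other_allele)
    list(exposure = exposure, outcome = outcome,
         truth = list(theta = theta, b = b, alpha = alpha,
                      invalid = invalid, swapped = swap, flipped = flip))
  })
}

#' Simulate an LD-structured two-trait region for colocalization
#'
#' LD follows an AR(1) correlation `Sigma[i,j] = rho^|i-j|`. Each trait's
#' z-vector is drawn from `MVN(Sigma %*% lambda, Sigma)` where `lambda`
#' carries `causal_z` at that trait's causal index (zero vector for a null
#' trait): the marginal z-scores of a single causal variant propagated
#' through LD. Scenarios: `H0` neither trait causal, `H1`/`H2` one trait,
#' `H3` distinct causal variants separated far enough that their LD
#' `r^2 < 0.01`, `H4` a shared variant. Betas are `z * se` with
#' `se = 1/sqrt(2*maf*(1-maf)*n)`.
#'
#' @param m_snps SNPs in the region.
#' @param scenario One of `"H0"`, `"H1"`, `"H2"`, `"H3"`, `"H4"`.
#' @param n1,n2 Per-trait sample sizes.
#' @param rho AR(1) LD parameter.
#' @param causal_z Marginal causal z-score.
#' @param seed Root seed.
#' @return List with `region` (a [region_pair()]) and `truth` (scenario and
#'   causal indices).
#' @export
simulate_coloc_region <- function(m_snps = 50,
                                  scenario = c("H4", "H0", "H1", "H2", "H3"),
                                  n1 = 10000, n2 = 10000, rho = 0.9,
                                  causal_z = 8, seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(m_snps >= 2 || scenario != "H3")
  with_seed(derive_seed(seed, "coloc_region"), {
    idx <- seq_len(m_snps)
    sigma <- rho^abs(outer(idx, idx, "-"))
    lam <- function(cidx) {
      l <- numeric(m_snps)
      if (length(cidx)) l[cidx] <- causal_z
      l
    }
    min_sep <- ceiling(log(0.01) / (2 * log(rho)))
    if (scenario == "H3" && m_snps <= min_sep)
      stop("region too small for unlinked distinct causal variants",
           call. = FALSE)
    c_shared <- sample.int(m_snps, 1)
    c1 <- switch(scenario,
                 H0 = integer(), H2 = integer(),
                 H1 = c_shared, H4 = c_shared,
                 H3 = sample.int(max(1, m_snps - min_sep - 1), 1))
    c2 <- switch(scenario,
                 H0 = integer(), H1 = integer(),
                 H2 = c_shared, H4 = c_shared,
                 H3 = min(m_snps, c1 + min_sep +
                            sample.int(m_snps - c1 - min_sep, 1)))
    z1 <- drop(MASS::mvrnorm(1, sigma %*% lam(c1), sigma))
    z2 <- drop(MASS::mvrnorm(1, sigma %*% lam(c2), sigma))
    maf <- stats::runif(m_snps, 0.05, 0.5)
    se1 <- 1 / sqrt(2 * maf * (1 - maf) * n1)
    se2 <- 1 / sqrt(2 * maf * (1 - maf) * n2)
    region <- region_pair(sprintf("rg%04d", idx),
                          beta1 = z1 * se1, se1 = se1,
                          beta2 = z2 * se2, se2 = se2,
                          type1 = "quantitative", type2 = "binary")
    list(region = region,
         truth = list(scenario = scenario, causal1 = c1, causal2 = c2,
                      ld = sigma, maf = maf))
  })
}
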