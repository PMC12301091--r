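# Bayesian colocalization of two traits' regional summary statistics via
# Wakefield approximate Bayes factors, comparing five hypotheses about a
# region: H0 no causal variant for either trait, H1/H2 a causal variant for
# one trait only, H3 distinct causal variants, H4 a shared causal variant.
# Per-SNP priors p1, p2, p12 are the probabilities that a given SNP is
# causal for trait 1 only, trait 2 only, or both.

#' Filter records to a cis window and optionally exclude the MHC
#'
#' Retains SNPs within `window` bp of the gene region on the gene's
#' chromosome; with `exclude_mhc`, SNPs inside the extended MHC
#' (chr6:26,000,000-34,000,000, GRCh37) are dropped regardless of window,
#' since its long-range LD undermines both instrument validity and
#' single-causal-variant assumptions.
#'
#' @param records Data frame in the canonical record layout with positions.
#' @param gene_region Region string `chr:start-end` for the gene body.
#' @param window Flanking distance in bp (default 1e6, i.e. ±1000 kb).
#' @param exclude_mhc Drop MHC SNPs (default `TRUE`).
#' @return The filtered records.
#' @export
cis_filter <- function(records, gene_region, window = 1e6,
                       exclude_mhc = TRUE) {
  r <- parse_region(gene_region)
  keep <- norm_chrom(records$chrom) == r$chrom &
    records$pos >= r$start - window & records$pos <= r$end + window
  if (exclude_mhc) {
    mhc <- norm_chrom(records$chrom) == "6" &
      records$pos >= 26e6 & records$pos <= 34e6
    keep <- keep & !mhc
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Wakefield log approximate Bayes factor
#'
#' For an estimate `beta` with variance `V = se^2` under a normal effect
#' prior with standard deviation `prior_sd` (so `W = prior_sd^2`), with
#' shrinkage `r = W/(V+W)` and `z = beta/se`:
#' `log ABF = 0.5 * (log(1 - r) + r * z^2)`.
#'
#' @param beta,se Effect estimate and its standard error (vectorised).
#' @param prior_sd Prior effect standard deviation; 0 gives log ABF = 0.
#' @return Log ABF, same length as `beta`.
#' @export
log_abf <- function(beta, se, prior_sd) {
  stopifnot(all(se > 0), all(prior_sd >= 0))
  v <- se^2
  w <- prior_sd^2
  r <- w / (v + w)
  z <- beta / se
  0.5 * (log1p(-r) + r * z^2)
}

#' Construct a two-trait regional summary-statistics pair
#'
#' @param snp_ids Shared SNP ids, ordered; both traits must follow this
#'   order.
#' @param beta1,se1,beta2,se2 Per-SNP effects and standard errors for the
#'   two traits.
#' @param type1,type2 `"quantitative"` or `"binary"` per trait; sets the
#'   default prior effect scale in [coloc_abf()].
#' @param region Optional region string for reporting.
#' @return An object of class `region_pair`.
#' @export
region_pair <- function(snp_ids, beta1, se1, beta2, se2,
                        type1 = "quantitative", type2 = "binary",
                        region = NA_character_) {
  stopifnot(length(snp_ids) >= 1,
            length(beta1) == length(snp_ids), length(se1) == length(snp_ids),
            length(beta2) == length(snp_ids), length(se2) == length(snp_ids),
            all(se1 > 0), all(se2 > 0), !anyDuplicated(snp_ids))
  structure(list(snp_ids = as.character(snp_ids),
                 beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
                 type1 = type1, type2 = type2, region = region),
            class = "region_pair")
}

default_prior_sd <- function(type) if (identical(type, "binary")) 0.2 else 0.15

#' Colocalization posteriors from approximate Bayes factors
#'
#' Assuming at most one causal variant per trait in the region, computes
#' posterior probabilities of H0-H4 from per-SNP Wakefield log ABFs
#' `l1[j]`, `l2[j]`. With `S1 = sum(exp(l1))`, `S2 = sum(exp(l2))` and
#' `S12 = sum(exp(l1 + l2))`, the unnormalised posteriors are
#' H0: 1, H1: `p1*S1`, H2: `p2*S2`, H3: `p1*p2*(S1*S2 - S12)`,
#' H4: `p12*S12`, evaluated in log space with log-sum-exp for overflow
#' safety and normalised to sum to one. A single-SNP region yields
#' `pph3 = 0` exactly (two distinct causal variants are impossible); a
#' negative H3 term from rounding is clamped to zero with a message.
#'
#' @param region A [region_pair()].
#' @param priors List with per-SNP priors `p1`, `p2`, `p12` (defaults
#'   1e-4, 1e-4, 1e-4).
#' @param prior_sd1,prior_sd2 Prior effect standard deviations; default
#'   0.15 for a quantitative trait and 0.2 (log-odds) for a binary trait.
#' @return Object of class `coloc_result`: posteriors `pph` (named
#'   h0..h4), `n_snps`, `priors`, and per-SNP log ABFs `labf1`, `labf2`.
#' @export
coloc_abf <- function(region,
                      priors = list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-4),
                      prior_sd1 = NULL, prior_sd2 = NULL) {
  stopifnot(inherits(region, "region_pair"))
  p1 <- priors$p1; p2 <- priors$p2; p12 <- priors$p12
  stopifnot(p1 > 0, p2 > 0, p12 > 0, p1 + p2 + p12 < 1)
  prior_sd1 <- prior_sd1 %||% default_prior_sd(region$type1)
  prior_sd2 <- prior_sd2 %||% default_prior_sd(region$type2)
  l1 <- log_abf(region$beta1, region$se1, prior_sd1)
  l2 <- log_abf(region$beta2, region$se2, prior_sd2)
  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls12 <- logsumexp(l1 + l2)
  m <- length(l1)
  if (m <= 1000) {
    # exact off-diagonal sum sum_{i != j} exp(l1_i + l2_j); avoids the
    # catastrophic cancellation of S1*S2 - S12 when one SNP dominates both
    grid <- outer(l1, l2, "+")
    diag(grid) <- -Inf
    lh3 <- logsumexp(grid)
  } else {
    lh3 <- logdiffexp(ls1 + ls2, ls12)
    if (!is.finite(lh3))
      message("coloc_abf: H3 term non-positive after rounding; clamped to 0")
  }
  lpost <- c(h0 = 0,
             h1 = log(p1) + ls1,
             h2 = log(p2) + ls2,
             h3 = log(p1) + log(p2) + lh3,
             h4 = log(p12) + ls12)
  pph <- exp(lpost - logsumexp(lpost))
  pph <- pph / sum(pph)
  structure(list(pph = pph, n_snps = length(l1),
                 priors = list(p1 = p1, p2 = p2, p12 = p12),
                 prior_sd = c(prior_sd1, prior_sd2),
                 labf1 = stats::setNames(l1, region$snp_ids),
                 labf2 = stats::setNames(l2, region$snp_ids),
                 region = region$region),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("colocalization over", x$n_snps, "SNPs\n")
  print(round(x$pph, 4))
  cat(sprintf("PP.H4 = %.1f%%\n", 100 * x$pph["h4"]))
  invisible(x)
}

#' Instrument-strength F statistic
#'
#' First-stage strength for one association signal: `F = (beta/se)^2`.
#' The conventional weak-instrument floor is `F >= 10`.
#'
#' @param beta,se Effect estimate and standard error (vectorised).
#' @return Named list with `f` and logical `strong` (`f >= 10`).
#' @export
f_statistic <- function(beta, se) {
  stopifnot(all(se > 0))
  f <- (beta / se)^2
  list(f = f, strong = f >= 10)
}
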