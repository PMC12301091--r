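# Two-sample Mendelian randomization estimators and diagnostics. The model:
# for instrument j with exposure association beta_x[j] (SE se_x[j]) and
# outcome association beta_y[j] (SE se_y[j]), a valid instrument satisfies
# E[beta_y[j]] = theta * beta_x[j]; estimators differ in their robustness to
# violations (directional pleiotropy, invalid instruments).
#
# Conventions (matching the mainstream MR package family): per-SNP weights
# beta_x^2 / se_y^2 (first-order); multiplicative random effects inflate the
# fixed-effect SE by max(1, sqrt(Q/df)); inference is two-sided normal;
# 95% CI = theta +/- 1.96 * se.

mr_estimate <- function(method, theta, se, n_snps,
                        q_stat = NA_real_, q_pval = NA_real_,
                        egger_intercept = NA_real_, intercept_se = NA_real_,
                        intercept_pval = NA_real_) {
  z <- theta / se
  est <- list(
    method = method, theta = theta, se = se,
    ci_low = theta - 1.96 * se, ci_high = theta + 1.96 * se,
    or_ = exp(theta), or_low = exp(theta - 1.96 * se),
    or_high = exp(theta + 1.96 * se),
    pval = 2 * stats::pnorm(-abs(z)),
    n_snps = n_snps, q_stat = q_stat, q_pval = q_pval,
    egger_intercept = egger_intercept, intercept_se = intercept_se,
    intercept_pval = intercept_pval
  )
  class(est) <- "mr_estimate"
  est
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: theta = %.4f (se %.4f), OR = %.3f [%.3f, %.3f], p = %.3g, nSNPs = %d\n",
              x$method, x$theta, x$se, x$or_, x$or_low, x$or_high, x$pval,
              x$n_snps))
  if (!is.na(x$q_stat))
    cat(sprintf("  heterogeneity Q = %.2f, p = %.3g\n", x$q_stat, x$q_pval))
  if (!is.na(x$egger_intercept))
    cat(sprintf("  Egger intercept = %.4f (se %.4f), p = %.3g\n",
                x$egger_intercept, x$intercept_se, x$intercept_pval))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snps = x$n_snps, theta = x$theta,
             se = x$se, pval = x$pval, or_ = x$or_, or_low = x$or_low,
             or_high = x$or_high, q_stat = x$q_stat, q_pval = x$q_pval,
             egger_intercept = x$egger_intercept,
             intercept_pval = x$intercept_pval, stringsAsFactors = FALSE)
}

check_pairs <- function(pairs, min_n = 1) {
  stopifnot(is.data.frame(pairs),
            all(c("beta_x", "se_x", "beta_y", "se_y") %in% names(pairs)))
  if (nrow(pairs) < min_n)
    stop("need at least ", min_n, " instrument(s), got ", nrow(pairs),
         call. = FALSE)
  if (any(pairs$se_x <= 0) || any(pairs$se_y <= 0))
    stop("instrument standard errors must be positive", call. = FALSE)
  invisible(pairs)
}

#' Select MR instruments from a GWAS table
#'
#' Applies the instrument rules: exposure p-value at most `p_max`
#' (inclusive), minor-allele frequency `min(eaf, 1 - eaf)` at least
#' `maf_min`, exclusion of listed genomic regions (e.g. the MHC,
#' chr6:26-34 Mb), then greedy LD pruning at `r2_max`.
#'
#' @param gwas Data frame in the canonical record layout.
#' @param ld Correlation matrix with SNP-id dimnames.
#' @param p_max Significance ceiling (inclusive).
#' @param r2_max Clumping threshold passed to [ld_prune()].
#' @param maf_min Minor-allele frequency floor; records lacking `eaf` are
#'   dropped with a message when `maf_min > 0`.
#' @param exclude_regions Character vector of `chr:start-end` regions whose
#'   SNPs are removed before pruning.
#' @return The retained records, with attribute `selection` recording the
#'   thresholds.
#' @export
select_instruments <- function(gwas, ld, p_max = 5e-8, r2_max = 0.001,
                               maf_min = 0.01, exclude_regions = character()) {
  stopifnot(p_max > 0, p_max < 1, r2_max > 0, r2_max < 1)
  keep <- gwas$pval <= p_max
  if (maf_min > 0) {
    no_eaf <- is.na(gwas$eaf)
    if (any(no_eaf & keep))
      message("select_instruments: dropped ", sum(no_eaf & keep),
              " record(s) lacking EAF under the MAF filter")
    maf <- pmin(gwas$eaf, 1 - gwas$eaf)
    keep <- keep & !no_eaf & maf >= maf_min
  }
  for (reg in exclude_regions) {
    r <- parse_region(reg)
    inside <- norm_chrom(gwas$chrom) == r$chrom &
      gwas$pos >= r$start & gwas$pos <= r$end
    keep <- keep & !inside
  }
  cand <- gwas[keep, , drop = FALSE]
  if (nrow(cand) == 0)
    stop("no instruments survive selection (p <= ", p_max, ", MAF >= ",
         maf_min, ")", call. = FALSE)
  ids <- ld_prune(cand, ld, r2_max)
  out <- cand[match(ids, cand$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "selection") <- list(p_max = p_max, r2_max = r2_max,
                                 maf_min = maf_min,
                                 exclude_regions = exclude_regions)
  out
}

#' Wald ratio for a single instrument
#'
#' `theta = beta_y / beta_x` with first-order delta-method standard error
#' `se_y / |beta_x|` (uncertainty in `beta_x` ignored, the convention for
#' strong instruments).
#'
#' @param pair One-row data frame with `beta_x`, `se_x`, `beta_y`, `se_y`.
#' @return An `mr_estimate`.
#' @export
wald_ratio <- function(pair) {
  check_pairs(pair, 1)
  if (pair$beta_x[1] == 0)
    stop("wald_ratio: undefined for beta_x = 0", call. = FALSE)
  mr_estimate("wald", pair$beta_y[1] / pair$beta_x[1],
              pair$se_y[1] / abs(pair$beta_x[1]), 1L)
}

#' Inverse-variance weighted estimate
#'
#' `theta = sum(beta_x * beta_y / se_y^2) / sum(beta_x^2 / se_y^2)`, the
#' weighted mean of per-SNP Wald ratios with first-order weights.
#' Heterogeneity is Cochran's `Q = sum(w_j * (ratio_j - theta)^2)` on
#' `J - 1` degrees of freedom; under the multiplicative random-effects
#' model the fixed-effect SE is inflated by `max(1, sqrt(Q/(J-1)))`.
#'
#' @param pairs Harmonized instrument data frame (see [harmonize()]).
#' @param model `"multiplicative_random"` (the primary analysis) or
#'   `"fixed"`.
#' @return An `mr_estimate`; with a single instrument it reduces to the
#'   Wald ratio and `Q` is reported absent.
#' @export
mr_ivw <- function(pairs, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  check_pairs(pairs, 1)
  if (all(pairs$beta_x == 0))
    stop("mr_ivw: degenerate, all beta_x are zero", call. = FALSE)
  w <- pairs$beta_x^2 / pairs$se_y^2
  theta <- sum(pairs$beta_x * pairs$beta_y / pairs$se_y^2) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  J <- nrow(pairs)
  method <- if (model == "fixed") "ivw_fe" else "ivw_mre"
  if (J == 1)
    return(mr_estimate(method, theta, se_fixed, 1L))
  ratios <- pairs$beta_y / pairs$beta_x
  q <- sum(w * (ratios - theta)^2)
  q_pval <- stats::pchisq(q, df = J - 1, lower.tail = FALSE)
  se <- if (model == "fixed") se_fixed
        else se_fixed * max(1, sqrt(q / (J - 1)))
  mr_estimate(method, theta, se, J, q_stat = q, q_pval = q_pval)
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of `beta_y` on `beta_x` with weights
#' `1/se_y^2` and a free intercept, after orienting every instrument so
#' `beta_x >= 0`. The slope estimates the causal effect; the intercept is
#' the directional-pleiotropy test. Residual heterogeneity `Q` has `J - 2`
#' degrees of freedom and scales both SEs under the multiplicative
#' random-effects model.
#'
#' @inheritParams mr_ivw
#' @return An `mr_estimate` carrying `egger_intercept`, `intercept_se` and
#'   `intercept_pval`.
#' @export
mr_egger <- function(pairs, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  check_pairs(pairs, 3)
  flip <- sign(pairs$beta_x)
  flip[flip == 0] <- 1
  bx <- pairs$beta_x * flip
  by <- pairs$beta_y * flip
  if (stats::sd(bx) == 0)
    stop("mr_egger: no variation in |beta_x| after orientation",
         call. = FALSE)
  w <- 1 / pairs$se_y^2
  fit <- stats::lm(by ~ bx, weights = w)
  J <- nrow(pairs)
  q <- sum(w * stats::residuals(fit)^2)
  sigma_hat <- sqrt(q / (J - 2))
  # SEs at unit dispersion, then multiplicative random-effects inflation
  X <- cbind(1, bx)
  se_raw <- sqrt(diag(solve(crossprod(X, X * w))))
  phi <- if (model == "fixed") 1 else max(1, sigma_hat)
  slope <- unname(stats::coef(fit)[2]); int <- unname(stats::coef(fit)[1])
  se_slope <- se_raw[2] * phi; se_int <- se_raw[1] * phi
  mr_estimate("egger", slope, unname(se_slope), J,
              q_stat = q,
              q_pval = stats::pchisq(q, df = J - 2, lower.tail = FALSE),
              egger_intercept = int, intercept_se = unname(se_int),
              intercept_pval = 2 * stats::pnorm(-abs(int / se_int)))
}

# Point estimate of the weighted median of per-SNP ratios: with weights
# normalised to 1 and ratios sorted, cumulative midpoint weights
# s_j = cumsum(w)_j - w_j/2; the estimate interpolates linearly between the
# ratios bracketing s = 0.5.
weighted_median_point <- function(ratios, w) {
  ord <- order(ratios)
  th <- ratios[ord]
  wn <- w[ord] / sum(w)
  s <- cumsum(wn) - wn / 2
  if (0.5 <= s[1]) return(th[1])
  if (0.5 >= s[length(s)]) return(th[length(th)])
  stats::approx(s, th, xout = 0.5, ties = "ordered")$y
}

boot_se <- function(pairs, n_boot, seed, point_fun) {
  if (n_boot < 100)
    warning("n_boot < 100 gives an unstable bootstrap SE", call. = FALSE)
  if (n_boot < 1) return(NA_real_)
  with_seed(seed, {
    est <- vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(nrow(pairs), pairs$beta_x, pairs$se_x)
      by <- stats::rnorm(nrow(pairs), pairs$beta_y, pairs$se_y)
      point_fun(by / bx, bx^2 / pairs$se_y^2)
    }, 0)
    stats::sd(est)
  })
}

#' Weighted-median estimator
#'
#' Consistent when instruments carrying at least half the weight are valid.
#' Per-SNP ratio estimates `beta_y/beta_x` are weighted by
#' `beta_x^2/se_y^2`; the estimate is the interpolated weighted median.
#' The SE comes from a parametric bootstrap: `beta_x` and `beta_y` are
#' redrawn from normal distributions with their standard errors and the
#' estimate recomputed.
#'
#' @inheritParams mr_ivw
#' @param n_boot Bootstrap draws for the SE (default 1000; values below 100
#'   warn). `n_boot = 0` skips the bootstrap (SE reported `NA`).
#' @param seed Integer seed for the bootstrap.
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(pairs, n_boot = 1000, seed = 1L) {
  check_pairs(pairs, 3)
  w <- pairs$beta_x^2 / pairs$se_y^2
  if (sum(w) <= 0 || any(!is.finite(w)))
    stop("mr_weighted_median: degenerate weights", call. = FALSE)
  theta <- weighted_median_point(pairs$beta_y / pairs$beta_x, w)
  se <- boot_se(pairs, n_boot, seed, weighted_median_point)
  mr_estimate("weighted_median", theta, se, nrow(pairs))
}

# Mode of the weighted kernel-smoothed ratio density. Bandwidth
# h = phi * 0.9 * min(sd, IQR/1.34) * J^(-1/5) over the positive spread
# measures; h = 0 (all ratios equal) returns the common ratio.
weighted_mode_point <- function(ratios, w, bandwidth_factor = 1) {
  J <- length(ratios)
  wn <- w / sum(w)
  spread <- c(stats::sd(ratios), stats::IQR(ratios) / 1.34)
  spread <- spread[spread > 0]
  if (!length(spread)) return(ratios[1])
  h <- bandwidth_factor * 0.9 * min(spread) * J^(-1 / 5)
  grid <- seq(min(ratios) - 3 * h, max(ratios) + 3 * h, length.out = 512)
  dens <- vapply(grid, function(x) sum(wn * stats::dnorm(x, ratios, h)), 0)
  grid[which.max(dens)]
}

#' Weighted-mode estimator
#'
#' Consistent when the largest homogeneous cluster of instruments is valid.
#' The estimate is the argmax of a weighted normal-kernel density over the
#' per-SNP ratio estimates, evaluated on a 512-point grid spanning the
#' ratios plus three bandwidths; SE by parametric bootstrap as in
#' [mr_weighted_median()].
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_factor Multiplier `phi` on the Silverman-type bandwidth
#'   `0.9 * min(sd, IQR/1.34) * J^(-1/5)` (default 1).
#' @return An `mr_estimate`.
#' @export
mr_weighted_mode <- function(pairs, bandwidth_factor = 1, n_boot = 1000,
                             seed = 1L) {
  check_pairs(pairs, 3)
  w <- pairs$beta_x^2 / pairs$se_y^2
  theta <- weighted_mode_point(pairs$beta_y / pairs$beta_x, w,
                               bandwidth_factor)
  se <- boot_se(pairs, n_boot, seed,
                function(r, w) weighted_mode_point(r, w, bandwidth_factor))
  mr_estimate("weighted_mode", theta, se, nrow(pairs))
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the causal effect excluding each instrument in turn
#' (multiplicative random-effects IVW), plus the all-SNP row labelled
#' `"(all)"`.
#'
#' @param pairs Harmonized instrument data frame with `snp_id`.
#' @return Data frame with `excluded_snp`, `theta`, `se`, `pval`,
#'   `n_snps`; `J + 1` rows.
#' @export
leave_one_out <- function(pairs) {
  check_pairs(pairs, 3)
  one <- function(excl) {
    sub <- if (is.na(excl)) pairs else pairs[pairs$snp_id != excl, ]
    est <- mr_ivw(sub, "multiplicative_random")
    data.frame(excluded_snp = ifelse(is.na(excl), "(all)", excl),
               theta = est$theta, se = est$se, pval = est$pval,
               n_snps = est$n_snps, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(c(pairs$snp_id, NA), one))
  rownames(out) <- NULL
  out
}

#' Phenome-wide MR screen
#'
#' Runs multiplicative random-effects IVW of a fixed exposure instrument
#' set against every trait in an outcome phenome, then adjusts the IVW
#' p-values across analysed traits with [bh_fdr()]. Traits with fewer than
#' two overlapping instruments are skipped with a message.
#'
#' @param exposure Canonical records for the exposure instruments.
#' @param phenome_betas Long data frame of per-trait outcome records:
#'   canonical record columns plus `trait_id`.
#' @param palindrome_policy Passed to [harmonize()].
#' @return Data frame sorted by adjusted p: `trait_id`, `n_snps`, `theta`,
#'   `se`, `pval`, `p_fdr`.
#' @export
mr_phewas <- function(exposure, phenome_betas,
                      palindrome_policy = "drop") {
  stopifnot("trait_id" %in% names(phenome_betas))
  traits <- unique(phenome_betas$trait_id)
  rows <- lapply(traits, function(tr) {
    out_t <- phenome_betas[phenome_betas$trait_id == tr, ]
    pairs <- tryCatch(
      suppressMessages(harmonize(exposure, out_t, palindrome_policy)),
      error = function(e) NULL)
    if (is.null(pairs) || nrow(pairs) < 2) {
      message("mr_phewas: skipping trait '", tr,
              "' (<2 overlapping instruments)")
      return(NULL)
    }
    est <- mr_ivw(pairs, "multiplicative_random")
    data.frame(trait_id = tr, n_snps = est$n_snps, theta = est$theta,
               se = est$se, pval = est$pval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0)
    stop("mr_phewas: no analysable traits", call. = FALSE)
  out$p_fdr <- bh_fdr(out$pval)
  out <- out[order(out$p_fdr, out$pval, out$trait_id), ]
  rownames(out) <- NULL
  out
}

#' Estimator panel for one exposure-outcome direction
#'
#' Runs IVW (multiplicative random effects, the primary analysis),
#' MR-Egger, weighted median and weighted mode on a harmonized instrument
#' set and returns the four-row report table.
#'
#' @inheritParams mr_weighted_median
#' @return Data frame with columns `method`, `n_snps`, `pval`, `or_`,
#'   `or_low`, `or_high`, `q_pval`, `intercept_pval`, `theta`, `se`.
#' @export
mr_panel <- function(pairs, n_boot = 1000, seed = 1L) {
  ests <- list(
    mr_ivw(pairs, "multiplicative_random"),
    mr_egger(pairs),
    mr_weighted_median(pairs, n_boot, derive_seed(seed, "wmedian")),
    mr_weighted_mode(pairs, n_boot = n_boot,
                     seed = derive_seed(seed, "wmode"))
  )
  out <- do.call(rbind, lapply(ests, as.data.frame))
  out[, c("method", "n_snps", "pval", "or_", "or_low", "or_high",
          "q_pval", "intercept_pval", "theta", "se")]
}

#' Bidirectional two-sample MR
#'
#' Direction A->B selects instruments from `gwas_a` (thresholds in
#' `settings_ab`), takes outcome effects from `gwas_b`, harmonizes and runs
#' the full estimator panel; direction B->A is symmetric. Instrument
#' thresholds are direction-specific because each exposure GWAS has its own
#' significance and clumping rules.
#'
#' @param gwas_a,gwas_b Canonical record tables for the two traits.
#' @param ld_a,ld_b LD matrices used for instrument clumping per direction.
#' @param settings_ab,settings_ba Lists with `p_max`, `r2_max`, `maf_min`,
#'   `exclude_regions` for each direction.
#' @param n_boot,seed Bootstrap settings for the median/mode SEs.
#' @return List with elements `a_to_b` and `b_to_a`, each a panel data
#'   frame from [mr_panel()] with attribute `pairs` (the harmonized
#'   instruments).
#' @export
bidirectional_mr <- function(gwas_a, gwas_b, ld_a, ld_b,
                             settings_ab = list(p_max = 1e-5, r2_max = 0.1,
                                                maf_min = 0.01,
                                                exclude_regions = character()),
                             settings_ba = list(p_max = 5e-8, r2_max = 0.001,
                                                maf_min = 0.01,
                                                exclude_regions = character()),
                             n_boot = 1000, seed = 1L) {
  one_direction <- function(exp_gwas, out_gwas, ld, st, label) {
    inst <- select_instruments(exp_gwas, ld, p_max = st$p_max,
                               r2_max = st$r2_max, maf_min = st$maf_min,
                               exclude_regions = st$exclude_regions %||%
                                 character())
    pairs <- harmonize(inst, out_gwas)
    panel <- mr_panel(pairs, n_boot, derive_seed(seed, label))
    attr(panel, "pairs") <- pairs
    panel
  }
  list(a_to_b = one_direction(gwas_a, gwas_b, ld_a, settings_ab, "ab"),
       b_to_a = one_direction(gwas_b, gwas_a, ld_b, settings_ba, "ba"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
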