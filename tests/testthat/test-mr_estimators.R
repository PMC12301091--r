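test_that("instrument selection applies inclusive p, MAF floor and region exclusion", {
  g <- make_gwas(paste0("rs", 1:4), "A", "G", beta = 0.1,
                 eaf = c(0.3, 0.995, 0.3, 0.3),
                 chrom = c("1", "1", "6", "2"),
                 pos = c(1e6, 2e6, 30e6, 5e6),
                 pval = c(1e-5, 1e-8, 1e-9, 2e-5))
  ld <- diag(4); dimnames(ld) <- list(g$snp_id, g$snp_id)
  inst <- select_instruments(g, ld, p_max = 1e-5, r2_max = 0.1,
                             maf_min = 0.01,
                             exclude_regions = "chr6:26000000-34000000")
  # rs1 retained at the boundary (p == p_max), rs2 dropped (MAF 0.005),
  # rs3 dropped (MHC), rs4 dropped (p > p_max)
  expect_identical(inst$snp_id, "rs1")
  expect_error(select_instruments(g, ld, p_max = 1e-12, r2_max = 0.1),
               "no instruments")
})

test_that("wald ratio arithmetic and orientation invariance", {
  pr <- make_pairs(0.1, 0.05, se_y = 0.02)
  w <- wald_ratio(pr)
  expect_equal(w$theta, 0.5)
  expect_equal(w$se, 0.2)
  expect_equal(wald_ratio(make_pairs(0.1, 0))$theta, 0)
  flipped <- make_pairs(-0.1, -0.05, se_y = 0.02)
  expect_equal(wald_ratio(flipped)$theta, w$theta)
  expect_error(wald_ratio(make_pairs(0, 0.05)), "beta_x = 0")
})

test_that("ivw reduces to the wald ratio for one instrument and to the weighted mean", {
  single <- make_pairs(0.1, 0.05, se_y = 0.02)
  e1 <- mr_ivw(single)
  w <- wald_ratio(single)
  expect_equal(e1$theta, w$theta)
  expect_equal(e1$se, w$se)
  expect_true(is.na(e1$q_stat))
  two <- make_pairs(c(1, 1), c(2, 4), se_y = 1)
  expect_equal(mr_ivw(two)$theta, 3.0)
})

test_that("fixed-effect ivw equals weighted least squares through the origin", {
  for (seed in 1:10) {
    h <- sim_pairs(J = 30, theta = 0.25, heterogeneity_sd = 0.01,
                   seed = seed)
    est <- mr_ivw(h, model = "fixed")
    orc <- oracle_ivw_fixed(h)
    expect_equal(est$theta, orc$theta, tolerance = 1e-10)
    expect_equal(est$se, orc$se, tolerance = 1e-10)
    # lm route as a second, independent fit
    fit <- stats::lm(beta_y ~ beta_x - 1, data = h, weights = 1 / h$se_y^2)
    expect_equal(est$theta, unname(coef(fit)), tolerance = 1e-10)
  }
})

test_that("multiplicative random effects never shrink the fixed SE and use chi-square Q", {
  h <- sim_pairs(J = 50, theta = 0.2, heterogeneity_sd = 0.05, seed = 3)
  fe <- mr_ivw(h, "fixed"); re <- mr_ivw(h)
  expect_equal(re$theta, fe$theta)
  expect_gte(re$se, fe$se)
  expect_equal(re$q_pval,
               stats::pchisq(re$q_stat, nrow(h) - 1, lower.tail = FALSE))
  # under heterogeneity the inflation is active
  expect_gt(re$q_stat / (nrow(h) - 1), 1)
})

test_that("egger recovers an exact affine relation with zero residual Q", {
  bx <- c(0.05, 0.08, 0.11, 0.14, 0.2)
  pr <- make_pairs(bx, 0.1 + 0.5 * bx, se_y = 0.02)
  e <- mr_egger(pr)
  expect_equal(e$theta, 0.5, tolerance = 1e-10)
  expect_equal(e$egger_intercept, 0.1, tolerance = 1e-10)
  expect_equal(e$q_stat, 0, tolerance = 1e-10)
  expect_error(mr_egger(make_pairs(c(0.1, 0.1, 0.1), c(1, 2, 3))),
               "variation")
})

test_that("egger equals a weighted regression oracle and orients beta_x >= 0", {
  h <- sim_pairs(J = 40, theta = 0.3, pleiotropy_sd = 0.03, seed = 8)
  e <- mr_egger(h, model = "fixed")
  flip <- sign(h$beta_x); flip[flip == 0] <- 1
  fit <- stats::lm(I(h$beta_y * flip) ~ I(h$beta_x * flip),
                   weights = 1 / h$se_y^2)
  expect_equal(e$theta, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(e$egger_intercept, unname(coef(fit)[1]), tolerance = 1e-10)
  # flipping any subset of pairs leaves the estimate unchanged
  h2 <- h
  idx <- seq(1, 40, by = 3)
  h2$beta_x[idx] <- -h2$beta_x[idx]; h2$beta_y[idx] <- -h2$beta_y[idx]
  for (fn in list(mr_ivw, mr_egger,
                  function(p) mr_weighted_median(p, 0, 1),
                  function(p) mr_weighted_mode(p, n_boot = 0, seed = 1))) {
    expect_equal(suppressWarnings(fn(h2)$theta),
                 suppressWarnings(fn(h)$theta), tolerance = 1e-9)
  }
})

test_that("egger with the intercept constrained to zero recovers fixed ivw", {
  h <- sim_pairs(J = 25, theta = 0.2, seed = 12)
  flip <- sign(h$beta_x); flip[flip == 0] <- 1
  fit0 <- stats::lm(I(h$beta_y * flip) ~ I(h$beta_x * flip) - 1,
                    weights = 1 / h$se_y^2)
  expect_equal(unname(coef(fit0)), mr_ivw(h, "fixed")$theta,
               tolerance = 1e-10)
})

test_that("the weighted median interpolates cumulative midpoint weights", {
  # equal weights on ratios (1, 2, 3): middle midpoint weight is exactly 0.5
  pr <- make_pairs(c(1, 1, 1), c(1, 2, 3), se_y = 1)
  expect_equal(suppressWarnings(mr_weighted_median(pr, 0, 1))$theta, 2.0)
  # hand interpolation with unequal weights: w = (4,1,1)/6 on ratios 1,2,3
  pr2 <- make_pairs(c(2, 1, 1), c(2, 2, 3), se_y = 1)
  s <- cumsum(c(4, 1, 1) / 6) - c(4, 1, 1) / 12
  hand <- stats::approx(s, c(1, 2, 3), xout = 0.5)$y
  expect_equal(suppressWarnings(mr_weighted_median(pr2, 0, 1))$theta, hand)
  # identical ratios collapse to the common value with a tiny bootstrap SE
  pr3 <- make_pairs(c(0.1, 0.2, 0.3), c(0.05, 0.10, 0.15),
                    se_x = 1e-6, se_y = 1e-6)
  wm <- mr_weighted_median(pr3, n_boot = 200, seed = 5)
  expect_equal(wm$theta, 0.5, tolerance = 1e-9)
  expect_lt(wm$se, 1e-4)
  wm2 <- mr_weighted_median(pr3, n_boot = 200, seed = 99)
  expect_equal(wm$theta, wm2$theta)
})

test_that("weighted median lies within the ratio range and duplication moves it at most one knot", {
  for (seed in 1:10) {
    h <- sim_pairs(J = 20, theta = 0.2, pleiotropy_sd = 0.1, seed = seed)
    th <- suppressWarnings(mr_weighted_median(h, 0, 1))$theta
    ratios <- sort(h$beta_y / h$beta_x)
    expect_gte(th, min(ratios)); expect_lte(th, max(ratios))
    # duplicating every pair re-knots the interpolation; the estimate can
    # move only within the gap between adjacent sorted ratios
    dup <- rbind(h, h)
    th_dup <- suppressWarnings(mr_weighted_median(dup, 0, 1))$theta
    expect_lte(abs(th_dup - th), max(diff(ratios)) + 1e-12)
    # and duplication never moves it outside the bracketing ratios
    expect_gte(th_dup, max(ratios[ratios <= min(th, th_dup)]))
  }
})

test_that("weighted mode finds the dominant ratio cluster", {
  pr <- make_pairs(c(0.2, 0.21, 0.19, 0.02), c(0.1, 0.105, 0.095, 0.1),
                   se_y = 0.02)
  ratios <- pr$beta_y / pr$beta_x
  h <- 0.9 * min(sd(ratios), IQR(ratios) / 1.34) * 4^(-1 / 5)
  est <- suppressWarnings(mr_weighted_mode(pr, n_boot = 0, seed = 1))
  expect_lt(abs(est$theta - 0.5), h)
  # all ratios equal: exact common value
  pr2 <- make_pairs(c(0.1, 0.2, 0.4), c(0.05, 0.10, 0.20), se_y = 0.01)
  expect_equal(suppressWarnings(mr_weighted_mode(pr2, n_boot = 0,
                                                 seed = 1))$theta, 0.5)
  # permutation invariance
  h3 <- sim_pairs(J = 15, theta = 0.3, seed = 4)
  perm <- h3[sample(nrow(h3)), ]
  expect_equal(suppressWarnings(mr_weighted_mode(perm, n_boot = 0,
                                                 seed = 1))$theta,
               suppressWarnings(mr_weighted_mode(h3, n_boot = 0,
                                                 seed = 1))$theta)
})

test_that("leave-one-out returns J+1 rows and flags a gross outlier", {
  h <- sim_pairs(J = 10, theta = 0.2, seed = 21)
  h$beta_y[4] <- h$beta_y[4] + 1   # gross outlier
  loo <- leave_one_out(h)
  expect_equal(nrow(loo), 11)
  expect_true("(all)" %in% loo$excluded_snp)
  all_row <- loo[loo$excluded_snp == "(all)", ]
  deltas <- abs(loo$theta[loo$excluded_snp != "(all)"] - all_row$theta)
  expect_equal(which.max(deltas), 4L)
  # identical instruments give identical rows
  same <- make_pairs(rep(0.1, 3), rep(0.05, 3))
  loo2 <- leave_one_out(same)
  expect_equal(length(unique(round(loo2$theta, 12))), 1)
})

test_that("mr_phewas ranks a planted causal trait first with calibrated nulls", {
  s <- simulate_two_sample_gwas(J = 35, theta = 0, n_x = 2e5, n_y = 2e5,
                                seed = 61)
  exposure <- s$exposure
  n_traits <- 40
  blocks <- lapply(seq_len(n_traits), function(t) {
    st <- simulate_two_sample_gwas(J = 35, theta = if (t == 5) 0.3 else 0,
                                   n_x = 2e5, n_y = 2e5, seed = 61)
    out <- st$outcome
    # fresh outcome noise per trait, same instruments
    set.seed(1000 + t)
    theta_t <- if (t == 5) 0.3 else 0
    out$beta <- theta_t * ifelse(st$truth$swapped, -1, 1) * st$truth$b +
      stats::rnorm(35, 0, out$se)
    out$trait_id <- sprintf("tr%02d", t)
    out
  })
  pb <- do.call(rbind, blocks)
  res <- mr_phewas(exposure, pb)
  expect_equal(res$trait_id[1], "tr05")
  expect_lt(res$p_fdr[1], 0.05)
  expect_equal(nrow(res), n_traits)
  expect_true(all(res$n_snps <= 35))
})

test_that("bidirectional_mr detects the causal direction and reports four methods", {
  # A causes B (theta = 0.3); B's GWAS is smaller, so A's instruments stay
  # below B's genome-wide instrument threshold and B's own instruments are
  # a disjoint null set
  s <- simulate_two_sample_gwas(J = 80, theta = 0.3, n_x = 2e5, n_y = 2e4,
                                seed = 77)
  gwas_a <- s$exposure
  gwas_b <- s$outcome      # B records at A's instruments
  # augment B with its own instruments that do nothing to A
  sb <- simulate_two_sample_gwas(J = 60, theta = 0, n_x = 2e5, n_y = 2e5,
                                 seed = 78)
  sb$exposure$snp_id <- sprintf("bv%04d", 1:60)
  sb$outcome$snp_id <- sprintf("bv%04d", 1:60)
  gwas_b2 <- rbind(gwas_b, sb$exposure)
  gwas_a2 <- rbind(gwas_a, sb$outcome)
  ids_a <- gwas_a2$snp_id; ids_b <- gwas_b2$snp_id
  ld_a <- diag(length(ids_a)); dimnames(ld_a) <- list(ids_a, ids_a)
  ld_b <- diag(length(ids_b)); dimnames(ld_b) <- list(ids_b, ids_b)
  res <- suppressMessages(suppressWarnings(bidirectional_mr(
    gwas_a2, gwas_b2, ld_a, ld_b,
    settings_ab = list(p_max = 1e-5, r2_max = 0.1, maf_min = 0.01),
    settings_ba = list(p_max = 5e-8, r2_max = 0.1, maf_min = 0.01),
    n_boot = 100, seed = 5)))
  expect_setequal(res$a_to_b$method,
                  c("ivw_mre", "egger", "weighted_median", "weighted_mode"))
  expect_equal(nrow(res$b_to_a), 4)
  ivw_ab <- res$a_to_b[res$a_to_b$method == "ivw_mre", ]
  ivw_ba <- res$b_to_a[res$b_to_a$method == "ivw_mre", ]
  expect_lt(ivw_ab$pval, 0.05)
  expect_gt(ivw_ba$pval, 0.05)
})
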