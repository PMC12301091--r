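test_that("generators are pure functions of parameters and seed", {
  u1 <- simulate_snp_universe(n_risk = 8, n_snps = 400, seed = 5)
  u2 <- simulate_snp_universe(n_risk = 8, n_snps = 400, seed = 5)
  expect_identical(u1, u2)
  u3 <- simulate_snp_universe(n_risk = 8, n_snps = 400, seed = 6)
  expect_false(identical(u1$annotations$maf, u3$annotations$maf))

  s1 <- simulate_two_sample_gwas(J = 20, theta = 0.2, seed = 9)
  s2 <- simulate_two_sample_gwas(J = 20, theta = 0.2, seed = 9)
  expect_identical(s1, s2)

  r1 <- simulate_coloc_region(m_snps = 20, scenario = "H4", seed = 4)
  r2 <- simulate_coloc_region(m_snps = 20, scenario = "H4", seed = 4)
  expect_identical(r1, r2)

  ph1 <- simulate_phenome(paste0("s", 1:10), paste0("s", 1:3),
                          n_traits = 20, seed = 2)
  ph2 <- simulate_phenome(paste0("s", 1:10), paste0("s", 1:3),
                          n_traits = 20, seed = 2)
  expect_identical(ph1, ph2)
})

test_that("generated tables pass every reader and invariant check", {
  u <- simulate_snp_universe(n_risk = 10, n_snps = 500, seed = 12)
  expect_true(validate_annotations(u$annotations))
  expect_true(validate_ld_matrix(u$ld))
  # universe round-trips through the annotation writer/reader
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(u$annotations, path)
  expect_equal(read_annotation_table(path), u$annotations)

  s <- simulate_two_sample_gwas(J = 30, theta = 0.2, seed = 13)
  for (tab in list(s$exposure, s$outcome)) {
    p <- withr::local_tempfile(fileext = ".tsv")
    write_gwas_table(tab, p)
    back <- read_gwas_table(p)
    expect_equal(attr(back, "n_dropped"), 0L)
    expect_equal(nrow(back), 30)
  }
})

test_that("universe covariates follow the specified distributions", {
  u <- simulate_snp_universe(n_risk = 35, n_snps = 10000, seed = 99)
  ann <- u$annotations
  # exclude engineered rows (risk slots, clones, unmatchable fillers)
  engineered <- c(u$risk_ids, unlist(u$guaranteed))
  plain <- ann[!ann$snp_id %in% engineered &
                 ann$dist_nearest_gene < 4e6, ]
  n <- nrow(plain)
  # MAF ~ U(0.01, 0.5): mean 0.255, var (0.49^2)/12
  expect_lt(abs(mean(plain$maf) - 0.255), 3 * sqrt(0.49^2 / 12 / n))
  # gene density ~ Poisson(8)
  expect_lt(abs(mean(plain$gene_density) - 8), 3 * sqrt(8 / n))
  # distance ~ Exp(mean 20 kb)
  expect_lt(abs(mean(plain$dist_nearest_gene) - 20000),
            3 * 20000 / sqrt(n))
  # LD buddies ~ NB(mean 30, size 5): var = 30 + 30^2/5
  expect_lt(abs(mean(plain$ld_buddies) - 30), 3 * sqrt(210 / n))
  # block LD: within-block r^2 = 0.3, across blocks 0
  expect_equal(u$ld[1, 2]^2, 0.3, tolerance = 1e-12)
  expect_equal(u$ld[1, 6], 0)
})

test_that("phenome association rates match the binomial expectation", {
  snps <- paste0("s", 1:175)
  ph <- simulate_phenome(snps, paste0("s", 1:35), n_traits = 2514,
                         base_rate = 0.01, seed = 44)
  # expected associated count per SNP ~ 25.14, binomial 3 sigma
  counts <- colSums(ph$pvals < 0.01)
  expect_lt(abs(mean(counts) - 2514 * 0.01),
            3 * sqrt(2514 * 0.01 * 0.99 / length(snps)))
  expect_true(all(ph$pvals > 0 & ph$pvals <= 1))
  expect_true(all(ph$trait_n >= 1000))
  # q1 = q0 embeds the planted trait in the null
  ph0 <- simulate_phenome(snps, paste0("s", 1:35), n_traits = 50,
                          planted = data.frame(trait = 3, q1 = 0.05,
                                               q0 = 0.05),
                          base_rate = 0.05, seed = 45)
  a <- count_associations(ph0, paste0("s", 1:35))
  expect_lt(abs(a[3] - 35 * 0.05), 3 * sqrt(35 * 0.05 * 0.95) + 1)
})

test_that("deliberately shuffled alleles are undone by harmonization", {
  s <- simulate_two_sample_gwas(J = 200, theta = 0.25, n_x = 2e5, n_y = 2e5,
                                seed = 21)
  expect_true(any(s$truth$swapped))
  h <- suppressMessages(harmonize(s$exposure, s$outcome))
  expect_equal(nrow(h), 200)
  # ground-truth outcome effect scale is recovered: regression of
  # harmonized beta_y on the true theta*b has slope 1
  truth_y <- s$truth$theta * s$truth$b
  fit <- stats::lm(h$beta_y ~ truth_y[match(h$snp_id, s$exposure$snp_id)])
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.2)
  # estimates identical to an unshuffled construction of the same pairs
  clean <- data.frame(snp_id = s$exposure$snp_id,
                      beta_x = s$exposure$beta, se_x = s$exposure$se,
                      beta_y = ifelse(s$truth$swapped, -s$outcome$beta,
                                      s$outcome$beta),
                      se_y = s$outcome$se, stringsAsFactors = FALSE)
  expect_equal(mr_ivw(h)$theta, mr_ivw(clean)$theta, tolerance = 1e-12)
})

test_that("coloc scenarios place the causal pattern where declared", {
  r4 <- simulate_coloc_region(m_snps = 40, scenario = "H4", seed = 8)
  expect_equal(r4$truth$causal1, r4$truth$causal2)
  r3 <- simulate_coloc_region(m_snps = 50, scenario = "H3", rho = 0.9,
                              seed = 8)
  sep <- abs(r3$truth$causal1 - r3$truth$causal2)
  expect_lt(0.9^(2 * sep), 0.01)   # distinct causals effectively unlinked
  r0 <- simulate_coloc_region(m_snps = 20, scenario = "H0", seed = 8)
  expect_length(r0$truth$causal1, 0)
  expect_length(r0$truth$causal2, 0)
  # H1: trait 1 signal only
  r1 <- simulate_coloc_region(m_snps = 30, scenario = "H1", seed = 8)
  expect_length(r1$truth$causal1, 1)
  expect_length(r1$truth$causal2, 0)
  expect_error(simulate_coloc_region(m_snps = 10, scenario = "H3",
                                     rho = 0.9, seed = 1),
               "too small")
})

test_that("a null two-sample study yields uniform ivw p-values", {
  pv <- vapply(1:200, function(i) {
    h <- sim_pairs(J = 40, theta = 0, n_x = 2e5, n_y = 2e5, seed = 3000 + i)
    mr_ivw(h)$pval
  }, 0)
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})
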