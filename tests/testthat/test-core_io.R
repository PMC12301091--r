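test_that("gwas tables round-trip bit-identically through the canonical dialect", {
  g <- make_gwas(c("rs1", "rs2", "rs3"), c("A", "C", "T"), c("G", "A", "C"),
                 beta = c(0.1, -0.2, 0.05))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gwas_table(g, path)
  back <- read_gwas_table(path)
  expect_equal(attr(back, "n_dropped"), 0L)
  expect_identical(back[names(g)], g)
  # and the re-written file is byte-identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_gwas_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("rows violating record invariants are dropped and counted", {
  g <- make_gwas(c("rs1", "rs2", "rs3", "rs4", "rs5"),
                 c("A", "C", "T", "A", "G"), c("G", "A", "C", "A", "C"),
                 beta = 0.1)
  g$se[2] <- 0          # non-positive SE
  # rs4 has identical alleles already; also plant an out-of-range p
  g$pval[5] <- 0
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gwas_table(g, path)
  expect_message(back <- read_gwas_table(path), "dropped 3")
  expect_equal(attr(back, "n_dropped"), 3L)
  expect_identical(back$snp_id, c("rs1", "rs3"))
})

test_that("column_map reads a foreign dialect identically to the canonical one", {
  g <- make_gwas(c("rs1", "rs2", "rs3"), c("A", "C", "T"), c("G", "A", "C"),
                 beta = c(0.1, -0.2, 0.05))
  canon <- withr::local_tempfile(fileext = ".tsv")
  write_gwas_table(g, canon)
  # eQTLGen-style public column names
  foreign <- data.frame(SNP = g$snp_id, SNPChr = g$chrom, SNPPos = g$pos,
                        AssessedAllele = g$effect_allele,
                        OtherAllele = g$other_allele, AlleleB_all = g$eaf,
                        Zscore_beta = g$beta, SEbeta = g$se,
                        Pvalue = g$pval, NrSamples = g$n)
  fpath <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(foreign, fpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mapped <- read_gwas_table(fpath, column_map = c(
    CHR = "SNPChr", POS = "SNPPos", EA = "AssessedAllele",
    OA = "OtherAllele", EAF = "AlleleB_all", BETA = "Zscore_beta",
    SE = "SEbeta", P = "Pvalue", N = "NrSamples"))
  expect_identical(mapped, read_gwas_table(canon))
})

test_that("missing mandatory columns and empty files are reported", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tCHR\tPOS\tEA\tBETA\tSE\tP",
               "rs1\t1\t100\tA\t0.1\t0.02\t0.5"), path)
  expect_error(read_gwas_table(path), "OA")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("SNP\tCHR\tPOS\tEA\tOA\tEAF\tBETA\tSE\tP\tN", path2)
  expect_warning(empty <- read_gwas_table(path2), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("LD matrices round-trip and are validated", {
  ids <- c("rs1", "rs2", "rs3")
  r <- diag(3); r[1, 2] <- r[2, 1] <- 0.6
  dimnames(r) <- list(ids, ids)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ld_matrix(r, path)
  expect_equal(read_ld_matrix(path), r)
  bad <- r; bad[1, 2] <- 0.9   # asymmetric
  expect_error(write_ld_matrix(bad, path), "symmetric")
})

test_that("outcome alleles swapped relative to exposure flip the beta sign", {
  ex <- make_gwas("rs1", "A", "G", beta = 0.10)
  ou <- make_gwas("rs1", "G", "A", beta = 0.05, eaf = 0.7)
  h <- harmonize(ex, ou)
  expect_equal(h$beta_y, -0.05)
  expect_equal(h$eaf_y, 0.3)
  expect_true(h$flipped)
})

test_that("strand-complemented alleles are treated as matching", {
  ex <- make_gwas("rs1", "A", "G", beta = 0.10)
  ou <- make_gwas("rs1", "T", "C", beta = 0.05)
  h <- harmonize(ex, ou)
  expect_equal(h$beta_y, 0.05)
  expect_false(h$flipped)
  # complement of a swap flips
  ou2 <- make_gwas("rs1", "C", "T", beta = 0.05)
  expect_equal(harmonize(ex, ou2)$beta_y, -0.05)
})

test_that("palindromic SNPs are dropped under the drop policy and oriented by frequency under keep", {
  ex <- make_gwas(c("rs1", "rs2"), c("A", "A"), c("T", "G"),
                  beta = c(0.1, 0.2), eaf = 0.2)
  ou <- make_gwas(c("rs1", "rs2"), c("A", "A"), c("T", "G"),
                  beta = c(0.3, 0.4), eaf = 0.2)
  h <- suppressMessages(harmonize(ex, ou, palindrome_policy = "drop"))
  expect_identical(h$snp_id, "rs2")
  expect_equal(attr(h, "n_palindromic_dropped"), 1L)
  # keep: same minor-allele side, no flip
  hk <- harmonize(ex, ou, palindrome_policy = "keep")
  expect_equal(nrow(hk), 2)
  expect_false(hk$flipped[hk$snp_id == "rs1"])
  # keep: opposite side implies the strands refer to opposite alleles
  ou_flip <- ou; ou_flip$eaf <- c(0.8, 0.2)
  hk2 <- harmonize(ex, ou_flip, palindrome_policy = "keep")
  expect_true(hk2$flipped[hk2$snp_id == "rs1"])
  expect_equal(hk2$beta_y[hk2$snp_id == "rs1"], -0.3)
  # keep: frequency near 0.5 is uninformative, SNP dropped
  ou_amb <- ou; ou_amb$eaf <- c(0.52, 0.3)
  hk3 <- suppressMessages(harmonize(ex, ou_amb, palindrome_policy = "keep"))
  expect_false("rs1" %in% hk3$snp_id)
})

test_that("harmonize is idempotent on aligned pairs and errors on empty overlap", {
  s <- simulate_two_sample_gwas(J = 40, theta = 0.2, seed = 42)
  h1 <- suppressMessages(harmonize(s$exposure, s$outcome))
  # re-express the harmonized outcome as records aligned to the exposure
  aligned <- s$exposure
  aligned$beta <- h1$beta_y[match(aligned$snp_id, h1$snp_id)]
  aligned <- aligned[!is.na(aligned$beta), ]
  h2 <- harmonize(s$exposure, aligned)
  expect_false(any(h2$flipped))
  expect_equal(h2$beta_y, h1$beta_y[match(h2$snp_id, h1$snp_id)])
  other <- make_gwas("zzz", "A", "G", beta = 0.1)
  expect_error(harmonize(s$exposure, other), "overlap")
})

test_that("exactly one allele transformation explains every emitted pair", {
  s <- simulate_two_sample_gwas(J = 150, theta = 0.2, seed = 9)
  h <- suppressMessages(harmonize(s$exposure, s$outcome))
  ex <- s$exposure[match(h$snp_id, s$exposure$snp_id), ]
  ou <- s$outcome[match(h$snp_id, s$outcome$snp_id), ]
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  same <- ou$effect_allele == ex$effect_allele
  swap <- ou$effect_allele == ex$other_allele
  flip_same <- comp[ou$effect_allele] == ex$effect_allele
  flip_swap <- comp[ou$effect_allele] == ex$other_allele
  # non-palindromic alleles: aligned cases are exactly the non-flipped ones
  expect_identical(unname(swap | flip_swap), h$flipped)
  expect_true(all(same | swap | flip_same | flip_swap))
  # flipped pairs recover the pre-swap simulated outcome effect
  raw_y <- ifelse(s$truth$swapped[match(h$snp_id, s$outcome$snp_id)],
                  -ou$beta, ou$beta)
  expect_equal(h$beta_y, raw_y)
})
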