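#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study inputs with known ground truth.
#
# Emulates the real study's data layout without any biobank download:
#   * a 1750-SNP universe with matching covariates and block LD, holding the
#     35 independent disease risk loci,
#   * a 2514-trait phenome of SNP-trait association p-values with one
#     planted enriched trait (risk-SNP association rate 0.45 vs 0.05),
#   * per-trait outcome effect tables for the phenome-wide MR screen, with
#     one planted causal trait (theta = 0.3),
#   * paired exposure/outcome GWAS for bidirectional MR (A causes B at
#     theta = 0.3; B's own instruments are null for A),
#   * two regional summary-statistics pairs for colocalization: one sharing
#     a causal variant (H4), one with distinct causal variants (H3).
#
# Usage: Rscript analysis/01_simulate_inputs.R [seed]
suppressPackageStartupMessages(library(phemr))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 2026L
dir <- "analysis/data/synthetic"
dir.create(dir, showWarnings = FALSE, recursive = TRUE)
msg <- function(...) message("[01_simulate] ", ...)

## SNP universe, risk loci, annotations, LD
u <- simulate_snp_universe(n_risk = 35, n_snps = 1750, seed = seed)
write_annotation_table(u$annotations, file.path(dir, "annotations.tsv"))
write_ld_matrix(u$ld, file.path(dir, "ld.tsv"))
risk_gwas <- data.frame(
  snp_id = u$annotations$snp_id, chrom = "2",
  pos = seq_len(nrow(u$annotations)) * 1e4,
  effect_allele = "A", other_allele = "G", eaf = u$annotations$maf,
  beta = 0.1, se = 0.02,
  pval = ifelse(u$annotations$snp_id %in% u$risk_ids, 1e-9, 0.5),
  n = 30000, stringsAsFactors = FALSE)
write_gwas_table(risk_gwas, file.path(dir, "risk_gwas.tsv"))
msg("universe: 1750 SNPs, 35 risk loci, block LD written")

## Phenome with one planted enriched trait (trait0042)
ph <- simulate_phenome(u$annotations$snp_id, u$risk_ids, n_traits = 2514,
                       planted = data.frame(trait = 42, q1 = 0.45,
                                            q0 = 0.05),
                       base_rate = 0.01, seed = seed)
long <- data.frame(
  TRAIT = rep(rownames(ph$pvals), ncol(ph$pvals)),
  SNP = rep(colnames(ph$pvals), each = nrow(ph$pvals)),
  P = as.vector(ph$pvals),
  N = rep(unname(ph$trait_n), ncol(ph$pvals)))
utils::write.table(long, file.path(dir, "phenome.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
msg("phenome: 2514 traits x 1750 SNPs, planted enriched trait0042")

## Phenome-wide MR outcome betas: 150 traits, trait mr0005 causal
s0 <- simulate_two_sample_gwas(J = 35, theta = 0, n_x = 2e5, n_y = 2e5,
                               seed = seed + 1)
mr_exposure <- s0$exposure
write_gwas_table(mr_exposure, file.path(dir, "mr_exposure.tsv"))
set.seed(seed + 2)
blocks <- lapply(1:150, function(t) {
  out <- s0$outcome
  theta_t <- if (t == 5) 0.3 else 0
  out$beta <- theta_t * ifelse(s0$truth$swapped, -1, 1) * s0$truth$b +
    stats::rnorm(35, 0, out$se)
  out$pval <- 2 * stats::pnorm(-abs(out$beta / out$se))
  cbind(TRAIT = sprintf("mr%04d", t),
        data.frame(SNP = out$snp_id, CHR = out$chrom, POS = out$pos,
                   EA = out$effect_allele, OA = out$other_allele,
                   EAF = out$eaf, BETA = out$beta, SE = out$se,
                   P = out$pval, N = out$n))
})
utils::write.table(do.call(rbind, blocks),
                   file.path(dir, "phenome_betas.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
msg("MR-PheWAS outcomes: 150 traits, planted causal trait mr0005")

## Bidirectional MR inputs
s <- simulate_two_sample_gwas(J = 60, theta = 0.3, n_x = 2e5, n_y = 2e4,
                              seed = seed + 3)
sb <- simulate_two_sample_gwas(J = 40, theta = 0, n_x = 2e5, n_y = 2e5,
                               seed = seed + 4)
sb$exposure$snp_id <- sb$outcome$snp_id <- sprintf("bv%04d", 1:40)
gwas_a <- rbind(s$exposure, sb$outcome)
gwas_b <- rbind(s$outcome, sb$exposure)
write_gwas_table(gwas_a, file.path(dir, "exposure.tsv"))
write_gwas_table(gwas_b, file.path(dir, "outcome.tsv"))
idm <- diag(nrow(gwas_a)); dimnames(idm) <- list(gwas_a$snp_id,
                                                 gwas_a$snp_id)
write_ld_matrix(idm, file.path(dir, "iv_ld.tsv"))
msg("bidirectional MR: A->B theta = 0.3 over 60 instruments; ",
    "40 null B instruments")

## Colocalization regions: geneA shares a causal variant, geneB does not
for (spec in list(list(name = "geneA", scenario = "H4", off = 5),
                  list(name = "geneB", scenario = "H3", off = 6))) {
  r <- simulate_coloc_region(m_snps = 50, scenario = spec$scenario,
                             n1 = 10000, n2 = 10000, rho = 0.9,
                             causal_z = 8, seed = seed + spec$off)
  rg <- r$region
  base <- data.frame(
    snp_id = rg$snp_ids, chrom = "11",
    pos = 64e6 + seq_along(rg$snp_ids) * 5000,
    effect_allele = "A", other_allele = "G",
    eaf = r$truth$maf, beta = rg$beta1, se = rg$se1,
    pval = 2 * stats::pnorm(-abs(rg$beta1 / rg$se1)), n = 10000,
    stringsAsFactors = FALSE)
  write_gwas_table(base, file.path(dir, paste0("eqtl_", spec$name, ".tsv")))
  base$beta <- rg$beta2; base$se <- rg$se2
  base$pval <- 2 * stats::pnorm(-abs(rg$beta2 / rg$se2))
  write_gwas_table(base, file.path(dir, paste0("trait_", spec$name, ".tsv")))
}
man <- data.frame(
  NAME = c("geneA", "geneB"),
  FILE1 = c("eqtl_geneA.tsv", "eqtl_geneB.tsv"),
  FILE2 = c("trait_geneA.tsv", "trait_geneB.tsv"),
  TYPE1 = "quantitative", TYPE2 = "binary",
  REGION = "chr11:64000000-64260000", stringsAsFactors = FALSE)
utils::write.table(man, file.path(dir, "coloc_manifest.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
msg("coloc regions: geneA (shared causal variant), geneB (distinct)")
msg("done; inputs under ", dir)
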