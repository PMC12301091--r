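#!/usr/bin/env Rscript
# Stage 2 — risk-locus pruning, matched-control selection, PheWAS
# enrichment. Reads the stage-1 inputs, prunes genome-wide-significant loci
# at r^2 >= 0.001, matches 4 covariate-matched unlinked controls per risk
# SNP, counts nominal (p < 0.01) SNP-trait associations, and tests
# per-trait enrichment of risk vs control SNPs by Fisher's exact test with
# Benjamini-Hochberg correction.
#
# Usage: Rscript analysis/02_phewas_enrichment.R [seed]
suppressPackageStartupMessages(library(phemr))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 2026L
dir <- "analysis/data/synthetic"
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
msg <- function(...) message("[02_enrichment] ", ...)

gwas <- read_gwas_table(file.path(dir, "risk_gwas.tsv"))
ld <- read_ld_matrix(file.path(dir, "ld.tsv"))
ann <- read_annotation_table(file.path(dir, "annotations.tsv"))

risk_ids <- ld_prune(gwas[gwas$pval < 5e-8, ], ld, r2_max = 0.001)
msg(length(risk_ids), " independent risk loci at p < 5e-8, r2 < 0.001")

matches <- match_controls(risk_ids, ann, ld, k = 4, seed = seed)
utils::write.table(matches, file.path(out, "matched_controls.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
msg(nrow(matches), " matched controls (", length(risk_ids), " + ",
    nrow(matches), " = ", length(risk_ids) + nrow(matches),
    " SNPs in the design)")

phen <- read_phenome_long(file.path(dir, "phenome.tsv"), min_n = 1000)
res <- enrich(phen, risk_ids, matches$control_snp_id, alpha = 0.01)
msg(attr(res, "m_tested"), " traits with >= 1 associated risk SNP; ",
    sum(res$p_fdr < 0.05), " significant after FDR")

report <- data.frame(
  trait = res$trait_id,
  associated_risk_snps = sprintf("%d/%d", res$a, res$n_risk),
  associated_control_snps = sprintf("%d/%d", res$b, res$n_control),
  p = res$p_fisher, p_fdr = res$p_fdr, stringsAsFactors = FALSE)
utils::write.table(report, file.path(out, "enrichment.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(trait = res$trait_id, neg_log10_p = -log10(res$p_fisher)),
  file.path(out, "phewas_manhattan.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

msg("top of the enrichment table:")
print(utils::head(report, 5), row.names = FALSE)
msg("wrote ", file.path(out, "enrichment.tsv"))
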