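#!/usr/bin/env Rscript
# Stage 3 — phenome-wide MR screen. Uses the fixed risk-locus instrument
# set as the exposure and runs multiplicative random-effects IVW against
# every trait's outcome effects, with FDR correction across traits.
#
# Usage: Rscript analysis/03_mr_phewas.R
suppressPackageStartupMessages(library(phemr))

dir <- "analysis/data/synthetic"
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
msg <- function(...) message("[03_mr_phewas] ", ...)

exposure <- read_gwas_table(file.path(dir, "mr_exposure.tsv"))
pb_raw <- utils::read.delim(file.path(dir, "phenome_betas.tsv"),
                            stringsAsFactors = FALSE)
pb <- data.frame(trait_id = pb_raw$TRAIT, snp_id = pb_raw$SNP,
                 chrom = as.character(pb_raw$CHR), pos = pb_raw$POS,
                 effect_allele = pb_raw$EA, other_allele = pb_raw$OA,
                 eaf = pb_raw$EAF, beta = pb_raw$BETA, se = pb_raw$SE,
                 pval = pb_raw$P, n = pb_raw$N, stringsAsFactors = FALSE)

res <- mr_phewas(exposure, pb)
utils::write.table(res, file.path(out, "mr_phewas.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
n_sig <- sum(res$p_fdr < 0.05)
msg(nrow(res), " traits screened with ", res$n_snps[1],
    " instruments; ", n_sig, " significant after FDR")
msg("top of the MR-PheWAS table:")
print(utils::head(res, 5), row.names = FALSE)
msg("wrote ", file.path(out, "mr_phewas.tsv"))
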