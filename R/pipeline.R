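# End-to-end orchestration: prune -> match -> enrich -> MR-PheWAS ->
# bidirectional MR -> colocalization, from a validated configuration, with
# every threshold, seed, dropped-record count and FDR family size logged.
# Stages whose inputs are not configured are skipped and recorded as such,
# so partial analyses (e.g. enrichment only) are first-class.

#' Build or validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file holding one) with a
#' `paths` section and a `params` section. Recognised paths:
#' `risk_gwas`, `ld`, `annotations`, `phenome` (long TSV),
#' `phenome_betas` (long canonical records + TRAIT column, for MR-PheWAS),
#' `exposure_gwas`, `outcome_gwas`, `exposure_ld`, `outcome_ld`
#' (bidirectional MR), `coloc_manifest` (TSV: NAME, FILE1, FILE2, TYPE1,
#' TYPE2, REGION). Defaults for `params` follow the study design:
#' `alpha = 0.01`, `k = 4`, matching tolerances 0.05/0.5/0.5/0.5,
#' `independence_r2 = 0.1`, risk-locus selection `p < 5e-8` at
#' `r^2 >= 0.001`, secondary-exposure selection `p <= 1e-5` at
#' `r^2 >= 0.1`, `maf_min = 0.01`, coloc priors `1e-4/1e-4/1e-4`,
#' `cis_window = 1e6`, MHC exclusion `chr6:26000000-34000000`,
#' `min_trait_n = 1000`, `pph4_threshold = 0.8`, `n_boot = 1000`.
#'
#' @param config Named list or path to a YAML file.
#' @return Validated config list with defaults filled in.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(
    alpha = 0.01, k = 4,
    tolerances = list(maf = 0.05, density = 0.5, distance = 0.5,
                      buddies = 0.5),
    independence_r2 = 0.1,
    risk_p_max = 5e-8, risk_r2_max = 0.001,
    exposure_p_max = 1e-5, exposure_r2_max = 0.1,
    maf_min = 0.01,
    priors = list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-4),
    cis_window = 1e6, exclude_mhc = TRUE,
    mhc_region = "chr6:26000000-34000000",
    min_trait_n = 1000, pph4_threshold = 0.8, n_boot = 1000
  )
  params <- utils::modifyList(defaults, config$params %||% list())
  paths <- config$paths %||% list()
  if (is.null(config$seed))
    stop("pipeline config: 'seed' is required (stochastic stages)",
         call. = FALSE)
  for (nm in names(paths))
    if (!file.exists(paths[[nm]]))
      stop("pipeline config: path '", nm, "' does not exist: ", paths[[nm]],
           call. = FALSE)
  stopifnot(params$alpha > 0, params$alpha < 1, params$k >= 1,
            params$maf_min >= 0, params$independence_r2 > 0,
            params$cis_window >= 0)
  list(paths = paths, params = params, seed = as.integer(config$seed))
}

#' Run the full analysis pipeline
#'
#' Executes, in order and where configured: risk-locus LD pruning, matched
#' control selection, PheWAS enrichment, MR-PheWAS screening, bidirectional
#' two-sample MR, and per-region colocalization. All outputs are
#' deterministic given the config (all randomness flows from its single
#' seed).
#'
#' @param config A list or YAML path accepted by [pipeline_config()].
#' @return A bundle list with elements `risk_ids`, `matches`,
#'   `enrichment`, `mr_phewas`, `bidirectional`, `coloc`, and `log`
#'   (character vector of stage messages).
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  paths <- cfg$paths; par <- cfg$params
  bundle <- list(config = cfg, log = character())
  note <- function(...) {
    line <- paste0(...)
    message("pipeline: ", line)
    bundle$log <<- c(bundle$log, line)
  }

  risk_ids <- NULL; ld <- NULL
  if (!is.null(paths$ld)) ld <- read_ld_matrix(paths$ld)
  if (!is.null(paths$risk_gwas)) {
    gwas <- read_gwas_table(paths$risk_gwas)
    note("risk GWAS: ", nrow(gwas), " records, ",
         attr(gwas, "n_dropped"), " dropped")
    sig <- gwas[gwas$pval < par$risk_p_max, , drop = FALSE]
    risk_ids <- ld_prune(sig, ld, par$risk_r2_max)
    note("risk loci: ", length(risk_ids), " independent at p < ",
         par$risk_p_max, ", r2 < ", par$risk_r2_max)
    bundle$risk_ids <- risk_ids
  }

  if (!is.null(paths$annotations) && !is.null(risk_ids)) {
    ann <- read_annotation_table(paths$annotations)
    bundle$matches <- match_controls(
      risk_ids, ann, ld, k = par$k, tolerances = par$tolerances,
      independence_r2 = par$independence_r2,
      seed = derive_seed(cfg$seed, "match"))
    note("matched controls: ", nrow(bundle$matches), " (k = ", par$k, ")")
  }

  if (!is.null(paths$phenome) && !is.null(risk_ids) &&
      !is.null(bundle$matches)) {
    phen <- read_phenome_long(paths$phenome, min_n = par$min_trait_n)
    bundle$enrichment <- enrich(phen, risk_ids,
                                bundle$matches$control_snp_id,
                                alpha = par$alpha)
    note("enrichment: ", attr(bundle$enrichment, "m_tested"),
         " traits in FDR family, ",
         sum(bundle$enrichment$p_fdr < 0.05), " at FDR < 0.05")
  }

  if (!is.null(paths$phenome_betas) && !is.null(risk_ids) &&
      !is.null(paths$risk_gwas)) {
    pb <- utils::read.delim(paths$phenome_betas, sep = "\t",
                            stringsAsFactors = FALSE)
    pb <- data.frame(
      trait_id = pb$TRAIT, snp_id = pb$SNP, chrom = norm_chrom(pb$CHR),
      pos = pb$POS, effect_allele = pb$EA, other_allele = pb$OA,
      eaf = pb$EAF, beta = pb$BETA, se = pb$SE, pval = pb$P,
      n = if ("N" %in% names(pb)) pb$N else NA_real_,
      stringsAsFactors = FALSE)
    expo <- gwas[match(risk_ids, gwas$snp_id), , drop = FALSE]
    bundle$mr_phewas <- mr_phewas(expo, pb)
    note("MR-PheWAS: ", nrow(bundle$mr_phewas), " traits analysed, ",
         sum(bundle$mr_phewas$p_fdr < 0.05), " at FDR < 0.05")
  }

  if (!is.null(paths$exposure_gwas) && !is.null(paths$outcome_gwas)) {
    ga <- read_gwas_table(paths$exposure_gwas)
    gb <- read_gwas_table(paths$outcome_gwas)
    ld_a <- read_ld_matrix(paths$exposure_ld)
    ld_b <- read_ld_matrix(paths$outcome_ld)
    mhc <- if (par$exclude_mhc) par$mhc_region else character()
    bundle$bidirectional <- bidirectional_mr(
      ga, gb, ld_a, ld_b,
      settings_ab = list(p_max = par$exposure_p_max,
                         r2_max = par$exposure_r2_max,
                         maf_min = par$maf_min, exclude_regions = mhc),
      settings_ba = list(p_max = par$risk_p_max, r2_max = par$risk_r2_max,
                         maf_min = par$maf_min, exclude_regions = mhc),
      n_boot = par$n_boot, seed = derive_seed(cfg$seed, "mr"))
    note("bidirectional MR: ",
         bundle$bidirectional$a_to_b$n_snps[1], " / ",
         bundle$bidirectional$b_to_a$n_snps[1], " instruments per direction")
  }

  if (!is.null(paths$coloc_manifest)) {
    man <- utils::read.delim(paths$coloc_manifest, sep = "\t",
                             stringsAsFactors = FALSE)
    res <- lapply(seq_len(nrow(man)), function(i) {
      t1 <- read_gwas_table(file.path(dirname(paths$coloc_manifest),
                                      man$FILE1[i]))
      t2 <- read_gwas_table(file.path(dirname(paths$coloc_manifest),
                                      man$FILE2[i]))
      t1 <- cis_filter(t1, man$REGION[i], window = par$cis_window,
                       exclude_mhc = par$exclude_mhc)
      t2 <- t2[match(t1$snp_id, t2$snp_id), , drop = FALSE]
      keep <- !is.na(t2$snp_id)
      t1 <- t1[keep, ]; t2 <- t2[keep, ]
      rp <- region_pair(t1$snp_id, t1$beta, t1$se, t2$beta, t2$se,
                        type1 = man$TYPE1[i], type2 = man$TYPE2[i],
                        region = man$REGION[i])
      cr <- coloc_abf(rp, priors = par$priors)
      fmax <- max(f_statistic(t1$beta, t1$se)$f)
      data.frame(name = man$NAME[i], region = man$REGION[i],
                 n_snps = cr$n_snps,
                 pph0 = cr$pph["h0"], pph1 = cr$pph["h1"],
                 pph2 = cr$pph["h2"], pph3 = cr$pph["h3"],
                 pph4 = cr$pph["h4"], max_f = fmax,
                 colocalized = unname(cr$pph["h4"] > par$pph4_threshold),
                 stringsAsFactors = FALSE)
    })
    bundle$coloc <- do.call(rbind, res)
    rownames(bundle$coloc) <- NULL
    note("colocalization: ", nrow(bundle$coloc), " region(s), ",
         sum(bundle$coloc$colocalized), " with PP.H4 > ",
         par$pph4_threshold)
  }
  bundle
}

#' Write report tables for a pipeline bundle
#'
#' Emits tab-separated reports mirroring the study's table layouts:
#' `enrichment.tsv` (trait, associated risk and control counts as `a/n`,
#' Fisher p, FDR-corrected p), `mr_phewas.tsv`, `mr_<direction>.tsv`
#' (method, nSNPs, p, OR with 95% CI, heterogeneity and pleiotropy p),
#' `coloc.tsv` (region, nSNPs, posteriors, PP.H4 as a percentage), a
#' Manhattan-style `phewas_manhattan.tsv` (trait, -log10 p) and
#' `run_log.txt`.
#'
#' @param bundle Result of [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
render_reports <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, p)
  }
  if (!is.null(bundle$enrichment)) {
    e <- bundle$enrichment
    emit(data.frame(
      trait = e$trait_id,
      associated_risk_snps = sprintf("%d/%d", e$a, e$n_risk),
      associated_control_snps = sprintf("%d/%d", e$b, e$n_control),
      p = e$p_fisher, p_fdr = e$p_fdr, stringsAsFactors = FALSE),
      "enrichment.tsv")
    emit(data.frame(trait = e$trait_id,
                    neg_log10_p = -log10(e$p_fisher),
                    stringsAsFactors = FALSE),
         "phewas_manhattan.tsv")
  }
  if (!is.null(bundle$mr_phewas)) emit(bundle$mr_phewas, "mr_phewas.tsv")
  if (!is.null(bundle$bidirectional)) {
    fmt <- function(panel) data.frame(
      method = panel$method, nSNPs = panel$n_snps, p = panel$pval,
      OR = panel$or_, OR_lci95 = panel$or_low, OR_uci95 = panel$or_high,
      heterogeneity_p = panel$q_pval, pleiotropy_p = panel$intercept_pval,
      stringsAsFactors = FALSE)
    emit(fmt(bundle$bidirectional$a_to_b), "mr_a_to_b.tsv")
    emit(fmt(bundle$bidirectional$b_to_a), "mr_b_to_a.tsv")
  }
  if (!is.null(bundle$coloc)) {
    cl <- bundle$coloc
    cl$pp_h4_abf_pct <- 100 * cl$pph4
    emit(cl, "coloc.tsv")
  }
  writeLines(bundle$log, file.path(out_dir, "run_log.txt"))
  written <- c(written, file.path(out_dir, "run_log.txt"))
  invisible(written)
}
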