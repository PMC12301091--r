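# LD pruning of significant loci into independent index SNPs, and selection
# of covariate-matched control SNPs. The matching emulates the SNPsnap
# procedure: controls share the index SNP's minor-allele frequency, gene
# density, distance to nearest gene and LD-buddy count within relative
# windows, and are unlinked to every risk SNP and to each other.

#' Greedy LD pruning by significance
#'
#' Retains the most significant SNP, removes all others correlated with it
#' at `r^2 >= r2_max`, and repeats over the remainder. Ties in p-value are
#' broken by lexicographic SNP id.
#'
#' @param records Data frame in the canonical record layout with at least
#'   `snp_id` and `pval`.
#' @param ld Correlation matrix with SNP-id dimnames; pairs absent from it
#'   are treated as unlinked with a warning.
#' @param r2_max Pruning threshold: a SNP is removed if its `r^2` with any
#'   retained SNP is `>= r2_max`.
#' @return Character vector of retained SNP ids, ordered by ascending
#'   p-value then id.
#' @export
ld_prune <- function(records, ld, r2_max) {
  if (nrow(records) == 0) return(character())
  ord <- order(records$pval, records$snp_id)
  ids <- records$snp_id[ord]
  r2 <- ld_r2(ld, ids, ids)
  retained <- character()
  for (id in ids) {
    if (length(retained) == 0 || all(r2[id, retained] < r2_max))
      retained <- c(retained, id)
  }
  retained
}

#' Select covariate-matched control SNPs for a set of risk SNPs
#'
#' For each risk SNP, candidate controls are universe members that are not
#' risk SNPs, are unlinked (`r^2 < independence_r2`) to every risk SNP and
#' every control already selected, and fall inside all four covariate
#' windows relative to the risk SNP's values: MAF within ±5%, gene density,
#' distance to nearest gene and LD-buddy count within ±50% by default.
#' `k` controls per risk SNP are drawn uniformly without replacement with
#' the seeded generator; controls are globally distinct.
#'
#' @param risk_ids Character vector of risk SNP ids.
#' @param universe Annotation data frame (see [read_annotation_table()])
#'   covering candidates and risk SNPs.
#' @param ld Correlation matrix with SNP-id dimnames.
#' @param k Controls to select per risk SNP.
#' @param tolerances Named list of relative half-widths:
#'   `maf` (default 0.05), `density`, `distance`, `buddies` (default 0.50).
#'   A candidate value must lie within `[v*(1-t), v*(1+t)]` of the risk
#'   SNP's value `v`. With `absolute = TRUE` the windows are `v ± t`
#'   instead.
#' @param independence_r2 LD ceiling between a control and any risk SNP or
#'   other control (default 0.1).
#' @param seed Integer seed for the candidate draw.
#' @param relax If `TRUE`, a deficient candidate pool triggers stepwise
#'   doubling of all tolerances (up to `relax_max_doublings`) and the
#'   controls found under widened windows are flagged `relaxed = TRUE`.
#'   If `FALSE` (default) a deficiency is an error reporting the pool size.
#' @param relax_max_doublings Cap on tolerance doublings under `relax`.
#' @param absolute Interpret tolerances as absolute half-widths.
#' @return Data frame with one row per control: `risk_snp_id`,
#'   `control_snp_id`, `relaxed`.
#' @export
match_controls <- function(risk_ids, universe, ld, k = 4,
                           tolerances = list(maf = 0.05, density = 0.5,
                                             distance = 0.5, buddies = 0.5),
                           independence_r2 = 0.1, seed = 1L,
                           relax = FALSE, relax_max_doublings = 3,
                           absolute = FALSE) {
  stopifnot(k >= 1, all(unlist(tolerances) > 0))
  miss <- setdiff(risk_ids, universe$snp_id)
  if (length(miss)) stop("risk SNP(s) absent from annotation universe: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  cand_ids <- setdiff(universe$snp_id, risk_ids)
  # r^2 of every candidate against every risk SNP, computed once
  r2_risk <- ld_r2(ld, cand_ids, risk_ids)
  rows <- match(cand_ids, universe$snp_id)
  covs <- c("maf", "gene_density", "dist_nearest_gene", "ld_buddies")
  tols <- c(tolerances$maf, tolerances$density, tolerances$distance,
            tolerances$buddies)

  in_windows <- function(risk_row, scale) {
    ok <- rep(TRUE, length(cand_ids))
    for (j in seq_along(covs)) {
      v <- universe[[covs[j]]][risk_row]
      x <- universe[[covs[j]]][rows]
      t_j <- tols[j] * scale
      if (absolute) {
        lo <- v - t_j; hi <- v + t_j
      } else if (v == 0 && covs[j] == "dist_nearest_gene") {
        # relative window degenerates at zero; fall back to +/- 10 kb
        message("match_controls: zero nearest-gene distance for ",
                universe$snp_id[risk_row], "; using absolute 10 kb window")
        lo <- 0; hi <- 10000 * scale
      } else {
        lo <- v * (1 - t_j); hi <- v * (1 + t_j)
      }
      ok <- ok & x >= lo & x <= hi
    }
    ok
  }

  with_seed(seed, {
    selected <- character()
    out <- vector("list", length(risk_ids))
    for (i in seq_along(risk_ids)) {
      risk_row <- match(risk_ids[i], universe$snp_id)
      unlinked <- rowSums(r2_risk >= independence_r2) == 0
      if (length(selected)) {
        r2_sel <- ld_r2(ld, cand_ids, selected)
        unlinked <- unlinked & rowSums(r2_sel >= independence_r2) == 0
      }
      free <- !(cand_ids %in% selected)
      scale <- 1
      relaxed_here <- FALSE
      repeat {
        pool <- cand_ids[free & unlinked & in_windows(risk_row, scale)]
        if (length(pool) >= k) break
        if (!relax || scale >= 2^relax_max_doublings)
          stop("match_controls: candidate pool for ", risk_ids[i],
               " has only ", length(pool), " member(s), need ", k,
               call. = FALSE)
        scale <- scale * 2
        relaxed_here <- TRUE
      }
      chosen <- sort(pool)[sample.int(length(pool), k)]
      selected <- c(selected, chosen)
      out[[i]] <- data.frame(risk_snp_id = risk_ids[i],
                             control_snp_id = chosen,
                             relaxed = relaxed_here,
                             stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
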