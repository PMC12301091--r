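# Allele harmonization of exposure and outcome summary statistics prior to
# two-sample MR. The outcome is re-oriented so its effect allele matches the
# exposure's, handling strand flips; palindromic (A/T, C/G) SNPs are dropped
# by default because strand cannot be resolved from alleles alone.

.complement <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) {
  ea %in% names(.complement) & oa %in% names(.complement) &
    unname(.complement[ea]) == oa
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome effects to the exposure's effect allele over the SNPs
#' present in both tables. When the outcome's effect/other alleles are
#' swapped relative to the exposure, the outcome beta sign is flipped and
#' its effect-allele frequency replaced by its complement; alleles that
#' match after complementing both (a strand flip) are treated as matching.
#' Pairs whose alleles cannot be reconciled are excluded and counted.
#'
#' @param exposure,outcome Data frames in the canonical record layout
#'   (see [read_gwas_table()]), keyed by `snp_id`.
#' @param palindrome_policy `"drop"` (default) removes palindromic SNPs;
#'   `"keep"` orients them by comparing effect-allele frequencies, dropping
#'   those whose frequency is uninformative (within `eaf_tol` of 0.5) or
#'   missing.
#' @param eaf_tol Frequency window around 0.5 inside which a palindromic
#'   SNP is considered unresolvable under `palindrome_policy = "keep"`.
#' @return Data frame with one row per aligned instrument: `snp_id`,
#'   `beta_x`, `se_x`, `beta_y`, `se_y`, `eaf_x`, `eaf_y`, `flipped`.
#'   Attributes `n_palindromic_dropped` and `n_incompatible` count
#'   exclusions.
#' @export
harmonize <- function(exposure, outcome, palindrome_policy = c("drop", "keep"),
                      eaf_tol = 0.08) {
  palindrome_policy <- match.arg(palindrome_policy)
  if (anyDuplicated(exposure$snp_id) || anyDuplicated(outcome$snp_id))
    stop("duplicate snp_id in exposure or outcome table", call. = FALSE)
  common <- intersect(exposure$snp_id, outcome$snp_id)
  if (length(common) == 0)
    stop("no overlapping SNPs between exposure and outcome", call. = FALSE)
  ex <- exposure[match(common, exposure$snp_id), ]
  ou <- outcome[match(common, outcome$snp_id), ]

  cmp <- function(x) ifelse(x %in% names(.complement),
                            unname(.complement[x]), NA_character_)
  same <- ou$effect_allele == ex$effect_allele &
    ou$other_allele == ex$other_allele
  swap <- ou$effect_allele == ex$other_allele &
    ou$other_allele == ex$effect_allele
  flip_same <- !is.na(cmp(ou$effect_allele)) &
    cmp(ou$effect_allele) == ex$effect_allele &
    cmp(ou$other_allele) == ex$other_allele
  flip_swap <- !is.na(cmp(ou$effect_allele)) &
    cmp(ou$effect_allele) == ex$other_allele &
    cmp(ou$other_allele) == ex$effect_allele
  pal <- is_palindromic(ex$effect_allele, ex$other_allele)

  aligned <- (same | flip_same) & !(swap | flip_swap)
  flipped <- (swap | flip_swap) & !(same | flip_same)
  compatible <- same | swap | flip_same | flip_swap

  keep <- compatible
  n_pal_dropped <- 0L
  if (palindrome_policy == "drop") {
    n_pal_dropped <- sum(pal & compatible)
    keep <- keep & !pal
  } else {
    # For a compatible palindromic SNP swap and strand-flip are
    # indistinguishable from alleles; orient by allele frequency instead.
    informative <- !is.na(ex$eaf) & !is.na(ou$eaf) &
      abs(ex$eaf - 0.5) > eaf_tol & abs(ou$eaf - 0.5) > eaf_tol
    pal_keep <- pal & compatible & informative
    n_pal_dropped <- sum(pal & compatible & !informative)
    keep <- keep & (!pal | pal_keep)
    same_side <- (ex$eaf > 0.5) == (ou$eaf > 0.5)
    flipped[pal_keep] <- !same_side[pal_keep]
    aligned[pal_keep] <- same_side[pal_keep]
  }
  n_incompatible <- sum(!compatible)
  if (n_incompatible > 0)
    message("harmonize: excluded ", n_incompatible,
            " SNP(s) with irreconcilable alleles")
  if (n_pal_dropped > 0)
    message("harmonize: dropped ", n_pal_dropped, " palindromic SNP(s)")

  out <- data.frame(
    snp_id = common,
    beta_x = ex$beta, se_x = ex$se,
    beta_y = ifelse(flipped, -ou$beta, ou$beta),
    se_y = ou$se,
    eaf_x = ex$eaf,
    eaf_y = ifelse(flipped, 1 - ou$eaf, ou$eaf),
    flipped = flipped,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_palindromic_dropped") <- n_pal_dropped
  attr(out, "n_incompatible") <- n_incompatible
  out
}
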