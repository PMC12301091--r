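# PheWAS trait-enrichment stage: count nominal SNP-trait associations,
# compare risk SNPs against matched controls per trait with Fisher's exact
# test, and correct across traits with the Benjamini-Hochberg FDR.

#' Construct a phenome p-value matrix
#'
#' A light container for per-trait, per-SNP association p-values, with
#' optional per-trait sample sizes.
#'
#' @param pvals Numeric matrix, traits in rows and SNPs in columns, with
#'   dimnames; entries in (0, 1], `NA` allowed (missing associations).
#' @param trait_n Optional named numeric vector of per-trait sample sizes.
#' @return An object of class `phenome`.
#' @export
phenome <- function(pvals, trait_n = NULL) {
  stopifnot(is.matrix(pvals), !is.null(rownames(pvals)),
            !is.null(colnames(pvals)))
  finite <- pvals[!is.na(pvals)]
  if (any(finite <= 0 | finite > 1))
    stop("phenome p-values must lie in (0, 1]", call. = FALSE)
  if (!is.null(trait_n)) {
    stopifnot(!is.null(names(trait_n)),
              all(rownames(pvals) %in% names(trait_n)))
    trait_n <- trait_n[rownames(pvals)]
  }
  structure(list(pvals = pvals, trait_n = trait_n), class = "phenome")
}

#' @export
print.phenome <- function(x, ...) {
  cat("phenome: ", nrow(x$pvals), " traits x ", ncol(x$pvals), " SNPs\n",
      sep = "")
  invisible(x)
}

#' Read a phenome from a long-format association table
#'
#' Tab-separated with header `TRAIT SNP P` and optionally `N` (per-trait
#' sample size). Missing trait-SNP combinations become `NA`.
#'
#' @param path Path to the file.
#' @param min_n Traits with sample size below this are excluded (the
#'   low-power filter; default 1000). Ignored when `N` is absent.
#' @return A [phenome()] object.
#' @export
read_phenome_long <- function(path, min_n = 1000) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  miss <- setdiff(c("TRAIT", "SNP", "P"), names(raw))
  if (length(miss)) stop("phenome table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  traits <- sort(unique(raw$TRAIT))
  snps <- sort(unique(raw$SNP))
  m <- matrix(NA_real_, length(traits), length(snps),
              dimnames = list(traits, snps))
  m[cbind(match(raw$TRAIT, traits), match(raw$SNP, snps))] <- raw$P
  trait_n <- NULL
  if ("N" %in% names(raw)) {
    trait_n <- tapply(raw$N, raw$TRAIT, function(x) x[1])[traits]
    keep <- !is.na(trait_n) & trait_n >= min_n
    if (any(!keep))
      message("read_phenome_long: excluded ", sum(!keep),
              " trait(s) with sample size < ", min_n)
    m <- m[keep, , drop = FALSE]
    trait_n <- trait_n[keep]
  }
  phenome(m, trait_n)
}

#' Count nominal associations per trait for a SNP set
#'
#' @param phen A [phenome()] object.
#' @param snp_set Character vector of SNP ids, all present in the phenome.
#' @param alpha Nominal threshold; an association counts when `p < alpha`
#'   (strict). Missing p-values never count.
#' @return Named integer vector of per-trait counts.
#' @export
count_associations <- function(phen, snp_set, alpha = 0.01) {
  stopifnot(inherits(phen, "phenome"))
  unknown <- setdiff(snp_set, colnames(phen$pvals))
  if (length(unknown)) stop("SNP id(s) not in phenome: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  sub <- phen$pvals[, snp_set, drop = FALSE]
  counts <- rowSums(sub < alpha, na.rm = TRUE)
  storage.mode(counts) <- "integer"
  counts
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value for the table `rbind(c(a, b), c(c, d))` with
#' fixed margins, by summing the hypergeometric probabilities of all tables
#' whose point probability does not exceed that of the observed table
#' (within relative tolerance 1e-7 for ties) — the convention of mainstream
#' statistics libraries.
#'
#' @param a,b,c_,d Non-negative integer cell counts (row 1: `a`, `b`;
#'   row 2: `c_`, `d`).
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c_, d) {
  cells <- c(a, b, c_, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells)))
    stop("fisher_exact_2x2: cells must be non-negative integers",
         call. = FALSE)
  r1 <- a + b; r2 <- c_ + d; k <- a + c_
  if (r1 + r2 == 0) stop("fisher_exact_2x2: empty table", call. = FALSE)
  support <- max(0, k - r2):min(r1, k)
  probs <- stats::dhyper(support, r1, r2, k)
  p_obs <- stats::dhyper(a, r1, r2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' `adj_(i) = min over j >= i of m * p_(j) / j`, capped at 1, returned in
#' the input order.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric())
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1))
    stop("bh_fdr: p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Per-trait enrichment of risk SNPs versus matched controls
#'
#' For each trait with at least one associated risk SNP, builds the 2x2
#' table (associated / not associated) x (risk set / control set), computes
#' the two-sided Fisher exact p-value, and adjusts across the tested traits
#' with [bh_fdr()]. Traits with zero associated risk SNPs are excluded from
#' the test and from the FDR family.
#'
#' @param phen A [phenome()] object covering both SNP sets.
#' @param risk_ids,control_ids Disjoint character vectors of SNP ids.
#' @param alpha Nominal association threshold passed to
#'   [count_associations()].
#' @return Data frame sorted by `p_fisher`: `trait_id`, `a` (associated
#'   risk SNPs), `n_risk`, `b` (associated controls), `n_control`,
#'   `p_fisher`, `p_fdr`. Attribute `m_tested` records the FDR family size.
#' @export
enrich <- function(phen, risk_ids, control_ids, alpha = 0.01) {
  if (length(intersect(risk_ids, control_ids)))
    stop("risk and control SNP sets overlap", call. = FALSE)
  a <- count_associations(phen, risk_ids, alpha)
  b <- count_associations(phen, control_ids, alpha)
  n_risk <- length(risk_ids); n_control <- length(control_ids)
  tested <- which(a >= 1)
  if (length(tested) == 0) {
    out <- data.frame(trait_id = character(), a = integer(),
                      n_risk = integer(), b = integer(),
                      n_control = integer(), p_fisher = numeric(),
                      p_fdr = numeric(), stringsAsFactors = FALSE)
    attr(out, "m_tested") <- 0L
    return(out)
  }
  p_fisher <- vapply(tested, function(i)
    fisher_exact_2x2(a[i], n_risk - a[i], b[i], n_control - b[i]), 0)
  out <- data.frame(
    trait_id = rownames(phen$pvals)[tested],
    a = a[tested], n_risk = n_risk, b = b[tested], n_control = n_control,
    p_fisher = p_fisher, p_fdr = bh_fdr(p_fisher),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_fisher, out$trait_id), ]
  rownames(out) <- NULL
  attr(out, "m_tested") <- length(tested)
  out
}
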