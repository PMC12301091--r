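# Reading, writing and validating GWAS summary-statistics tables and LD
# matrices. The canonical file dialect is tab-separated with header
# SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N; other dialects are mapped in
# via `column_map`. Positions are 1-based on GRCh37 (the build matters only
# for the MHC window constant used downstream).

.canonical_cols <- c(
  snp_id = "SNP", chrom = "CHR", pos = "POS", effect_allele = "EA",
  other_allele = "OA", eaf = "EAF", beta = "BETA", se = "SE",
  pval = "P", n = "N"
)
.mandatory_cols <- c("SNP", "CHR", "POS", "EA", "OA", "BETA", "SE", "P")

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated association table into the package's canonical
#' per-SNP record layout (`snp_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`). Rows violating the
#' record invariants (`se > 0`, `pval` in (0, 1], distinct alleles,
#' `pos >= 1`) are dropped with a message; the drop count is attached as
#' attribute `n_dropped`.
#'
#' @param path Path to a tab-separated file with a header row. The canonical
#'   header is `SNP CHR POS EA OA EAF BETA SE P N`; `EAF` and `N` are
#'   optional.
#' @param column_map Named character vector mapping canonical names to the
#'   file's column names, e.g. `c(SNP = "rsid", P = "pvalue")`, for
#'   non-canonical dialects. Unmapped canonical names are looked up
#'   verbatim.
#' @param trait_type `"quantitative"` or `"binary"`; recorded as attribute
#'   `trait_type` (for binary traits `beta` is a log odds ratio).
#' @return A `data.frame` of validated records, one per retained input row,
#'   input order preserved.
#' @export
read_gwas_table <- function(path, column_map = NULL,
                            trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0) {
    warning("empty summary-statistics file: ", path, call. = FALSE)
    out <- empty_gwas_table()
    attr(out, "trait_type") <- trait_type
    return(out)
  }
  lookup <- .canonical_cols
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), .canonical_cols)
    if (length(bad)) stop("unknown canonical column(s) in column_map: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    internal <- names(.canonical_cols)[match(names(column_map),
                                             .canonical_cols)]
    lookup[internal] <- unname(column_map)
  }
  for (canon in .mandatory_cols) {
    internal <- names(.canonical_cols)[.canonical_cols == canon]
    if (!lookup[[internal]] %in% names(raw))
      stop("missing mandatory column '", lookup[[internal]],
           "' (", canon, ") in ", path, call. = FALSE)
  }
  getcol <- function(internal, default = NA) {
    nm <- lookup[[internal]]
    if (nm %in% names(raw)) raw[[nm]] else rep(default, nrow(raw))
  }
  rec <- data.frame(
    snp_id = as.character(getcol("snp_id")),
    chrom = norm_chrom(getcol("chrom")),
    pos = as.numeric(getcol("pos")),
    effect_allele = toupper(as.character(getcol("effect_allele"))),
    other_allele = toupper(as.character(getcol("other_allele"))),
    eaf = as.numeric(getcol("eaf")),
    beta = as.numeric(getcol("beta")),
    se = as.numeric(getcol("se")),
    pval = as.numeric(getcol("pval")),
    n = as.numeric(getcol("n")),
    stringsAsFactors = FALSE
  )
  keep <- validate_gwas_records(rec)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message("read_gwas_table: dropped ", n_dropped,
            " row(s) violating record invariants")
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  attr(out, "trait_type") <- trait_type
  out
}

empty_gwas_table <- function() {
  out <- data.frame(
    snp_id = character(), chrom = character(), pos = numeric(),
    effect_allele = character(), other_allele = character(),
    eaf = numeric(), beta = numeric(), se = numeric(), pval = numeric(),
    n = numeric(), stringsAsFactors = FALSE
  )
  attr(out, "n_dropped") <- 0L
  out
}

# Logical vector: which rows satisfy the per-record invariants. eaf and n may
# be missing; when present eaf must lie in [0, 1].
validate_gwas_records <- function(rec) {
  ok <- !is.na(rec$snp_id) & nzchar(rec$snp_id) &
    !is.na(rec$pos) & rec$pos >= 1 &
    !is.na(rec$effect_allele) & !is.na(rec$other_allele) &
    rec$effect_allele != rec$other_allele &
    !is.na(rec$se) & rec$se > 0 &
    !is.na(rec$pval) & rec$pval > 0 & rec$pval <= 1 &
    !is.na(rec$beta)
  ok & (is.na(rec$eaf) | (rec$eaf >= 0 & rec$eaf <= 1))
}

#' Write a GWAS summary-statistics table in the canonical dialect
#'
#' @param records Data frame in the canonical record layout
#'   (see [read_gwas_table()]).
#' @param path Output path; a tab-separated file with header
#'   `SNP CHR POS EA OA EAF BETA SE P N` is written.
#' @export
write_gwas_table <- function(records, path) {
  out <- data.frame(
    SNP = records$snp_id, CHR = records$chrom, POS = records$pos,
    EA = records$effect_allele, OA = records$other_allele,
    EAF = records$eaf, BETA = records$beta, SE = records$se,
    P = records$pval, N = records$n, stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a pairwise LD matrix
#'
#' Square tab-separated numeric file whose header row and first column carry
#' SNP ids. Validated to be symmetric with unit diagonal and `|r| <= 1`.
#'
#' @param path Path to the file.
#' @return Numeric matrix of correlations `r` with SNP ids as dimnames.
#' @export
read_ld_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                           stringsAsFactors = FALSE, check.names = FALSE)
  r <- as.matrix(raw)
  storage.mode(r) <- "double"
  validate_ld_matrix(r)
  r
}

#' Validate an LD correlation matrix
#'
#' Checks squareness, matching SNP-id dimnames, unit diagonal, symmetry and
#' `|r| <= 1`.
#'
#' @param r Numeric matrix to check.
#' @param tol Numeric tolerance for the checks.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
validate_ld_matrix <- function(r, tol = 1e-8) {
  if (nrow(r) != ncol(r)) stop("LD matrix is not square", call. = FALSE)
  if (is.null(rownames(r)) || is.null(colnames(r)) ||
      !identical(rownames(r), colnames(r)))
    stop("LD matrix row/column SNP ids do not match", call. = FALSE)
  if (any(abs(diag(r) - 1) > tol)) stop("LD matrix diagonal is not 1", call. = FALSE)
  if (max(abs(r - t(r))) > tol) stop("LD matrix is not symmetric", call. = FALSE)
  if (max(abs(r)) > 1 + tol) stop("LD matrix has |r| > 1", call. = FALSE)
  invisible(TRUE)
}

#' @rdname read_ld_matrix
#' @param r Correlation matrix with SNP-id dimnames.
#' @export
write_ld_matrix <- function(r, path) {
  validate_ld_matrix(r)
  df <- data.frame(SNP = rownames(r), r, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Pairwise r^2 between two sets of ids; ids absent from the matrix are
# treated as unlinked (r^2 = 0) with a single warning.
ld_r2 <- function(ld, ids_a, ids_b) {
  known_a <- ids_a %in% rownames(ld)
  known_b <- ids_b %in% rownames(ld)
  if (!all(known_a) || !all(known_b))
    warning("SNP id(s) absent from LD matrix treated as unlinked (r^2 = 0)",
            call. = FALSE)
  out <- matrix(0, length(ids_a), length(ids_b),
                dimnames = list(ids_a, ids_b))
  if (any(known_a) && any(known_b))
    out[known_a, known_b] <- ld[ids_a[known_a], ids_b[known_b], drop = FALSE]^2
  out
}

#' Read an annotation table of SNP-matching covariates
#'
#' Tab-separated with header `SNP MAF GENE_DENSITY DIST_NEAREST_GENE
#' LD_BUDDIES`: minor-allele frequency, count of genes in a fixed window,
#' distance in bp to the nearest gene, and count of LD buddies
#' (other SNPs with r^2 >= 0.50).
#'
#' @param path Path to the file.
#' @return Data frame with columns `snp_id`, `maf`, `gene_density`,
#'   `dist_nearest_gene`, `ld_buddies`.
#' @export
read_annotation_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("SNP", "MAF", "GENE_DENSITY", "DIST_NEAREST_GENE", "LD_BUDDIES")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("annotation table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  ann <- data.frame(
    snp_id = as.character(raw$SNP), maf = as.numeric(raw$MAF),
    gene_density = as.numeric(raw$GENE_DENSITY),
    dist_nearest_gene = as.numeric(raw$DIST_NEAREST_GENE),
    ld_buddies = as.numeric(raw$LD_BUDDIES), stringsAsFactors = FALSE
  )
  validate_annotations(ann)
  ann
}

#' Validate a SNP annotation table
#'
#' Checks the covariate invariants: MAF in (0, 0.5], non-negative counts
#' and distances, unique SNP ids.
#'
#' @param ann Annotation data frame.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
validate_annotations <- function(ann) {
  stopifnot(all(ann$maf > 0 & ann$maf <= 0.5),
            all(ann$gene_density >= 0), all(ann$dist_nearest_gene >= 0),
            all(ann$ld_buddies >= 0), !anyDuplicated(ann$snp_id))
  invisible(TRUE)
}

#' @rdname read_annotation_table
#' @param ann Annotation data frame as returned by [read_annotation_table()].
#' @export
write_annotation_table <- function(ann, path) {
  out <- data.frame(SNP = ann$snp_id, MAF = ann$maf,
                    GENE_DENSITY = ann$gene_density,
                    DIST_NEAREST_GENE = ann$dist_nearest_gene,
                    LD_BUDDIES = ann$ld_buddies, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
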