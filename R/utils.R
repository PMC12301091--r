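# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb the
# session's random stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive an independent substream seed from a root seed and a label, so adding
# a generator never perturbs the draws of another. Kept below 2^31.
derive_seed <- function(seed, label) {
  v <- utf8ToInt(label)
  h <- sum(v * seq_along(v)) %% 65521
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h * 16807) %% 2147483629 + 1)
}

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference underflows
# or b >= a (rounding), which callers treat as a zero term.
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# Parse "chr6:26000000-34000000" (en-dash tolerated) into a list.
parse_region <- function(x) {
  x <- gsub("–", "-", trimws(x))
  m <- regmatches(x, regexec("^(chr)?([0-9XYMxym]+):([0-9,]+)-([0-9,]+)$", x))[[1]]
  if (length(m) == 0)
    stop("malformed region string: '", x, "' (expected chr:start-end)", call. = FALSE)
  start <- as.numeric(gsub(",", "", m[4]))
  end <- as.numeric(gsub(",", "", m[5]))
  if (is.na(start) || is.na(end) || start > end)
    stop("malformed region string: '", x, "'", call. = FALSE)
  list(chrom = m[3], start = start, end = end)
}

# Normalise chromosome labels ("chr6", "6" -> "6") for comparisons.
norm_chrom <- function(x) sub("^chr", "", as.character(x))
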