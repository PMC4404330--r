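# Internal helpers shared across the package.

# Chromosome names in the two genotype dialects differ in the "chr" prefix
# ("chr9" vs "9"); all (chromosome, position) matching goes through this.
norm_chrom <- function(x) {
  sub("^chr", "", as.character(x), ignore.case = TRUE)
}

# Canonical key for locus matching between tables and genotypes.
locus_key <- function(chrom, pos) {
  paste0(norm_chrom(chrom), ":", as.integer(pos))
}

MISSING_MARKERS <- c("-", ".", "--", "")

is_missing_allele <- function(x) {
  is.na(x) | x %in% MISSING_MARKERS
}

ALLELE_RE <- "^[ACGT]+$"

check_alleles <- function(x, what, call = rlang::caller_env()) {
  bad <- !grepl(ALLELE_RE, x)
  if (any(bad)) {
    abort(
      sprintf(
        "%s must be non-empty strings over {A,C,G,T}; offending value(s): %s",
        what, paste(unique(x[bad]), collapse = ", ")
      ),
      class = "hemotyper_validation_error", call = call
    )
  }
  invisible(x)
}

# Column-wise minima / first-argmin for small distance matrices
# (rows = haplotype rows, cols = configurations).
col_mins <- function(m) {
  if (nrow(m) == 1L) return(m[1L, ])
  do.call(pmin, lapply(seq_len(nrow(m)), function(i) m[i, ]))
}

col_which_min <- function(m) {
  max.col(-t(m), ties.method = "first")
}

`%s/%` <- function(a, b) file.path(a, b)
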