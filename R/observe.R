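#' Project a genotype onto a haplotype table's loci
#'
#' Variants are considered if and only if their (chromosome, position) is a
#' locus of the table; anything else in the genotype is irrelevant to this
#' gene and ignored. Table loci absent from the genotype are filled in with
#' the reference allele on both chromatids. The result is the per-locus
#' observed state the phasing engine enumerates over, plus the counts
#' reported in logs: N homozygous records, M heterozygous records, and the
#' number of missing records at table loci.
#'
#' @param x A `bg_genotype` (or a data frame acceptable to [genotype()]).
#' @param table A `bg_table`.
#' @param missing How to handle records whose alleles could not be called:
#'   `"exclude-locus"` (default) drops the locus from distance computation
#'   for every row, `"as-reference"` treats it as reference on both
#'   chromatids, and `"fail"` refuses the sample, naming it.
#' @return A `bg_observed`: a list with per-locus `state_a` / `state_b`
#'   (chromatid-unassigned at heterozygous loci), the heterozygous locus
#'   indices `het_idx`, the `active` locus mask used for distances, and
#'   counts `n_hom`, `n_het`, `n_missing`.
#' @export
select_relevant <- function(x, table,
                            missing = c("exclude-locus", "as-reference", "fail")) {
  missing <- match.arg(missing)
  stopifnot(inherits(table, "bg_table"))
  if (!inherits(x, "bg_genotype")) x <- genotype(x)
  if (!identical(norm_assembly(assembly(x)), norm_assembly(table$assembly))) {
    abort(sprintf(
      "assembly mismatch: genotype is %s, table is %s (no silent lift-over)",
      assembly(x), table$assembly
    ), class = "hemotyper_validation_error")
  }

  L <- n_loci(table)
  state_a <- table$loci$ref
  state_b <- table$loci$ref
  active <- rep(TRUE, L)

  gkey <- locus_key(x$chrom, x$pos)
  tkey <- locus_key(table$loci$chrom, table$loci$pos)
  hit <- match(tkey, gkey)

  found <- which(!is.na(hit))
  r <- hit[found]
  zyg <- x$zygosity[r]

  miss <- found[zyg == "missing"]
  n_missing <- length(miss)
  if (n_missing && missing == "fail") {
    abort(sprintf(
      "sample %s has a missing call at table locus %s (missing mode 'fail')",
      sample_id(x), tkey[miss[1L]]
    ), class = "hemotyper_missing_error")
  }
  if (missing == "exclude-locus") active[miss] <- FALSE
  # as-reference: the fill-in states already stand at masked loci

  called <- zyg != "missing"
  state_a[found[called]] <- x$allele_a[r[called]]
  state_b[found[called]] <- x$allele_b[r[called]]
  het_idx <- found[zyg == "heterozygous"]
  n_het <- length(het_idx)
  n_hom <- sum(zyg == "homozygous")

  structure(
    list(
      sample_id = sample_id(x),
      state_a = state_a, state_b = state_b,
      het_idx = het_idx, active = active,
      n_hom = n_hom, n_het = n_het, n_missing = n_missing,
      missing_mode = missing
    ),
    class = "bg_observed"
  )
}

norm_assembly <- function(x) tolower(gsub("[^a-z0-9]", "", tolower(x)))

#' @export
print.bg_observed <- function(x, ...) {
  cat(sprintf(
    "<bg_observed> sample %s: %d homozygous, %d heterozygous, %d missing record(s) at table loci\n",
    x$sample_id, x$n_hom, x$n_het, x$n_missing
  ))
  invisible(x)
}
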