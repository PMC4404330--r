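#' Weighted Hamming distance between allele vectors
#'
#' The distance between a chromatid's allele vector and a haplotype-table
#' row is the (weighted) count of loci where the two allele symbols differ.
#' Allele strings compare as whole symbols: an indel mismatch (`"GG"` vs
#' `"G"`) costs exactly as much as a substitution, and strings are never
#' aligned character by character. With unit weights the result is an
#' integer; under maximum parsimony, lower means a more plausible haplotype.
#'
#' @param a,b Character vectors of allele symbols, aligned to the same loci.
#' @param weights Per-locus non-negative weights; default 1 everywhere.
#' @param active Logical mask (or integer indices) of loci to include;
#'   default all. Loci excluded under the `"exclude-locus"` missingness mode
#'   are dropped here.
#' @return A single non-negative number.
#' @examples
#' hamming_distance(c("GG", "C", "G"), c("GG", "T", "G"))  # 1
#' hamming_distance(c("G", "C", "G"), c("GG", "C", "A"))   # 2: indel + SNV
#' @export
hamming_distance <- function(a, b, weights = NULL, active = NULL) {
  if (length(a) != length(b)) {
    abort(sprintf("allele vectors differ in length (%d vs %d)",
                  length(a), length(b)),
          class = "hemotyper_validation_error")
  }
  w <- weights %||% rep(1, length(a))
  if (length(w) != length(a)) {
    abort("weights must match the vector length",
          class = "hemotyper_validation_error")
  }
  keep <- rep(TRUE, length(a))
  if (!is.null(active)) {
    keep[] <- FALSE
    keep[active] <- TRUE
  }
  sum(w[keep] * (a[keep] != b[keep]))
}

#' Nearest haplotype row for one chromatid
#'
#' The 1-nearest-neighbour call: the phenotype of the table row closest to
#' the chromatid's allele vector under [hamming_distance()]. All rows at the
#' minimal distance are surfaced in `tied_rows` (in table order); the
#' reported phenotype is deterministically the first of them.
#'
#' @param vec Character vector of allele symbols, one per table locus.
#' @param table A `bg_table`.
#' @param active Logical mask or indices of loci to include; default all.
#' @param weights Per-locus weights; defaults to the table's weights.
#' @return A list of class `bg_chromatid_call` with elements `phenotype`,
#'   `row_index`, `distance` and `tied_rows`.
#' @examples
#' abo <- read_haplotype_table(system.file("extdata", "abo_mini.tsv",
#'                                         package = "hemotyper"))
#' nearest_row(c("GG", "T", "G"), abo)  # A102 at distance 0
#' @export
nearest_row <- function(vec, table, active = NULL, weights = NULL) {
  stopifnot(inherits(table, "bg_table"))
  w <- weights %||% table$loci$weight
  d <- vapply(seq_len(n_haplotype_rows(table)), function(r) {
    hamming_distance(vec, table$alleles[r, ], weights = w, active = active)
  }, numeric(1))
  dmin <- min(d)
  ties <- which(d == dmin)
  structure(
    list(phenotype = table$phenotype[ties[1L]],
         row_index = ties[1L],
         distance = dmin,
         tied_rows = table$phenotype[ties]),
    class = "bg_chromatid_call"
  )
}

#' @export
print.bg_chromatid_call <- function(x, ...) {
  cat(sprintf("<chromatid call> %s (row %d) at distance %s%s\n",
              x$phenotype, x$row_index, format(x$distance),
              if (length(x$tied_rows) > 1L)
                sprintf("; tied with %s",
                        paste(setdiff(x$tied_rows, x$phenotype), collapse = ", "))
              else ""))
  invisible(x)
}

#' Enumerate chromatid assignments of the heterozygous loci
#'
#' Homozygous loci sit on both chromatids, so only the M heterozygous loci
#' need phasing. Each configuration assigns one allele of every heterozygous
#' pair to chromatid A and the other to B; fixing the first heterozygous
#' locus's first allele to chromatid A removes the A/B relabelling symmetry,
#' leaving exactly `2^(M-1)` distinct configurations (one for `M = 0`).
#' Six heterozygous loci, as in a typical ABO AB sample, give 32.
#'
#' @param observed A `bg_observed` from [select_relevant()].
#' @param max_het Enumeration cap on M (default 20, about 5e5
#'   configurations). Above this the call errors and suggests restricting
#'   the locus panel; in practice single genes carry few heterozygous exonic
#'   variants.
#' @return A tibble with one row per configuration: `config` (canonical
#'   index), `mask` (string of 0/1 per heterozygous locus; 1 means the
#'   record's first allele went to chromatid A), and list-columns
#'   `vector_a`, `vector_b` with the full per-locus allele vectors.
#' @export
enumerate_configurations <- function(observed, max_het = 20) {
  stopifnot(inherits(observed, "bg_observed"))
  masks <- configuration_masks(length(observed$het_idx), max_het = max_het)
  n_cfg <- ncol(masks)
  het <- observed$het_idx
  vecs_a <- vector("list", n_cfg)
  vecs_b <- vector("list", n_cfg)
  for (k in seq_len(n_cfg)) {
    va <- observed$state_a
    vb <- observed$state_b
    if (length(het)) {
      swap <- het[!masks[, k]]
      va[swap] <- observed$state_b[swap]
      vb[swap] <- observed$state_a[swap]
    }
    vecs_a[[k]] <- va
    vecs_b[[k]] <- vb
  }
  new_tibble(
    list(
      config = seq_len(n_cfg),
      mask = apply(masks, 2L, function(m) paste(as.integer(m), collapse = "")),
      vector_a = vecs_a,
      vector_b = vecs_b
    ),
    nrow = n_cfg
  )
}

# Canonical mask matrix: M x 2^(M-1) logical; column k is configuration k.
# Row 1 (the first heterozygous locus) is pinned TRUE; the remaining rows
# count through k-1 in binary, little-endian.
configuration_masks <- function(m, max_het = 20) {
  if (m > max_het) {
    abort(sprintf(
      paste0("%d heterozygous table loci exceed the enumeration cap of %d ",
             "(2^%d configurations); restrict the locus panel or raise max_het"),
      m, max_het, m - 1L
    ), class = "hemotyper_enumeration_cap")
  }
  n_cfg <- if (m == 0L) 1L else 2L^(m - 1L)
  masks <- matrix(TRUE, nrow = m, ncol = n_cfg)
  if (m >= 2L) {
    k <- seq_len(n_cfg) - 1L
    for (j in 2:m) {
      masks[j, ] <- bitwAnd(k, bitwShiftL(1L, j - 2L)) > 0L
    }
  }
  masks
}

#' Score one configuration against the table
#'
#' Each chromatid is called independently by [nearest_row()]; the
#' configuration's total score is the sum of the two distances. The
#' best-scoring configuration is the maximum-parsimony phase.
#'
#' @param vector_a,vector_b Per-locus allele vectors for the two chromatids.
#' @param table A `bg_table`.
#' @param active,weights As in [nearest_row()].
#' @return A list with `call_a`, `call_b` (each a `bg_chromatid_call`) and
#'   `total_score`.
#' @export
score_configuration <- function(vector_a, vector_b, table,
                                active = NULL, weights = NULL) {
  call_a <- nearest_row(vector_a, table, active = active, weights = weights)
  call_b <- nearest_row(vector_b, table, active = active, weights = weights)
  list(call_a = call_a, call_b = call_b,
       total_score = call_a$distance + call_b$distance)
}

# Vectorized scoring of every configuration at once.
#
# For each haplotype row the distance splits into a base term from the
# shared (homozygous / filled-in) loci plus, per heterozygous locus, the
# mismatch cost of whichever allele the mask assigns to that chromatid.
# That makes the R x n_cfg distance matrices two small matrix products.
phase_core <- function(observed, table, max_het = 20) {
  het <- observed$het_idx
  m <- length(het)
  masks <- configuration_masks(m, max_het = max_het)
  n_cfg <- ncol(masks)

  A <- table$alleles
  w <- table$loci$weight
  act <- observed$active

  hom_idx <- setdiff(which(act), het)
  if (length(hom_idx)) {
    mm <- A[, hom_idx, drop = FALSE] !=
      matrix(observed$state_a[hom_idx], nrow = nrow(A),
             ncol = length(hom_idx), byrow = TRUE)
    base <- as.vector(mm %*% w[hom_idx])
  } else {
    base <- numeric(nrow(A))
  }

  if (m > 0L) {
    wh <- w[het] * act[het]
    ma <- (A[, het, drop = FALSE] !=
             matrix(observed$state_a[het], nrow = nrow(A), ncol = m,
                    byrow = TRUE)) %*% diag(wh, nrow = m)
    mb <- (A[, het, drop = FALSE] !=
             matrix(observed$state_b[het], nrow = nrow(A), ncol = m,
                    byrow = TRUE)) %*% diag(wh, nrow = m)
    num_masks <- masks + 0
    dA <- base + ma %*% num_masks + mb %*% (1 - num_masks)
    dB <- base + ma %*% (1 - num_masks) + mb %*% num_masks
  } else {
    dA <- matrix(base, ncol = 1L)
    dB <- dA
  }

  min_a <- col_mins(dA)
  min_b <- col_mins(dB)
  idx_a <- col_which_min(dA)
  idx_b <- col_which_min(dB)
  totals <- min_a + min_b

  list(masks = masks, n_cfg = n_cfg, dA = dA, dB = dB,
       min_a = min_a, min_b = min_b, idx_a = idx_a, idx_b = idx_b,
       totals = totals)
}
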