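#' Build a haplotype table
#'
#' A haplotype table is the knowledge base for one gene of a blood group
#' system: an ordered set of genomic loci plus one row per known
#' phenotype-defining haplotype, giving the allele expected on a single
#' chromatid at every locus. Allele cells are atomic symbols — an insertion
#' is written as a longer string at its anchor position (e.g. `"GG"` where
#' the reference carries `"G"`) and is never aligned character by character.
#'
#' All alleles are plus-strand genomic alleles of the stated assembly, even
#' for genes transcribed from the minus strand, so that table cells compare
#' directly against variant-caller output. Coordinates are 1-based and
#' anchored, matching VCF conventions.
#'
#' @param rows A data frame with a `phenotype` column and one column per
#'   locus, named `"Chr<chrom>:<pos>"` (e.g. `"Chr9:136131650"`). Cells are
#'   allele strings over `{A,C,G,T}`.
#' @param ref Reference-assembly alleles, one per locus: either an unnamed
#'   character vector aligned with the locus columns or a named vector keyed
#'   by locus column name. May be omitted when `reference_row` is given, in
#'   which case that row supplies the reference alleles.
#' @param system,gene Blood-system name and gene symbol (e.g. `"ABO"`).
#' @param assembly Reference assembly tag; defaults to `"hg19"`.
#' @param reference_row Optional phenotype label of the row whose alleles
#'   equal the reference at every locus (for ABO the hg19 reference matches
#'   the O group, not A).
#' @param weights Optional per-locus non-negative weights used by the
#'   distance; defaults to 1 everywhere (all variants count equally).
#'
#' @return An object of class `bg_table`.
#' @examples
#' abo <- haplotype_table(
#'   tibble::tribble(
#'     ~phenotype, ~`Chr9:136132908`, ~`Chr9:136131650`, ~`Chr9:136131414`,
#'     "A101", "GG", "C", "G",
#'     "A102", "GG", "T", "G",
#'     "O02",  "G",  "C", "G",
#'     "B101", "GG", "C", "A"
#'   ),
#'   system = "ABO", gene = "ABO", reference_row = "O02"
#' )
#' abo
#' @export
haplotype_table <- function(rows, ref = NULL, system = "unknown",
                            gene = system, assembly = "hg19",
                            reference_row = NULL, weights = NULL) {
  rows <- as.data.frame(rows, check.names = FALSE)
  if (!"phenotype" %in% names(rows)) {
    names(rows)[1L] <- "phenotype"
  }
  locus_cols <- setdiff(names(rows), "phenotype")
  if (length(locus_cols) == 0L) {
    abort("a haplotype table needs at least one locus column",
          class = "hemotyper_validation_error")
  }
  if (nrow(rows) == 0L) {
    abort("a haplotype table needs at least one row",
          class = "hemotyper_validation_error")
  }
  loci <- parse_locus_headers(locus_cols)
  key <- locus_key(loci$chrom, loci$pos)
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate locus column(s): %s",
                  paste(key[duplicated(key)], collapse = ", ")),
          class = "hemotyper_validation_error")
  }

  alleles <- toupper(as.matrix(rows[locus_cols]))
  dimnames(alleles) <- list(NULL, locus_cols)
  check_alleles(as.vector(alleles), "haplotype-table allele cells")
  phenotype <- as.character(rows$phenotype)

  if (is.null(ref)) {
    if (is.null(reference_row)) {
      abort("supply `ref` alleles or a `reference_row` label",
            class = "hemotyper_validation_error")
    }
    i <- match(reference_row, phenotype)
    if (is.na(i)) {
      abort(sprintf("reference_row '%s' is not a phenotype in the table",
                    reference_row),
            class = "hemotyper_validation_error")
    }
    ref <- alleles[i, ]
  }
  if (!is.null(names(ref)) && all(locus_cols %in% names(ref))) {
    ref <- ref[locus_cols]
  }
  ref <- toupper(unname(as.character(ref)))
  if (length(ref) != length(locus_cols)) {
    abort("`ref` must supply one allele per locus",
          class = "hemotyper_validation_error")
  }
  check_alleles(ref, "reference alleles")

  if (is.null(weights)) weights <- rep(1, length(locus_cols))
  weights <- as.numeric(weights)
  if (length(weights) != length(locus_cols) || any(weights < 0) ||
      any(!is.finite(weights))) {
    abort("`weights` must be one finite non-negative number per locus",
          class = "hemotyper_validation_error")
  }

  if (!is.null(reference_row)) {
    i <- match(reference_row, phenotype)
    if (is.na(i)) {
      abort(sprintf("reference_row '%s' is not a phenotype in the table",
                    reference_row),
            class = "hemotyper_validation_error")
    }
    if (!all(alleles[i, ] == ref)) {
      abort(sprintf(
        "reference_row '%s' does not carry the reference allele at every locus",
        reference_row
      ), class = "hemotyper_validation_error")
    }
  }

  loci$ref <- ref
  loci$weight <- weights
  structure(
    list(
      system = as.character(system),
      gene = as.character(gene),
      assembly = as.character(assembly),
      loci = loci,
      phenotype = phenotype,
      alleles = alleles,
      reference_row = reference_row
    ),
    class = "bg_table"
  )
}

parse_locus_headers <- function(x, call = rlang::caller_env()) {
  m <- regmatches(x, regexec("^[Cc]hr([^:]+):([0-9]+)$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    abort(sprintf("malformed locus header(s): %s (expected Chr<name>:<position>)",
                  paste(x[bad], collapse = ", ")),
          class = "hemotyper_parse_error", call = call)
  }
  pos <- vapply(m, function(g) as.integer(g[3L]), 1L)
  if (any(pos < 1L)) {
    abort("locus positions must be >= 1", class = "hemotyper_parse_error",
          call = call)
  }
  tibble(
    label = x,
    chrom = vapply(m, function(g) g[2L], ""),
    pos = pos
  )
}

#' @export
print.bg_table <- function(x, ...) {
  cat(sprintf("<bg_table> system %s, gene %s (%s): %d haplotype row(s) x %d locus/loci\n",
              x$system, x$gene, x$assembly, nrow(x$alleles), nrow(x$loci)))
  if (!is.null(x$reference_row)) {
    cat(sprintf("reference row: %s\n", x$reference_row))
  }
  print(as_tibble(x), ...)
  invisible(x)
}

#' Convert a haplotype table to a tibble
#'
#' Returns the phenotype column plus one allele column per locus, in the
#' table's locus order — the same layout as the on-disk TSV.
#'
#' @param x A `bg_table`.
#' @param ... Unused.
#' @return A tibble.
#' @method as_tibble bg_table
#' @export
as_tibble.bg_table <- function(x, ...) {
  out <- c(list(phenotype = x$phenotype),
           setNames(lapply(seq_len(nrow(x$loci)), function(i) x$alleles[, i]),
                    x$loci$label))
  new_tibble(out, nrow = length(x$phenotype))
}

#' Number of loci / rows in a haplotype table
#' @param table A `bg_table`.
#' @return An integer.
#' @export
n_loci <- function(table) nrow(table$loci)

#' @rdname n_loci
#' @export
n_haplotype_rows <- function(table) length(table$phenotype)

#' Read a haplotype table from a TSV file
#'
#' The format is tab-separated UTF-8 with optional `#`-prefixed metadata
#' lines (`#system=`, `#gene=`, `#assembly=`, `#ref=G,C,G` aligned with the
#' header loci, `#reference_row=`, `#weights=1,1,1`), then a header line
#' `Phenotype<TAB>Chr<c>:<pos>...` and one row per haplotype.
#'
#' @param path Path to the file (or a connection).
#' @return A `bg_table`.
#' @export
read_haplotype_table <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  meta_lines <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  if (length(body) < 2L) {
    abort("haplotype table file needs a header line and at least one row",
          class = "hemotyper_parse_error")
  }
  meta <- parse_meta(meta_lines)

  cells <- strsplit(body, "\t", fixed = TRUE)
  header <- cells[[1L]]
  n_col <- length(header)
  ragged <- which(vapply(cells[-1L], length, 1L) != n_col)
  if (length(ragged)) {
    first_bad <- cells[-1L][[ragged[1L]]]
    abort(sprintf("ragged row %d ('%s ...'): expected %d fields",
                  ragged[1L], first_bad[1L], n_col),
          class = "hemotyper_parse_error")
  }
  rows <- as.data.frame(
    do.call(rbind, cells[-1L]), stringsAsFactors = FALSE
  )
  names(rows) <- c("phenotype", header[-1L])

  split_meta <- function(key) {
    if (is.null(meta[[key]])) return(NULL)
    trimws(strsplit(meta[[key]], ",", fixed = TRUE)[[1L]])
  }
  haplotype_table(
    rows,
    ref = split_meta("ref"),
    system = meta$system %||% "unknown",
    gene = meta$gene %||% meta$system %||% "unknown",
    assembly = meta$assembly %||% "hg19",
    reference_row = meta$reference_row,
    weights = if (!is.null(meta$weights)) as.numeric(split_meta("weights"))
  )
}

parse_meta <- function(lines) {
  out <- list()
  for (ln in lines) {
    kv <- sub("^#+\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      out[[trimws(substr(kv, 1L, eq - 1L))]] <-
        trimws(substr(kv, eq + 1L, nchar(kv)))
    }
  }
  out
}

#' Write a haplotype table to a TSV file
#'
#' Inverse of [read_haplotype_table()]: `read_haplotype_table()` applied to
#' the written file reproduces the table field for field.
#'
#' @param table A `bg_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(table, path) {
  stopifnot(inherits(table, "bg_table"))
  meta <- c(
    sprintf("#system=%s", table$system),
    sprintf("#gene=%s", table$gene),
    sprintf("#assembly=%s", table$assembly),
    sprintf("#ref=%s", paste(table$loci$ref, collapse = ",")),
    if (!is.null(table$reference_row))
      sprintf("#reference_row=%s", table$reference_row),
    if (any(table$loci$weight != 1))
      sprintf("#weights=%s", paste(table$loci$weight, collapse = ","))
  )
  header <- paste(c("Phenotype", table$loci$label), collapse = "\t")
  body <- vapply(seq_along(table$phenotype), function(i) {
    paste(c(table$phenotype[i], table$alleles[i, ]), collapse = "\t")
  }, "")
  readr::write_lines(c(meta, header, body), path)
  invisible(path)
}

#' Diagnose curation problems in a haplotype table
#'
#' Manual curation of phenotype-defining variant combinations is error-prone;
#' this reports (without rejecting) the common hazards: rows whose
#' (phenotype, allele-vector) pair is duplicated, loci whose allele is
#' identical across all rows (they can never discriminate phenotypes), and
#' rows with identical allele vectors but different phenotype labels (the
#' engine can then only ever report a tie between them).
#'
#' @param table A `bg_table`.
#' @return A tibble with columns `type` (`"duplicate_row"`,
#'   `"non_discriminative_locus"`, `"ambiguous_rows"`), `item` (the locus
#'   label or the phenotype labels involved) and `detail`. Zero rows means a
#'   clean table.
#' @export
validate_haplotype_table <- function(table) {
  stopifnot(inherits(table, "bg_table"))
  diags <- list()
  vec_sig <- apply(table$alleles, 1L, paste, collapse = "\t")

  dup <- duplicated(paste(table$phenotype, vec_sig, sep = "\r"))
  if (any(dup)) {
    diags[[length(diags) + 1L]] <- tibble(
      type = "duplicate_row",
      item = table$phenotype[dup],
      detail = sprintf("row repeats (phenotype, allele-vector) pair: %s",
                       vec_sig[dup])
    )
  }

  if (nrow(table$alleles) > 1L) {
    constant <- vapply(seq_len(ncol(table$alleles)), function(i) {
      length(unique(table$alleles[, i])) == 1L
    }, TRUE)
    if (any(constant)) {
      diags[[length(diags) + 1L]] <- tibble(
        type = "non_discriminative_locus",
        item = table$loci$label[constant],
        detail = sprintf("all rows carry '%s' here",
                         table$alleles[1L, constant])
      )
    }
  }

  for (sig in unique(vec_sig[duplicated(vec_sig)])) {
    labs <- unique(table$phenotype[vec_sig == sig])
    if (length(labs) > 1L) {
      diags[[length(diags) + 1L]] <- tibble(
        type = "ambiguous_rows",
        item = paste(labs, collapse = ","),
        detail = sprintf("identical allele vector (%s) with different labels",
                         gsub("\t", ",", sig, fixed = TRUE))
      )
    }
  }

  if (length(diags) == 0L) {
    return(tibble(type = character(), item = character(), detail = character()))
  }
  bind_rows(diags)
}

#' Reorder loci into canonical (chromosome, position) order
#'
#' Allele vectors are indexed by locus, so permuting the columns of the file
#' together with each row's cells yields an equivalent table; this puts any
#' such permutation into a canonical order for comparison.
#'
#' @param table A `bg_table`.
#' @return A `bg_table` with loci sorted by normalized chromosome name then
#'   position, and row alleles realigned.
#' @export
canonicalize_loci <- function(table) {
  stopifnot(inherits(table, "bg_table"))
  ord <- order(norm_chrom(table$loci$chrom), table$loci$pos)
  table$loci <- table$loci[ord, ]
  table$alleles <- table$alleles[, ord, drop = FALSE]
  table
}

#' Enumerate the single-chromatid haplotype space of a locus panel
#'
#' A genotyping panel covering a fixed set of loci can only ever distinguish
#' as many chromatid haplotypes as the product of per-locus allele counts:
#' 5 biallelic loci admit 2^5 = 32 distinct haplotypes, however many named
#' subgroups exist. The per-locus allele sets are taken from the table rows
#' plus the reference allele.
#'
#' @param table A `bg_table`.
#' @param loci Optional subset of locus labels (a sparse panel); default all.
#' @return A tibble with one row per distinct haplotype, one column per
#'   locus; `nrow()` of it is the size of the distinguishable space.
#' @export
haplotype_space <- function(table, loci = NULL) {
  stopifnot(inherits(table, "bg_table"))
  idx <- seq_len(n_loci(table))
  if (!is.null(loci)) {
    idx <- match(loci, table$loci$label)
    if (anyNA(idx)) {
      abort(sprintf("unknown locus label(s): %s",
                    paste(loci[is.na(idx)], collapse = ", ")),
            class = "hemotyper_validation_error")
    }
  }
  sets <- lapply(idx, function(i) {
    sort(unique(c(table$alleles[, i], table$loci$ref[i])))
  })
  grid <- expand.grid(sets, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(grid) <- table$loci$label[idx]
  as_tibble(grid)
}
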