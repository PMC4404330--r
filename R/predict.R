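#' Call a diplotype: joint phasing and phenotype prediction
#'
#' The engine of the package. Heterozygous variants at table loci are
#' enumerated over all chromatid assignments; each configuration's two
#' chromatids are labelled by 1-nearest-neighbour Hamming distance to the
#' haplotype table, and configurations are ranked by the summed distance.
#' The lowest total is the maximum-parsimony phase and yields the two
#' phenotype calls. All optimal configurations are retained; when they
#' disagree on the unordered phenotype pair the prediction is flagged
#' `ambiguous` rather than silently resolved — a tie between, say, Rh+ and
#' Rh- rows is a statement of uncertainty, not a call.
#'
#' @param x A `bg_genotype`, or any data frame acceptable to [genotype()].
#' @param table A `bg_table`.
#' @param missing Missingness policy, see [select_relevant()].
#' @param max_het Enumeration cap on heterozygous table loci, see
#'   [enumerate_configurations()].
#' @return A `bg_call` object. Use [glance()] for the one-row summary,
#'   [tidy()] for the full configuration ranking, and [autoplot()] to plot
#'   the score landscape.
#' @examples
#' abo <- read_haplotype_table(system.file("extdata", "abo_mini.tsv",
#'                                         package = "hemotyper"))
#' gt <- genotype(
#'   tibble::tribble(
#'     ~chrom, ~pos, ~alleles,
#'     "9", 136132908, "GG/GG",
#'     "9", 136131650, "C/T"
#'   ),
#'   sample_id = "demo"
#' )
#' call <- bg_predict(gt, abo)
#' glance(call)
#' @export
bg_predict <- function(x, table,
                       missing = c("exclude-locus", "as-reference", "fail"),
                       max_het = 20) {
  observed <- if (inherits(x, "bg_observed")) x else
    select_relevant(x, table, missing = missing)
  core <- phase_core(observed, table, max_het = max_het)

  phen_a <- table$phenotype[core$idx_a]
  phen_b <- table$phenotype[core$idx_b]
  pair <- paste(pmin(phen_a, phen_b), pmax(phen_a, phen_b), sep = " / ")

  best_score <- min(core$totals)
  best <- which(core$totals == best_score)
  ambiguous <- length(unique(pair[best])) > 1L
  k <- best[1L]   # canonical representative: first optimal configuration

  tied_at <- function(d, mn) table$phenotype[d == mn]
  call_a <- structure(
    list(phenotype = phen_a[k], row_index = core$idx_a[k],
         distance = core$min_a[k],
         tied_rows = tied_at(core$dA[, k], core$min_a[k])),
    class = "bg_chromatid_call"
  )
  call_b <- structure(
    list(phenotype = phen_b[k], row_index = core$idx_b[k],
         distance = core$min_b[k],
         tied_rows = tied_at(core$dB[, k], core$min_b[k])),
    class = "bg_chromatid_call"
  )

  structure(
    list(
      sample_id = observed$sample_id,
      system = table$system, gene = table$gene,
      call_a = call_a, call_b = call_b,
      total_score = best_score,
      best_configurations = new_tibble(
        list(config = best, mask = mask_strings(core$masks, best),
             phenotype_a = phen_a[best], phenotype_b = phen_b[best],
             pair = pair[best]),
        nrow = length(best)
      ),
      ambiguous = ambiguous,
      masks = core$masks,
      ranking = new_tibble(
        list(config = seq_len(core$n_cfg),
             phenotype_a = phen_a, distance_a = core$min_a,
             phenotype_b = phen_b, distance_b = core$min_b,
             total_score = core$totals),
        nrow = core$n_cfg
      ),
      n_hom = observed$n_hom, n_het = observed$n_het,
      n_missing = observed$n_missing,
      missing_mode = observed$missing_mode,
      het_loci = table$loci$label[observed$het_idx]
    ),
    class = "bg_call"
  )
}

#' @export
print.bg_call <- function(x, ...) {
  cat(sprintf("<bg_call> sample %s, %s/%s\n", x$sample_id, x$system, x$gene))
  cat(sprintf("  chromatid A: %s (distance %s)\n",
              x$call_a$phenotype, format(x$call_a$distance)))
  cat(sprintf("  chromatid B: %s (distance %s)\n",
              x$call_b$phenotype, format(x$call_b$distance)))
  cat(sprintf("  total score %s over %d configuration(s); %d optimal%s\n",
              format(x$total_score), nrow(x$ranking),
              nrow(x$best_configurations),
              if (x$ambiguous) " — AMBIGUOUS phenotype pair" else ""))
  invisible(x)
}

#' Tidy the configuration ranking of a diplotype call
#'
#' One row per enumerated configuration, ordered by total score then by
#' canonical configuration index, with the per-chromatid nearest phenotypes
#' and distances.
#'
#' @param x A `bg_call`.
#' @param ... Unused.
#' @return A tibble with columns `rank`, `config`, `mask`, `phenotype_a`,
#'   `distance_a`, `phenotype_b`, `distance_b`, `total_score`, `best`.
#' @method tidy bg_call
#' @export
tidy.bg_call <- function(x, ...) {
  r <- x$ranking
  ord <- order(r$total_score, r$config)
  out <- r[ord, ]
  out$mask <- mask_strings(x$masks, out$config)
  out$rank <- seq_len(nrow(out))
  out$best <- out$total_score == x$total_score
  out[, c("rank", "config", "mask", "phenotype_a", "distance_a",
          "phenotype_b", "distance_b", "total_score", "best")]
}

# "1" = the record's first allele on chromatid A, one character per
# heterozygous locus; "" when there is nothing to phase.
mask_strings <- function(masks, cols) {
  if (nrow(masks) == 0L) return(rep("", length(cols)))
  vapply(cols, function(k) paste(as.integer(masks[, k]), collapse = ""), "")
}

#' One-row summary of a diplotype call
#'
#' The same fields the TSV prediction report carries: the two phenotype
#' calls and distances, total score, the number of optimal configurations,
#' the ambiguity flag, any tied labels, and the N/M/missing record counts.
#'
#' @param x A `bg_call`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance bg_call
#' @export
glance.bg_call <- function(x, ...) {
  tied <- sort(unique(c(
    x$call_a$tied_rows, x$call_b$tied_rows,
    x$best_configurations$phenotype_a, x$best_configurations$phenotype_b
  )))
  tibble(
    sample = x$sample_id, system = x$system, gene = x$gene,
    phenotype_a = x$call_a$phenotype, distance_a = x$call_a$distance,
    phenotype_b = x$call_b$phenotype, distance_b = x$call_b$distance,
    total_score = x$total_score,
    n_best_configurations = nrow(x$best_configurations),
    ambiguous = x$ambiguous,
    tied_labels = paste(tied, collapse = ","),
    n_hom = x$n_hom, n_het = x$n_het, n_missing = x$n_missing
  )
}

#' Plot the configuration score landscape of a call
#'
#' Total Hamming score of every enumerated chromatid configuration, in rank
#' order, with the optimal configuration(s) highlighted. A flat left edge
#' with several optima signals an ambiguous phase.
#'
#' @param object A `bg_call`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bg_call
#' @export
autoplot.bg_call <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$total_score)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$best), size = 2) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#D55E00",
                                            `FALSE` = "grey40"),
                                 name = "optimal") +
    ggplot2::labs(
      x = "configuration rank",
      y = "total Hamming score",
      title = sprintf("%s/%s, sample %s: %d configuration(s)",
                      object$system, object$gene, object$sample_id,
                      nrow(d)),
      subtitle = sprintf("best pair: %s / %s%s",
                         object$call_a$phenotype, object$call_b$phenotype,
                         if (object$ambiguous) " (ambiguous)" else "")
    ) +
    ggplot2::theme_minimal()
}

#' Predict across a manifest of haplotype tables
#'
#' Runs [bg_predict()] once per table and binds the one-row summaries.
#' Multi-gene systems (Rh is RhD plus RhCE) appear as one row per gene under
#' the shared system name; no cross-gene interpretation is attempted —
#' combining the two chromatid calls into a serological trait is left to
#' the user. A failure on one gene is recorded in that gene's row; the other
#' genes still run.
#'
#' @param x A `bg_genotype` or data frame acceptable to [genotype()].
#' @param tables A list of `bg_table` objects, or a manifest tibble from
#'   [read_system_manifest()].
#' @param ... Passed to [bg_predict()] (`missing`, `max_het`).
#' @return A tibble: the [glance()] columns plus an `error` column (NA on
#'   success).
#' @export
predict_system <- function(x, tables, ...) {
  if (is.data.frame(tables) && "table" %in% names(tables)) {
    tables <- tables$table
  }
  if (inherits(tables, "bg_table")) tables <- list(tables)
  if (length(tables) == 0L) {
    abort("manifest is empty", class = "hemotyper_validation_error")
  }
  if (!inherits(x, "bg_genotype")) x <- genotype(x)
  rows <- purrr::map(tables, function(tb) {
    res <- tryCatch(glance(bg_predict(x, tb, ...)), error = function(e) {
      tibble(sample = sample_id(x), system = tb$system, gene = tb$gene,
             phenotype_a = NA_character_, distance_a = NA_real_,
             phenotype_b = NA_character_, distance_b = NA_real_,
             total_score = NA_real_, n_best_configurations = NA_integer_,
             ambiguous = NA, tied_labels = NA_character_,
             n_hom = NA_integer_, n_het = NA_integer_,
             n_missing = NA_integer_, error = conditionMessage(e))
    })
    if (!"error" %in% names(res)) res$error <- NA_character_
    res
  })
  bind_rows(rows)
}

#' Read a system manifest
#'
#' A manifest groups haplotype-table files by blood system: a TSV with two
#' fields per line, `system` and `path` (relative paths are resolved against
#' the manifest's directory). `#` lines are comments.
#'
#' @param path Manifest path.
#' @return A tibble with columns `system`, `gene`, `path` and a `table`
#'   list-column of parsed `bg_table` objects.
#' @export
read_system_manifest <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    abort("manifest is empty", class = "hemotyper_parse_error")
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(cells, length, 1L) < 2L
  if (any(bad)) {
    abort(sprintf("manifest line without a path: '%s'", lines[bad][1L]),
          class = "hemotyper_parse_error")
  }
  sys <- vapply(cells, `[`, "", 1L)
  rel <- vapply(cells, `[`, "", 2L)
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", rel), rel,
                file.path(dirname(path), rel))
  gone <- !file.exists(abs)
  if (any(gone)) {
    abort(sprintf("manifest references missing table file(s): %s",
                  paste(abs[gone], collapse = ", ")),
          class = "hemotyper_parse_error")
  }
  tabs <- lapply(abs, read_haplotype_table)
  for (i in seq_along(tabs)) tabs[[i]]$system <- sys[i]
  tibble(system = sys,
         gene = vapply(tabs, function(t) t$gene, ""),
         path = abs, table = tabs)
}

#' Build the genotype implied by a pair of haplotype rows
#'
#' The generative assumption of the whole approach: a sample's genotype at a
#' gene is the union of two table haplotypes. Loci where the two rows agree
#' with the reference produce no record (reference fill-in covers them);
#' loci where they agree on a non-reference allele produce a homozygous
#' record; loci where they differ produce a heterozygous record.
#'
#' @param table A `bg_table`.
#' @param row_a,row_b Row indices or phenotype labels (first match).
#' @param sample_id Sample identifier for the emitted genotype.
#' @return A `bg_genotype`.
#' @export
diplotype_genotype <- function(table, row_a, row_b, sample_id = "planted") {
  stopifnot(inherits(table, "bg_table"))
  ia <- resolve_row(table, row_a)
  ib <- resolve_row(table, row_b)
  al_a <- table$alleles[ia, ]
  al_b <- table$alleles[ib, ]
  ref <- table$loci$ref
  keep <- !(al_a == ref & al_b == ref)
  a <- al_a[keep]; b <- al_b[keep]
  new_bg_genotype(
    chrom = table$loci$chrom[keep], pos = table$loci$pos[keep],
    allele_a = a, allele_b = b,
    zygosity = ifelse(a == b, "homozygous", "heterozygous"),
    sample_id = sample_id, assembly = table$assembly
  )
}

resolve_row <- function(table, row) {
  if (is.numeric(row)) {
    row <- as.integer(row)
    if (row < 1L || row > n_haplotype_rows(table)) {
      abort(sprintf("row index %d out of range", row),
            class = "hemotyper_validation_error")
    }
    return(row)
  }
  i <- match(row, table$phenotype)
  if (is.na(i)) {
    abort(sprintf("no haplotype row labelled '%s'", row),
          class = "hemotyper_validation_error")
  }
  i
}
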