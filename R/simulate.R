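# Planted-diplotype simulation: genotypes with known ground truth, used to
# exercise the caller end to end without any external data.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a random haplotype table
#'
#' A synthetic knowledge base for simulation studies: one reference row plus
#' `n_rows - 1` variant rows, each differing from the reference at a random
#' subset of loci. Useful for property tests and cohort simulations where
#' the real curated tables are too small or too entangled.
#'
#' @param n_rows,n_loci Table dimensions (including the reference row).
#' @param p_alt Per-locus probability that a variant row deviates from the
#'   reference allele (at least one deviation is forced so rows are distinct
#'   from the reference).
#' @param unique_unions If `TRUE`, resample until every unordered pair of
#'   rows has a distinct locus-wise allele-pair union — the condition under
#'   which a planted diplotype is recoverable without ambiguity.
#' @param chrom,start_pos,spacing Locus coordinates to synthesize.
#' @param seed Optional seed; the global RNG state is restored afterwards.
#' @return A `bg_table` with system/gene `"SYN"`, reference row `"REF"` and
#'   variant rows `"H02"`, `"H03"`, ...
#' @export
random_haplotype_table <- function(n_rows, n_loci, p_alt = 0.35,
                                   unique_unions = FALSE,
                                   chrom = "1", start_pos = 10000L,
                                   spacing = 100L, seed = NULL) {
  stopifnot(n_rows >= 1L, n_loci >= 1L)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    for (attempt in seq_len(1000L)) {
      ref <- sample(bases, n_loci, replace = TRUE)
      alleles <- matrix(rep(ref, each = n_rows), nrow = n_rows)
      for (r in seq_len(n_rows)[-1L]) {
        flip <- which(stats::runif(n_loci) < p_alt)
        if (length(flip) == 0L) flip <- sample.int(n_loci, 1L)
        for (j in flip) {
          alleles[r, j] <- sample(setdiff(bases, ref[j]), 1L)
        }
      }
      labels <- c("REF", sprintf("H%02d", seq_len(n_rows)[-1L]))
      df <- as.data.frame(alleles, stringsAsFactors = FALSE)
      names(df) <- sprintf("Chr%s:%d", chrom,
                           start_pos + spacing * (seq_len(n_loci) - 1L))
      df <- cbind(phenotype = labels, df)
      tb <- haplotype_table(df, ref = ref, system = "SYN", gene = "SYN",
                            reference_row = "REF")
      if (!unique_unions || has_unique_unions(tb)) return(tb)
    }
    abort("could not generate a table with unique pairwise unions; enlarge n_loci",
          class = "hemotyper_validation_error")
  })
}

# Signature of the unordered diplotype a row pair implies: at each locus the
# unordered allele pair. Distinct signatures across all i <= j pairs mean
# every planted diplotype identifies its pair uniquely.
has_unique_unions <- function(table) {
  A <- table$alleles
  n <- nrow(A)
  sigs <- character(n * (n + 1L) / 2L)
  k <- 0L
  for (i in seq_len(n)) {
    for (j in i:n) {
      k <- k + 1L
      sigs[k] <- paste(pmin(A[i, ], A[j, ]), pmax(A[i, ], A[j, ]),
                       sep = "|", collapse = "\t")
    }
  }
  !anyDuplicated(sigs)
}

#' Simulate one genotype with a planted diplotype
#'
#' Draws two haplotype rows (with replacement), forms the locus-wise allele
#' pairs, then applies — in this order — call-level noise, missingness
#' masking, and panel subsetting, and emits the resulting genotype in
#' caller style (reference-homozygous loci produce no record).
#'
#' Noise is planted at the variant-call level, not simulated from reads:
#' with probability `noise_rate` per locus, one randomly chosen chromatid's
#' allele is replaced by a base the table does not use at that locus.
#' Masking turns an emitted record into a missing call. `panel_loci`
#' restricts records to a fixed subset of loci, emulating a sparse
#' genotyping array as opposed to whole-genome calls.
#'
#' @param table A `bg_table`.
#' @param index Sample index; with `seed` it fully determines the draw.
#' @param row_weights Sampling probabilities over rows (default uniform).
#' @param noise_rate,missing_rate Per-locus probabilities in `[0, 1]`.
#' @param panel_loci Optional character vector of locus labels to keep.
#' @param seed Optional integer; per-sample stream derived from
#'   `(seed, index)`.
#' @param sample_prefix Prefix for the generated sample id.
#' @return A one-row tibble: `sample_id`, `row_a`, `row_b` (planted labels),
#'   `idx_a`, `idx_b`, and a `genotype` list-column.
#' @export
sample_diplotype <- function(table, index = 1L, row_weights = NULL,
                             noise_rate = 0, missing_rate = 0,
                             panel_loci = NULL, seed = NULL,
                             sample_prefix = "sim") {
  stopifnot(inherits(table, "bg_table"))
  check_rates(noise_rate, missing_rate, row_weights, table)
  sub_seed <- if (is.null(seed)) NULL else
    (as.integer(seed) * 1000003L + as.integer(index)) %% 2147483587L
  with_seed(sub_seed, {
    n <- n_haplotype_rows(table)
    w <- row_weights %||% rep(1 / n, n)
    picks <- sample.int(n, 2L, replace = TRUE, prob = w)
    ia <- picks[1L]; ib <- picks[2L]
    al_a <- table$alleles[ia, ]
    al_b <- table$alleles[ib, ]
    ref <- table$loci$ref
    bases <- c("A", "C", "G", "T")

    if (noise_rate > 0) {
      for (j in which(stats::runif(n_loci(table)) < noise_rate)) {
        pool <- setdiff(bases, c(table$alleles[, j], ref[j]))
        side <- sample(c("a", "b"), 1L)
        cur <- if (side == "a") al_a[j] else al_b[j]
        if (length(pool) == 0L) pool <- setdiff(bases, cur)
        novel <- sample(pool, 1L)
        if (side == "a") al_a[j] <- novel else al_b[j] <- novel
      }
    }

    emitted <- !(al_a == ref & al_b == ref)
    if (missing_rate > 0) {
      mask <- emitted & stats::runif(n_loci(table)) < missing_rate
      al_a[mask] <- NA_character_
      al_b[mask] <- NA_character_
    }
    if (!is.null(panel_loci)) {
      emitted <- emitted & table$loci$label %in% panel_loci
    }

    df <- tibble(
      chrom = table$loci$chrom[emitted],
      pos = table$loci$pos[emitted],
      allele_a = al_a[emitted],
      allele_b = al_b[emitted]
    )
    sid <- sprintf("%s%04d", sample_prefix, as.integer(index))
    gt <- genotype(df, sample_id = sid, assembly = table$assembly)
    tibble(sample_id = sid,
           row_a = table$phenotype[ia], row_b = table$phenotype[ib],
           idx_a = ia, idx_b = ib,
           genotype = list(gt))
  })
}

check_rates <- function(noise_rate, missing_rate, row_weights, table) {
  if (noise_rate < 0 || noise_rate > 1 || missing_rate < 0 || missing_rate > 1) {
    abort("noise_rate and missing_rate must lie in [0, 1]",
          class = "hemotyper_validation_error")
  }
  if (!is.null(row_weights)) {
    if (length(row_weights) != n_haplotype_rows(table) ||
        any(row_weights < 0) || abs(sum(row_weights) - 1) > 1e-8) {
      abort("row_weights must be one probability per row, summing to 1",
            class = "hemotyper_validation_error")
    }
  }
  invisible(NULL)
}

#' Simulate a cohort of planted diplotypes
#'
#' Repeated [sample_diplotype()] draws; fully reproducible under a fixed
#' seed and independent of iteration order (each sample's stream is derived
#' from `(seed, index)`).
#'
#' @inheritParams sample_diplotype
#' @param n_samples Number of samples.
#' @return A tibble with one row per sample (see [sample_diplotype()]).
#' @examples
#' tb <- random_haplotype_table(4, 6, seed = 1)
#' cohort <- simulate_cohort(tb, n_samples = 5, seed = 7)
#' cohort
#' @export
simulate_cohort <- function(table, n_samples, row_weights = NULL,
                            noise_rate = 0, missing_rate = 0,
                            panel_loci = NULL, seed = NULL,
                            sample_prefix = "sim") {
  stopifnot(n_samples >= 0L)
  if (n_samples == 0L) {
    return(tibble(sample_id = character(), row_a = character(),
                  row_b = character(), idx_a = integer(), idx_b = integer(),
                  genotype = list()))
  }
  bind_rows(lapply(seq_len(n_samples), function(i) {
    sample_diplotype(table, index = i, row_weights = row_weights,
                     noise_rate = noise_rate, missing_rate = missing_rate,
                     panel_loci = panel_loci, seed = seed,
                     sample_prefix = sample_prefix)
  }))
}

#' Run the caller over a simulated cohort
#'
#' @param cohort A tibble from [simulate_cohort()] (needs `sample_id` and a
#'   `genotype` list-column).
#' @param table A `bg_table`.
#' @param ... Passed to [bg_predict()].
#' @return A tibble of [glance()] rows, one per sample.
#' @export
predict_cohort <- function(cohort, table, ...) {
  bind_rows(lapply(seq_len(nrow(cohort)), function(i) {
    glance(bg_predict(cohort$genotype[[i]], table, ...))
  }))
}

#' Write a simulated cohort to disk
#'
#' Emits one tabular genotype file per sample under `dir/genotypes/` and a
#' `truth.tsv` (`sample_id`, `row_a`, `row_b`).
#'
#' @param cohort A tibble from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  gdir <- file.path(dir, "genotypes")
  dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(cohort))) {
    write_genotype(cohort$genotype[[i]],
                   file.path(gdir, paste0(cohort$sample_id[i], ".tsv")))
  }
  readr::write_tsv(cohort[, c("sample_id", "row_a", "row_b")],
                   file.path(dir, "truth.tsv"))
  invisible(dir)
}
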