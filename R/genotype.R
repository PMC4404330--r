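#' Build a genotype object from a data frame
#'
#' A genotype is one sample's set of observed variants, unphased: each record
#' gives the two alleles seen at a (chromosome, position) with no information
#' about which chromatid carries which. Sites not listed are taken to carry
#' the reference allele on both chromatids (reference fill-in), matching how
#' variant callers emit only non-reference sites.
#'
#' @param x A data frame with columns `chrom` and `pos`, plus either a single
#'   `alleles` column (`"C/T"`, `"GG/G"`, missing marker `-` or `.`) or two
#'   columns `allele_a` / `allele_b`. Zygosity is derived: equal alleles are
#'   homozygous, different alleles heterozygous, and any missing marker makes
#'   the record missing.
#' @param sample_id Sample identifier carried into reports.
#' @param assembly Reference assembly tag the coordinates refer to.
#' @return A `bg_genotype`: a tibble with columns `chrom`, `pos`, `allele_a`,
#'   `allele_b`, `zygosity` and attributes `sample_id` and `assembly`.
#' @examples
#' genotype(
#'   tibble::tribble(
#'     ~chrom, ~pos, ~alleles,
#'     "9", 136131650, "C/T",
#'     "9", 136131414, "A/A"
#'   ),
#'   sample_id = "demo"
#' )
#' @export
genotype <- function(x, sample_id = "sample", assembly = "hg19") {
  x <- as_tibble(x)
  if (!all(c("chrom", "pos") %in% names(x))) {
    abort("genotype needs `chrom` and `pos` columns",
          class = "hemotyper_parse_error")
  }
  pos <- suppressWarnings(as.integer(x$pos))
  if (anyNA(pos)) {
    abort(sprintf("malformed position(s): %s",
                  paste(unique(x$pos[is.na(pos)]), collapse = ", ")),
          class = "hemotyper_parse_error")
  }
  if ("alleles" %in% names(x) && !"allele_a" %in% names(x)) {
    parts <- strsplit(as.character(x$alleles), "/", fixed = TRUE)
    bad <- vapply(parts, length, 1L) != 2L
    if (any(bad)) {
      abort(sprintf("allele field must be 'X/Y'; offending: %s",
                    paste(unique(x$alleles[bad]), collapse = ", ")),
            class = "hemotyper_parse_error")
    }
    allele_a <- vapply(parts, `[`, "", 1L)
    allele_b <- vapply(parts, `[`, "", 2L)
  } else if (all(c("allele_a", "allele_b") %in% names(x))) {
    allele_a <- as.character(x$allele_a)
    allele_b <- as.character(x$allele_b)
  } else {
    abort("genotype needs an `alleles` column or `allele_a`/`allele_b`",
          class = "hemotyper_parse_error")
  }

  allele_a <- toupper(trimws(allele_a))
  allele_b <- toupper(trimws(allele_b))
  miss_a <- is_missing_allele(allele_a)
  miss_b <- is_missing_allele(allele_b)
  allele_a[miss_a] <- NA_character_
  allele_b[miss_b] <- NA_character_
  ok <- !miss_a & !miss_b
  check_alleles(c(allele_a[!miss_a], allele_b[!miss_b]), "genotype alleles")

  zygosity <- rep("missing", length(allele_a))
  zygosity[ok & allele_a == allele_b] <- "homozygous"
  zygosity[ok & allele_a != allele_b] <- "heterozygous"

  out <- new_tibble(
    list(chrom = as.character(x$chrom), pos = pos,
         allele_a = allele_a, allele_b = allele_b, zygosity = zygosity),
    nrow = length(pos)
  )

  key <- locus_key(out$chrom, out$pos)
  if (anyDuplicated(key)) {
    dup_keys <- unique(key[duplicated(key)])
    for (k in dup_keys) {
      recs <- out[key == k, c("allele_a", "allele_b")]
      if (nrow(unique(recs)) > 1L) {
        abort(sprintf("conflicting duplicate records at %s", k),
              class = "hemotyper_parse_error")
      }
    }
    warn(sprintf("dropping identical duplicate record(s) at: %s",
                 paste(dup_keys, collapse = ", ")))
    out <- out[!duplicated(key), ]
  }

  new_bg_genotype(out$chrom, out$pos, out$allele_a, out$allele_b,
                  out$zygosity, sample_id, assembly)
}

# Trusted fast path: no validation, no duplicate checks. Used internally
# where the records are correct by construction.
new_bg_genotype <- function(chrom, pos, allele_a, allele_b, zygosity,
                            sample_id, assembly) {
  out <- new_tibble(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         allele_a = allele_a, allele_b = allele_b,
         zygosity = as.character(zygosity)),
    nrow = length(pos)
  )
  structure(out,
            class = c("bg_genotype", class(out)),
            sample_id = as.character(sample_id),
            assembly = as.character(assembly))
}

#' @export
print.bg_genotype <- function(x, ...) {
  cat(sprintf("<bg_genotype> sample %s (%s): %d record(s)\n",
              attr(x, "sample_id"), attr(x, "assembly"), nrow(x)))
  NextMethod()
}

#' Sample and assembly accessors for genotypes
#' @param x A `bg_genotype`.
#' @return A string.
#' @export
sample_id <- function(x) attr(x, "sample_id") %||% "sample"

#' @rdname sample_id
#' @export
assembly <- function(x) attr(x, "assembly") %||% "hg19"

#' Read a genotype from the tabular dialect
#'
#' A minimal VCF-like TSV: optional `#`-prefixed metadata (`#sample=`,
#' `#assembly=`), an optional header line starting with `chrom`, then one
#' record per line with fields `chrom`, `pos`, `alleles` (`X/Y`; `-` or `.`
#' marks a missing allele) and an optional trailing zygosity field, which is
#' ignored in favour of deriving zygosity from the allele pair.
#'
#' @param path Path to the file.
#' @param sample_id Overrides the `#sample=` metadata when given.
#' @return A `bg_genotype`.
#' @export
read_genotype <- function(path, sample_id = NULL) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  meta <- parse_meta(lines[startsWith(lines, "#")])
  body <- lines[!startsWith(lines, "#")]
  if (length(body) && grepl("^chrom\\b", body[1L], ignore.case = TRUE)) {
    body <- body[-1L]
  }
  cells <- strsplit(body, "\t", fixed = TRUE)
  short <- vapply(cells, length, 1L) < 3L
  if (any(short)) {
    abort(sprintf("genotype line(s) with fewer than 3 fields: '%s'",
                  body[short][1L]),
          class = "hemotyper_parse_error")
  }
  df <- tibble(
    chrom = vapply(cells, `[`, "", 1L),
    pos = vapply(cells, `[`, "", 2L),
    alleles = vapply(cells, `[`, "", 3L)
  )
  genotype(df,
           sample_id = sample_id %||% meta$sample %||% "sample",
           assembly = meta$assembly %||% "hg19")
}

#' Write a genotype in the tabular dialect
#'
#' @param x A `bg_genotype`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype <- function(x, path) {
  stopifnot(inherits(x, "bg_genotype"))
  a <- ifelse(is.na(x$allele_a), "-", x$allele_a)
  b <- ifelse(is.na(x$allele_b), "-", x$allele_b)
  lines <- c(
    sprintf("#sample=%s", sample_id(x)),
    sprintf("#assembly=%s", assembly(x)),
    "chrom\tpos\talleles\tzygosity",
    sprintf("%s\t%d\t%s/%s\t%s", x$chrom, x$pos, a, b, x$zygosity)
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a genotype from a single-sample VCF
#'
#' Only `CHROM`, `POS`, `REF`, `ALT` and the `GT` field are consulted.
#' `0/1` becomes a heterozygous (REF, ALT) record; `1/1` homozygous ALT;
#' `1/2` heterozygous (ALT1, ALT2); `./.` a missing record; `0/0` sites are
#' simply not recorded (reference fill-in covers them). Haploid calls are
#' treated as homozygous. Symbolic ALT alleles (`<DEL>` and friends) are
#' skipped with a warning.
#'
#' @param path Path to a VCF 4.x file.
#' @param sample For a multi-sample VCF, the name of the sample column to
#'   read; with a single sample it may be omitted.
#' @param assembly Assembly tag to attach (VCF headers rarely state it
#'   reliably).
#' @return A `bg_genotype`.
#' @export
read_genotype_vcf <- function(path, sample = NULL, assembly = "hg19") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L) {
    abort("VCF has no genotype (FORMAT/sample) columns",
          class = "hemotyper_parse_error")
  }
  samples <- colnames(gt)[-1L]
  if (is.null(sample)) {
    if (length(samples) > 1L) {
      abort(sprintf("multi-sample VCF (%d samples): pass `sample=` to choose one",
                    length(samples)),
            class = "hemotyper_parse_error")
    }
    sample <- samples[1L]
  } else if (!sample %in% samples) {
    abort(sprintf("sample '%s' not in VCF (has: %s)", sample,
                  paste(samples, collapse = ", ")),
          class = "hemotyper_parse_error")
  }

  gt_field <- vapply(seq_len(nrow(gt)), function(i) {
    fmt <- strsplit(gt[i, 1L], ":", fixed = TRUE)[[1L]]
    val <- strsplit(gt[i, sample], ":", fixed = TRUE)[[1L]]
    j <- match("GT", fmt)
    if (is.na(j) || j > length(val)) NA_character_ else val[j]
  }, "")

  recs <- vector("list", nrow(gt))
  n_skipped <- 0L
  for (i in seq_len(nrow(gt))) {
    ref <- toupper(fix[i, "REF"])
    alts <- if (is.na(fix[i, "ALT"])) character() else
      toupper(strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]])
    alleles_here <- c(ref, alts)
    if (is.na(gt_field[i])) {
      # "./." (and friends) surface as NA: a listed site with no usable call
      a <- NA_character_; b <- NA_character_
    } else {
      idx <- strsplit(gt_field[i], "[/|]")[[1L]]
      if (length(idx) == 1L) idx <- rep(idx, 2L)  # hemizygous -> homozygous
      if (length(idx) != 2L) next
      pick <- function(k) {
        if (k == ".") return(NA_character_)
        alleles_here[as.integer(k) + 1L]
      }
      a <- pick(idx[1L]); b <- pick(idx[2L])
      if (!is.na(a) && !is.na(b) && a == ref && b == ref) next  # 0/0: fill-in
      if (any(grepl("[^ACGT]", c(a, b)), na.rm = TRUE)) {
        n_skipped <- n_skipped + 1L   # <DEL>, breakends, non-ACGT codes
        next
      }
    }
    recs[[i]] <- tibble(chrom = fix[i, "CHROM"], pos = fix[i, "POS"],
                        allele_a = a, allele_b = b)
  }
  if (n_skipped > 0L) {
    warn(sprintf("skipped %d record(s) with symbolic ALT alleles", n_skipped))
  }
  df <- bind_rows(recs)
  if (nrow(df) == 0L) {
    df <- tibble(chrom = character(), pos = integer(),
                 allele_a = character(), allele_b = character())
  }
  genotype(df, sample_id = sample, assembly = assembly)
}
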