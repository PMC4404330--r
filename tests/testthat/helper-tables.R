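# Shared fixtures, built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

abo_table <- function() {
  read_haplotype_table(system.file("extdata", "abo_mini.tsv",
                                   package = "hemotyper"))
}

# Two-locus table where two disjoint row pairs explain the same double-het
# genotype at score 0: phasing alone cannot decide the phenotype pair.
ambiguous_table <- function() {
  haplotype_table(
    tibble::tribble(
      ~phenotype, ~`Chr1:100`, ~`Chr1:200`,
      "REF", "A", "C",
      "X",   "C", "A",
      "Z1",  "A", "A",
      "Z2",  "C", "C"
    ),
    system = "SYN", gene = "SYN", reference_row = "REF"
  )
}

write_tmp_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# Minimal single-sample VCF body for read_genotype_vcf tests.
vcf_fixture <- function(records,
                        samples = "S1",
                        envir = parent.frame()) {
  f <- withr::local_tempfile(fileext = ".vcf", .local_envir = envir)
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records
  ), f)
  f
}
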