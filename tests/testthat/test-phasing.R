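test_that("configuration counts follow 2^(M-1) with swap symmetry removed", {
  tb <- abo_table()
  # M = 0: the single unphased-free configuration
  obs0 <- select_relevant(diplotype_genotype(tb, "O02", "O02"), tb)
  cfg0 <- enumerate_configurations(obs0)
  expect_equal(nrow(cfg0), 1L)
  expect_equal(cfg0$vector_a[[1]], cfg0$vector_b[[1]])

  # M = 1: still a single configuration after pinning the first assignment
  obs1 <- select_relevant(
    genotype(tibble::tibble(chrom = "9", pos = 136131650, alleles = "C/T")),
    tb
  )
  expect_equal(nrow(enumerate_configurations(obs1)), 1L)

  # M = 6 heterozygous table loci: 32 configurations
  tb6 <- random_haplotype_table(4, 6, seed = 5)
  gt6 <- genotype(tibble::tibble(
    chrom = tb6$loci$chrom, pos = tb6$loci$pos,
    allele_a = rep("A", 6), allele_b = rep("C", 6)
  ))
  expect_equal(nrow(enumerate_configurations(select_relevant(gt6, tb6))), 32L)
})

test_that("enumeration matches a brute-force labeling + swap-dedup oracle", {
  for (m in 0:10) {
    tb <- random_haplotype_table(3, max(m, 1), p_alt = 0.5, seed = 100 + m)
    n_rec <- min(m, n_loci(tb))
    gt_df <- tibble::tibble(
      chrom = tb$loci$chrom[seq_len(n_rec)],
      pos = tb$loci$pos[seq_len(n_rec)],
      allele_a = rep("A", n_rec), allele_b = rep("C", n_rec)
    )
    cfg <- enumerate_configurations(select_relevant(genotype(gt_df), tb))
    expect_equal(nrow(cfg), max(1, 2^(m - 1)), info = paste("M =", m))
    expect_equal(nrow(cfg), oracle_predict(gt_df, tb)$n_configs,
                 info = paste("oracle M =", m))

    # no two configurations equal, none the chromatid swap of another
    sig <- purrr::map2_chr(cfg$vector_a, cfg$vector_b,
                           ~ paste(c(.x, "|", .y), collapse = "\r"))
    sig_sw <- purrr::map2_chr(cfg$vector_b, cfg$vector_a,
                              ~ paste(c(.x, "|", .y), collapse = "\r"))
    expect_false(any(duplicated(sig)))
    hit <- match(sig, sig_sw)  # cfg k equals the swap of cfg hit[k]
    expect_true(all(is.na(hit) | hit == seq_along(sig)),
                info = paste("swap pair at M =", m))
    if (m >= 2) expect_true(all(sig != sig_sw))
  }
})

test_that("the enumeration cap stops exponential blow-up with advice", {
  tb <- random_haplotype_table(3, 25, p_alt = 0.5, seed = 9)
  gt <- genotype(tibble::tibble(
    chrom = tb$loci$chrom[1:22], pos = tb$loci$pos[1:22],
    allele_a = rep("A", 22), allele_b = rep("C", 22)
  ))
  obs <- select_relevant(gt, tb)
  expect_error(enumerate_configurations(obs), "panel",
               class = "hemotyper_enumeration_cap")
  expect_error(bg_predict(gt, tb), class = "hemotyper_enumeration_cap")

  gt13 <- genotype(gt[1:13, c("chrom", "pos", "allele_a", "allele_b")])
  expect_error(bg_predict(gt13, tb, max_het = 12),
               class = "hemotyper_enumeration_cap")
  expect_equal(nrow(bg_predict(gt13, tb)$ranking), 2^12)
})

test_that("Hamming distance counts mismatching symbols, indels included", {
  a101 <- c("GG", "C", "G"); a102 <- c("GG", "T", "G")
  o02 <- c("G", "C", "G"); b101 <- c("GG", "C", "A")
  expect_equal(hamming_distance(a101, a102), 1)
  expect_equal(hamming_distance(a101, a101), 0)
  expect_equal(hamming_distance(o02, b101), 2)  # one indel + one SNV
  expect_equal(hamming_distance(a101, a102, weights = c(1, 3, 1)), 3)
  expect_equal(hamming_distance(a101, b101, active = c(1, 2)), 0)
  expect_equal(hamming_distance(a101, b101, active = c(1, 3)), 1)
  expect_error(hamming_distance(a101, c("G", "C")),
               class = "hemotyper_validation_error")
})

test_that("Hamming distance is a metric under unit weights", {
  set.seed(42)
  syms <- c("A", "C", "G", "T", "GG", "AT")
  for (i in 1:50) {
    x <- sample(syms, 6, replace = TRUE)
    y <- sample(syms, 6, replace = TRUE)
    z <- sample(syms, 6, replace = TRUE)
    expect_equal(hamming_distance(x, y), hamming_distance(y, x))
    expect_gte(hamming_distance(x, z) + hamming_distance(z, y),
               hamming_distance(x, y))
    expect_equal(hamming_distance(x, x), 0)
  }
})

test_that("nearest_row transfers the closest row's phenotype with ties kept", {
  tb <- abo_table()
  c1 <- nearest_row(c("GG", "T", "G"), tb)
  expect_equal(c1$phenotype, "A102")
  expect_equal(c1$distance, 0)
  c2 <- nearest_row(c("G", "C", "G"), tb)
  expect_equal(c2$phenotype, "O02")
  expect_equal(c2$distance, 0)

  # (GG, T, A) is at distance 1 from both A102 and B101
  c3 <- nearest_row(c("GG", "T", "A"), tb)
  expect_equal(c3$distance, 1)
  expect_equal(c3$tied_rows, c("A102", "B101"))
  expect_equal(c3$phenotype, "A102")  # first in table order
  expect_true(c3$phenotype %in% c3$tied_rows)
})

test_that("configuration scores sum the two chromatid distances", {
  tb <- abo_table()
  s0 <- score_configuration(c("GG", "T", "G"), c("G", "C", "G"), tb)
  expect_equal(s0$total_score, 0)
  s1 <- score_configuration(c("GG", "T", "G"), c("GG", "T", "A"), tb)
  expect_equal(s1$total_score, 1)
  expect_equal(s1$call_b$distance, 1)
})

test_that("splitting a known haplotype across chromatids scores worse", {
  # genotype = reference row + B101: the B-like configuration concentrates
  # both heterozygous alternates on one chromatid and wins outright
  tb <- abo_table()
  obs <- select_relevant(diplotype_genotype(tb, "O02", "B101"), tb)
  cfg <- enumerate_configurations(obs)
  scores <- purrr::map_dbl(seq_len(nrow(cfg)), function(k) {
    score_configuration(cfg$vector_a[[k]], cfg$vector_b[[k]], tb)$total_score
  })
  concentrated <- purrr::map_lgl(seq_len(nrow(cfg)), function(k) {
    any(purrr::map_lgl(list(cfg$vector_a[[k]], cfg$vector_b[[k]]),
                       ~ all(.x == tb$alleles[match("B101", tb$phenotype), ])))
  })
  expect_true(any(concentrated))
  expect_lt(max(scores[concentrated]), min(scores[!concentrated]))
})
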