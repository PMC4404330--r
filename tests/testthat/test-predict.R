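test_that("a planted diplotype is recovered at score zero", {
  tb <- abo_table()
  call <- bg_predict(diplotype_genotype(tb, "A102", "B101"), tb)
  expect_equal(call$total_score, 0)
  expect_false(call$ambiguous)
  expect_setequal(c(call$call_a$phenotype, call$call_b$phenotype),
                  c("A102", "B101"))
  expect_equal(glance(call)$n_het, 2L)
})

test_that("an empty genotype calls the reference phenotype on both sides", {
  tb <- abo_table()
  gt <- genotype(tibble::tibble(chrom = character(), pos = integer(),
                                allele_a = character(),
                                allele_b = character()))
  call <- bg_predict(gt, tb)
  expect_equal(call$call_a$phenotype, "O02")
  expect_equal(call$call_b$phenotype, "O02")
  expect_equal(call$total_score, 0)
  expect_false(call$ambiguous)
})

test_that("relabelling chromatids A and B changes nothing that matters", {
  tb <- random_haplotype_table(6, 8, seed = 21)
  set.seed(22)
  for (i in 1:20) {
    pair <- sample.int(6, 2, replace = TRUE)
    gt <- diplotype_genotype(tb, pair[1], pair[2])
    sw <- genotype(tibble::tibble(chrom = gt$chrom, pos = gt$pos,
                                  allele_a = gt$allele_b,
                                  allele_b = gt$allele_a))
    p1 <- bg_predict(gt, tb)
    p2 <- bg_predict(sw, tb)
    expect_equal(p2$total_score, p1$total_score)
    expect_equal(sort(c(p2$call_a$phenotype, p2$call_b$phenotype)),
                 sort(c(p1$call_a$phenotype, p1$call_b$phenotype)))
    expect_equal(p2$ambiguous, p1$ambiguous)
  }
})

test_that("the optimum agrees with the brute-force minimizer", {
  # randomized genotypes that are not clean diplotypes, M up to 8
  set.seed(31)
  seeds <- sample.int(1e6, 60)
  for (s in seeds) {
    inst <- random_instance(n_rows = sample(2:8, 1), n_loci = sample(4:9, 1),
                            m_het = sample(0:8, 1), seed = s)
    want <- oracle_predict(inst$gt, inst$table)
    got <- bg_predict(genotype(inst$gt), inst$table)
    expect_equal(got$total_score, want$best_total, info = paste("seed", s))
    expect_equal(sort(unique(got$best_configurations$pair)),
                 want$best_pairs, info = paste("seed", s))
    expect_equal(got$ambiguous, length(want$best_pairs) > 1L,
                 info = paste("seed", s))
  }
})

test_that("equal-score configurations with different pairs flag ambiguity", {
  tb <- ambiguous_table()
  gt <- genotype(tibble::tibble(chrom = "1", pos = c(100, 200),
                                alleles = c("A/C", "C/A")))
  call <- bg_predict(gt, tb)
  expect_true(call$ambiguous)
  expect_equal(call$total_score, 0)
  expect_setequal(unique(call$best_configurations$pair),
                  c("REF / X", "Z1 / Z2"))
  # scored downstream as a miss, not a guess
  ev <- evaluate_cohort(
    tibble::tibble(sample_id = sample_id(gt), row_a = "REF", row_b = "X"),
    glance(call)
  )
  expect_equal(ev$accuracy, 0)
})

test_that("removing a table row never improves the optimum", {
  tb <- random_haplotype_table(6, 8, seed = 41)
  set.seed(42)
  for (i in 1:10) {
    pair <- sample.int(6, 2, replace = TRUE)
    gt <- diplotype_genotype(tb, pair[1], pair[2])
    full <- bg_predict(gt, tb)$total_score
    drop <- sample.int(6, 1)
    sub <- haplotype_table(as_tibble(tb)[-drop, ], ref = tb$loci$ref,
                           system = tb$system, gene = tb$gene)
    expect_gte(bg_predict(gt, sub)$total_score, full)
  }
})

test_that("one extra heterozygous alternate raises the optimum by at most 1", {
  tb <- random_haplotype_table(6, 8, seed = 51)
  set.seed(52)
  for (i in 1:10) {
    pair <- sample.int(6, 2, replace = TRUE)
    gt <- diplotype_genotype(tb, pair[1], pair[2])
    base <- bg_predict(gt, tb)$total_score
    # pick a locus without a record and add a het ref/alt pair where some
    # row carries the alternate
    free <- setdiff(seq_len(n_loci(tb)), match(gt$pos, tb$loci$pos))
    free <- free[vapply(free, function(j)
      any(tb$alleles[, j] != tb$loci$ref[j]), TRUE)]
    if (length(free) == 0L) next
    j <- free[1L]
    alt <- setdiff(tb$alleles[, j], tb$loci$ref[j])[1L]
    gt2 <- genotype(dplyr::bind_rows(
      tibble::as_tibble(gt)[, c("chrom", "pos", "allele_a", "allele_b")],
      tibble::tibble(chrom = tb$loci$chrom[j], pos = tb$loci$pos[j],
                     allele_a = tb$loci$ref[j], allele_b = alt)
    ))
    after <- bg_predict(gt2, tb)$total_score
    expect_lte(after, base + 1)
  }
})

test_that("exact recovery holds whenever the pair union is unique", {
  tb <- random_haplotype_table(8, 7, unique_unions = TRUE, seed = 61)
  for (i in seq_len(8)) {
    for (j in i:8) {
      call <- bg_predict(diplotype_genotype(tb, i, j), tb)
      expect_equal(call$total_score, 0)
      expect_false(call$ambiguous)
      expect_equal(sort(c(call$call_a$phenotype, call$call_b$phenotype)),
                   sort(tb$phenotype[c(i, j)]))
    }
  }
})

test_that("tidy ranking is ordered and flags the optimal configurations", {
  tb <- abo_table()
  call <- bg_predict(diplotype_genotype(tb, "A102", "B101"), tb)
  r <- tidy(call)
  expect_equal(r$rank, seq_len(nrow(r)))
  expect_true(all(diff(r$total_score) >= 0))
  expect_equal(sum(r$best), nrow(call$best_configurations))
  expect_equal(nchar(r$mask[1]), call$n_het)
  p <- autoplot(call)
  expect_s3_class(p, "ggplot")
})

test_that("predict_system reports each gene of a manifest independently", {
  dir <- withr::local_tempdir()
  tb_abo <- abo_table()
  write_haplotype_table(tb_abo, file.path(dir, "abo.tsv"))
  rhd <- random_haplotype_table(3, 4, seed = 71)
  rhd$gene <- "RHD"
  rhce <- random_haplotype_table(3, 4, seed = 72, start_pos = 90000L)
  rhce$gene <- "RHCE"
  write_haplotype_table(rhd, file.path(dir, "rhd.tsv"))
  write_haplotype_table(rhce, file.path(dir, "rhce.tsv"))
  writeLines(c("ABO\tabo.tsv", "Rh\trhd.tsv", "Rh\trhce.tsv"),
             file.path(dir, "manifest.tsv"))

  man <- read_system_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(man$system, c("ABO", "Rh", "Rh"))

  gt <- diplotype_genotype(tb_abo, "A101", "O02", sample_id = "huX")
  res <- predict_system(gt, man)
  expect_equal(nrow(res), 3L)
  expect_equal(res$system, c("ABO", "Rh", "Rh"))
  expect_equal(sort(c(res$phenotype_a[1], res$phenotype_b[1])),
               c("A101", "O02"))
  # Rh genes see no relevant variant: reference call on both chromatids
  expect_equal(res$phenotype_a[2:3], c("REF", "REF"))
  expect_true(all(is.na(res$error)))
})

test_that("one failing gene does not take down the other predictions", {
  tb <- abo_table()
  hg38 <- abo_table(); hg38$assembly <- "hg38"
  gt <- diplotype_genotype(tb, "A101", "B101")
  res <- predict_system(gt, list(tb, hg38))
  expect_true(is.na(res$error[1]))
  expect_match(res$error[2], "assembly")
  expect_error(predict_system(gt, list()),
               class = "hemotyper_validation_error")
})

test_that("thirty tables on one genotype stay fast", {
  tabs <- lapply(1:30, function(i) {
    tb <- random_haplotype_table(5, 6, seed = 300 + i,
                                 chrom = as.character((i %% 22) + 1),
                                 start_pos = 1000L * i)
    tb$system <- sprintf("SYS%02d", i)
    tb$gene <- tb$system
    tb
  })
  gt <- diplotype_genotype(tabs[[1]], 2, 3)
  t0 <- Sys.time()
  res <- predict_system(gt, tabs)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 5)
  expect_equal(nrow(res), 30L)
  expect_true(all(is.na(res$error)))
})
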