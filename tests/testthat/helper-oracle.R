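# Independent brute-force oracle for the phasing engine. Deliberately naive:
# enumerate every one of the 2^M labelings of the heterozygous loci, compute
# row distances with plain loops, and deduplicate chromatid swaps afterwards.
# Shares no code with the package's vectorized core.

# Observed state from a genotype data frame (chrom, pos, allele_a, allele_b)
# against a table given as (phenotype vector, allele matrix, loci df).
oracle_observe <- function(gt_df, table) {
  L <- nrow(table$loci)
  sa <- table$loci$ref
  sb <- table$loci$ref
  het <- integer()
  for (i in seq_len(L)) {
    hit <- which(sub("^chr", "", gt_df$chrom, ignore.case = TRUE) ==
                   sub("^chr", "", table$loci$chrom, ignore.case = TRUE)[i] &
                 gt_df$pos == table$loci$pos[i])
    if (length(hit) == 1L) {
      a <- gt_df$allele_a[hit]; b <- gt_df$allele_b[hit]
      sa[i] <- a; sb[i] <- b
      if (a != b) het <- c(het, i)
    }
  }
  list(sa = sa, sb = sb, het = het)
}

oracle_dist <- function(vec, row_alleles, weights) {
  d <- 0
  for (i in seq_along(vec)) {
    if (vec[i] != row_alleles[i]) d <- d + weights[i]
  }
  d
}

oracle_nearest <- function(vec, table) {
  w <- table$loci$weight
  d <- numeric(length(table$phenotype))
  for (r in seq_along(d)) d[r] <- oracle_dist(vec, table$alleles[r, ], w)
  list(dist = min(d), label = table$phenotype[which.min(d)])
}

# All 2^M labelings; returns best total score, the set of unordered best
# phenotype pairs, and the number of labelings surviving swap-deduplication.
oracle_predict <- function(gt_df, table) {
  obs <- oracle_observe(gt_df, table)
  m <- length(obs$het)
  n_label <- 2^m
  seen <- character()
  best_total <- Inf
  best_pairs <- character()
  for (k in seq_len(n_label) - 1L) {
    va <- obs$sa; vb <- obs$sb
    for (j in seq_len(m)) {
      bit <- bitwAnd(k, bitwShiftL(1L, j - 1L)) > 0L
      if (bit) {  # swap the pair at this heterozygous locus
        i <- obs$het[j]
        tmp <- va[i]; va[i] <- vb[i]; vb[i] <- tmp
      }
    }
    sig <- paste(c(va, "|", vb), collapse = "\r")
    sig_sw <- paste(c(vb, "|", va), collapse = "\r")
    if (sig %in% seen || sig_sw %in% seen) next
    seen <- c(seen, sig)
    na <- oracle_nearest(va, table)
    nb <- oracle_nearest(vb, table)
    tot <- na$dist + nb$dist
    pair <- paste(sort(c(na$label, nb$label)), collapse = " / ")
    if (tot < best_total) {
      best_total <- tot
      best_pairs <- pair
    } else if (tot == best_total) {
      best_pairs <- union(best_pairs, pair)
    }
  }
  list(best_total = best_total, best_pairs = sort(best_pairs),
       n_configs = length(seen))
}

# Random instance generator for property tests: a table plus a genotype that
# is not necessarily a clean diplotype (random per-locus pairs).
random_instance <- function(n_rows, n_loci, m_het, seed) {
  set.seed(seed)
  tb <- random_haplotype_table(n_rows, n_loci, p_alt = 0.4)
  bases <- c("A", "C", "G", "T")
  n_rec <- min(m_het + 2L, n_loci)
  loci_idx <- sample.int(n_loci, n_rec)
  recs <- lapply(seq_len(n_rec), function(j) {
    i <- loci_idx[j]
    pair <- if (j <= m_het) sample(bases, 2L) else rep(sample(bases, 1L), 2L)
    tibble::tibble(chrom = tb$loci$chrom[i], pos = tb$loci$pos[i],
                   allele_a = pair[1L], allele_b = pair[2L])
  })
  list(table = tb, gt = dplyr::bind_rows(recs))
}
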