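---
title: "Haplotype matching: how hemotyper phases and calls blood group diplotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype matching: how hemotyper phases and calls blood group diplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemotyper)
```

## The model

A blood group phenotype is determined by the combination of alleles carried
on each chromatid of one gene (or, for systems like Rh, a couple of genes).
`hemotyper` encodes that knowledge as a *haplotype table*: an ordered panel
of genomic loci plus one row per named phenotype, giving the allele a
single chromatid is expected to carry at every locus. The caller's job is
to explain an unphased genotype as a pair of such rows.

Two assumptions do all the work:

* **Generative assumption.** A sample's genotype at the gene is (up to
  noise) the union of two table haplotypes — one per chromatid. This is why
  a planted-diplotype simulator is the natural test harness for the engine.
* **Intra-gene linkage disequilibrium.** Alleles within the gene's coding
  region are inherited together, so whole-row matching is meaningful and a
  chromatid that partially matches several rows is *less* plausible than
  one matching a single row well. A meiotic crossover inside the gene
  violates this and will be mis-phased by design (see Limitations).

Homozygous variants sit on both chromatids and need no phasing. With *M*
heterozygous variants at table loci, each assignment of the heterozygous
alleles to the two chromatids is a *configuration*; pinning the first
heterozygous locus's first allele to chromatid A removes the A/B swap
symmetry, leaving `2^(M-1)` distinct configurations (`1` when `M = 0`).
The engine enumerates them all — exhaustive search, not statistical
phasing. Population-reference phasing (HapMap panels, HMM/EM methods) is
deliberately out of scope: it is expensive, and rare haplotypes — exactly
the interesting ones for minor blood groups — are invisible to it.

Each configuration's two allele vectors are labelled by the **1-nearest
neighbour** rule under the Hamming distance: the number of loci (weighted,
weights default to 1) where the chromatid and the row disagree, with each
allele cell compared as an atomic symbol. An anchored insertion (`"GG"` vs
reference `"G"`) mismatching costs 1, the same as a substitution; allele
strings are never aligned character by character. The configuration score
is the **sum** of the two chromatid distances, and the minimum-score
configuration — maximum parsimony — is the reported phase and diplotype.

### Why the sum?

For a joint phase-and-call criterion some combination of the two chromatid
distances is needed; we use the sum. It is the natural parsimony count
(total number of unexplained variant mismatches in the sample), it makes
the score of an exactly explained diplotype 0, and it treats the two
chromatids symmetrically. Minimizing the best single-chromatid distance
instead would let one perfectly matching chromatid mask an arbitrarily bad
partner. The brute-force oracle used in the test suite minimizes the same
summed objective over all `2^M` labelings, so any divergence between rule
variants would surface there.

### Ties and ambiguity

Two kinds of ties exist and both are surfaced, never resolved silently:

* *Within a chromatid*: several rows at the same minimal distance. The
  deterministic primary label is the first tied row in table order, and all
  tied labels are kept in `tied_rows`.
* *Across configurations*: several configurations at the same minimal total
  score. All are reported in `best_configurations`; if they disagree on the
  unordered phenotype pair the prediction is flagged `ambiguous`. Cohort
  evaluation counts ambiguous calls as errors — a caller that cannot
  distinguish an Rh+ from an Rh− explanation at equal score has not made a
  call. Population-frequency tie-breaking would be a natural extension but
  is intentionally not implemented.

## Parameters that matter

* **`missing`** (`exclude-locus`, `as-reference`, `fail`; default
  `exclude-locus`): what to do with a record whose alleles could not be
  called. Excluding the locus from every row's distance is the least biased
  default; `as-reference` reproduces the reference fill-in convention but
  silently favours reference-like rows; `fail` refuses the sample, which is
  the honest choice for clinical-style reporting. The three modes exist
  because exclusion-vs-assumption is a real trade-off, not a solved
  problem.
* **`max_het`** (default 20): enumeration cap on *M*, about `5×10^5`
  configurations — beyond it the engine errors and suggests restricting
  the panel. Single genes rarely show more than a handful of heterozygous
  exonic variants, so in practice the cap is never hit on real panels; it
  exists to fail loudly instead of hanging on pathological input.
* **Per-locus weights** (table metadata `#weights=`, default 1
  everywhere): uniform weighting is a known limitation — a single
  fully penetrant variant (such as the O-determining frameshift) can be
  outvoted by many co-occurring variants of another haplotype. The data
  model accepts non-uniform weights, but none of the shipped or simulated
  tables set them; choosing good weights is curation, not engine, work.
* **K = 1**: only the closest row labels a chromatid. Distance-weighted
  K > 1 voting is a conceivable extension, but the tables' rows are class
  *definitions*, not samples, so the nearest definition is the meaningful
  one.

## What the simulator does and does not emulate

`simulate_cohort()` draws two table rows per sample (uniformly by default),
forms the locus-wise allele pairs, then applies in order: call-level
**noise** (with probability `noise_rate` per locus, one chromatid's allele
is replaced by a base the table does not use there), **masking** (an
emitted record becomes a missing call with probability `missing_rate`), and
**panel subsetting** (`panel_loci`, emulating a sparse genotyping array as
opposed to whole-genome variant calls). Reference-homozygous loci emit no
record, so simulated files look like real caller output. Both noise and
missingness default to 0: the clean planted-diplotype regime in which exact
recovery must hold.

Draws are reproducible: each sample's RNG stream is derived from
`(seed, index)`, so cohorts are identical across runs and independent of
iteration order.

The simulator plants noise at the *variant call* level; it does not emulate
read-level sequencing error, alignment artefacts, indel left-shifting
across representations, linkage structure beyond "two table rows per
sample", or realistic population frequencies. Passing simulation tests
therefore demonstrates that the engine is correct *given its input
contract*, not that upstream variant calling meets that contract on real
genomes.

## Numerical and representational choices

* All table alleles are plus-strand genomic alleles of the stated assembly
  (even for minus-strand genes like ABO on 9q34), 1-based, anchored like
  VCF — so table cells compare directly with caller output and the engine
  contains no per-gene reverse-complement logic.
* Reference alleles travel in the table's `#ref=` metadata rather than
  requiring an assembly FASTA. In the shipped ABO excerpt the reference row
  is O02, reflecting that the hg19 reference sequence corresponds to the O
  group, and the reference at the indel locus is the short (`G`) allele.
* Chromosome names are normalized (`chr9` ≡ `9`); assemblies are not —
  an assembly mismatch between genotype and table is an error, never a
  silent lift-over.
* A position with several alternative alleles is encoded as several rows,
  one allele string per cell.
* Configurations are enumerated in a canonical binary order, ranking ties
  are broken by that order, and the engine contains no randomness, so
  reports are byte-reproducible.
* Genotypes with two different non-reference alleles (`1/2`-style calls),
  hemizygous calls (treated as homozygous), and indel records are all
  legal input; no indel left-normalization is attempted, so the genotype
  and the table must agree on the anchor representation.

## Problem sizes in the test suite

The suite checks exact recovery over every row pair of 1,000 randomly
generated 20-row × 10-locus tables with unique pairwise unions (210,000
predictions), brute-force agreement on 500 randomized instances with up to
8 heterozygous loci, enumeration counts against an independent
labeling-and-deduplication oracle for M = 0…10, and noise/panel
degradation on cohorts of 2,000 samples per operating point. These sizes
were chosen to give the randomized properties enough coverage to be
convincing while keeping a full test run in the minutes range.

## Known limitations

* **Crossover and hybrid alleles.** A recombination inside the gene (the
  classic RhD–RhCE hybrids, or an ABO crossover) breaks the whole-row
  matching assumption; such samples will be called as the nearest
  non-hybrid rows, possibly confidently.
* **Dominance is not modelled.** The output is two chromatid-level allele
  calls (e.g. A102 / O02); collapsing them to a serological phenotype
  (A, in that example) is left to the user.
* **Uniform weights** can overrule a single fully penetrant variant, as
  discussed above.
* **Sparse panels** may be structurally uninformative: if a panel's
  distinguishable haplotype space (see `haplotype_space()`) is smaller
  than the set of phenotypes, no algorithm can separate them, and the
  honest output is an ambiguous or reference-leaning call. The degradation
  experiments reproduce this regime deliberately.
* **Table quality is destiny.** The engine faithfully reflects its
  knowledge base; `validate_haplotype_table()` flags duplicate rows,
  non-discriminative loci and identically defined phenotypes, but cannot
  detect a wrong coordinate or a mis-curated allele.
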