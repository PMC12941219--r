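geneA_layout <- function(locus) {
  al <- locus$anchors$geneA$end_layout
  end_structure_layout(locus$anchors$geneA$end_fragment,
                       helix_motif = al$helix_motif, hairpin = al$hairpin,
                       linker = al$linker, trna_like = al$trna_like)
}

# gene plus its downstream tRNA-like element, transcript orientation
gene_with_tail <- function(leaf, pad = 80L) {
  tm <- truth_gene_model(leaf$truth, "geneA")
  subseq_dna(leaf$seq, tm$gene_iv$start,
             min(seq_len_bp(leaf$seq), tm$gene_iv$end + pad), id = leaf$seq$id)
}

test_that("end-structure lengths are exact at zero divergence", {
  fix <- local_cohort(seed = 1L)
  g <- subseq_dna(fix$locus$contig,
                  truth_gene_model(fix$locus$truth, "geneA")$gene_iv$start,
                  truth_gene_model(fix$locus$truth, "geneA")$gene_iv$end + 80L)
  es <- extract_end_structures(g, NULL, geneA_layout(fix$locus))
  expect_equal(es$helix_motif$length, 20L)
  expect_equal(es$hairpin$length, 29L)
  expect_equal(es$linker$length, 30L)
  expect_equal(es$trna_like$length, nchar(trna_like_reference("geneA")$seq))
})

test_that("indel-free evolution keeps hairpin and linker lengths constant", {
  fix <- local_cohort(seed = 3L, rates = list(indel_rate = 0))
  lens <- t(vapply(fix$cohort$leaves, function(lf) {
    es <- extract_end_structures(gene_with_tail(lf), NULL,
                                 geneA_layout(fix$locus))
    c(es$hairpin$length, es$linker$length)
  }, c(0L, 0L)))
  expect_equal(sd(lens[, 1]), 0)
  expect_equal(sd(lens[, 2]), 0)
  expect_true(all(lens[, 1] == 29L))
})

test_that("a missing element yields a partial model, not a failure", {
  fix <- local_cohort(seed = 1L)
  tm <- truth_gene_model(fix$locus$truth, "geneA")
  g <- subseq_dna(fix$locus$contig, tm$gene_iv$start, tm$gene_iv$end)  # no tail
  set.seed(6)
  chars <- strsplit(g$residues, "")[[1]]
  n <- length(chars)
  es <- extract_end_structures(dna_sequence("trunc", paste(chars, collapse = "")),
                               NULL, geneA_layout(fix$locus))
  expect_true(is.na(es$trna_like$length) || es$trna_like$end > n - 5)
  expect_equal(es$helix_motif$length, 20L)
})

test_that("column conservation counts identical columns correctly", {
  msa <- rep("ACGTACGT", 10)
  cc <- column_conservation(msa)
  expect_equal(cc$identical_fraction, 1)

  msa2 <- c(rep("ACGTACGT", 9), "ACGTACTT")  # one row mutated at column 7
  cc2 <- column_conservation(msa2)
  expect_false(cc2$identical[7])
  expect_equal(sum(cc2$identical), 7L)
  expect_error(column_conservation(character(0)))

  # gap handling: a mostly-gap column cannot be called identical
  msa3 <- c("A-", "A-", "AC", "AC", "A-")
  cc3 <- column_conservation(msa3)
  expect_true(cc3$identical[1])
  expect_false(cc3$identical[2])
})

test_that("the conserved gene's tRNA-like MSA is more conserved than the divergent one", {
  fix <- local_cohort(seed = 1L)
  msa_of <- function(nm) {
    seqs <- lapply(fix$cohort$leaves, function(lf) {
      f <- lf$truth$features
      tr <- f[f$name == nm, ]
      subseq_dna(lf$seq, tr$start, tr$end, id = lf$seq$id)
    })
    align_ref_anchored(unname(seqs))
  }
  ccA <- column_conservation(msa_of("trna_A"))
  ccB <- column_conservation(msa_of("trna_B"))
  expect_gt(ccB$identical_fraction, ccA$identical_fraction)
})

test_that("covariation scores reproduce their hand-classified cases exactly", {
  all_gc <- covariation(rep("GC", 10), data.frame(i = 1, j = 2))
  expect_equal(all_gc$score, 1)
  expect_equal(all_gc$n_compensatory, 0L)

  mixed <- covariation(c(rep("GC", 5), rep("AT", 5)), data.frame(i = 1, j = 2))
  expect_equal(mixed$score, 1)
  expect_equal(mixed$n_compensatory, 5L)

  half <- covariation(c(rep("GC", 5), rep("GA", 5)), data.frame(i = 1, j = 2))
  expect_equal(half$score, 0)
  expect_equal(half$n_inconsistent, 5L)

  # permutation invariance and bounds
  set.seed(131)
  rows <- sample(c("GC", "AT", "GA", "CU", "UG"), 30, TRUE)
  a <- covariation(rows, data.frame(i = 1, j = 2))
  b <- covariation(sample(rows), data.frame(i = 1, j = 2))
  expect_equal(a$score, b$score)
  expect_true(a$score >= -1 && a$score <= 1)
})

test_that("dot-bracket parsing validates balance", {
  p <- dotbracket_pairs("((..)).")
  expect_equal(p, data.frame(i = c(2L, 1L), j = c(5L, 6L)))
  expect_error(dotbracket_pairs("(()"), "unbalanced")
  expect_error(dotbracket_pairs("())"), "unbalanced")
})

test_that("compensatory constraint raises pair scores over free evolution", {
  canon <- c("AU", "UA", "GC", "CG", "GU", "UG")
  evolve_stem <- function(constrained, seed) {
    set.seed(seed)
    n_row <- 12; n_pair <- 10; m <- 0.3
    rows <- matrix("", n_row, 2 * n_pair)
    for (r in seq_len(n_row)) {
      for (p in seq_len(n_pair)) {
        pair <- "GC"
        if (runif(1) < m) {
          pair <- if (constrained) sample(canon, 1)
                  else paste0(sample(c("A", "C", "G", "U"), 1),
                              sample(c("A", "C", "G", "U"), 1))
        }
        rows[r, p] <- substr(pair, 1, 1)
        rows[r, 2 * n_pair - p + 1] <- substr(pair, 2, 2)
      }
    }
    msa <- apply(rows, 1, paste, collapse = "")
    pairs <- data.frame(i = seq_len(n_pair), j = 2 * n_pair - seq_len(n_pair) + 1)
    mean(covariation(msa, pairs)$score)
  }
  wins <- sum(vapply(1:20, function(s) {
    evolve_stem(TRUE, s) > evolve_stem(FALSE, s + 1000)
  }, TRUE))
  expect_gte(wins, 18L)
})
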