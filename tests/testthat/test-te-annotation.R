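toy_candidates <- data.frame(
  te_name = c("teA", "teB", "teC"),
  start = c(100L, 500L, 900L), end = c(350L, 570L, 1020L),
  pident = c(85, 99, 75), length = c(250L, 70L, 120L),
  te_coverage = c(250 / 300, 1.0, 0.9))

test_that("the 80-80-80 rule keeps exactly the qualifying candidate", {
  acc <- te_808080_filter(toy_candidates)
  expect_equal(nrow(acc), 1L)
  expect_equal(acc$te_name, "teA")   # teB fails min 80 bp, teC fails 80% identity
})

test_that("overlap resolution is greedy by identity-weighted length", {
  cand <- data.frame(te_name = c("hi", "lo"), start = c(100L, 190L),
                     end = c(300L, 340L), pident = c(100, 100),
                     length = c(200L, 150L), te_coverage = c(1, 1))
  acc <- te_808080_filter(cand)
  expect_equal(acc$te_name, "hi")

  # tie-break chain: equal score -> higher pident -> leftmost -> name
  tie <- data.frame(te_name = c("zeta", "alpha"), start = c(0L, 50L),
                    end = c(100L, 150L), pident = c(90, 90),
                    length = c(100L, 100L), te_coverage = c(1, 1))
  expect_equal(te_808080_filter(tie)$te_name, "zeta")
})

test_that("tightening any threshold never increases the accepted count", {
  set.seed(81)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    cand <- data.frame(
      te_name = paste0("te", seq_len(n)),
      start = sample(0:2000, n), pident = runif(n, 70, 100),
      length = sample(60:400, n, TRUE), te_coverage = runif(n, 0.6, 1))
    cand$end <- cand$start + cand$length
    base <- nrow(te_808080_filter(cand))
    expect_lte(nrow(te_808080_filter(cand, min_len = 120)), base)
    expect_lte(nrow(te_808080_filter(cand, min_pident = 90)), base)
    expect_lte(nrow(te_808080_filter(cand, min_coverage = 0.9)), base)
  }
})

test_that("the accepted set is independent, maximal and priority-consistent", {
  set.seed(82)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    cand <- data.frame(
      te_name = paste0("te", seq_len(n)),
      start = sample(0:1000, n), pident = runif(n, 80, 100),
      length = sample(80:300, n, TRUE), te_coverage = runif(n, 0.8, 1))
    cand$end <- cand$start + cand$length
    acc <- te_808080_filter(cand)
    overlaps <- function(a, b) min(a[2], b[2]) - max(a[1], b[1]) > 0
    if (nrow(acc) >= 2) {
      for (a in seq_len(nrow(acc) - 1)) for (b in (a + 1):nrow(acc))
        expect_false(overlaps(c(acc$start[a], acc$end[a]),
                              c(acc$start[b], acc$end[b])))
    }
    # maximality + greedy consistency: every rejected candidate overlaps an
    # accepted one of higher or equal priority
    rej <- cand[!cand$te_name %in% acc$te_name, , drop = FALSE]
    pri <- function(d) d$pident * d$length
    for (r in seq_len(nrow(rej))) {
      blockers <- vapply(seq_len(nrow(acc)), function(a) {
        overlaps(c(rej$start[r], rej$end[r]), c(acc$start[a], acc$end[a])) &&
          pri(acc[a, ]) >= pri(rej[r, ]) - 1e-9
      }, TRUE)
      expect_true(any(blockers))
    }
  }
})

test_that("planted TEs are recovered by name with a clean control", {
  fix <- local_cohort(seed = 1L)
  lib <- default_te_library()
  lf <- fix$cohort$leaves$L4
  g <- truth_gene_seq(lf)
  ann <- annotate_tes(g, lib)
  truth_te <- lf$truth$features[lf$truth$features$type == "repeat_region", ]
  expect_equal(nrow(ann), 6L)
  expect_setequal(ann$te_name, sub("\\.\\d+$", "", truth_te$name))

  set.seed(83)
  control <- dna_sequence("ctrl", rnd_dna(21000,
                                          c(A = .28, C = .19, G = .22, T = .31)))
  expect_equal(nrow(annotate_tes(control, lib)), 0L)
})

test_that("positional profiles bin by midpoint and flip cleanly", {
  ann <- data.frame(te_name = "x", start = 6900L, end = 7100L)  # midpoint 7000
  p <- te_positional_profile(ann, 20000L, n_bins = 20)
  expect_equal(which(p$counts == 1L) - 1L, 7L)   # 35% -> 0-based bin 7
  expect_equal(sum(p$counts), 1L)

  p0 <- te_positional_profile(ann[0, ], 20000L)
  expect_true(all(p0$counts == 0L))

  # reverse-complementing the gene and flipping coordinates mirrors the bins
  # (generic midpoint: a midpoint exactly on a bin edge flips asymmetrically)
  L <- 20000L
  ann2 <- data.frame(te_name = "x", start = 6900L, end = 7110L)
  p2 <- te_positional_profile(ann2, L, n_bins = 20)
  flipped <- data.frame(te_name = "x", start = L - ann2$end, end = L - ann2$start)
  pf <- te_positional_profile(flipped, L, n_bins = 20)
  expect_equal(p2$counts, rev(pf$counts))
})

test_that("presence matrix flags a planted excision and only that", {
  tree3 <- "((X:0.02,Y:0.02):0.01,Z:0.03);"
  locus <- build_root_locus(synthetic_locus_spec(), 55L)
  te_nm <- locus$truth$features$name[locus$truth$features$type == "repeat_region"][2]
  coh <- evolve_along_tree(locus, tree3, seed = 55L,
                           planted_excisions = setNames(list(te_nm), "Y"))
  lib <- default_te_library()
  genes <- lapply(coh$leaves, truth_gene_seq)
  anns <- lapply(genes, annotate_tes, library = lib)
  pm <- te_presence_matrix(anns, genes, tree3)
  expect_equal(dim(pm$status), c(3L, 6L))
  expect_equal(nrow(pm$excisions), 1L)
  expect_equal(pm$excisions$leaf, "Y")
  loc <- pm$excisions$locus
  expect_equal(unname(pm$status["Y", loc]), "absent")
  expect_true(all(pm$status[c("X", "Z"), loc] == "present"))

  # no excisions planted: zero flags
  coh0 <- evolve_along_tree(locus, tree3, seed = 56L)
  genes0 <- lapply(coh0$leaves, truth_gene_seq)
  anns0 <- lapply(genes0, annotate_tes, library = lib)
  pm0 <- te_presence_matrix(anns0, genes0, tree3)
  expect_equal(nrow(pm0$excisions), 0L)
  expect_true(all(pm0$status == "present"))
})

test_that("a deleted flank yields unresolved, never absent", {
  tree3 <- "((X:0.01,Y:0.01):0.01,Z:0.02);"
  locus <- build_root_locus(synthetic_locus_spec(), 57L)
  coh <- evolve_along_tree(locus, tree3, seed = 57L)
  lib <- default_te_library()
  genes <- lapply(coh$leaves, truth_gene_seq)
  anns <- lapply(genes, annotate_tes, library = lib)
  # erase one TE plus its flanks from Z
  tz <- anns$Z[1, ]
  gz <- genes$Z
  set.seed(4)
  lo <- max(0, tz$start - 220); hi <- min(seq_len_bp(gz), tz$end + 220)
  chars <- strsplit(gz$residues, "")[[1]]
  chars[(lo + 1):hi] <- sample(c("A", "C", "G", "T"), hi - lo, TRUE)
  genes$Z <- dna_sequence("Z", paste(chars, collapse = ""))
  anns$Z <- annotate_tes(genes$Z, lib)
  pm <- te_presence_matrix(anns, genes, tree3)
  loc <- pm$loci$name[pm$loci$te_name == tz$te_name][1]
  expect_equal(unname(pm$status["Z", loc]), "unresolved")
})
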