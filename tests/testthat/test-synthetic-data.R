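test_that("root locus construction plants the specified architecture", {
  spec <- synthetic_locus_spec()
  locus <- build_root_locus(spec, 1L)
  expect_gte(seq_len_bp(locus$contig), 21000 + 7000 + 36755)
  f <- locus$truth$features
  gA <- f[f$type == "gene" & f$gene == "geneA", ]
  expect_equal(gA$end - gA$start, 21000L)
  pas <- f[f$type == "polyA_signal", ]
  expect_equal(pas$start, gA$start + 3500L)
  expect_equal(substr(locus$contig$residues, pas$start + 1, pas$start + 6),
               "AATAAA")
  expect_equal(substr(locus$contig$residues, gA$start + 1, gA$start + 6),
               "TATAAA")
  gB <- f[f$type == "gene" & f$gene == "geneB", ]
  expect_equal(gB$start - gA$end, 36755L)
  expect_equal(sum(f$type == "repeat_region"), 6L)
  expect_equal(sum(f$type == "inverted_repeat"), 4L)  # 2 pairs

  # zero-feature control
  spec0 <- synthetic_locus_spec(n_te = 0, n_inverted_repeat_pairs = 0,
                                n_g4 = 0, plant_pas = FALSE)
  f0 <- build_root_locus(spec0, 1L)$truth$features
  expect_equal(sum(f0$type %in% c("repeat_region", "inverted_repeat",
                                  "G_quadruplex", "polyA_signal")), 0L)

  # determinism: same spec and seed give a byte-identical contig
  expect_identical(build_root_locus(spec, 7L)$contig$residues,
                   build_root_locus(spec, 7L)$contig$residues)
  expect_false(identical(build_root_locus(spec, 7L)$contig$residues,
                         build_root_locus(spec, 8L)$contig$residues))
})

test_that("the planted PAS is the only motif in its guard zone", {
  locus <- build_root_locus(synthetic_locus_spec(), 3L)
  f <- locus$truth$features
  gA <- f[f$type == "gene" & f$gene == "geneA", ]
  pas <- f[f$type == "polyA_signal", ]$start - gA$start
  g <- extract_gene_sequence(locus$contig, truth_gene_model(locus$truth, "geneA"))
  win <- substr(g$residues, pas - 600 + 1, pas + 606)
  m <- gregexpr("AATAAA", win, fixed = TRUE)[[1]]
  expect_equal(as.integer(m), 601L)  # exactly the planted one

  # marsupial mode: second signal ~500 bp downstream
  locm <- build_root_locus(synthetic_locus_spec(marsupial_pas = TRUE), 3L)
  offs <- truth_pas_offsets(locm$truth)
  expect_length(offs, 2L)
  expect_equal(diff(offs), 500L)
})

test_that("evolution with zero rates reproduces the root at every leaf", {
  fix <- local_cohort(seed = 2L)
  coh0 <- evolve_along_tree(fix$locus, default_tree(),
                            rates = list(subst_rate_scale = 0, indel_rate = 0),
                            seed = 2L)
  for (lf in coh0$leaves) {
    expect_identical(lf$seq$residues, fix$locus$contig$residues)
    expect_equal(lf$truth$features, fix$locus$truth$features,
                 ignore_attr = TRUE)
  }
})

test_that("pairwise identity of JC69-evolved leaves matches the closed form", {
  locus <- build_root_locus(synthetic_locus_spec(), 5L)
  for (d in c(0.1, 0.25)) {
    tree <- sprintf("(A:%f,B:%f);", d / 2, d / 2)
    coh <- evolve_along_tree(locus, tree, rates = list(indel_rate = 0),
                             seed = 17L)
    a <- truth_gene_seq(coh$leaves$A)$residues
    b <- truth_gene_seq(coh$leaves$B)$residues
    obs <- mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
    expf <- 1 / 4 + 3 / 4 * exp(-4 * d / 3)
    tol <- 3 * sqrt(expf * (1 - expf) / nchar(a)) + 130 / nchar(a)
    expect_lt(abs(obs - expf), tol)
  }
})

test_that("truth coordinates lift exactly through indels along the tree", {
  fix <- local_cohort(seed = 4L)
  lib <- default_te_library()
  lf <- fix$cohort$leaves$L6
  f <- lf$truth$features
  tes <- f[f$type == "repeat_region", ]
  expect_equal(nrow(tes), 6L)
  for (i in seq_len(nrow(tes))) {
    fam <- sub("\\.\\d+$", "", tes$name[i])
    tseq <- subseq_dna(lf$seq, tes$start[i], tes$end[i], id = "te")
    h <- local_align(lib[[fam]], tseq, min_len = 50)
    expect_gte(nrow(h), 1L)
    expect_gte(h$pident[1], 80)
    expect_gte(h$length[1], 0.9 * seq_len_bp(lib[[fam]]))
  }
  # inverted-repeat arms remain reverse-complementary
  irs <- f[f$type == "inverted_repeat", ]
  a1 <- subseq_dna(lf$seq, irs$start[1], irs$end[1], id = "a1")
  a2 <- subseq_dna(lf$seq, irs$start[2], irs$end[2], id = "a2")
  h <- local_align(a1, reverse_complement(a2), min_len = 100)
  expect_gte(nrow(h), 1L)
  expect_gte(h$pident[1], 80)
})

test_that("planted truth serializes losslessly to GFF3 + JSON", {
  fix <- local_cohort(seed = 1L)
  truth <- fix$cohort$leaves$L3$truth
  gff <- tempfile(fileext = ".gff3")
  js <- tempfile(fileext = ".json")
  write_truth(truth, gff, js)
  back <- read_truth(gff, js)
  expect_equal(back$features, truth$features, ignore_attr = TRUE)
  expect_equal(back$zones, truth$zones, ignore_attr = TRUE)
  expect_equal(back$params$seed, truth$params$seed)
  expect_equal(back$params$spec$geneA_length, truth$params$spec$geneA_length)
  expect_equal(back$contig_id, truth$contig_id)
})

test_that("raising the substitution rate monotonically lowers leaf ANI", {
  locus <- build_root_locus(synthetic_locus_spec(), 6L)
  anis <- vapply(c(0.5, 1, 2), function(sc) {
    coh <- evolve_along_tree(locus, "(A:0.05,B:0.05);",
                             rates = list(subst_rate_scale = sc,
                                          indel_rate = 0), seed = 23L)
    ani_pair(truth_gene_seq(coh$leaves$A), truth_gene_seq(coh$leaves$B))$ani
  }, 0)
  expect_true(all(diff(anis) < 0))
})

test_that("a planted excision removes the TE from exactly one leaf", {
  locus <- build_root_locus(synthetic_locus_spec(), 9L)
  te_nm <- locus$truth$features$name[locus$truth$features$type == "repeat_region"][1]
  coh <- evolve_along_tree(locus, default_tree(), seed = 9L,
                           planted_excisions = setNames(list(te_nm), "L4"))
  for (nm in names(coh$leaves)) {
    present <- te_nm %in% coh$leaves[[nm]]$truth$features$name
    expect_equal(present, nm != "L4")
  }
  ev <- coh$leaves$L4$truth$events
  expect_true(any(ev$event == "excision" & ev$name == te_nm))
  # requesting an excision of a missing TE is skipped with a log entry
  expect_message(
    coh2 <- evolve_along_tree(locus, default_tree(), seed = 9L,
                              planted_excisions = setNames(list("nonexistent.99"),
                                                           "L1")),
    "skipped")
})
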