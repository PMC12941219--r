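# A gene-like sequence guaranteed free of spurious PAS motifs except the
# ones planted.
clean_gene <- function(n, plants = integer()) {
  res <- rnd_dna(n)
  while (grepl("AATAAA", res, fixed = TRUE))
    res <- sub("AATAAA", "AACAAA", res, fixed = TRUE)
  chars <- strsplit(res, "")[[1]]
  for (p in plants) chars[(p + 1):(p + 6)] <- c("A", "A", "T", "A", "A", "A")
  dna_sequence("g", paste(chars, collapse = ""))
}

test_that("reference PAS projection handles identity, offsets and failure", {
  set.seed(71)
  ref <- clean_gene(8000, plants = 3500)
  expect_equal(project_reference_pas(ref, ref, 3500), 3500L)

  ins <- dna_sequence("ins", paste0(substr(ref$residues, 1, 2000), rnd_dna(100),
                                    substr(ref$residues, 2001, 8000)))
  expect_equal(project_reference_pas(ins, ref, 3500), 3600L)

  unrelated <- clean_gene(8000)
  expect_true(is_no_call(project_reference_pas(unrelated, ref, 3500)))
})

test_that("projection recovers the planted PAS on evolved leaves", {
  fix <- local_cohort(seed = 1L)
  ref <- truth_gene_seq(fix$cohort$leaves$L1)
  ref_pas <- truth_pas_offsets(fix$cohort$leaves$L1$truth)[1]
  ok <- 0L
  for (nm in names(fix$cohort$leaves)[-1]) {
    lf <- fix$cohort$leaves[[nm]]
    g <- truth_gene_seq(lf)
    proj <- project_reference_pas(g, ref, ref_pas)
    truthp <- truth_pas_offsets(lf$truth)[1]
    if (!is_no_call(proj) && abs(proj - truthp) <= 30) ok <- ok + 1L
  }
  expect_gte(ok, 4L)  # 5 leaves tested
})

test_that("the single-motif window rule calls, rejects and flags ambiguity", {
  set.seed(73)
  g1 <- clean_gene(6000, plants = 3550)
  call <- call_main_pas(g1, 3500)
  expect_equal(call$status, "called")
  expect_equal(call$offset_from_projection, 50L)
  expect_equal(call$position, 3550L)

  g2 <- clean_gene(6000, plants = 3650)   # +150: outside the 110 bp window
  nc <- call_main_pas(g2, 3500)
  expect_equal(nc$status, "no_call")
  expect_equal(nc$reason, "absent")
  # but a wider window finds it
  expect_equal(call_main_pas(g2, 3500, window = 200)$status, "called")

  g3 <- clean_gene(6000, plants = c(3470, 3540))  # -30 and +40
  amb <- call_main_pas(g3, 3500)
  expect_equal(amb$status, "no_call")
  expect_equal(amb$reason, "ambiguous")
})

test_that("alternative-PAS scan reports exactly the planted nearby signals", {
  set.seed(74)
  g <- clean_gene(6000, plants = 3500)
  main <- call_main_pas(g, 3500)
  expect_equal(nrow(find_alternative_pas(g, main)), 0L)

  g2 <- clean_gene(6000, plants = c(3500, 3980))
  main2 <- call_main_pas(g2, 3500)
  alt <- find_alternative_pas(g2, main2)
  expect_equal(alt$position, 3980L)
  expect_equal(alt$offset, 480L)
  # a signal outside the 600 bp window is not reported
  g3 <- clean_gene(6000, plants = c(3500, 4200))
  expect_equal(nrow(find_alternative_pas(g3, call_main_pas(g3, 3500))), 0L)
})

test_that("marsupial two-PAS loci yield one main and one ~+500 alternative", {
  spec <- synthetic_locus_spec(marsupial_pas = TRUE)
  locus <- build_root_locus(spec, 31L)
  coh <- evolve_along_tree(locus, default_tree(), seed = 31L)
  for (nm in c("L1", "L6")) {
    lf <- coh$leaves[[nm]]
    g <- truth_gene_seq(lf)
    offs <- truth_pas_offsets(lf$truth)
    main <- call_main_pas(g, offs[1])
    expect_equal(main$status, "called")
    alt <- find_alternative_pas(g, main, kind = "marsupial_pair")
    expect_equal(nrow(alt), 1L)
    expect_lte(abs(alt$offset - 500), 30)
    expect_equal(alt$kind, "marsupial_pair")
  }
})

test_that("calls are strand-consistent and equal a brute-force motif scan", {
  set.seed(75)
  for (i in 1:5) {
    plants <- sort(sample(seq(3100, 3900, by = 25), 3))
    g <- clean_gene(6000, plants = plants)
    main_pos <- plants[2]
    main <- structure(list(status = "called", position = main_pos,
                           motif = "AATAAA", kind = "main",
                           offset_from_projection = 0L,
                           reason = NA_character_), class = "pas_call")
    alt <- find_alternative_pas(g, main, window = 600)
    brute <- as.integer(gregexpr("AATAAA", g$residues, fixed = TRUE)[[1]]) - 1L
    brute <- brute[abs(brute - main_pos) <= 600 & brute != main_pos]
    expect_equal(sort(alt$position), sort(brute))
    # shrinking the window never adds calls
    alt_narrow <- find_alternative_pas(g, main, window = 200)
    expect_true(all(alt_narrow$position %in% alt$position))

    # strand consistency: transcript coordinates survive reverse complement
    rc <- reverse_complement(g)
    rc_hits <- as.integer(gregexpr("TTTATT", rc$residues, fixed = TRUE)[[1]]) - 1L
    mapped <- sort(seq_len_bp(g) - rc_hits - 6L)
    expect_true(all(sort(c(main_pos, brute)) %in% mapped))
  }
})

test_that("positional rescue calls a lone motif in the prior window", {
  set.seed(76)
  g <- clean_gene(8000, plants = 3400)
  r <- call_rescue_pas(g)
  expect_equal(r$status, "called")
  expect_true(isTRUE(r$rescue))
  expect_equal(r$position, 3400L)
  g2 <- clean_gene(8000)
  expect_equal(call_rescue_pas(g2)$reason, "absent")
  g3 <- clean_gene(8000, plants = c(3200, 4000))
  expect_equal(call_rescue_pas(g3)$reason, "ambiguous")
})
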