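test_that("reverse complement follows Watson-Crick pairing and is an involution", {
  expect_equal(reverse_complement(dna_sequence("s", "ACGT"))$residues, "ACGT")
  expect_equal(reverse_complement(dna_sequence("s", "AAAC"))$residues, "GTTT")
  expect_equal(reverse_complement(dna_sequence("s", "ANT"))$residues, "ANT")
  set.seed(11)
  for (i in 1:100) {
    s <- dna_sequence("r", rnd_dna(50))
    expect_equal(reverse_complement(reverse_complement(s))$residues, s$residues)
  }
  expect_error(dna_sequence("bad", "ACGU"), "alphabet")
})

test_that("k-mer counting covers all windows and skips N-containing ones", {
  cc <- kmer_counts(dna_sequence("a", "AAAA"), 2)
  expect_equal(unname(cc[["AA"]]), 3L)
  expect_equal(sum(cc), 3L)
  set.seed(3)
  s <- dna_sequence("b", rnd_dna(500))
  c6 <- kmer_counts(s, 6)
  expect_equal(sum(c6), 500L - 5L)
  expect_equal(attr(c6, "skipped"), 0L)
  expect_length(c6, 4096L)           # the full hexamer key space
  sn <- dna_sequence("n", paste0(rnd_dna(100), "N", rnd_dna(100)))
  cn <- kmer_counts(sn, 6)
  expect_equal(sum(cn) + attr(cn, "skipped"), 201L - 5L)
  expect_equal(attr(cn, "skipped"), 6L)  # six windows touch the N
  expect_warning(out <- kmer_counts(dna_sequence("t", "ACG"), 5), "length")
  expect_length(out, 0L)
})

test_that("local alignment finds identity, planted and no spurious homology", {
  set.seed(21)
  a <- dna_sequence("a", rnd_dna(500))
  h <- local_align(a, a)
  hp <- h[h$strand == "+", ]
  expect_equal(nrow(hp), 1L)
  expect_equal(hp$pident, 100)
  expect_equal(hp$length, 500L)
  expect_equal(c(hp$qstart, hp$qend), c(0L, 500L))

  # 300 bp fragment planted in 5 kb background with 5% point mutations
  frag <- rnd_dna(300)
  mut <- mutate_chr(frag, 15)
  bg <- rnd_dna(5000)
  subj <- dna_sequence("s", paste0(substr(bg, 1, 2000), mut,
                                   substr(bg, 2001, 5000)))
  h2 <- local_align(dna_sequence("q", frag), subj)
  top <- h2[1, ]
  expect_gte(top$qend - top$qstart, 0.95 * 300)
  expect_gte(top$pident, 90)
  expect_lte(top$pident, 100)
  expect_lte(abs(top$sstart - 2000), 10)

  # independent random sequences: no hit at min_len 100
  for (i in 1:50) {
    q <- dna_sequence("q", rnd_dna(200))
    s <- dna_sequence("s", rnd_dna(200))
    expect_equal(nrow(local_align(q, s, min_len = 100)), 0L)
  }
})

test_that("alignment is symmetric under query/subject role swap", {
  set.seed(31)
  for (i in 1:5) {
    core <- rnd_dna(400)
    q <- dna_sequence("q", paste0(rnd_dna(300), mutate_chr(core, 20), rnd_dna(200)))
    s <- dna_sequence("s", paste0(rnd_dna(150), core, rnd_dna(350)))
    h1 <- local_align(q, s)
    h2 <- local_align(s, q)
    expect_equal(nrow(h1), nrow(h2))
    k1 <- h1[order(h1$qstart, h1$sstart),
             c("qstart", "qend", "sstart", "send", "pident", "length")]
    k2 <- h2[order(h2$sstart, h2$qstart),
             c("sstart", "send", "qstart", "qend", "pident", "length")]
    names(k2) <- names(k1)
    expect_equal(k1, k2, ignore_attr = TRUE)
  }
})

test_that("identity-weighted hit length never exceeds alignment length", {
  set.seed(41)
  core <- rnd_dna(300)
  q <- dna_sequence("q", mutate_chr(core, 12))
  s <- dna_sequence("s", paste0(rnd_dna(100), core, rnd_dna(100)))
  h <- local_align(q, s)
  expect_true(nrow(h) >= 1)
  w <- h$pident / 100 * h$length
  expect_true(all(w <= h$length + 1e-9))
  hid <- local_align(q, q)
  expect_true(all(abs(hid$pident[1] - 100) < 1e-12))
  expect_equal(hid$pident[1] / 100 * hid$length[1], hid$length[1])
})

test_that("HSP identity agrees with a DP local-alignment oracle on short inputs", {
  set.seed(51)
  # unique-optimum cases: flanks that cannot align, interior-only mutations
  for (i in 1:20) {
    core <- rnd_dna(40)
    chars <- strsplit(core, "")[[1]]
    for (p in sample(5:35, sample(0:3, 1)))
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    a <- paste0(strrep("A", 12), core, strrep("A", 12))
    b <- paste0(strrep("C", 10), paste(chars, collapse = ""), strrep("C", 14))
    h <- local_align(dna_sequence("a", a), dna_sequence("b", b),
                     both_strands = FALSE, min_len = 10)
    orc <- sw_oracle_pident(a, b)
    expect_gte(nrow(h), 1L)
    expect_lte(abs(h$pident[1] - orc[["pident"]]), 1)
    expect_equal(h$score[1], unname(orc[["score"]]))
  }
  # general random cases: optimal score always matches the DP oracle
  for (i in 1:10) {
    core <- rnd_dna(40)
    a <- paste0(rnd_dna(12), core, rnd_dna(12))
    b <- paste0(rnd_dna(10), mutate_chr(core, sample(0:3, 1)), rnd_dna(14))
    h <- local_align(dna_sequence("a", a), dna_sequence("b", b),
                     both_strands = FALSE, min_len = 10)
    orc <- sw_oracle_pident(a, b)
    expect_equal(h$score[1], unname(orc[["score"]]))
  }
})

test_that("HSP tables and FASTA round-trip through their writers", {
  set.seed(61)
  seqs <- list(dna_sequence("s1", rnd_dna(80), meta = c(taxon = "x")),
               dna_sequence("s2", rnd_dna(133)))
  fa <- tempfile(fileext = ".fasta")
  write_dna_fasta(seqs, fa)
  back <- read_dna_fasta(fa)
  expect_equal(names(back), c("s1", "s2"))
  expect_equal(back$s2$residues, seqs[[2]]$residues)

  a <- dna_sequence("a", rnd_dna(300))
  h <- local_align(a, a)
  tsv <- tempfile(fileext = ".tsv")
  write_hsp_table(h, tsv)
  lines <- readLines(tsv)
  expect_match(lines[1], "0-based")
  expect_equal(strsplit(lines[2], "\t")[[1]],
               c("qid", "sid", "qstart", "qend", "sstart", "send", "strand",
                 "pident", "length", "score"))
})

test_that("genomic intervals validate their invariants", {
  iv <- genomic_interval("c", 10, 20, "+")
  expect_equal(iv$end - iv$start, 10L)
  expect_error(genomic_interval("c", 20, 10), "start")
  expect_error(genomic_interval("c", -1, 10), "start")
  expect_error(genomic_interval("c", 0, 10, "x"), "strand")
})
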