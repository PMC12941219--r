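jaspar_file <- function() {
  f <- tempfile(fileext = ".jaspar")
  writeLines(c(
    ">MA0001.1 TFA",
    "A  [ 10  0  0  5  2  1  0  9 ]",
    "C  [  0 10  0  3  2  1  0  0 ]",
    "G  [  0  0 10  1  4  1 10  0 ]",
    "T  [  0  0  0  1  2  7  0  1 ]",
    ">MA0002.1 TFB",
    "A 1 2 3 4",
    "C 1 2 3 4",
    "G 1 2 3 2",
    "T 7 4 1 0"), f)
  f
}

test_that("JASPAR and MEME readers produce identical pseudocounted PWMs", {
  ps <- read_pwms(jaspar_file())
  expect_length(ps, 2L)
  expect_equal(ps[[1]]$tf_name, "TFA")
  expect_equal(ps[[1]]$width, 8L)
  expect_true(all(abs(colSums(ps[[1]]$matrix) - 1) < 1e-9))

  # MEME letter-probability block with the equivalent counts (nsites 10)
  f2 <- tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "MOTIF TFB", "",
               "letter-probability matrix: alength= 4 w= 4 nsites= 10 E= 0",
               " 0.1 0.1 0.1 0.7", " 0.2 0.2 0.2 0.4", " 0.3 0.3 0.3 0.1",
               " 0.4 0.4 0.2 0.0"), f2)
  pm <- read_pwms(f2)[[1]]
  expect_equal(pm$matrix, ps[[2]]$matrix, tolerance = 1e-12)

  # malformed record skipped with a warning; empty file errors
  f3 <- tempfile()
  writeLines(c(">BAD broken", "A 1 2", "C 1", ">MA0003.1 OK",
               "A 1 1 2 1", "C 1 1 1 1", "G 1 1 1 2", "T 1 1 1 1"), f3)
  expect_warning(ok <- read_pwms(f3), "malformed")
  expect_length(ok, 1L)
  f4 <- tempfile(); writeLines(character(0), f4)
  expect_error(read_pwms(f4), "empty")
})

test_that("the exact DP null distribution matches brute-force enumeration", {
  set.seed(141)
  for (w in c(4L, 6L, 8L)) {
    p <- random_pwm(paste0("w", w), w)
    d <- pwm_score_distribution(p)
    expect_lt(abs(sum(d$probs) - 1), 1e-12)
    expect_true(all(diff(d$pvalues) <= 1e-15))
    s <- round(log2(p$matrix / 0.25) / 0.001)
    words <- as.matrix(expand.grid(rep(list(1:4), w)))
    sc <- vapply(seq_len(nrow(words)), function(i)
      sum(s[cbind(words[i, ], seq_len(w))]), 0)
    # enumeration oracle: uniform background, each word probability 4^-w
    qs <- sort(unique(sc))
    picks <- qs[unique(pmax(1, round(length(qs) * c(0.5, 0.9, 0.99, 1))))]
    for (q in picks) {
      p_enum <- mean(sc >= q)
      p_dp <- d$pvalues[max(1, min(length(d$pvalues), q - d$min_score + 1))]
      expect_lt(abs(p_enum - p_dp), 1e-9)
    }
  }
})

test_that("scanning finds a planted consensus site at maximal score", {
  set.seed(142)
  p <- sharp_pwm("SHARP", "TGACGTCA")
  bg <- rnd_dna(800)
  s <- dna_sequence("prom", paste0(substr(bg, 1, 400), "TGACGTCA",
                                   substr(bg, 401, 800)))
  hits <- scan_pwm(s, p)
  expect_true(400 %in% hits$start)
  top <- hits[hits$start == 400, ]
  d <- pwm_score_distribution(p)
  max_score <- (length(d$pvalues) - 1 + d$min_score) * d$granularity
  expect_equal(top$score, max_score, tolerance = 1e-9)

  # uniform PWM scores 0 everywhere: p = 1, no hits
  u <- pwm("UNIF", matrix(0.25, 4, 6))
  expect_equal(nrow(scan_pwm(s, u)), 0L)

  # lowering the threshold never adds hits
  h_loose <- scan_pwm(s, p, pthresh = 1e-3)
  h_tight <- scan_pwm(s, p, pthresh = 1e-5)
  expect_true(all(h_tight$start %in% h_loose$start))
})

test_that("minus-strand hits equal a forward scan of the reverse complement", {
  set.seed(143)
  p <- sharp_pwm("S2", "GATTACA")
  s <- dna_sequence("x", paste0(rnd_dna(200), "TGTAATC", rnd_dna(200)))
  both <- scan_pwm(s, p, pthresh = 1e-3)
  minus <- both[both$strand == "-", ]
  fwd_on_rc <- scan_pwm(reverse_complement(s), p, pthresh = 1e-3,
                        both_strands = FALSE)
  L <- seq_len_bp(s)
  expect_setequal(minus$start, L - fwd_on_rc$end)
  expect_true(200 %in% minus$start)
})

test_that("shared-TF selection applies the prevalence threshold inclusively", {
  hits <- c(lapply(1:7, function(i) "TF1"), lapply(1:3, function(i) character(0)))
  names(hits) <- paste0("g", 1:10)
  for (i in 1:6) hits[[i]] <- c(hits[[i]], "TF2")
  sh <- shared_tfs(hits, fraction = 0.65)
  expect_true("TF1" %in% sh$tf_name)      # 7/10 = 0.70 >= 0.65
  expect_false("TF2" %in% sh$tf_name)     # 6/10 = 0.60 < 0.65
  expect_equal(sh$n_genes[sh$tf_name == "TF1"], 7L)
})

test_that("a planted TF is recovered across promoters with rare decoys", {
  set.seed(144)
  planted <- sharp_pwm("PLANTED", "TTGACGTCAT")
  decoys <- lapply(1:10, function(i) random_pwm(paste0("DECOY", i), 8))
  n_gene <- 8
  hits <- list()
  for (g in seq_len(n_gene)) {
    bg <- rnd_dna(1000)
    prom <- dna_sequence(paste0("g", g),
                         paste0(substr(bg, 1, 500), "TTGACGTCAT",
                                substr(bg, 501, 1000)))
    hh <- do.call(rbind, lapply(c(list(planted), decoys), scan_pwm, seq = prom))
    hits[[paste0("g", g)]] <- hh
  }
  sh <- shared_tfs(hits, fraction = 0.65)
  expect_true("PLANTED" %in% sh$tf_name)
  expect_lte(sum(grepl("DECOY", sh$tf_name)), 1L)
})

test_that("GO joining counts terms over the shared TF list", {
  go <- data.frame(tf = c("TF1", "TF1", "TF2", "TF3"),
                   term = c("apoptosis", "circadian", "apoptosis", "neuro"))
  out <- go_term_summary(c("TF1", "TF2"), go)
  expect_equal(out$n_tfs[out$term == "apoptosis"], 2L)
  expect_false("neuro" %in% out$term)
  expect_equal(out$tf_list[out$term == "apoptosis"], "TF1,TF2")
  expect_equal(shared_tf_intersection(c("A", "B", "C"), c("B", "C", "D")),
               c("B", "C"))
})
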