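# Shared fixtures and independent oracles for the test suite.

rnd_dna <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

mutate_chr <- function(res, n_mut) {
  chars <- strsplit(res, "")[[1]]
  pos <- sample(length(chars), n_mut)
  for (p in pos)
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}

# Independent dynamic-programming local-alignment oracle (Biostrings
# Smith-Waterman), same scoring as the package aligner.
sw_oracle_pident <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                       Biostrings::DNAString(b),
                                       type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 5, gapExtension = 2)
  c(pident = Biostrings::pid(aln, type = "PID1"),
    score = Biostrings::score(aln))
}

# Brute-force G-quadruplex oracle: enumerate all windows of four
# consecutive qualifying G-runs with valid loop lengths, then apply
# leftmost greedy non-overlapping selection. Minus strand by scanning the
# reverse complement and flipping coordinates.
oracle_g4_strand <- function(res, min_tract = 3, loop_min = 1, loop_max = 7) {
  r <- rle(strsplit(res, "")[[1]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  qi <- which(r$values == "G" & r$lengths >= min_tract)
  cand <- list()
  if (length(qi) >= 4) {
    for (a in seq_len(length(qi) - 3)) {
      idx <- qi[a:(a + 3)]
      gaps <- starts[idx[2:4]] - ends[idx[1:3]]
      if (all(gaps >= loop_min & gaps <= loop_max))
        cand[[length(cand) + 1]] <- c(starts[idx[1]], ends[idx[4]])
    }
  }
  sel <- list(); lastend <- -1
  for (cd in cand) {
    if (cd[1] >= lastend) { sel[[length(sel) + 1]] <- cd; lastend <- cd[2] }
  }
  sel
}

oracle_g4 <- function(res, min_tract = 3, loop_min = 1, loop_max = 7) {
  L <- nchar(res)
  plus <- oracle_g4_strand(res, min_tract, loop_min, loop_max)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(res)))
  minus <- lapply(oracle_g4_strand(rc, min_tract, loop_min, loop_max),
                  function(cd) c(L - cd[2], L - cd[1]))
  p <- if (length(plus)) cbind(do.call(rbind, plus), 1L) else NULL
  m <- if (length(minus)) cbind(do.call(rbind, minus), 2L) else NULL
  out <- rbind(p, m)
  if (is.null(out)) return(data.frame(start = integer(), end = integer(),
                                      strand = character()))
  d <- data.frame(start = out[, 1], end = out[, 2],
                  strand = c("+", "-")[out[, 3]])
  d <- d[order(d$start, d$strand), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# A sharp PWM whose consensus scores far above background.
sharp_pwm <- function(name, consensus, weight = 100) {
  bases <- c("A", "C", "G", "T")
  w <- nchar(consensus)
  counts <- matrix(1, 4, w, dimnames = list(bases, NULL))
  cc <- strsplit(consensus, "")[[1]]
  for (j in seq_len(w)) counts[cc[j], j] <- weight
  pwm_from_counts(name, counts)
}

random_pwm <- function(name, width) {
  counts <- matrix(stats::rpois(4 * width, 10) + 1, 4, width,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm_from_counts(name, counts)
}

# One small cohort (root locus + leaves), cached per test run.
local_cohort <- local({
  cache <- new.env()
  function(seed = 1L, spec = NULL, rates = list(), tree = NULL) {
    key <- paste0(seed, "_", is.null(spec), "_",
                  paste(names(rates), unlist(rates), collapse = ","))
    if (!is.null(cache[[key]])) return(cache[[key]])
    if (is.null(spec)) spec <- synthetic_locus_spec()
    if (is.null(tree)) tree <- default_tree()
    locus <- build_root_locus(spec, seed)
    cohort <- evolve_along_tree(locus, tree, rates = rates, seed = seed)
    out <- list(locus = locus, cohort = cohort)
    cache[[key]] <- out
    out
  }
})

truth_gene_seq <- function(leaf, gene = "geneA") {
  extract_gene_sequence(leaf$seq, truth_gene_model(leaf$truth, gene),
                        id = leaf$seq$id)
}
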