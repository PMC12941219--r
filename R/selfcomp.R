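#' Find self-complementary region pairs within a gene
#'
#' Aligns a gene against itself and keeps only reverse-complementary
#' (minus-strand) hits, the signature of inverted-repeat pairs that can fold
#' into stem-loops (IRAlu-like when the two arms are close). The trivial
#' full-length plus-strand self-hit is excluded by construction (plus-strand
#' hits are not searched); each hit's mirror-image duplicate is collapsed to
#' a single region with the leftmost arm first.
#'
#' A minus-strand hit whose two intervals overlap is a palindrome/hairpin
#' within one HSP; it is reported (split at the midpoint) only when both
#' arms are at least `min_len`.
#'
#' @param gene A [dna_sequence()]; must be longer than `2 * min_len`.
#' @param min_len Minimum arm alignment length (default 100, the same
#'   threshold the ANI statistic applies to qualifying hits).
#' @param min_pident Minimum percent identity between arms (default 80).
#' @param proximal_threshold Separation (bp) at or below which a pair is
#'   classed `proximal` rather than `distal` (default 2000).
#' @param ... Passed to [local_align()].
#' @return `data.frame` with columns gene_id, a_start, a_end, b_start,
#'   b_end, pident, length, separation, class.
#' @export
find_self_complementary <- function(gene, min_len = 100L, min_pident = 80,
                                    proximal_threshold = 2000L, ...) {
  stopifnot(inherits(gene, "dna_sequence"))
  if (seq_len_bp(gene) <= 2L * min_len)
    stop("gene must be longer than 2 * min_len")
  h <- local_align(gene, gene, min_pident = min_pident, min_len = min_len,
                   both_strands = TRUE, ...)
  h <- h[h$strand == "-", , drop = FALSE]
  empty <- data.frame(gene_id = character(), a_start = integer(),
                      a_end = integer(), b_start = integer(), b_end = integer(),
                      pident = numeric(), length = integer(),
                      separation = integer(), class = character())
  if (!nrow(h)) return(empty)
  rows <- list()
  for (i in seq_len(nrow(h))) {
    a <- c(h$qstart[i], h$qend[i]); b <- c(h$sstart[i], h$send[i])
    if (a[1] > b[1]) { tmp <- a; a <- b; b <- tmp }
    if (b[1] < a[2]) {
      # overlapping arms: palindrome within one HSP
      mid <- (a[1] + b[2]) %/% 2L
      a2 <- c(a[1], mid); b2 <- c(mid, b[2])
      if (min(a2[2] - a2[1], b2[2] - b2[1]) < min_len) next
      a <- a2; b <- b2
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gene$id, a_start = a[1], a_end = a[2], b_start = b[1],
      b_end = b[2], pident = h$pident[i], length = h$length[i],
      separation = b[1] - a[2], score = h$score[i])
  }
  if (!length(rows)) return(empty)
  d <- do.call(rbind, rows)
  d <- d[order(-d$score), , drop = FALSE]
  # collapse mirror duplicates: reciprocal overlap >= 50% on both arms
  keep <- rep(TRUE, nrow(d))
  ov <- function(s1, e1, s2, e2) max(0L, min(e1, e2) - max(s1, s2))
  for (i in seq_len(nrow(d))) {
    if (!keep[i]) next
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      oa <- ov(d$a_start[i], d$a_end[i], d$a_start[j], d$a_end[j])
      ob <- ov(d$b_start[i], d$b_end[i], d$b_start[j], d$b_end[j])
      la <- min(d$a_end[i] - d$a_start[i], d$a_end[j] - d$a_start[j])
      lb <- min(d$b_end[i] - d$b_start[i], d$b_end[j] - d$b_start[j])
      if (oa >= 0.5 * la && ob >= 0.5 * lb) { keep[i] <- FALSE; break }
    }
  }
  d <- d[keep, , drop = FALSE]
  d$class <- ifelse(d$separation <= proximal_threshold, "proximal", "distal")
  d$score <- NULL
  d <- d[order(d$a_start), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Write self-complementarity results as TSV
#'
#' Also writes an optional two-column arc file (arm midpoints) for external
#' linked-arc plotting.
#'
#' @param regions Result of [find_self_complementary()].
#' @param path Output TSV path.
#' @param arc_path Optional arc-plot data path.
#' @export
write_selfcomp_table <- function(regions, path, arc_path = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 0-based half-open", con)
  utils::write.table(regions, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(arc_path)) {
    arcs <- data.frame(a_mid = (regions$a_start + regions$a_end) / 2,
                       b_mid = (regions$b_start + regions$b_end) / 2)
    utils::write.table(arcs, arc_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
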