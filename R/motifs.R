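#' Find canonical G-quadruplex motifs
#'
#' Scans for the canonical four-tract pattern: four runs of at least
#' `min_tract` consecutive guanines separated by loops of `loop_min` to
#' `loop_max` residues. Tracts are maximal G-runs; a G-run shorter than
#' `min_tract` may sit inside a loop, but a qualifying run cannot. Hits are
#' selected left-to-right greedily and do not overlap (per strand).
#' Minus-strand hits are found on the reverse complement and reported in
#' forward coordinates with strand `"-"`.
#'
#' @param seq A [dna_sequence()].
#' @param min_tract Minimum G-tract length (default 3).
#' @param loop_min,loop_max Loop length bounds (defaults 1 and 7).
#' @param both_strands Scan both strands (default TRUE).
#' @return `data.frame` with columns start, end (0-based half-open, forward
#'   frame), strand, n_tracts, tract_lengths, loop_lengths (comma-joined,
#'   reported 5'->3' on the hit strand).
#' @export
find_g4 <- function(seq, min_tract = 3L, loop_min = 1L, loop_max = 7L,
                    both_strands = TRUE) {
  stopifnot(inherits(seq, "dna_sequence"))
  scan1 <- function(res) {
    m <- gregexpr(sprintf("G{%d,}", min_tract), res)[[1]]
    out <- list()
    if (m[1] == -1) return(out)
    starts <- as.integer(m) - 1L
    lens <- attr(m, "match.length")
    ends <- starts + lens
    i <- 1L
    n <- length(starts)
    while (i + 3L <= n) {
      gaps <- starts[(i + 1L):(i + 3L)] - ends[i:(i + 2L)]
      if (all(gaps >= loop_min & gaps <= loop_max)) {
        out[[length(out) + 1L]] <- list(start = starts[i], end = ends[i + 3L],
                                        tracts = lens[i:(i + 3L)], loops = gaps)
        i <- i + 4L
      } else i <- i + 1L
    }
    out
  }
  rows <- list()
  add <- function(hits, strand, L) {
    for (h in hits) {
      st <- h$start; en <- h$end
      if (strand == "-") { st <- L - h$end; en <- L - h$start }
      rows[[length(rows) + 1L]] <<- data.frame(
        start = st, end = en, strand = strand, n_tracts = length(h$tracts),
        tract_lengths = paste(h$tracts, collapse = ","),
        loop_lengths = paste(h$loops, collapse = ","))
    }
  }
  L <- seq_len_bp(seq)
  add(scan1(seq$residues), "+", L)
  if (both_strands) add(scan1(revcomp_chr(seq$residues)), "-", L)
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      n_tracts = integer(), tract_lengths = character(),
                      loop_lengths = character()))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hexamer profile of a gene
#'
#' Global counts over the full 4^6 = 4,096 hexamer key space plus, for each
#' queried motif, occurrence counts per fractional-length bin (positions are
#' window starts; overlapping occurrences all count). RNA motifs are
#' accepted and matched in DNA space (`U` maps to `T`).
#'
#' @param gene A [dna_sequence()].
#' @param query_motifs Character vector of 6-mers (DNA or RNA alphabet).
#' @param n_bins Number of positional bins for queried motifs (default 10).
#' @return Object of class `hexamer_profile`: list with `gene_id`, `counts`
#'   (named length-4096 integer vector), `skipped` (N-containing windows),
#'   `query_bins` (motif x bin count matrix) and `query_counts`.
#' @export
hexamer_profile <- function(gene, query_motifs = character(), n_bins = 10L) {
  stopifnot(inherits(gene, "dna_sequence"))
  counts <- kmer_counts(gene, 6L)
  skipped <- attr(counts, "skipped")
  L <- seq_len_bp(gene)
  qb <- matrix(0L, nrow = length(query_motifs), ncol = n_bins,
               dimnames = list(toupper(query_motifs), NULL))
  qc <- integer(length(query_motifs))
  if (length(query_motifs)) {
    for (i in seq_along(query_motifs)) {
      motif <- chartr("Uu", "Tt", toupper(query_motifs[i]))
      if (nchar(motif) != 6L || grepl("[^ACGT]", motif))
        stop("query motifs must be 6-mers over ACGT/U: ", query_motifs[i])
      m <- Biostrings::matchPattern(motif, as_dnastring(gene))
      pos <- Biostrings::start(m) - 1L
      qc[i] <- length(pos)
      if (length(pos)) {
        b <- frac_bin(pos, L, n_bins)
        tb <- tabulate(b + 1L, nbins = n_bins)
        qb[i, ] <- tb
      }
      rownames(qb)[i] <- chartr("U", "T", toupper(query_motifs[i]))
    }
  }
  structure(list(gene_id = gene$id, counts = counts, skipped = skipped,
                 query_bins = qb, query_counts = setNames(qc, rownames(qb)),
                 n_bins = as.integer(n_bins)),
            class = "hexamer_profile")
}

#' @export
print.hexamer_profile <- function(x, ...) {
  cat(sprintf("<hexamer_profile> %s: %d windows counted, %d skipped\n",
              x$gene_id, sum(x$counts), x$skipped))
  if (nrow(x$query_bins)) {
    cat("queried motifs:\n")
    print(x$query_counts)
  }
  invisible(x)
}

#' Hexamers shared by every profiled gene
#'
#' Intersection-style motif discovery: hexamers observed at least
#' `min_per_gene` times in every profile, ranked by the minimum count
#' across genes (descending), ties by mean count, then lexicographically.
#'
#' @param profiles List of [hexamer_profile()] objects (>= 2).
#' @param min_per_gene Minimum count required in each gene (default 1).
#' @return `data.frame` with columns hexamer, min_count, mean_count.
#' @export
shared_motifs <- function(profiles, min_per_gene = 1L) {
  stopifnot(length(profiles) >= 2L)
  mat <- vapply(profiles, function(p) p$counts, integer(4096))
  keep <- apply(mat, 1L, min) >= min_per_gene
  hex <- rownames(mat)[keep]
  mn <- apply(mat[keep, , drop = FALSE], 1L, min)
  mu <- rowMeans(mat[keep, , drop = FALSE])
  ord <- order(-mn, -mu, hex)
  data.frame(hexamer = hex[ord], min_count = as.integer(mn[ord]),
             mean_count = mu[ord], row.names = NULL)
}

#' Nucleotide usage of a gene
#'
#' Overall and per-bin base percentages. `N` residues are excluded from
#' denominators; a bin consisting only of `N` is reported as missing (NA).
#'
#' @param gene A [dna_sequence()].
#' @param n_bins Number of positional bins (default 20, i.e. 5% segments).
#' @return Object of class `nucleotide_usage`: list with `overall` (named
#'   percentage vector summing to 100) and `per_bin` (n_bins x 4 matrix).
#' @export
nucleotide_usage <- function(gene, n_bins = 20L) {
  stopifnot(inherits(gene, "dna_sequence"))
  chars <- strsplit(gene$residues, "")[[1]]
  L <- length(chars)
  bases <- c("A", "C", "G", "T")
  pct <- function(v) {
    v <- v[v != "N"]
    if (!length(v)) return(rep(NA_real_, 4L))
    100 * vapply(bases, function(b) sum(v == b), 0L) / length(v)
  }
  overall <- setNames(pct(chars), bases)
  bin <- frac_bin(seq_len(L) - 1L, L, n_bins)
  per_bin <- t(vapply(0:(n_bins - 1L), function(b) pct(chars[bin == b]),
                      numeric(4L)))
  colnames(per_bin) <- bases
  structure(list(overall = overall, per_bin = per_bin,
                 n_bins = as.integer(n_bins)),
            class = "nucleotide_usage")
}

#' @export
print.nucleotide_usage <- function(x, ...) {
  cat("<nucleotide_usage> overall %:\n")
  print(round(x$overall, 2))
  invisible(x)
}
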