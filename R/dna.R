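#' Create a DNA sequence object
#'
#' The elementary sequence carrier of the package: an identifier, the
#' residues (restricted to the alphabet `A`, `C`, `G`, `T`, `N`), and an
#' optional key/value metadata map (taxon, order, assembly, ...).
#'
#' @param id Single non-empty identifier string, unique within a collection.
#' @param residues Single non-empty string over `ACGTN` (lower case accepted
#'   and upper-cased).
#' @param meta Named character vector of free-form metadata.
#' @return An object of class `dna_sequence`.
#' @export
dna_sequence <- function(id, residues, meta = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (!nzchar(residues)) stop("residues must be non-empty")
  if (grepl("[^ACGTN]", residues))
    stop("invalid residue in sequence '", id, "': alphabet is ACGTN")
  if (length(meta) && is.null(names(meta))) stop("meta must be named")
  structure(list(id = id, residues = residues, meta = meta),
            class = "dna_sequence")
}

#' @export
print.dna_sequence <- function(x, ...) {
  n <- nchar(x$residues)
  preview <- if (n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(sprintf("<dna_sequence> %s (%d bp)\n  %s\n", x$id, n, preview))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), x$meta, sep = "=", collapse = "; "), "\n")
  invisible(x)
}

#' @export
length.dna_sequence <- function(x) nchar(x$residues)

seq_len_bp <- function(x) nchar(x$residues)

as_dnastring <- function(x) Biostrings::DNAString(x$residues)

#' Extract a subsequence
#'
#' @param x A [dna_sequence()].
#' @param start,end 0-based half-open coordinates.
#' @param id Identifier for the extracted piece.
#' @return A `dna_sequence` of length `end - start`.
#' @export
subseq_dna <- function(x, start, end, id = x$id) {
  stopifnot(start >= 0, end > start, end <= seq_len_bp(x))
  dna_sequence(id, substr(x$residues, start + 1L, end), meta = x$meta)
}

#' Reverse complement of a DNA sequence
#'
#' Standard Watson-Crick complement, reversed; `N` maps to `N`.
#' Applying it twice returns the original sequence.
#'
#' @param seq A [dna_sequence()].
#' @return A `dna_sequence` with id suffixed `_rc`.
#' @export
reverse_complement <- function(seq) {
  stopifnot(inherits(seq, "dna_sequence"))
  rc <- as.character(Biostrings::reverseComplement(as_dnastring(seq)))
  dna_sequence(paste0(seq$id, "_rc"), rc, meta = seq$meta)
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Count k-mers in a sequence
#'
#' Counts over all `length - k + 1` sliding windows. Windows containing `N`
#' are skipped; the number of skipped windows is attached as attribute
#' `skipped`. For `k <= 8` the full 4^k key space is returned (zeros
#' included), which also enumerates the theoretical motif space (4,096
#' hexamers, 16,384 7-mers); for larger `k` only observed k-mers are kept.
#'
#' @param seq A [dna_sequence()].
#' @param k Word size, `1 <= k`.
#' @return Named integer vector of counts with attribute `skipped`.
#' @export
kmer_counts <- function(seq, k) {
  stopifnot(inherits(seq, "dna_sequence"), k >= 1)
  L <- seq_len_bp(seq)
  if (k > L) {
    warning("k exceeds sequence length; returning empty counts")
    out <- integer(0)
    attr(out, "skipped") <- 0L
    return(out)
  }
  counts <- Biostrings::oligonucleotideFrequency(as_dnastring(seq), width = k)
  counts <- as.integer(counts) |> setNames(names(counts))
  if (k > 8) counts <- counts[counts > 0L]
  attr(counts, "skipped") <- as.integer((L - k + 1L) - sum(counts))
  counts
}

#' Genomic interval
#'
#' 0-based half-open interval on a named sequence with a strand.
#'
#' @param seq_id Sequence identifier.
#' @param start,end 0-based half-open offsets, `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `genomic_interval`.
#' @export
genomic_interval <- function(seq_id, start, end, strand = "+") {
  stopifnot(is.character(seq_id), length(seq_id) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (!(start >= 0L && start < end)) stop("need 0 <= start < end")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(seq_id = seq_id, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<interval> %s:%d-%d(%s) len=%d\n", x$seq_id, x$start, x$end,
              x$strand, x$end - x$start))
  invisible(x)
}

iv_length <- function(iv) iv$end - iv$start

#' Read a multi-record FASTA file
#'
#' @param path FASTA file.
#' @return Named list of [dna_sequence()] objects (names = record ids).
#' @export
read_dna_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate record ids in ", path)
  out <- lapply(seq_along(ss), function(i) {
    desc <- sub("^\\S+\\s*", "", names(ss)[i])
    meta <- character()
    # DFAM-style class tag in the description: "#SINE/Alu"
    if (grepl("#", ids[i])) {
      meta <- c(class = sub("^.*#", "", ids[i]))
      ids_i <- sub("#.*$", "", ids[i])
    } else if (grepl("#", desc)) {
      meta <- c(class = sub("^.*#", "", desc))
      ids_i <- ids[i]
    } else ids_i <- ids[i]
    dna_sequence(ids_i, as.character(ss[[i]]), meta = meta)
  })
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Write sequences to FASTA (wrapped at 60 columns)
#'
#' @param seqs A `dna_sequence` or list of them.
#' @param path Output file.
#' @export
write_dna_fasta <- function(seqs, path) {
  if (inherits(seqs, "dna_sequence")) seqs <- list(seqs)
  ss <- Biostrings::DNAStringSet(vapply(seqs, `[[`, "", "residues"))
  names(ss) <- vapply(seqs, `[[`, "", "id")
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Local homology search (seed-and-extend)
#'
#' Finds gapped local alignments between two sequences in the manner of a
#' pairwise blastn search: exact word seeds (default word size 11) are
#' extended in both directions with affine gap scores and x-drop
#' termination. Minus-strand matches are found by searching the reverse
#' complement of the subject and are reported with strand `"-"` and subject
#' coordinates on the forward frame. `N` never matches anything.
#'
#' Each row of the result is one high-scoring pair (HSP); `pident` is
#' percent identity over alignment columns (gaps included), `length` the
#' alignment column count, and `pident / 100 * length` is the
#' identity-weighted hit length used by [ani_pair()].
#'
#' @param query,subject [dna_sequence()] objects.
#' @param word_size Exact-match seed length (>= 4).
#' @param min_pident Minimum percent identity to report.
#' @param min_len Minimum alignment length (columns) to report.
#' @param both_strands Also search the minus strand.
#' @param match,mismatch,gap_open,gap_extend,xdrop Alignment scores
#'   (penalties negative); the first gap residue costs
#'   `gap_open + gap_extend`.
#' @return A `data.frame` of class `hsp_table`, sorted by descending score
#'   then (qstart, sstart), with columns qid, sid, qstart, qend, sstart,
#'   send, strand, pident, length, score, nident (0-based half-open).
#' @export
local_align <- function(query, subject, word_size = 11L, min_pident = 60,
                        min_len = 30L, both_strands = TRUE, match = 1L,
                        mismatch = -2L, gap_open = -5L, gap_extend = -2L,
                        xdrop = 50L) {
  stopifnot(inherits(query, "dna_sequence"), inherits(subject, "dna_sequence"))
  stopifnot(word_size >= 4)
  run1 <- function(subj_res, strand) {
    df <- .cpp_local_align(query$residues, subj_res, as.integer(word_size),
                           min_pident, as.integer(min_len), as.integer(match),
                           as.integer(abs(mismatch)) * -1L,
                           as.integer(abs(gap_open)), as.integer(abs(gap_extend)),
                           as.integer(xdrop))
    if (!nrow(df)) return(NULL)
    if (strand == "-") {
      Ls <- nchar(subj_res)
      s0 <- Ls - df$send; s1 <- Ls - df$sstart
      df$sstart <- s0; df$send <- s1
    }
    df$strand <- strand
    df
  }
  parts <- list(run1(subject$residues, "+"))
  if (both_strands) parts <- c(parts, list(run1(revcomp_chr(subject$residues), "-")))
  parts <- Filter(Negate(is.null), parts)
  if (!length(parts)) {
    out <- data.frame(qid = character(), sid = character(), qstart = integer(),
                      qend = integer(), sstart = integer(), send = integer(),
                      strand = character(), pident = numeric(), length = integer(),
                      score = integer(), nident = integer())
    class(out) <- c("hsp_table", "data.frame")
    return(out)
  }
  df <- do.call(rbind, parts)
  out <- data.frame(qid = query$id, sid = subject$id, qstart = df$qstart,
                    qend = df$qend, sstart = df$sstart, send = df$send,
                    strand = df$strand, pident = df$pident, length = df$length,
                    score = df$score, nident = df$nident)
  out <- out[order(-out$score, out$qstart, out$sstart), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hsp_table", "data.frame")
  out
}

#' Write an HSP table as tab-separated text
#'
#' Column order follows the familiar blast outfmt-6-like layout:
#' qid, sid, qstart, qend, sstart, send, strand, pident, length, score.
#' Coordinates are 0-based half-open (stated in a header comment line).
#'
#' @param hsps An `hsp_table` from [local_align()].
#' @param path Output file.
#' @export
write_hsp_table <- function(hsps, path) {
  cols <- c("qid", "sid", "qstart", "qend", "sstart", "send", "strand",
            "pident", "length", "score")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 0-based half-open", con)
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(hsps))
    utils::write.table(hsps[, cols], con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}
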