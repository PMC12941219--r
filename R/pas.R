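#' Project a reference polyadenylation-signal position onto a gene
#'
#' Maps a known PAS offset in a reference ortholog into the coordinates of
#' another gene via the best local-alignment hit covering the reference
#' position; the offset is mapped exactly through a gapped realignment of
#' the matched segments, so indels between the two genes are accounted
#' for. When no hit covers the position, a whole-sequence pairwise
#' alignment is used as fallback. If no homology exists near the reference
#' PAS at all, a `lnc_nocall` with reason `projection_failure` is returned
#' (distinct from "no PAS in the window").
#'
#' @param gene A [dna_sequence()] in transcript orientation.
#' @param reference Reference [dna_sequence()] carrying a known PAS.
#' @param ref_pas_pos 0-based offset of the PAS motif start in `reference`.
#' @param ... Passed to [local_align()].
#' @return Integer projected offset in gene coordinates, or a
#'   [no_call()] with reason `"projection_failure"`.
#' @export
project_reference_pas <- function(gene, reference, ref_pas_pos, ...) {
  stopifnot(ref_pas_pos >= 0, ref_pas_pos < seq_len_bp(reference))
  # work from a 1 kb reference window centred on the PAS
  wlo <- max(0L, as.integer(ref_pas_pos) - 500L)
  whi <- min(seq_len_bp(reference), as.integer(ref_pas_pos) + 506L)
  frag <- subseq_dna(reference, wlo, whi, id = "ref_pas_window")
  rel <- as.integer(ref_pas_pos) - wlo
  h <- local_align(frag, gene, both_strands = FALSE, ...)
  h <- h[h$qstart <= rel & h$qend > rel, , drop = FALSE]
  if (nrow(h)) {
    h1 <- h[1L, ]
    qfrag <- substr(frag$residues, h1$qstart + 1L, h1$qend)
    sfrag <- substr(gene$residues, h1$sstart + 1L, h1$send)
    aln <- global_alignment_strings(qfrag, sfrag)
    off <- map_offset_through_alignment(aln$x, aln$y, rel - h1$qstart)
    if (!is.na(off)) return(as.integer(h1$sstart + off))
  }
  # fallback: Smith-Waterman of the window against the gene, column mapping
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(frag$residues),
                                       as_dnastring(gene), type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 5, gapExtension = 2)
  pat <- Biostrings::pattern(aln)
  p0 <- Biostrings::start(pat) - 1L
  p1 <- Biostrings::end(pat)
  if (Biostrings::score(aln) < 30 || rel < p0 || rel >= p1)
    return(no_call("projection_failure"))
  off <- map_offset_through_alignment(
    as.character(Biostrings::alignedPattern(aln)),
    as.character(Biostrings::alignedSubject(aln)), rel - p0)
  if (is.na(off)) return(no_call("projection_failure"))
  as.integer(Biostrings::start(Biostrings::subject(aln)) - 1L + off)
}

.pas_motif <- "AATAAA"

# All 0-based AATAAA motif-start positions in a window (overlapping
# occurrences included).
.scan_pas <- function(gene, lo, hi) {
  L <- seq_len_bp(gene)
  lo <- max(0L, lo); hi <- min(L - 6L, hi)
  if (lo > hi) return(integer())
  m <- Biostrings::matchPattern(.pas_motif, as_dnastring(gene))
  pos <- Biostrings::start(m) - 1L
  pos[pos >= lo & pos <= hi]
}

#' Call the main polyadenylation signal of the short isoform
#'
#' Scans `projected - window` to `projected + window` (motif-start
#' anchored) on the transcript strand for the canonical hexamer `AATAAA`.
#' Exactly one occurrence yields a call; zero or several yield a no-call
#' with reason `absent` or `ambiguous` respectively — mirroring the rule
#' that a single signal within 110 bp in both directions marks an active
#' PAS. A window extending past the gene ends is truncated (with a
#' message).
#'
#' @param gene A [dna_sequence()] in transcript orientation.
#' @param projected Projected reference PAS offset (0-based motif start).
#' @param window Scan half-width in bp (default 110).
#' @return Object of class `pas_call` with fields status
#'   (`called`/`no_call`), position, motif, kind, offset_from_projection,
#'   reason.
#' @export
call_main_pas <- function(gene, projected, window = 110L) {
  stopifnot(projected >= 0, projected < seq_len_bp(gene))
  if (projected - window < 0 || projected + window + 6L > seq_len_bp(gene))
    message("PAS scan window truncated at gene boundary")
  pos <- .scan_pas(gene, projected - window, projected + window)
  if (length(pos) == 1L) {
    structure(list(status = "called", position = pos, motif = .pas_motif,
                   kind = "main", offset_from_projection = pos - as.integer(projected),
                   reason = NA_character_), class = "pas_call")
  } else {
    structure(list(status = "no_call", position = NA_integer_, motif = .pas_motif,
                   kind = "main", offset_from_projection = NA_integer_,
                   reason = if (length(pos) == 0L) "absent" else "ambiguous"),
              class = "pas_call")
  }
}

#' @export
print.pas_call <- function(x, ...) {
  if (x$status == "called")
    cat(sprintf("<pas_call> %s at %d (offset %+d from projection)\n", x$kind,
                x$position, x$offset_from_projection))
  else cat(sprintf("<pas_call> no-call (%s)\n", x$reason))
  invisible(x)
}

#' Find alternative polyadenylation signals around the main PAS
#'
#' All `AATAAA` occurrences within `window` bp on either side of the main
#' call, excluding the main position itself.
#'
#' @param gene A [dna_sequence()] in transcript orientation.
#' @param main A called [call_main_pas()] result.
#' @param window Half-width of the alternative-PAS scan (default 600).
#' @param kind Label for the reported signals: `"alternative"` (default) or
#'   `"marsupial_pair"` for the two-PAS mode seen in marsupial orthologs.
#' @return `data.frame` with columns position, kind, offset (signed bp from
#'   the main PAS).
#' @export
find_alternative_pas <- function(gene, main, window = 600L,
                                 kind = c("alternative", "marsupial_pair")) {
  kind <- match.arg(kind)
  stopifnot(inherits(main, "pas_call"), main$status == "called")
  pos <- .scan_pas(gene, main$position - window, main$position + window)
  pos <- pos[pos != main$position]
  data.frame(position = pos, kind = rep(kind, length(pos)),
             offset = pos - main$position)
}

#' Positional rescue call for the short-isoform PAS
#'
#' Optional fallback when reference projection fails: if a single `AATAAA`
#' lies in a fixed positional prior window (default gene offsets
#' 3,000-4,500, where short-isoform lengths concentrate), call it and flag
#' `rescue = TRUE`. Off by default in the pipeline.
#'
#' @param gene A [dna_sequence()] in transcript orientation.
#' @param lo,hi Prior window bounds (0-based offsets).
#' @return A `pas_call` (with `$rescue = TRUE` when called) or no-call.
#' @export
call_rescue_pas <- function(gene, lo = 3000L, hi = 4500L) {
  pos <- .scan_pas(gene, lo, hi - 6L)
  if (length(pos) == 1L) {
    out <- structure(list(status = "called", position = pos, motif = .pas_motif,
                          kind = "main", offset_from_projection = NA_integer_,
                          reason = NA_character_, rescue = TRUE),
                     class = "pas_call")
    return(out)
  }
  structure(list(status = "no_call", position = NA_integer_, motif = .pas_motif,
                 kind = "main", offset_from_projection = NA_integer_,
                 reason = if (length(pos) == 0L) "absent" else "ambiguous",
                 rescue = TRUE), class = "pas_call")
}
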