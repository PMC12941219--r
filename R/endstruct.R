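#' Reference layout of the 3'-end structures
#'
#' Describes where the sub-elements of the 3' end sit inside a reference
#' end fragment: the triple-helix-forming motif, the hairpin, the linker
#' (the helix ends the gene), and the downstream tRNA-like element. The
#' boundaries are user input (figure-derived in practice), not constants.
#'
#' @param fragment Reference [dna_sequence()] end fragment.
#' @param helix_motif,hairpin,linker,trna_like Length-2 integer vectors of
#'   0-based half-open offsets within `fragment`, contiguous and ordered
#'   5' to 3'.
#' @return Object of class `end_structure_layout`.
#' @export
end_structure_layout <- function(fragment, helix_motif, hairpin, linker,
                                 trna_like) {
  stopifnot(inherits(fragment, "dna_sequence"))
  elems <- list(helix_motif = helix_motif, hairpin = hairpin, linker = linker,
                trna_like = trna_like)
  prev_end <- NULL
  for (nm in names(elems)) {
    e <- elems[[nm]]
    stopifnot(length(e) == 2L, e[1] >= 0, e[2] > e[1],
              e[2] <= seq_len_bp(fragment))
    if (!is.null(prev_end) && e[1] < prev_end)
      stop("end-structure elements must be ordered and non-overlapping")
    prev_end <- e[2]
  }
  structure(c(list(fragment = fragment), elems), class = "end_structure_layout")
}

#' Measure 3'-end structural elements of a gene
#'
#' Maps the reference layout's element boundaries onto the gene's 3'
#' region by gapped alignment and reports each element's interval and
#' length (gene offsets, transcript orientation). An element whose
#' boundaries fail to map is reported absent; the others are retained.
#'
#' @param gene A [dna_sequence()] in transcript orientation.
#' @param model The gene's [gene_model()] (used to bound the 3' search
#'   region); may be NULL to search the final 1 kb.
#' @param layout An [end_structure_layout()].
#' @param ... Passed to [local_align()].
#' @return Object of class `end_structure_model`: per element, interval
#'   (start, end) and length, NA when absent.
#' @export
extract_end_structures <- function(gene, model = NULL, layout, ...) {
  stopifnot(inherits(gene, "dna_sequence"),
            inherits(layout, "end_structure_layout"))
  L <- seq_len_bp(gene)
  lo <- max(0L, L - 1000L)
  region <- subseq_dna(gene, lo, L, id = gene$id)
  out <- list()
  for (nm in c("helix_motif", "hairpin", "linker", "trna_like")) {
    offs <- layout[[nm]]
    s <- .map_anchor_offset(layout$fragment, region, offs[1], ...)
    e <- .map_anchor_offset(layout$fragment, region, offs[2], ...)
    if (is.na(s) || is.na(e) || e <= s) {
      out[[nm]] <- list(start = NA_integer_, end = NA_integer_,
                        length = NA_integer_)
    } else {
      out[[nm]] <- list(start = lo + s, end = lo + e, length = e - s)
    }
  }
  structure(out, class = "end_structure_model")
}

#' @export
print.end_structure_model <- function(x, ...) {
  for (nm in names(x))
    cat(sprintf("  %-12s %s\n", nm,
                if (is.na(x[[nm]]$length)) "absent"
                else sprintf("%d-%d (len %d)", x[[nm]]$start, x[[nm]]$end,
                             x[[nm]]$length)))
  invisible(x)
}

# Coerce an MSA given as a character vector of equal-length strings (or a
# matrix of single characters) to a character matrix rows x columns.
.msa_matrix <- function(msa) {
  if (is.matrix(msa)) return(msa)
  stopifnot(is.character(msa), length(msa) >= 1L)
  w <- unique(nchar(msa))
  if (length(w) != 1L) stop("MSA rows must have equal length")
  do.call(rbind, strsplit(toupper(msa), ""))
}

#' Reference-anchored multiple alignment of short elements
#'
#' Aligns every sequence pairwise (global, gapped) to the first sequence
#' and merges the results on reference coordinates, padding insertions.
#' Adequate for short, well-conserved elements; not a general-purpose
#' progressive aligner.
#'
#' @param seqs List of [dna_sequence()] objects; the first is the
#'   reference.
#' @return Named character vector of gapped rows (equal width).
#' @export
align_ref_anchored <- function(seqs) {
  stopifnot(length(seqs) >= 2L)
  ref <- seqs[[1L]]$residues
  n_ref <- nchar(ref)
  alns <- lapply(seqs[-1L], function(s) global_alignment_strings(ref, s$residues))
  # insertion length after each reference position (0 = before first)
  ins <- integer(n_ref + 1L)
  per_seq <- list()
  for (k in seq_along(alns)) {
    xs <- strsplit(alns[[k]]$x, "")[[1]]
    ys <- strsplit(alns[[k]]$y, "")[[1]]
    pieces <- vector("list", n_ref + 1L)  # [i+1] = insertion after ref pos i
    aligned <- character(n_ref)           # residue (or -) at each ref pos
    ri <- 0L
    buf <- character()
    for (c in seq_along(xs)) {
      if (xs[c] == "-") {
        buf <- c(buf, ys[c])
      } else {
        pieces[[ri + 1L]] <- buf
        buf <- character()
        ri <- ri + 1L
        aligned[ri] <- ys[c]
      }
    }
    pieces[[n_ref + 1L]] <- buf
    lens <- vapply(pieces, length, 0L)
    ins <- pmax(ins, lens)
    per_seq[[k]] <- list(pieces = pieces, aligned = aligned)
  }
  pad <- function(v, n) c(v, rep("-", n - length(v)))
  build_row <- function(pieces, aligned) {
    out <- pad(pieces[[1L]], ins[1L])
    for (i in seq_len(n_ref))
      out <- c(out, aligned[i], pad(pieces[[i + 1L]], ins[i + 1L]))
    paste(out, collapse = "")
  }
  ref_chars <- strsplit(ref, "")[[1]]
  rows <- c(build_row(lapply(ins, function(n) character()), ref_chars),
            vapply(per_seq, function(p) build_row(p$pieces, p$aligned), ""))
  names(rows) <- vapply(seqs, `[[`, "", "id")
  rows
}

#' Per-column conservation of an MSA
#'
#' Base frequencies per column excluding gaps; a column is "identical"
#' when a single base has frequency 1 among non-gap rows and at least half
#' the rows are non-gap.
#'
#' @param msa Character vector of gapped rows (equal width) or a character
#'   matrix.
#' @return List with `freq` (4 x width matrix over ACGT), `identical`
#'   (logical per column) and `identical_fraction`.
#' @export
column_conservation <- function(msa) {
  m <- .msa_matrix(msa)
  if (!nrow(m) || !ncol(m)) stop("empty MSA")
  bases <- c("A", "C", "G", "T")
  freq <- apply(m, 2L, function(col) {
    col <- chartr("U", "T", col)
    col <- col[col %in% bases]
    if (!length(col)) return(rep(NA_real_, 4L))
    vapply(bases, function(b) mean(col == b), 0)
  })
  rownames(freq) <- bases
  nongap <- apply(m, 2L, function(col) mean(col != "-"))
  identical_col <- vapply(seq_len(ncol(m)), function(j) {
    f <- freq[, j]
    !anyNA(f) && any(f == 1) && nongap[j] >= 0.5
  }, TRUE)
  list(freq = freq, identical = identical_col,
       identical_fraction = mean(identical_col))
}

#' Base pairs of a dot-bracket structure
#'
#' @param db Dot-bracket string using `(`, `)` and `.`.
#' @return `data.frame` with 1-based paired column indices i < j.
#' @export
dotbracket_pairs <- function(db) {
  chars <- strsplit(db, "")[[1]]
  stack <- integer()
  pairs <- list()
  for (k in seq_along(chars)) {
    if (chars[k] == "(") stack <- c(stack, k)
    else if (chars[k] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[[length(pairs) + 1L]] <- c(i, k)
    } else if (chars[k] != ".") stop("dot-bracket alphabet is ( ) .")
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  if (!length(pairs)) return(data.frame(i = integer(), j = integer()))
  m <- do.call(rbind, pairs)
  data.frame(i = m[, 1], j = m[, 2])
}

#' Base-pair covariation across an MSA
#'
#' For each paired column couple (i, j), classifies every row's base pair
#' as canonical (AU/UA/GC/CG/GU/UG in RNA space; DNA input is mapped
#' T to U), else inconsistent; rows with a gap at either column are
#' counted separately. Compensatory pairs are canonical pairs differing
#' from the majority canonical pair — the signature of co-evolution under
#' structural constraint. The covariation score is
#' `(fraction majority-canonical + fraction compensatory) -
#' fraction inconsistent`, i.e. canonical fraction minus inconsistent
#' fraction over all rows, bounded in `[-1, 1]`.
#'
#' @param msa Character vector of gapped rows or a character matrix.
#' @param pairs `data.frame` of 1-based column indices (i, j), e.g. from
#'   [dotbracket_pairs()].
#' @return `data.frame` with columns i, j, n_canonical, n_compensatory,
#'   n_inconsistent, n_gapped, score.
#' @export
covariation <- function(msa, pairs) {
  m <- .msa_matrix(msa)
  stopifnot(all(pairs$i >= 1), all(pairs$j <= ncol(m)))
  canon <- c("AU", "UA", "GC", "CG", "GU", "UG")
  out <- lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs$i[r]; j <- pairs$j[r]
    bi <- chartr("T", "U", m[, i]); bj <- chartr("T", "U", m[, j])
    gap <- !(bi %in% c("A", "C", "G", "U")) | !(bj %in% c("A", "C", "G", "U"))
    pr <- paste0(bi, bj)
    is_can <- !gap & pr %in% canon
    n_can <- sum(is_can)
    n_inc <- sum(!gap & !is_can)
    n_comp <- 0L
    if (n_can > 0L) {
      tab <- sort(table(pr[is_can]), decreasing = TRUE)
      maj <- names(tab)[1L]
      n_comp <- sum(pr[is_can] != maj)
    }
    n <- nrow(m)
    data.frame(i = i, j = j, n_canonical = n_can, n_compensatory = n_comp,
               n_inconsistent = n_inc, n_gapped = sum(gap),
               score = (n_can - n_inc) / n)
  })
  do.call(rbind, out)
}
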