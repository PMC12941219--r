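#' Apply the 80-80-80 rule and resolve overlaps among TE candidates
#'
#' Filters candidate transposable-element hits by the classic triple
#' threshold — alignment length >= 80 bp, identity >= 80%, and coverage of
#' at least 80% of the TE consensus — then greedily accepts candidates by
#' descending `pident * aln_length`, discarding any candidate overlapping an
#' already accepted one on the gene. Ties break deterministically: higher
#' pident, then leftmost gene start, then lexicographic TE name.
#'
#' @param candidates `data.frame` with columns te_name, start, end (gene
#'   coordinates, 0-based half-open), pident, length (alignment length),
#'   te_coverage (fraction of consensus aligned); extra columns pass
#'   through.
#' @param min_len,min_pident,min_coverage The three thresholds (defaults
#'   80, 80, 0.80).
#' @return The accepted subset, ordered by gene start.
#' @export
te_808080_filter <- function(candidates, min_len = 80L, min_pident = 80,
                             min_coverage = 0.80) {
  need <- c("te_name", "start", "end", "pident", "length", "te_coverage")
  stopifnot(all(need %in% names(candidates)))
  d <- candidates[candidates$length >= min_len &
                  candidates$pident >= min_pident &
                  candidates$te_coverage >= min_coverage, , drop = FALSE]
  if (!nrow(d)) { rownames(d) <- NULL; return(d) }
  d$.score <- d$pident * d$length
  d <- d[order(-d$.score, -d$pident, d$start, d$te_name), , drop = FALSE]
  keep <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (min(d$end[i], d$end[j]) - max(d$start[i], d$start[j]) > 0) {
        ok <- FALSE; break
      }
    }
    keep[i] <- ok
  }
  d <- d[keep, , drop = FALSE]
  d$.score <- NULL
  d <- d[order(d$start), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Annotate transposable elements in a gene
#'
#' Runs the local homology search of every library consensus against the
#' gene (both strands), computes consensus coverage from the query span,
#' and applies [te_808080_filter()]. TE classes are read from library
#' metadata (`meta["class"]`, DFAM-style `name#class` headers accepted by
#' [read_dna_fasta()]).
#'
#' @param gene A [dna_sequence()].
#' @param library List of [dna_sequence()] TE consensus sequences with
#'   class metadata.
#' @param min_len,min_pident,min_coverage 80-80-80 thresholds.
#' @param ... Passed to [local_align()].
#' @return `data.frame` of class `te_annotation` with columns te_name,
#'   te_class, start, end, strand, pident, length, te_coverage.
#' @export
annotate_tes <- function(gene, library, min_len = 80L, min_pident = 80,
                         min_coverage = 0.80, ...) {
  stopifnot(inherits(gene, "dna_sequence"), length(library) >= 1L)
  cand <- list()
  for (te in library) {
    h <- local_align(te, gene, both_strands = TRUE, ...)
    if (!nrow(h)) next
    cls <- if ("class" %in% names(te$meta)) unname(te$meta[["class"]]) else "Unknown"
    cand[[length(cand) + 1L]] <- data.frame(
      te_name = te$id, te_class = cls, start = h$sstart, end = h$send,
      strand = h$strand, pident = h$pident, length = h$length,
      te_coverage = (h$qend - h$qstart) / seq_len_bp(te))
  }
  if (!length(cand)) {
    out <- data.frame(te_name = character(), te_class = character(),
                      start = integer(), end = integer(), strand = character(),
                      pident = numeric(), length = integer(),
                      te_coverage = numeric())
  } else {
    out <- te_808080_filter(do.call(rbind, cand), min_len = min_len,
                            min_pident = min_pident, min_coverage = min_coverage)
  }
  class(out) <- c("te_annotation", "data.frame")
  out
}

#' Positional profile of TE annotations along a gene
#'
#' Each accepted TE is assigned to the fractional-length bin containing its
#' interval midpoint; counts are summable across genes of different
#' lengths.
#'
#' @param annotations A [annotate_tes()] result (or compatible data.frame).
#' @param gene_length Gene length in bp.
#' @param n_bins Number of bins (default 20, i.e. 5% segments).
#' @return A [binned_profile()].
#' @export
te_positional_profile <- function(annotations, gene_length, n_bins = 20L) {
  counts <- integer(n_bins)
  if (nrow(annotations)) {
    stopifnot(all(annotations$start >= 0), all(annotations$end <= gene_length))
    mids <- (annotations$start + annotations$end) / 2
    b <- frac_bin(mids, gene_length, n_bins)
    counts <- tabulate(b + 1L, nbins = n_bins)
  }
  binned_profile(counts, n_bins, note = "TE interval midpoints, per-gene fractional length")
}

# Locate one flank sequence in a gene; returns c(start, end) of the best
# hit or NULL.
.find_flank <- function(flank, gene, min_len = 80L, min_pident = 60, ...) {
  if (nchar(flank) < min_len) min_len <- max(30L, nchar(flank) %/% 2L)
  f <- dna_sequence("flank", flank)
  h <- local_align(f, gene, min_pident = min_pident, min_len = min_len,
                   both_strands = FALSE, ...)
  if (!nrow(h)) return(NULL)
  c(h$sstart[1], h$send[1])
}

#' TE presence/absence matrix across orthologs with excision calling
#'
#' Clusters annotated TE loci across leaves by homology of their flanking
#' sequences (`flank` bp each side), fills a leaf-by-locus status matrix,
#' and flags excision candidates: a locus absent in exactly one leaf inside
#' the clade of carriers, where the absent leaf's flanks align contiguously
#' across the gap (junction residue <= `junction_tol` bp).
#'
#' Status per (leaf, locus): `present` (annotation assigned), `absent`
#' (both flanks found with a contiguous junction), or `unresolved` (a flank
#' failed to anchor, or the flanks bracket a residual gap too large to call
#' a clean junction) — an anchoring failure is never reported as absence.
#'
#' @param annotated Named list (leaf -> [annotate_tes()] result).
#' @param genes Named list (leaf -> [dna_sequence()]), same names.
#' @param tree `ape::phylo` or newick string containing the leaves.
#' @param flank Flank length used for locus anchoring (default 200).
#' @param junction_tol Max residue at an excision junction (default 10).
#' @return List of class `te_presence`: `status` matrix (leaf x locus),
#'   `loci` data.frame, and `excisions` data.frame (leaf, locus).
#' @export
te_presence_matrix <- function(annotated, genes, tree, flank = 200L,
                               junction_tol = 10L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  leaves <- tree$tip.label
  stopifnot(all(leaves %in% names(annotated)), all(leaves %in% names(genes)))
  loci <- list()  # each: list(name, te_name, left, right) flanks from first carrier
  assign_tab <- list()
  for (leaf in leaves) {
    ann <- annotated[[leaf]]
    g <- genes[[leaf]]
    if (!nrow(ann)) next
    for (i in seq_len(nrow(ann))) {
      ls <- max(0L, ann$start[i] - flank)
      lf <- substr(g$residues, ls + 1L, ann$start[i])
      rf <- substr(g$residues, ann$end[i] + 1L,
                   min(seq_len_bp(g), ann$end[i] + flank))
      hit <- NULL
      for (k in seq_along(loci)) {
        if (loci[[k]]$te_name != ann$te_name[i]) next
        lm <- .find_flank(loci[[k]]$left, g)
        rm_ <- .find_flank(loci[[k]]$right, g)
        if (!is.null(lm) && !is.null(rm_) &&
            lm[2] <= ann$start[i] + 50L && lm[2] >= ls - 50L &&
            rm_[1] >= ann$end[i] - 50L) { hit <- k; break }
      }
      if (is.null(hit)) {
        loci[[length(loci) + 1L]] <- list(
          name = sprintf("locus%02d_%s", length(loci) + 1L, ann$te_name[i]),
          te_name = ann$te_name[i], left = lf, right = rf)
        hit <- length(loci)
      }
      assign_tab[[length(assign_tab) + 1L]] <- data.frame(leaf = leaf, locus = hit)
    }
  }
  nloc <- length(loci)
  status <- matrix("unresolved", nrow = length(leaves), ncol = nloc,
                   dimnames = list(leaves, vapply(loci, `[[`, "", "name")))
  if (nloc == 0L)
    return(structure(list(status = status,
                          loci = data.frame(name = character(), te_name = character()),
                          excisions = data.frame(leaf = character(), locus = character())),
                     class = "te_presence"))
  for (a in assign_tab) status[a$leaf, a$locus] <- "present"
  for (leaf in leaves) {
    g <- genes[[leaf]]
    for (k in seq_len(nloc)) {
      if (status[leaf, k] == "present") next
      lm <- .find_flank(loci[[k]]$left, g)
      rm_ <- .find_flank(loci[[k]]$right, g)
      if (is.null(lm) || is.null(rm_)) next  # unresolved
      gap <- rm_[1] - lm[2]
      if (gap >= -junction_tol && gap <= junction_tol) status[leaf, k] <- "absent"
      # larger residual gap: stays unresolved (diverged remnant?)
    }
  }
  # excision flags: exactly one absent leaf, inside the carriers' clade
  exc <- list()
  for (k in seq_len(nloc)) {
    pres <- leaves[status[, k] == "present"]
    abs_ <- leaves[status[, k] == "absent"]
    if (length(abs_) != 1L || length(pres) < 2L) next
    mrca_leaves <- if (length(pres) == length(leaves) - 1L) leaves else {
      node <- ape::getMRCA(tree, pres)
      ape::extract.clade(tree, node)$tip.label
    }
    if (abs_ %in% mrca_leaves)
      exc[[length(exc) + 1L]] <- data.frame(leaf = abs_, locus = colnames(status)[k])
  }
  structure(list(
    status = status,
    loci = data.frame(name = colnames(status),
                      te_name = vapply(loci, `[[`, "", "te_name")),
    excisions = if (length(exc)) do.call(rbind, exc)
                else data.frame(leaf = character(), locus = character())),
    class = "te_presence")
}

#' @export
print.te_presence <- function(x, ...) {
  cat(sprintf("<te_presence> %d leaves x %d loci; %d excision flag(s)\n",
              nrow(x$status), ncol(x$status), nrow(x$excisions)))
  print(x$status)
  invisible(x)
}

#' Write a TE presence/absence matrix as TSV in tree leaf order
#'
#' @param x A [te_presence_matrix()] result.
#' @param path Output file.
#' @export
write_te_presence <- function(x, path) {
  df <- data.frame(leaf = rownames(x$status), x$status, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
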