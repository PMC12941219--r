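#' Anchor set for synteny-based gene delineation
#'
#' The three anchors used to delineate a divergent gene from its conserved
#' flanking structures: a conserved-gene reference (the syntenic partner,
#' used as the contig-selection anchor), a promoter fragment containing the
#' TATA-box, and a 3'-end fragment containing the triple helix followed by
#' the tRNA-like structure.
#'
#' @param conserved_gene_reference,promoter_fragment,end_fragment
#'   [dna_sequence()] objects; fragments must be at least 30 bp.
#' @param tata_offset_in_promoter 0-based offset of the TATA-box start
#'   inside the promoter fragment.
#' @param helix_end_offset_in_end_fragment 0-based offset (exclusive end)
#'   of the triple helix inside the end fragment — the gene's 3' boundary.
#' @param end_layout Optional named list of 0-based half-open offset pairs
#'   within the end fragment: `helix_motif`, `hairpin`, `linker`,
#'   `trna_like`.
#' @return Object of class `anchor_set`.
#' @export
anchor_set <- function(conserved_gene_reference, promoter_fragment, end_fragment,
                       tata_offset_in_promoter, helix_end_offset_in_end_fragment,
                       end_layout = NULL) {
  stopifnot(inherits(conserved_gene_reference, "dna_sequence"),
            inherits(promoter_fragment, "dna_sequence"),
            inherits(end_fragment, "dna_sequence"))
  if (seq_len_bp(promoter_fragment) < 30L || seq_len_bp(end_fragment) < 30L)
    stop("anchor fragments must be >= 30 bp")
  stopifnot(tata_offset_in_promoter >= 0,
            tata_offset_in_promoter < seq_len_bp(promoter_fragment),
            helix_end_offset_in_end_fragment > 0,
            helix_end_offset_in_end_fragment <= seq_len_bp(end_fragment))
  structure(list(conserved_gene_reference = conserved_gene_reference,
                 promoter_fragment = promoter_fragment,
                 end_fragment = end_fragment,
                 tata_offset_in_promoter = as.integer(tata_offset_in_promoter),
                 helix_end_offset_in_end_fragment =
                   as.integer(helix_end_offset_in_end_fragment),
                 end_layout = end_layout),
            class = "anchor_set")
}

# Chain HSPs of one strand into collinear groups; returns list of chains
# (data.frames). On the minus strand, collinearity in the forward frame
# means subject coordinates decrease as query coordinates increase.
.chain_hsps <- function(h, strand, max_gap) {
  h <- h[h$strand == strand, , drop = FALSE]
  if (!nrow(h)) return(list())
  h <- h[order(h$qstart), , drop = FALSE]
  chains <- list()
  cur <- NULL
  for (i in seq_len(nrow(h))) {
    row <- h[i, ]
    if (is.null(cur)) { cur <- row; next }
    last <- cur[nrow(cur), ]
    qgap <- row$qstart - last$qend
    sgap <- if (strand == "+") row$sstart - last$send else last$sstart - row$send
    if (qgap >= -100 && qgap <= max_gap && sgap >= -100 && sgap <= max_gap) {
      cur <- rbind(cur, row)
    } else {
      chains[[length(chains) + 1L]] <- cur
      cur <- row
    }
  }
  chains[[length(chains) + 1L]] <- cur
  chains
}

#' Locate the conserved anchor gene on a contig
#'
#' Finds the contiguous region covered by a collinear chain of local hits
#' to the conserved-gene reference. A chain keeps one strand, is collinear,
#' and tolerates gaps up to `max_chain_gap`. Returns a no-call when no
#' chain reaches the score floor; raises an ambiguity error (class
#' `lncortho_ambiguity`) when a second non-overlapping chain scores
#' comparably — a silent pick is never made.
#'
#' @param contig A [dna_sequence()].
#' @param anchors An [anchor_set()].
#' @param max_chain_gap Maximum within-chain gap (default 5000).
#' @param score_floor Minimum identical-residue count for a chain (default
#'   2 x the aligner word size).
#' @param ambiguity_ratio Second-chain score fraction that triggers the
#'   ambiguity error (default 0.5).
#' @param word_size Seed word size passed to [local_align()].
#' @param ... Further [local_align()] parameters.
#' @return [genomic_interval()] of the anchor region (forward frame,
#'   strand from the chain), or a [no_call()].
#' @export
locate_conserved_anchor <- function(contig, anchors, max_chain_gap = 5000L,
                                    score_floor = NULL, ambiguity_ratio = 0.5,
                                    word_size = 11L, ...) {
  stopifnot(inherits(contig, "dna_sequence"), inherits(anchors, "anchor_set"))
  if (is.null(score_floor)) score_floor <- 2L * word_size
  h <- local_align(anchors$conserved_gene_reference, contig,
                   word_size = word_size, ...)
  chains <- c(.chain_hsps(h, "+", max_chain_gap), .chain_hsps(h, "-", max_chain_gap))
  if (!length(chains)) return(no_call("no_anchor"))
  scores <- vapply(chains, function(ch) sum(ch$nident), 0)
  chains <- chains[scores >= score_floor]
  scores <- scores[scores >= score_floor]
  if (!length(chains)) return(no_call("no_anchor"))
  ord <- order(-scores)
  chains <- chains[ord]; scores <- scores[ord]
  span <- function(ch) c(min(ch$sstart), max(ch$send))
  best <- span(chains[[1L]])
  if (length(chains) >= 2L) {
    for (k in 2:length(chains)) {
      sp <- span(chains[[k]])
      overlapping <- min(best[2], sp[2]) - max(best[1], sp[1]) > 0
      if (!overlapping && scores[k] >= ambiguity_ratio * scores[1L]) {
        cand <- sprintf("%d-%d(score %d)", sp[1], sp[2], as.integer(scores[k]))
        stop(structure(class = c("lncortho_ambiguity", "error", "condition"),
                       list(message = paste0(
                              "ambiguous anchor placement: ",
                              sprintf("%d-%d(score %d) vs ", best[1], best[2],
                                      as.integer(scores[1L])), cand),
                            call = sys.call(-1))))
      }
    }
  }
  genomic_interval(contig$id, best[1], best[2], chains[[1L]]$strand[1L])
}

# Map an offset inside an anchor fragment onto the target sequence through
# the best plus-strand HSP, realigning the matched segments so indels are
# handled exactly. Returns integer offset in target coordinates or NA.
.map_anchor_offset <- function(fragment, target, offset, ...) {
  h <- local_align(fragment, target, both_strands = FALSE, ...)
  h <- h[h$qstart <= offset & h$qend >= offset, , drop = FALSE]
  if (!nrow(h)) return(NA_integer_)
  h1 <- h[1L, ]
  qfrag <- substr(fragment$residues, h1$qstart + 1L, h1$qend)
  sfrag <- substr(target$residues, h1$sstart + 1L, h1$send)
  aln <- global_alignment_strings(qfrag, sfrag)
  rel <- offset - h1$qstart
  if (rel == h1$qend - h1$qstart) {  # exclusive end offset: map last base + 1
    off <- map_offset_through_alignment(aln$x, aln$y, rel - 1L)
    if (is.na(off)) return(NA_integer_)
    return(as.integer(h1$sstart + off + 1L))
  }
  off <- map_offset_through_alignment(aln$x, aln$y, rel)
  if (is.na(off)) return(NA_integer_)
  as.integer(h1$sstart + off)
}

#' Gene model container
#'
#' @param contig_id Contig identifier.
#' @param strand Gene strand on the contig.
#' @param gene_iv [genomic_interval()] from TATA-box start to triple-helix
#'   end (forward frame).
#' @param tata_iv,helix_iv,trna_like_iv Feature intervals (forward frame);
#'   may be NULL when unresolved.
#' @param pas_main,pas_alternatives PAS positions in transcript
#'   coordinates (filled by the PAS stage).
#' @param gapped Flag for gapped/unreliable assemblies (excluded from
#'   length statistics).
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(contig_id, strand, gene_iv, tata_iv = NULL,
                       helix_iv = NULL, trna_like_iv = NULL, pas_main = NULL,
                       pas_alternatives = NULL, gapped = FALSE) {
  structure(list(contig_id = contig_id, strand = strand, gene_iv = gene_iv,
                 tata_iv = tata_iv, helix_iv = helix_iv,
                 trna_like_iv = trna_like_iv, pas_main = pas_main,
                 pas_alternatives = pas_alternatives, gapped = gapped),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s:%d-%d(%s) len=%d\n", x$contig_id,
              x$gene_iv$start, x$gene_iv$end, x$strand, iv_length(x$gene_iv)))
  invisible(x)
}

#' Delineate a gene from its promoter and 3'-end anchors
#'
#' The 5' boundary is the TATA-box start lifted over from the promoter
#' fragment's best hit; the 3' boundary is the triple-helix end lifted from
#' the end fragment. The gene is reported in forward-frame coordinates with
#' its transcript strand; reverse-complementing the contig yields the same
#' forward-frame model with the strand toggled. The model is rejected
#' (no-call) when either anchor is missing, boundaries are inverted, or the
#' implied length falls outside `[min_len, max_len]`.
#'
#' @param contig A [dna_sequence()].
#' @param search_window [genomic_interval()] restricting the search, or
#'   NULL for the whole contig.
#' @param anchors An [anchor_set()].
#' @param min_len,max_len Plausible gene length bounds (defaults 2 kb and
#'   60 kb).
#' @param ... Passed to [local_align()].
#' @return A [gene_model()] or [no_call()] naming the missing anchor
#'   (`"5prime_anchor"` / `"3prime_anchor"`) or the rejection reason.
#' @export
locate_gene <- function(contig, search_window = NULL, anchors, min_len = 2000L,
                        max_len = 60000L, ...) {
  stopifnot(inherits(contig, "dna_sequence"), inherits(anchors, "anchor_set"))
  ws <- 0L; we <- seq_len_bp(contig)
  if (!is.null(search_window)) {
    stopifnot(search_window$start >= 0, search_window$end <= we)
    ws <- search_window$start; we <- search_window$end
  }
  sub <- subseq_dna(contig, ws, we, id = contig$id)
  # orientation from the promoter fragment's best hit
  ph <- local_align(anchors$promoter_fragment, sub, both_strands = TRUE, ...)
  if (!nrow(ph)) return(no_call("5prime_anchor"))
  strand <- ph$strand[1L]
  work <- if (strand == "+") sub else {
    rc <- reverse_complement(sub); rc$id <- sub$id; rc
  }
  Lw <- seq_len_bp(work)
  tata_start <- .map_anchor_offset(anchors$promoter_fragment, work,
                                   anchors$tata_offset_in_promoter, ...)
  if (is.na(tata_start)) return(no_call("5prime_anchor"))
  gene_end <- .map_anchor_offset(anchors$end_fragment, work,
                                 anchors$helix_end_offset_in_end_fragment, ...)
  if (is.na(gene_end)) return(no_call("3prime_anchor"))
  if (gene_end <= tata_start) return(no_call("inverted_boundaries"))
  glen <- gene_end - tata_start
  if (glen < min_len || glen > max_len) return(no_call("length_out_of_range"))
  map_elem <- function(offs) {
    s <- .map_anchor_offset(anchors$end_fragment, work, offs[1], ...)
    e <- .map_anchor_offset(anchors$end_fragment, work, offs[2], ...)
    if (is.na(s) || is.na(e) || e <= s) return(NULL)
    c(s, e)
  }
  helix <- trna <- NULL
  if (!is.null(anchors$end_layout)) {
    hm <- anchors$end_layout$helix_motif
    if (!is.null(hm)) helix <- map_elem(hm)
    tl <- anchors$end_layout$trna_like
    if (!is.null(tl)) trna <- map_elem(tl)
  }
  # map back from working (possibly reverse-complemented) frame to the
  # forward frame of the full contig
  to_fwd <- function(s, e) {
    if (strand == "+") c(ws + s, ws + e) else c(ws + Lw - e, ws + Lw - s)
  }
  g <- to_fwd(tata_start, gene_end)
  t6 <- to_fwd(tata_start, tata_start + 6L)
  mk_iv <- function(p) genomic_interval(contig$id, p[1], p[2], strand)
  gene_model(contig_id = contig$id, strand = strand, gene_iv = mk_iv(g),
             tata_iv = mk_iv(t6),
             helix_iv = if (!is.null(helix)) mk_iv(to_fwd(helix[1], helix[2])),
             trna_like_iv = if (!is.null(trna)) mk_iv(to_fwd(trna[1], trna[2])))
}

#' Refine a shared boundary across candidate fragments by modal MSA column
#'
#' Optional second pass after per-contig anchor liftover: the candidate
#' boundary regions from several contigs are aligned (reference-anchored,
#' first sequence is the reference), each provisional boundary offset is
#' mapped to its alignment column, and every sequence's boundary is snapped
#' to the modal column. This reproduces the effect of curating boundaries
#' on a grouped alignment without hard-coding taxon groups.
#'
#' @param seqs List of [dna_sequence()] boundary fragments (comparable
#'   regions, e.g. gene ends plus margin).
#' @param offsets Integer vector of provisional 0-based boundary offsets,
#'   one per fragment.
#' @return Integer vector of refined 0-based offsets (one per fragment).
#' @export
refine_boundary_msa <- function(seqs, offsets) {
  stopifnot(length(seqs) == length(offsets), length(seqs) >= 2L)
  msa <- align_ref_anchored(seqs)
  col_of <- function(row, off) {
    chars <- strsplit(row, "")[[1]]
    ri <- -1L
    for (k in seq_along(chars)) {
      if (chars[k] != "-") {
        ri <- ri + 1L
        if (ri == off) return(k)
      }
    }
    NA_integer_
  }
  cols <- mapply(col_of, msa, offsets)
  cols <- cols[!is.na(cols)]
  if (!length(cols)) stop("no boundary offset could be mapped to the MSA")
  modal <- as.integer(names(sort(table(cols), decreasing = TRUE))[1L])
  vapply(msa, function(row) {
    chars <- strsplit(row, "")[[1]]
    max(0L, sum(chars[seq_len(modal)] != "-") - 1L)
  }, 0L)
}

#' Synteny check between two gene models
#'
#' @param a,b [gene_model()] objects.
#' @return Object of class `synteny_report`: `same_contig`, `same_strand`,
#'   and `intergenic_distance` (bp between the gene intervals on the
#'   forward frame; 0 if overlapping; NA when on different contigs).
#' @export
check_synteny <- function(a, b) {
  same_contig <- identical(a$contig_id, b$contig_id)
  dist <- NA_integer_
  if (same_contig) {
    gap <- max(a$gene_iv$start, b$gene_iv$start) -
      min(a$gene_iv$end, b$gene_iv$end)
    dist <- max(0L, gap)
  }
  structure(list(same_contig = same_contig,
                 same_strand = identical(a$strand, b$strand),
                 intergenic_distance = dist),
            class = "synteny_report")
}

#' @export
print.synteny_report <- function(x, ...) {
  cat(sprintf("<synteny_report> same_contig=%s same_strand=%s distance=%s\n",
              x$same_contig, x$same_strand,
              if (is.na(x$intergenic_distance)) "NA" else x$intergenic_distance))
  invisible(x)
}

#' Extract a gene's sequence in transcript orientation
#'
#' @param contig A [dna_sequence()].
#' @param model A [gene_model()].
#' @param id Identifier for the extracted gene.
#' @return A [dna_sequence()]; reverse-complemented when the gene is on
#'   the minus strand.
#' @export
extract_gene_sequence <- function(contig, model, id = paste0(contig$id, "_gene")) {
  s <- subseq_dna(contig, model$gene_iv$start, model$gene_iv$end, id = id)
  if (model$strand == "-") { s <- reverse_complement(s); s$id <- id }
  s
}
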