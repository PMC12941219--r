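#' Position weight matrix
#'
#' Per-position base probabilities (pseudocount-adjusted) with a
#' background model. Columns must each sum to 1.
#'
#' @param tf_name Transcription factor / motif name.
#' @param matrix 4 x width numeric matrix of probabilities, rows A, C, G,
#'   T.
#' @param background Length-4 base probabilities (default uniform).
#' @return Object of class `pwm`.
#' @export
pwm <- function(tf_name, matrix, background = rep(0.25, 4)) {
  stopifnot(is.matrix(matrix), nrow(matrix) == 4L, ncol(matrix) >= 4L)
  if (any(abs(colSums(matrix) - 1) > 1e-6)) stop("PWM columns must sum to 1")
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  rownames(matrix) <- c("A", "C", "G", "T")
  structure(list(tf_name = tf_name, matrix = matrix,
                 background = setNames(background, c("A", "C", "G", "T")),
                 width = ncol(matrix)), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (width %d)\n", x$tf_name, x$width))
  invisible(x)
}

#' Build a PWM from a count matrix
#'
#' Adds a pseudocount of 0.1 per cell and normalizes each column.
#'
#' @param tf_name Motif name.
#' @param counts 4 x width count matrix (rows A, C, G, T).
#' @param pseudocount Per-cell pseudocount (default 0.1).
#' @param background Background base probabilities.
#' @return A [pwm()].
#' @export
pwm_from_counts <- function(tf_name, counts, pseudocount = 0.1,
                            background = rep(0.25, 4)) {
  stopifnot(is.matrix(counts), nrow(counts) == 4L)
  p <- counts + pseudocount
  p <- sweep(p, 2L, colSums(p), "/")
  pwm(tf_name, p, background)
}

#' Read PWMs from JASPAR or MEME text files
#'
#' JASPAR count blocks (`>ID NAME` followed by four `A [ ... ]` rows, with
#' or without brackets) and MEME minimal format (`MOTIF` +
#' `letter-probability matrix`) are supported. MEME probabilities are
#' converted back to counts using the stated `nsites` (default 20) so both
#' routes produce identical pseudocount-adjusted matrices. Malformed
#' records are skipped with a warning; a file yielding no motif is an
#' error.
#'
#' @param path Motif file.
#' @param pseudocount Per-cell pseudocount (default 0.1).
#' @param background Background base probabilities (default uniform).
#' @return List of [pwm()] objects.
#' @export
read_pwms <- function(path, pseudocount = 0.1, background = rep(0.25, 4)) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty PWM file: ", path)
  out <- list()
  is_meme <- any(grepl("letter-probability matrix", lines, fixed = TRUE)) ||
    any(grepl("^MEME version", lines))
  if (is_meme) {
    i <- 1L
    while (i <= length(lines)) {
      if (grepl("^MOTIF\\s+", lines[i])) {
        nm <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
        j <- i + 1L
        while (j <= length(lines) && !grepl("letter-probability matrix", lines[j]))
          j <- j + 1L
        if (j > length(lines)) { warning("motif without matrix: ", nm); break }
        hdr <- lines[j]
        w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
        nsites <- if (grepl("nsites=", hdr))
          as.numeric(sub(".*nsites=\\s*([0-9.]+).*", "\\1", hdr)) else 20
        rows <- lines[(j + 1L):(j + w)]
        vals <- suppressWarnings(lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
        if (any(vapply(vals, function(v) length(v) != 4L || anyNA(v), TRUE))) {
          warning("malformed MEME matrix for motif ", nm)
          i <- j + 1L
          next
        }
        counts <- t(do.call(rbind, vals)) * nsites
        p <- tryCatch(pwm_from_counts(nm, counts, pseudocount, background),
                      error = function(e) NULL)
        if (is.null(p)) warning("malformed MEME matrix for motif ", nm)
        else out[[length(out) + 1L]] <- p
        i <- j + w + 1L
      } else i <- i + 1L
    }
  } else {
    starts <- grep("^>", lines)
    bounds <- c(starts, length(lines) + 1L)
    for (k in seq_along(starts)) {
      block <- lines[starts[k]:(bounds[k + 1L] - 1L)]
      hdr <- sub("^>\\s*", "", block[1L])
      nm <- strsplit(trimws(hdr), "\\s+")[[1]]
      nm <- if (length(nm) >= 2L) nm[2L] else nm[1L]
      rows <- grep("^[ACGTacgt]\\s", block, value = TRUE)
      if (length(rows) != 4L) { warning("malformed JASPAR record: ", nm); next }
      base <- toupper(substr(trimws(rows), 1L, 1L))
      vals <- lapply(rows, function(r) {
        r <- gsub("[][]", " ", sub("^\\s*[ACGTacgt]", "", r))
        suppressWarnings(as.numeric(strsplit(trimws(r), "\\s+")[[1]]))
      })
      lens <- vapply(vals, length, 0L)
      if (length(unique(lens)) != 1L || any(vapply(vals, anyNA, TRUE)) ||
          !setequal(base, c("A", "C", "G", "T"))) {
        warning("malformed JASPAR record: ", nm)
        next
      }
      counts <- do.call(rbind, vals)[order(match(base, c("A", "C", "G", "T"))), ]
      p <- tryCatch(pwm_from_counts(nm, counts, pseudocount, background),
                    error = function(e) NULL)
      if (is.null(p)) { warning("malformed JASPAR record: ", nm); next }
      out[[length(out) + 1L]] <- p
    }
  }
  if (!length(out)) stop("no valid PWM records in ", path)
  out
}

# Integer log-odds matrix on the discretized score lattice (units of
# `granularity` bits).
.pwm_int_scores <- function(pwm, granularity = 0.001) {
  lo <- log2(pwm$matrix / pwm$background)
  round(lo / granularity)
}

#' Exact null score distribution of a PWM by dynamic programming
#'
#' Log-odds scores are discretized on a lattice (default 1/1000 bits) and
#' the exact distribution of the window score under the background model
#' is accumulated position by position. The returned p-values are
#' `P(score >= s)`.
#'
#' @param pwm A [pwm()].
#' @param granularity Lattice step in bits (default 0.001).
#' @return List with `min_score` (lattice offset), `probs` (density over
#'   lattice scores), `pvalues` (upper tail), `granularity`.
#' @export
pwm_score_distribution <- function(pwm, granularity = 0.001) {
  s <- .pwm_int_scores(pwm, granularity)
  bg <- pwm$background
  # iterative convolution, tracking the currently reachable range
  cur <- 1
  cur_lo <- 0L
  for (j in seq_len(ncol(s))) {
    nxt_lo <- cur_lo + min(s[, j])
    nxt_hi <- (cur_lo + length(cur) - 1L) + max(s[, j])
    nxt <- numeric(nxt_hi - nxt_lo + 1L)
    for (b in 1:4) {
      off <- cur_lo + s[b, j] - nxt_lo
      idx <- (off + 1L):(off + length(cur))
      nxt[idx] <- nxt[idx] + cur * bg[b]
    }
    cur <- nxt
    cur_lo <- nxt_lo
  }
  pv <- rev(cumsum(rev(cur)))
  list(min_score = cur_lo, probs = cur, pvalues = pv, granularity = granularity)
}

# p-value of an integer lattice score against a distribution from
# pwm_score_distribution.
.pwm_pvalue <- function(dist, iscore) {
  idx <- iscore - dist$min_score + 1L
  n <- length(dist$pvalues)
  ifelse(idx < 1L, 1, ifelse(idx > n, 0, dist$pvalues[pmax(1L, pmin(n, idx))]))
}

#' Scan a sequence with a PWM using exact p-values
#'
#' Log-odds scan of every window on both strands; window p-values come
#' from the exact lattice distribution of [pwm_score_distribution()] and
#' hits with `p < pthresh` are reported. When both strands hit the same
#' position, only the better-scoring strand is kept. Windows containing
#' `N` are skipped.
#'
#' @param seq A [dna_sequence()] (length >= PWM width).
#' @param pwm A [pwm()].
#' @param pthresh P-value threshold (default 1e-4).
#' @param both_strands Scan both strands (default TRUE).
#' @param granularity Score lattice step in bits.
#' @return `data.frame` of class `tf_hits`: tf_name, start, end (0-based
#'   half-open, forward frame), strand, score (bits), pvalue.
#' @export
scan_pwm <- function(seq, pwm, pthresh = 1e-4, both_strands = TRUE,
                     granularity = 0.001) {
  stopifnot(inherits(seq, "dna_sequence"), inherits(pwm, "pwm"))
  W <- pwm$width
  L <- seq_len_bp(seq)
  if (L < W) stop("sequence shorter than PWM width")
  dist <- pwm_score_distribution(pwm, granularity)
  s <- .pwm_int_scores(pwm, granularity)
  win_scores <- function(res) {
    code <- match(strsplit(res, "")[[1]], c("A", "C", "G", "T"))
    n <- length(code) - W + 1L
    tot <- numeric(n)
    bad <- logical(n)
    for (j in seq_len(W)) {
      cj <- code[j:(j + n - 1L)]
      bad <- bad | is.na(cj)
      v <- s[, j][cj]
      v[is.na(v)] <- 0
      tot <- tot + v
    }
    tot[bad] <- NA
    tot
  }
  hits <- list()
  sc_f <- win_scores(seq$residues)
  pv_f <- .pwm_pvalue(dist, sc_f)
  keep <- which(!is.na(sc_f) & pv_f < pthresh)
  if (length(keep))
    hits[[1L]] <- data.frame(tf_name = pwm$tf_name, start = keep - 1L,
                             end = keep - 1L + W, strand = "+",
                             score = sc_f[keep] * granularity,
                             pvalue = pv_f[keep])
  if (both_strands) {
    rc <- revcomp_chr(seq$residues)
    sc_r <- win_scores(rc)
    pv_r <- .pwm_pvalue(dist, sc_r)
    keep <- which(!is.na(sc_r) & pv_r < pthresh)
    if (length(keep)) {
      # map reverse-complement window start to forward frame
      fstart <- L - (keep - 1L) - W
      hits[[length(hits) + 1L]] <- data.frame(tf_name = pwm$tf_name,
                                              start = fstart, end = fstart + W,
                                              strand = "-",
                                              score = sc_r[keep] * granularity,
                                              pvalue = pv_r[keep])
    }
  }
  if (!length(hits)) {
    out <- data.frame(tf_name = character(), start = integer(), end = integer(),
                      strand = character(), score = numeric(), pvalue = numeric())
  } else {
    out <- do.call(rbind, hits)
    # deduplicate to the better strand per position
    out <- out[order(out$start, -out$score, out$strand), , drop = FALSE]
    out <- out[!duplicated(out$start), , drop = FALSE]
    out <- out[order(out$start), , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("tf_hits", "data.frame")
  out
}

#' Transcription factors shared across ortholog promoters
#'
#' TFs with at least one predicted site in at least `fraction` of the
#' genes (the permissive shared-regulation rule), sorted by prevalence
#' then name.
#'
#' @param hits_per_gene Named list: gene id -> character vector of TF
#'   names (or a `tf_hits` data.frame, from which names are taken).
#' @param fraction Minimum fraction of genes (default 0.65); inclusion is
#'   `prevalence >= fraction`.
#' @return `data.frame` with columns tf_name, n_genes, prevalence.
#' @export
shared_tfs <- function(hits_per_gene, fraction = 0.65) {
  stopifnot(length(hits_per_gene) >= 2L)
  sets <- lapply(hits_per_gene, function(h) {
    if (is.data.frame(h)) unique(h$tf_name) else unique(as.character(h))
  })
  all_tf <- sort(unique(unlist(sets)))
  n <- length(sets)
  cnt <- vapply(all_tf, function(tf) sum(vapply(sets, function(s) tf %in% s, TRUE)), 0L)
  prev <- cnt / n
  keep <- prev >= fraction
  d <- data.frame(tf_name = all_tf[keep], n_genes = cnt[keep],
                  prevalence = prev[keep], row.names = NULL)
  d[order(-d$prevalence, d$tf_name), , drop = FALSE]
}

#' Intersection of two shared-TF lists
#'
#' @param a,b Results of [shared_tfs()] (or character vectors).
#' @return Sorted character vector of TFs shared by both gene sets.
#' @export
shared_tf_intersection <- function(a, b) {
  va <- if (is.data.frame(a)) a$tf_name else a
  vb <- if (is.data.frame(b)) b$tf_name else b
  sort(intersect(va, vb))
}

#' Join shared TFs against a TF-to-GO annotation table
#'
#' Plain term counting (no enrichment statistics): each TF contributes all
#' terms associated with it.
#'
#' @param tfs Character vector (or [shared_tfs()] result).
#' @param go_table `data.frame` with columns `tf` and `term`.
#' @return `data.frame` with columns term, n_tfs, tf_list, sorted by
#'   descending n_tfs.
#' @export
go_term_summary <- function(tfs, go_table) {
  if (is.data.frame(tfs)) tfs <- tfs$tf_name
  stopifnot(all(c("tf", "term") %in% names(go_table)))
  sub <- go_table[go_table$tf %in% tfs, , drop = FALSE]
  if (!nrow(sub))
    return(data.frame(term = character(), n_tfs = integer(),
                      tf_list = character()))
  sp <- split(unique(sub[, c("tf", "term")])$tf, unique(sub[, c("tf", "term")])$term)
  d <- data.frame(term = names(sp),
                  n_tfs = vapply(sp, length, 0L),
                  tf_list = vapply(sp, function(v) paste(sort(v), collapse = ","), ""),
                  row.names = NULL)
  d[order(-d$n_tfs, d$term), , drop = FALSE]
}
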