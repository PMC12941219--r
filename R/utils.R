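#' No-call marker
#'
#' Several locator/caller operations decline to answer rather than guess
#' (missing anchor, ambiguous signal, projection failure). They return a
#' `lnc_nocall` object carrying the reason, which propagates through the
#' pipeline instead of raising an error.
#'
#' @param reason Short machine-readable reason string.
#' @param detail Optional human-readable detail.
#' @return An object of class `lnc_nocall`.
#' @export
no_call <- function(reason, detail = NULL) {
  structure(list(reason = reason, detail = detail), class = "lnc_nocall")
}

#' @rdname no_call
#' @param x Object to test.
#' @export
is_no_call <- function(x) inherits(x, "lnc_nocall")

#' @export
print.lnc_nocall <- function(x, ...) {
  cat("<no-call>", x$reason, if (!is.null(x$detail)) paste0("(", x$detail, ")"), "\n")
  invisible(x)
}

# Run code with a private RNG state seeded from `seed`, restoring the
# caller's stream afterwards. Keeps generation deterministic without
# clobbering user RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# Small deterministic string hash, kept below 2^31 so derived seeds are
# valid R integers.
hash_seed <- function(seed, name) {
  h <- 0
  for (v in utf8ToInt(name)) h <- (h * 131 + v) %% 1977326743
  as.integer((seed %% 1000003) * 2011 + h) %% 2147483629L
}

# Map a 0-based offset in `x` to the corresponding 0-based offset in `y`
# through a pairwise alignment of the two (gapped strings of equal width).
# Offsets falling in a gap map to the next aligned y position.
map_offset_through_alignment <- function(x_aln, y_aln, offset) {
  xs <- strsplit(x_aln, "")[[1]]
  ys <- strsplit(y_aln, "")[[1]]
  stopifnot(length(xs) == length(ys))
  xi <- -1L; yi <- -1L
  for (k in seq_along(xs)) {
    if (xs[k] != "-") xi <- xi + 1L
    if (ys[k] != "-") yi <- yi + 1L
    if (xi == offset && xs[k] != "-") {
      return(if (ys[k] != "-") yi else yi + 1L)
    }
  }
  NA_integer_
}

# Global pairwise alignment of two character sequences via dynamic
# programming (Biostrings), returning the two gapped strings.
global_alignment_strings <- function(x, y, match = 1, mismatch = -2,
                                     gap_open = 5, gap_extend = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(x),
                                       Biostrings::DNAString(y),
                                       type = "global", substitutionMatrix = mat,
                                       gapOpening = gap_open,
                                       gapExtension = gap_extend)
  list(x = as.character(Biostrings::alignedPattern(aln)),
       y = as.character(Biostrings::alignedSubject(aln)))
}

#' Positional bin profile
#'
#' Counts of features per fractional-length bin; bin boundaries cover `[0, 1]`
#' exactly and counts are summable across genes.
#'
#' @param counts Integer vector, one count per bin.
#' @param n_bins Number of bins.
#' @param note Free-text normalization note.
#' @return An object of class `binned_profile`.
#' @export
binned_profile <- function(counts, n_bins = length(counts),
                           note = "per-gene fractional length") {
  stopifnot(length(counts) == n_bins, all(counts >= 0))
  structure(list(n_bins = as.integer(n_bins), counts = as.integer(counts),
                 note = note), class = "binned_profile")
}

#' @export
print.binned_profile <- function(x, ...) {
  cat(sprintf("<binned_profile> %d bins (%s)\n", x$n_bins, x$note))
  print(setNames(x$counts, sprintf("[%.2f,%.2f)", (seq_len(x$n_bins) - 1) / x$n_bins,
                                   seq_len(x$n_bins) / x$n_bins)))
  invisible(x)
}

# Fractional-position bin index (0-based) with the right-edge point clamped
# into the last bin.
frac_bin <- function(pos, total_len, n_bins) {
  pmin(as.integer(floor(pos / total_len * n_bins)), n_bins - 1L)
}

rand_dna <- function(n, probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}
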