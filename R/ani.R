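#' Average nucleotide identity between two genes
#'
#' The pairwise ANI statistic: every local-alignment hit longer than
#' `min_hit_len` contributes its identity-weighted length
#' (`pident / 100 * aln_length`) to both genes' sums; each sum is
#' normalized by its gene's length, the two coverages are averaged and
#' expressed as a percentage:
#'
#' \deqn{ANI = (\sum w / L_1 + \sum w / L_2) / 2 \times 100}
#'
#' All hits are summed, so repeat-rich genes can push the raw value above
#' 100%; the result is then clamped to 100 and flagged. An optional mode
#' merges query-side overlapping hits before summation.
#'
#' @param g1,g2 [dna_sequence()] objects.
#' @param min_hit_len Strict minimum alignment length for a qualifying hit
#'   (default 100: hits must be *longer than* 100 bp).
#' @param merge_overlaps Merge query-overlapping hits before summing
#'   (default FALSE, the literal formula).
#' @param ... Passed to [local_align()].
#' @return Object of class `ani_result`: list with gene ids, the two
#'   weighted sums, gene lengths, `ani` (percent) and `clamped` flag.
#' @export
ani_pair <- function(g1, g2, min_hit_len = 100L, merge_overlaps = FALSE, ...) {
  stopifnot(inherits(g1, "dna_sequence"), inherits(g2, "dna_sequence"))
  h <- local_align(g1, g2, ...)
  h <- h[h$length > min_hit_len, , drop = FALSE]
  if (merge_overlaps && nrow(h) > 1L) {
    # greedily drop hits whose query span overlaps a better hit already kept
    keep <- logical(nrow(h))
    for (i in seq_len(nrow(h))) {
      ok <- TRUE
      for (j in which(keep)) {
        if (min(h$qend[i], h$qend[j]) - max(h$qstart[i], h$qstart[j]) > 0) {
          ok <- FALSE; break
        }
      }
      keep[i] <- ok
    }
    h <- h[keep, , drop = FALSE]
  }
  w <- sum(h$pident / 100 * h$length)
  l1 <- seq_len_bp(g1); l2 <- seq_len_bp(g2)
  raw <- (w / l1 + w / l2) / 2 * 100
  structure(list(gene1_id = g1$id, gene2_id = g2$id, weighted_sum_g1 = w,
                 weighted_sum_g2 = w, length_g1 = l1, length_g2 = l2,
                 ani = min(raw, 100), raw_ani = raw, clamped = raw > 100),
            class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("<ani_result> %s vs %s: ANI = %.2f%%%s\n", x$gene1_id, x$gene2_id,
              x$ani, if (x$clamped) " (clamped from >100)" else ""))
  invisible(x)
}

#' All-vs-all ANI matrix
#'
#' @param genes List of [dna_sequence()] objects with unique ids.
#' @param leaf_order Optional character vector of ids giving the output
#'   row/column order (e.g. a phylogenetic leaf order).
#' @param ... Passed to [ani_pair()].
#' @return Symmetric percent matrix of class `ani_matrix` with 100 on the
#'   diagonal.
#' @export
ani_matrix <- function(genes, leaf_order = NULL, ...) {
  stopifnot(length(genes) >= 2L)
  ids <- vapply(genes, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate gene ids")
  n <- length(ids)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- ani_pair(genes[[i]], genes[[j]], ...)$ani
      m[i, j] <- a; m[j, i] <- a
    }
  }
  if (!is.null(leaf_order)) {
    if (!setequal(leaf_order, ids)) stop("leaf_order must be a permutation of gene ids")
    m <- m[leaf_order, leaf_order]
  }
  class(m) <- c("ani_matrix", class(m))
  m
}

#' Select archetypes (maximally dissimilar representatives)
#'
#' Farthest-first greedy selection on the dissimilarity d = 100 - ANI:
#' start from the pair with maximal d (ties broken by lexicographic id
#' order), then repeatedly add the gene maximizing its minimum d to the
#' already-selected set. Deterministic. The greedy is a 1/2-approximation
#' of the exact max-min objective; see [archetype_maxmin_exact()] for the
#' brute-force optimum on small inputs.
#'
#' @param m An [ani_matrix()].
#' @param k Number of archetypes, `2 <= k <= n`.
#' @return Character vector of selected gene ids (selection order).
#' @export
select_archetypes <- function(m, k) {
  ids <- rownames(m)
  n <- length(ids)
  if (k < 2L || k > n) stop("need 2 <= k <= number of genes")
  d <- 100 - unclass(m)
  # starting pair: max d, ties by lexicographic (id_i, id_j)
  best <- -Inf; pick <- NULL
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pr <- sort(c(ids[i], ids[j]))
    if (d[i, j] > best ||
        (d[i, j] == best && (pr[1] < pick[1] || (pr[1] == pick[1] && pr[2] < pick[2])))) {
      best <- d[i, j]; pick <- pr
    }
  }
  sel <- pick
  while (length(sel) < k) {
    rest <- setdiff(ids, sel)
    mind <- vapply(rest, function(g) min(d[g, sel]), 0)
    top <- rest[mind == max(mind)]
    sel <- c(sel, sort(top)[1])
  }
  sel
}

#' Exact max-min archetype subsets by brute force
#'
#' Enumerates all k-subsets and returns those maximizing the minimum
#' pairwise dissimilarity (100 - ANI). Exponential; intended as an oracle
#' for small n.
#'
#' @param m An [ani_matrix()].
#' @param k Subset size.
#' @return List with `objective` (the optimal min pairwise d) and `sets`
#'   (list of id vectors attaining it).
#' @export
archetype_maxmin_exact <- function(m, k) {
  ids <- rownames(m)
  n <- length(ids)
  if (k < 2L || k > n) stop("need 2 <= k <= number of genes")
  if (choose(n, k) > 2e5) stop("too many subsets for brute force")
  d <- 100 - unclass(m)
  combs <- utils::combn(n, k)
  obj <- apply(combs, 2L, function(s) min(d[s, s][upper.tri(matrix(0, k, k))]))
  best <- max(obj)
  sets <- lapply(which(obj >= best - 1e-9), function(ix) ids[combs[, ix]])
  list(objective = best, sets = sets)
}

#' Gene length statistics by taxon, with a phylogenetic trend test
#'
#' Mean and standard deviation of gene length per taxon and overall
#' (gapped-assembly models are excluded), plus the Spearman rank
#' correlation of length against patristic distance from a designated
#' reference leaf, with a two-sided permutation p-value.
#'
#' @param models Named list of `gene_model` objects (names = leaf ids).
#' @param taxonomy Named character vector mapping leaf id to taxon; NULL
#'   puts everything in one taxon.
#' @param tree An `ape::phylo` tree or newick string (optional).
#' @param reference_leaf Leaf from which patristic distances are measured.
#' @param n_perm Number of permutations for the p-value (default 999).
#' @param perm_seed RNG seed for the permutation null.
#' @return List with `table` (taxon, n, mean, sd), `rho` and `p_value`
#'   (NA when no tree/reference given).
#' @export
length_stats <- function(models, taxonomy = NULL, tree = NULL,
                         reference_leaf = NULL, n_perm = 999L, perm_seed = 1L) {
  gapped <- vapply(models, function(m) isTRUE(m$gapped), TRUE)
  models <- models[!gapped]
  if (!length(models)) stop("no gapless gene models")
  lens <- vapply(models, function(m) iv_length(m$gene_iv), 0L)
  ids <- names(models)
  tax <- if (is.null(taxonomy)) setNames(rep("all", length(ids)), ids) else taxonomy[ids]
  agg <- lapply(split(lens, tax), function(v) {
    c(n = length(v), mean = mean(v), sd = if (length(v) >= 2L) sd(v) else NA_real_)
  })
  tab <- data.frame(taxon = names(agg),
                    n = vapply(agg, `[[`, 0, "n"),
                    mean = vapply(agg, `[[`, 0, "mean"),
                    sd = vapply(agg, `[[`, 0, "sd"), row.names = NULL)
  tab <- rbind(tab, data.frame(taxon = "overall", n = length(lens),
                               mean = mean(lens),
                               sd = if (length(lens) >= 2L) sd(lens) else NA_real_))
  rho <- NA_real_; pval <- NA_real_
  if (!is.null(tree) && !is.null(reference_leaf)) {
    if (is.character(tree)) tree <- ape::read.tree(text = tree)
    pd <- ape::cophenetic.phylo(tree)[reference_leaf, ]
    common <- intersect(ids, names(pd))
    if (length(common) >= 3L) {
      x <- pd[common]; y <- lens[common]
      rho <- cor(x, y, method = "spearman")
      perm <- with_seed(perm_seed, {
        vapply(seq_len(n_perm), function(i) cor(x, sample(y), method = "spearman"), 0)
      })
      pval <- (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
    }
  }
  list(table = tab, rho = rho, p_value = pval)
}

#' Write an ANI matrix as TSV with header row and column
#'
#' @param m An [ani_matrix()].
#' @param path Output file.
#' @export
write_ani_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), unclass(m), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
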