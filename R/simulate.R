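# --- fixed synthetic end-structure constants -------------------------------
# Triple-helix-forming motifs are held substitution-free by the generator
# (their real counterparts show no mismatches across orthologs); the
# tRNA-like elements are synthetic cloverleaf-style sequences built from
# complementary stems so that covariation analysis has planted structure.

.helix_motif_A <- "GGCCAAGGAGTTGTGGCCAA"
.helix_motif_B <- "GGTTCAGGTCATGCGGTTCA"

.make_trna <- function(stem1, loop1, spacer, stem2, loop2, tail) {
  rc <- function(s) revcomp_chr(s)
  seq <- paste0(stem1, loop1, rc(stem1), spacer, stem2, loop2, rc(stem2), tail)
  db <- paste0(strrep("(", nchar(stem1)), strrep(".", nchar(loop1)),
               strrep(")", nchar(stem1)), strrep(".", nchar(spacer)),
               strrep("(", nchar(stem2)), strrep(".", nchar(loop2)),
               strrep(")", nchar(stem2)), strrep(".", nchar(tail)))
  list(seq = seq, structure = db)
}

# remove every AATAAA occurrence, including overlapping ones
.scrub_all_pas <- function(res) {
  while (grepl("AATAAA", res, fixed = TRUE))
    res <- sub("AATAAA", "AACAAA", res, fixed = TRUE)
  res
}

.trna_A <- .make_trna("GGCAGGC", "TTCGAA", "ACTAT", "GCTGGA", "TTTACGA",
                      "CAATCCACCA")
.trna_B <- .make_trna("GCCTACG", "TTCAAT", "GATCA", "CGAGGT", "TAACGTA",
                      "TACTGCACCA")

#' Dot-bracket structure of the synthetic tRNA-like elements
#'
#' @param gene `"geneA"` or `"geneB"`.
#' @return List with `seq` (DNA) and `structure` (dot-bracket).
#' @export
trna_like_reference <- function(gene = c("geneA", "geneB")) {
  gene <- match.arg(gene)
  if (gene == "geneA") .trna_A else .trna_B
}

#' Built-in synthetic TE consensus library
#'
#' Six deterministic synthetic consensus sequences emulating the major TE
#' classes (names carry the `_syn` suffix to mark them as synthetic
#' stand-ins, with DFAM-style class metadata). The canonical
#' polyadenylation hexamer is scrubbed from each consensus so planted TEs
#' never interfere with PAS calling.
#'
#' @return Named list of [dna_sequence()] objects with `class` metadata.
#' @export
default_te_library <- function() {
  fams <- data.frame(
    name = c("SINE_Alu_syn", "SINE_B1_syn", "SINE_MIR_syn", "LINE_L1_syn",
             "LTR_ERVL_syn", "DNA_hAT_syn"),
    class = c("SINE/Alu", "SINE/B1", "SINE/MIR", "LINE/L1", "LTR/ERVL",
              "DNA/hAT"),
    len = c(300L, 180L, 250L, 600L, 400L, 350L))
  with_seed(7919L, {
    out <- lapply(seq_len(nrow(fams)), function(i) {
      res <- rand_dna(fams$len[i], c(A = 0.27, C = 0.23, G = 0.23, T = 0.27))
      res <- .scrub_all_pas(res)
      dna_sequence(fams$name[i], res, meta = c(class = fams$class[i]))
    })
    names(out) <- fams$name
    out
  })
}

#' Default study phylogeny
#'
#' A six-leaf tree with branch lengths in expected substitutions per site.
#' Root-to-leaf depths (0.055-0.07) are chosen by a detectability power
#' analysis: the two arms of a planted inverted repeat diverge from each
#' other at twice the leaf depth, so the deepest leaf keeps expected
#' arm-pair identity near 87%, more than three binomial standard
#' deviations above the 80% detection threshold, while pairwise leaf
#' divergences (0.06-0.125) still span a meaningful conservation
#' contrast.
#'
#' @return Newick string.
#' @export
default_tree <- function() {
  "((L1:0.03,L2:0.03):0.025,((L3:0.04,L4:0.04):0.015,(L5:0.045,L6:0.045):0.015):0.01);"
}

#' Specification of a synthetic two-gene locus
#'
#' Describes the planted architecture: a divergent ~21 kb gene (gene A) and
#' a conserved ~7 kb gene (gene B) on one strand, separated by a fixed
#' intergenic distance, with TATA-boxes, a PAS at a fixed offset, 3'-end
#' triple-helix/tRNA-like blocks, TEs concentrated in two fractional-length
#' bins, inverted-repeat pairs, G-quadruplexes, GU-rich tracts near the 3'
#' end and isolated core hexamer motifs in the gene centre.
#'
#' @param contig_length Total contig length; NULL derives it from the
#'   components plus flanks.
#' @param geneA_length,geneB_length Gene lengths (defaults 21,000 and
#'   7,000).
#' @param intergenic_distance Gap between gene A end and gene B start
#'   (default 36,755).
#' @param strand Strand carrying both genes.
#' @param pas_offset PAS motif start offset from gene A start (default
#'   3,500).
#' @param marsupial_pas Plant a second PAS 500 bp downstream (the
#'   marsupial/monotreme two-PAS mode).
#' @param plant_pas Plant the PAS at all (FALSE gives a PAS-free control;
#'   the guard zone is still scrubbed of the motif).
#' @param te_bins List of fractional-length intervals receiving TEs.
#' @param n_te Number of planted TEs (split across bins; 0 for control).
#' @param n_inverted_repeat_pairs Number of inverted-repeat pairs.
#' @param ir_arm_length Arm length of each pair (default 300).
#' @param ir_spacers Spacer length per pair (defaults 1,000 and 5,000 bp:
#'   one proximal, one distal pair).
#' @param ir_arm1_windows Fractional windows for each pair's upstream arm.
#' @param n_g4 Planted G-quadruplexes (split between the two gene ends).
#' @param gu_tract `list(count, unit, window)`: GU-repeat tracts of
#'   `unit` GT dinucleotides planted in the 3' fractional window.
#' @param core_motifs `list(count_each, window)`: isolated plants of the
#'   central core hexamers TCTGTG and CTGTGT.
#' @param flank Flanking background on each side of the locus.
#' @param background Base sampling probabilities (T-enriched, C-depleted).
#' @param te_library TE consensus list (default [default_te_library()]).
#' @return Object of class `synthetic_locus_spec`.
#' @export
synthetic_locus_spec <- function(contig_length = NULL, geneA_length = 21000L,
                                 geneB_length = 7000L,
                                 intergenic_distance = 36755L, strand = "+",
                                 pas_offset = 3500L, marsupial_pas = FALSE,
                                 plant_pas = TRUE,
                                 te_bins = list(c(0.30, 0.40), c(0.70, 0.80)),
                                 n_te = 6L, n_inverted_repeat_pairs = 2L,
                                 ir_arm_length = 300L,
                                 ir_spacers = c(1000L, 5000L),
                                 ir_arm1_windows = list(c(0.45, 0.52),
                                                        c(0.405, 0.425)),
                                 n_g4 = 4L,
                                 gu_tract = list(count = 8L, unit = 12L,
                                                 window = c(0.82, 0.96)),
                                 core_motifs = list(count_each = 30L,
                                                    window = c(0.42, 0.65)),
                                 flank = 3000L,
                                 background = c(A = 0.28, C = 0.19, G = 0.22,
                                                T = 0.31),
                                 te_library = NULL) {
  spec <- list(contig_length = contig_length, geneA_length = as.integer(geneA_length),
               geneB_length = as.integer(geneB_length),
               intergenic_distance = as.integer(intergenic_distance),
               strand = strand, pas_offset = as.integer(pas_offset),
               marsupial_pas = marsupial_pas, plant_pas = plant_pas,
               te_bins = te_bins, n_te = as.integer(n_te),
               n_inverted_repeat_pairs = as.integer(n_inverted_repeat_pairs),
               ir_arm_length = as.integer(ir_arm_length),
               ir_spacers = as.integer(ir_spacers),
               ir_arm1_windows = ir_arm1_windows, n_g4 = as.integer(n_g4),
               gu_tract = gu_tract, core_motifs = core_motifs,
               flank = as.integer(flank), background = background,
               te_library = te_library)
  stopifnot(spec$pas_offset < spec$geneA_length, spec$pas_offset > 710L)
  for (b in spec$te_bins) stopifnot(b[1] >= 0, b[2] <= 1, b[1] < b[2])
  stopifnot(length(spec$ir_spacers) >= spec$n_inverted_repeat_pairs,
            length(spec$ir_arm1_windows) >= spec$n_inverted_repeat_pairs,
            abs(sum(spec$background) - 1) < 1e-9, strand %in% c("+", "-"))
  min_len <- spec$flank * 2L + spec$geneA_length + spec$intergenic_distance +
    spec$geneB_length
  if (is.null(spec$contig_length)) spec$contig_length <- min_len
  if (spec$contig_length < min_len)
    stop("genes plus intergenic distance do not fit the contig")
  structure(spec, class = "synthetic_locus_spec")
}

# Non-overlap placement registry helpers ------------------------------------

.reg_collides <- function(reg, start, end, margin) {
  if (!nrow(reg)) return(character())
  hit <- reg$start < end + margin & reg$end > start - margin
  reg$name[hit]
}

.reg_place_random <- function(reg, len, win_lo, win_hi, name, margin = 10L,
                              tries = 500L) {
  lo <- as.integer(ceiling(win_lo)); hi <- as.integer(floor(win_hi)) - len
  if (hi < lo)
    stop("cannot place feature ", name, ": window too small")
  for (t in seq_len(tries)) {
    s <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    coll <- .reg_collides(reg, s, s + len, margin)
    if (!length(coll)) {
      reg[nrow(reg) + 1L, ] <- list(name, s, s + len)
      return(list(reg = reg, start = s))
    }
  }
  stop("cannot place feature ", name, ": collides with ",
       paste(unique(coll), collapse = ", "))
}

.reg_place_fixed <- function(reg, start, end, name, margin = 0L) {
  coll <- .reg_collides(reg, start, end, margin)
  if (length(coll))
    stop("cannot place feature ", name, ": collides with ",
         paste(unique(coll), collapse = ", "))
  reg[nrow(reg) + 1L, ] <- list(name, start, end)
  reg
}

# Replace stray PAS hexamers inside guard zones (keeping planted motifs).
.scrub_pas <- function(chars, zones, planted_starts) {
  guards <- zones[zones$kind == "guard", , drop = FALSE]
  for (zi in seq_len(nrow(guards))) {
    lo <- max(0L, guards$start[zi] - 5L)
    hi <- min(length(chars), guards$end[zi] + 5L)
    repeat {
      win <- paste(chars[(lo + 1L):hi], collapse = "")
      m <- gregexpr("AATAAA", win, fixed = TRUE)[[1]]
      if (m[1] == -1) break
      pos <- lo + as.integer(m) - 1L  # 0-based contig positions
      pos <- pos[!(pos %in% planted_starts)]
      if (!length(pos)) break
      chars[pos + 3L] <- "C"  # break the motif at its T
    }
  }
  chars
}

#' Build the root locus of a synthetic cohort
#'
#' Assembles the contig described by a [synthetic_locus_spec()] with every
#' planted feature recorded as ground truth. Exactly one `AATAAA` lies
#' within 110 bp of the planted PAS and none elsewhere within a +-600 bp
#' guard zone (unless the marsupial two-PAS mode is requested, which adds
#' the second signal ~500 bp downstream). Same spec and seed give a
#' byte-identical contig.
#'
#' @param spec A [synthetic_locus_spec()].
#' @param seed Integer RNG seed.
#' @return Object of class `synthetic_locus`: list with `contig`
#'   ([dna_sequence()]), `truth` (`synthetic_truth`), and `anchors` (list
#'   of [anchor_set()] for gene A and gene B).
#' @export
build_root_locus <- function(spec, seed) {
  stopifnot(inherits(spec, "synthetic_locus_spec"))
  with_seed(seed, .build_root_locus_impl(spec, seed))
}

.build_root_locus_impl <- function(spec, seed) {
  LA <- spec$geneA_length; LB <- spec$geneB_length
  gA0 <- spec$flank
  gAe <- gA0 + LA
  gB0 <- gAe + spec$intergenic_distance
  gBe <- gB0 + LB
  L <- spec$contig_length
  trnaA_len <- nchar(.trna_A$seq); trnaB_len <- nchar(.trna_B$seq)
  stopifnot(gBe + trnaB_len + 100L <= L)

  chars <- strsplit(rand_dna(L, spec$background), "")[[1]]
  feats <- list(); reg <- data.frame(name = character(), start = integer(),
                                     end = integer())
  put <- function(start, str) {
    chars[(start + 1L):(start + nchar(str))] <<- strsplit(str, "")[[1]]
  }
  feat <- function(type, name, gene, start, end) {
    feats[[length(feats) + 1L]] <<- data.frame(type = type, name = name,
                                               gene = gene, start = start,
                                               end = end, strand = "+")
  }

  # fixed architecture: TATA boxes, 3'-end blocks, tRNA-like elements
  blockA <- nchar(.helix_motif_A) + 29L + 30L       # motif + hairpin + linker
  blockB <- nchar(.helix_motif_B) + 31L + 24L
  put(gA0, "TATAAA"); feat("TATA_box", "TATA_A", "geneA", gA0, gA0 + 6L)
  put(gB0, "TATAAA"); feat("TATA_box", "TATA_B", "geneB", gB0, gB0 + 6L)
  hA0 <- gAe - blockA
  put(hA0, .helix_motif_A)
  feat("triple_helix", "helix_A", "geneA", hA0, hA0 + nchar(.helix_motif_A))
  feat("helix_hairpin", "hairpin_A", "geneA", hA0 + nchar(.helix_motif_A),
       hA0 + nchar(.helix_motif_A) + 29L)
  feat("helix_linker", "linker_A", "geneA", gAe - 30L, gAe)
  put(gAe, .trna_A$seq); feat("tRNA_like", "trna_A", "geneA", gAe, gAe + trnaA_len)
  hB0 <- gBe - blockB
  put(hB0, .helix_motif_B)
  feat("triple_helix", "helix_B", "geneB", hB0, hB0 + nchar(.helix_motif_B))
  feat("helix_hairpin", "hairpin_B", "geneB", hB0 + nchar(.helix_motif_B),
       hB0 + nchar(.helix_motif_B) + 31L)
  feat("helix_linker", "linker_B", "geneB", gBe - 24L, gBe)
  put(gBe, .trna_B$seq); feat("tRNA_like", "trna_B", "geneB", gBe, gBe + trnaB_len)
  feat("gene", "geneA", "geneA", gA0, gAe)
  feat("gene", "geneB", "geneB", gB0, gBe)

  reg <- .reg_place_fixed(reg, gA0, gA0 + 6L, "TATA_A")
  reg <- .reg_place_fixed(reg, gB0, gB0 + 6L, "TATA_B")
  reg <- .reg_place_fixed(reg, hA0, gAe + trnaA_len, "end_block_A")
  reg <- .reg_place_fixed(reg, hB0, gBe + trnaB_len, "end_block_B")

  # PAS and guard zone
  pas_abs <- gA0 + spec$pas_offset
  guard_lo <- pas_abs - 710L
  guard_hi <- pas_abs + 716L + if (spec$marsupial_pas) 500L else 0L
  planted_pas <- integer()
  if (spec$plant_pas) {
    put(pas_abs, "AATAAA")
    feat("polyA_signal", "PAS_main", "geneA", pas_abs, pas_abs + 6L)
    planted_pas <- pas_abs
    if (spec$marsupial_pas) {
      put(pas_abs + 500L, "AATAAA")
      feat("polyA_signal", "PAS_second", "geneA", pas_abs + 500L,
           pas_abs + 506L)
      planted_pas <- c(planted_pas, pas_abs + 500L)
    }
  }
  reg <- .reg_place_fixed(reg, guard_lo, guard_hi, "PAS_guard")

  afrac <- function(f) gA0 + as.integer(round(f * LA))

  # TEs split evenly across the requested fractional bins
  lib <- spec$te_library
  if (is.null(lib)) lib <- default_te_library()
  if (spec$n_te > 0L) {
    per_bin <- rep(spec$n_te %/% length(spec$te_bins), length(spec$te_bins))
    extra <- spec$n_te - sum(per_bin)
    if (extra > 0L) per_bin[seq_len(extra)] <- per_bin[seq_len(extra)] + 1L
    fam_idx <- rep(seq_along(lib), length.out = spec$n_te)
    k <- 0L
    for (b in seq_along(spec$te_bins)) {
      for (t in seq_len(per_bin[b])) {
        k <- k + 1L
        te <- lib[[fam_idx[k]]]
        nm <- sprintf("%s.%d", te$id, k)
        pl <- .reg_place_random(reg, seq_len_bp(te), afrac(spec$te_bins[[b]][1]),
                                afrac(spec$te_bins[[b]][2]), nm, margin = 20L)
        reg <- pl$reg
        put(pl$start, te$residues)
        feat("repeat_region", nm, "geneA", pl$start, pl$start + seq_len_bp(te))
      }
    }
  }

  # inverted-repeat pairs
  if (spec$n_inverted_repeat_pairs > 0L) {
    for (p in seq_len(spec$n_inverted_repeat_pairs)) {
      arm <- .scrub_all_pas(rand_dna(spec$ir_arm_length, spec$background))
      win <- spec$ir_arm1_windows[[p]]
      lo <- afrac(win[1]); hi <- afrac(win[2])
      a1 <- NA_integer_
      for (tr in 1:500) {
        cand <- lo + sample.int(max(1L, hi - lo), 1L) - 1L
        c2 <- cand + spec$ir_arm_length + spec$ir_spacers[p]
        if (!length(.reg_collides(reg, cand, cand + spec$ir_arm_length, 20L)) &&
            !length(.reg_collides(reg, c2, c2 + spec$ir_arm_length, 20L))) {
          a1 <- cand; break
        }
      }
      if (is.na(a1))
        stop("cannot place feature IR", p, ": no free slot for both arms")
      a2 <- a1 + spec$ir_arm_length + spec$ir_spacers[p]
      reg <- .reg_place_fixed(reg, a1, a1 + spec$ir_arm_length,
                              sprintf("IR%d_arm1", p))
      reg <- .reg_place_fixed(reg, a2, a2 + spec$ir_arm_length,
                              sprintf("IR%d_arm2", p))
      put(a1, arm); put(a2, revcomp_chr(arm))
      feat("inverted_repeat", sprintf("IR%d_arm1", p), "geneA", a1,
           a1 + spec$ir_arm_length)
      feat("inverted_repeat", sprintf("IR%d_arm2", p), "geneA", a2,
           a2 + spec$ir_arm_length)
    }
  }

  # G-quadruplexes: canonical 4-tract pattern, split between the gene ends
  if (spec$n_g4 > 0L) {
    g4seq <- "GGGTTAGGGTTAGGGTTAGGG"
    wins <- rep(list(c(0.02, 0.12), c(0.86, 0.97)), length.out = spec$n_g4)
    for (g in seq_len(spec$n_g4)) {
      w <- wins[[g]]
      pl <- .reg_place_random(reg, nchar(g4seq), afrac(w[1]), afrac(w[2]),
                              sprintf("G4_%d", g), margin = 15L)
      reg <- pl$reg
      put(pl$start, g4seq)
      feat("G_quadruplex", sprintf("G4_%d", g), "geneA", pl$start,
           pl$start + nchar(g4seq))
    }
  }

  # GU tracts (3'-biased) and isolated core hexamer motifs (central)
  if (spec$gu_tract$count > 0L) {
    tract <- strrep("GT", spec$gu_tract$unit)
    for (g in seq_len(spec$gu_tract$count)) {
      w <- spec$gu_tract$window
      pl <- .reg_place_random(reg, nchar(tract), afrac(w[1]), afrac(w[2]),
                              sprintf("GU_%d", g), margin = 15L)
      reg <- pl$reg
      put(pl$start, tract)
      feat("GU_tract", sprintf("GU_%d", g), "geneA", pl$start,
           pl$start + nchar(tract))
    }
  }
  if (spec$core_motifs$count_each > 0L) {
    for (m in c("TCTGTG", "CTGTGT")) {
      for (g in seq_len(spec$core_motifs$count_each)) {
        w <- spec$core_motifs$window
        pl <- .reg_place_random(reg, 6L, afrac(w[1]), afrac(w[2]),
                                sprintf("core_%s_%d", m, g), margin = 8L)
        reg <- pl$reg
        put(pl$start, m)
      }
    }
  }

  zones <- rbind(
    data.frame(kind = "guard", start = guard_lo, end = guard_hi),
    data.frame(kind = "noindel",
               start = c(gA0, gB0, hA0, hB0, planted_pas, guard_lo),
               end = c(gA0 + 6L, gB0 + 6L, gAe + trnaA_len, gBe + trnaB_len,
                       planted_pas + 6L, guard_hi)),
    data.frame(kind = "nosub",
               start = c(gA0, gB0, hA0, hB0, planted_pas),
               end = c(gA0 + 6L, gB0 + 6L, hA0 + nchar(.helix_motif_A),
                       hB0 + nchar(.helix_motif_B), planted_pas + 6L)))

  chars <- .scrub_pas(chars, zones, planted_pas)
  if (!spec$plant_pas) {
    # control mode: also make sure the guard zone really is motif-free
    stopifnot(!grepl("AATAAA",
                     paste(chars[(guard_lo + 1L):guard_hi], collapse = "")))
  }

  contig_id <- sprintf("synthetic_locus_seed%d", seed)
  features <- do.call(rbind, feats)
  res <- paste(chars, collapse = "")

  # anchors are extracted from the plus-strand frame before any flipping
  frag <- function(s, e) substr(res, s + 1L, e)
  mkanch <- function(g0, ge, helix_motif, block, trna_len, layout_hairpin,
                     layout_linker, ref) {
    promoter <- dna_sequence("promoter_fragment", frag(g0 - 150L, g0 + 100L))
    ef_lo <- ge - block - 50L
    endfrag <- dna_sequence("end_fragment", frag(ef_lo, ge + trna_len + 20L))
    hm_off <- 50L
    anchor_set(ref, promoter, endfrag, tata_offset_in_promoter = 150L,
               helix_end_offset_in_end_fragment = 50L + block,
               end_layout = list(
                 helix_motif = c(hm_off, hm_off + nchar(helix_motif)),
                 hairpin = c(hm_off + nchar(helix_motif),
                             hm_off + nchar(helix_motif) + layout_hairpin),
                 linker = c(50L + block - layout_linker, 50L + block),
                 trna_like = c(50L + block, 50L + block + trna_len)))
  }
  refB <- dna_sequence("geneB_reference", frag(gB0, gBe))
  anchors <- list(
    geneA = mkanch(gA0, gAe, .helix_motif_A, blockA, trnaA_len, 29L, 30L, refB),
    geneB = mkanch(gB0, gBe, .helix_motif_B, blockB, trnaB_len, 31L, 24L, refB))

  truth <- structure(list(contig_id = contig_id, features = features,
                          zones = zones,
                          events = data.frame(leaf = character(),
                                              event = character(),
                                              name = character(),
                                              position = integer()),
                          params = list(seed = seed, spec = unclass(spec),
                                        rates = NULL)),
                     class = "synthetic_truth")

  if (spec$strand == "-") {
    res <- revcomp_chr(res)
    flip <- function(df) {
      s <- L - df$end; e <- L - df$start
      df$start <- s; df$end <- e
      if ("strand" %in% names(df))
        df$strand <- ifelse(df$strand == "+", "-", "+")
      df
    }
    truth$features <- flip(truth$features)
    truth$zones <- flip(truth$zones)
  }

  structure(list(contig = dna_sequence(contig_id, res),
                 truth = truth, anchors = anchors),
            class = "synthetic_locus")
}

#' @export
print.synthetic_locus <- function(x, ...) {
  cat(sprintf("<synthetic_locus> %s (%d bp), %d planted features\n",
              x$contig$id, seq_len_bp(x$contig), nrow(x$truth$features)))
  invisible(x)
}

#' Gene model from planted truth
#'
#' @param truth A `synthetic_truth`.
#' @param gene `"geneA"` or `"geneB"`.
#' @return A [gene_model()] built from the planted coordinates.
#' @export
truth_gene_model <- function(truth, gene = c("geneA", "geneB")) {
  gene <- match.arg(gene)
  f <- truth$features
  grab <- function(type) f[f$type == type & f$gene == gene, , drop = FALSE]
  g <- grab("gene"); tata <- grab("TATA_box"); hx <- grab("triple_helix")
  tr <- grab("tRNA_like")
  strand <- g$strand[1]
  iv <- function(row) genomic_interval(truth$contig_id, row$start[1], row$end[1],
                                       strand)
  gene_model(truth$contig_id, strand, iv(g), tata_iv = iv(tata),
             helix_iv = iv(hx), trna_like_iv = iv(tr))
}

#' Planted PAS offsets in transcript coordinates
#'
#' @param truth A `synthetic_truth`.
#' @return Integer vector of motif-start offsets from the gene A 5' end
#'   (transcript orientation), main PAS first.
#' @export
truth_pas_offsets <- function(truth) {
  f <- truth$features
  g <- f[f$type == "gene" & f$gene == "geneA", ]
  p <- f[f$type == "polyA_signal", , drop = FALSE]
  if (!nrow(p)) return(integer())
  p <- p[order(match(p$name, c("PAS_main", "PAS_second"))), , drop = FALSE]
  if (g$strand[1] == "+") p$start - g$start else g$end - p$end
}

# --- evolution along a tree -------------------------------------------------

.default_rates <- function() {
  list(subst_rate_scale = 1, indel_rate = 0.005, indel_len_geom_p = 1 / 3,
       te_insert_rate = 0, te_excise_rate = 0)
}

# Lift 0-based half-open coordinates through one edit.
.lift <- function(df, pos, len, type) {
  if (type == "ins") {
    df$start <- ifelse(df$start >= pos, df$start + len, df$start)
    df$end <- ifelse(df$end > pos, df$end + len, df$end)
  } else {
    mapc <- function(x) x - pmin(pmax(0L, x - pos), len)
    df$start <- mapc(df$start); df$end <- mapc(df$end)
  }
  df
}

.apply_edit <- function(state, pos, len, type, insert_str = NULL) {
  res <- state$res
  if (type == "ins") {
    state$res <- paste0(substr(res, 1L, pos), insert_str,
                        substr(res, pos + 1L, nchar(res)))
  } else {
    state$res <- paste0(substr(res, 1L, pos), substr(res, pos + len + 1L,
                                                     nchar(res)))
  }
  state$truth$features <- .lift(state$truth$features, pos, len, type)
  state$truth$zones <- .lift(state$truth$zones, pos, len, type)
  # drop features erased entirely
  keep <- state$truth$features$end > state$truth$features$start
  state$truth$features <- state$truth$features[keep, , drop = FALSE]
  state
}

.in_zone <- function(zones, kind, lo, hi) {
  z <- zones[zones$kind == kind, , drop = FALSE]
  any(z$start < hi & z$end > lo)
}

# Evolve one branch: JC69 substitutions (conserved gene at a reduced
# rate), geometric-length indels outside protected zones, and optional TE
# turnover. Guard zones are re-scrubbed so no mutation creates a stray
# PAS motif near the planted one.
.evolve_branch <- function(state, d, rates, conserved_factor, lib,
                           excise_names = character()) {
  truth <- state$truth
  chars <- strsplit(state$res, "")[[1]]
  L <- length(chars)

  # per-site substitution probability (JC69), region-scaled
  w <- rep(1, L)
  gB <- truth$features[truth$features$type == "gene" &
                       truth$features$gene == "geneB", ]
  if (nrow(gB)) {
    lo <- gB$start[1]
    hi <- min(L, gB$end[1] + 80L)  # include the end block + tRNA
    w[(lo + 1L):hi] <- conserved_factor
  }
  p <- 0.75 * (1 - exp(-4 / 3 * d * rates$subst_rate_scale * w))
  hit <- runif(L) < p
  ns <- truth$zones[truth$zones$kind == "nosub", , drop = FALSE]
  for (zi in seq_len(nrow(ns))) {
    if (ns$end[zi] > ns$start[zi])
      hit[(ns$start[zi] + 1L):ns$end[zi]] <- FALSE
  }
  idx <- which(hit)
  if (length(idx)) {
    bases <- c("A", "C", "G", "T")
    cur <- match(chars[idx], bases)
    shift <- sample.int(3L, length(idx), replace = TRUE)
    new <- (cur - 1L + shift) %% 4L + 1L
    ok <- !is.na(cur)
    chars[idx[ok]] <- bases[new[ok]]
  }
  planted <- truth$features$start[truth$features$type == "polyA_signal"]
  chars <- .scrub_pas(chars, truth$zones, planted)
  state$res <- paste(chars, collapse = "")
  state$truth <- truth

  # indels
  n_ind <- stats::rpois(1L, rates$indel_rate * d * rates$subst_rate_scale * L)
  for (i in seq_len(n_ind)) {
    for (try in 1:20) {
      len <- min(50L, stats::rgeom(1L, rates$indel_len_geom_p) + 1L)
      pos <- sample.int(nchar(state$res) - len - 1L, 1L)
      is_del <- runif(1) < 0.5
      span_hi <- if (is_del) pos + len else pos + 1L
      if (.in_zone(state$truth$zones, "noindel", pos, span_hi)) next
      if (is_del) state <- .apply_edit(state, pos, len, "del")
      else state <- .apply_edit(state, pos, len, "ins",
                                rand_dna(len, c(A = .28, C = .19, G = .22,
                                                T = .31)))
      break
    }
  }

  # TE turnover
  tes <- which(state$truth$features$type == "repeat_region")
  if (length(excise_names)) {
    for (nm in excise_names) {
      row <- which(state$truth$features$type == "repeat_region" &
                   state$truth$features$name == nm)
      if (!length(row)) {
        message("excision of ", nm, " skipped: TE not present")
        state$truth$events[nrow(state$truth$events) + 1L, ] <-
          list(state$leaf %||% NA_character_, "excision_skipped", nm, NA_integer_)
        next
      }
      fr <- state$truth$features[row[1L], ]
      state$truth$events[nrow(state$truth$events) + 1L, ] <-
        list(state$leaf %||% NA_character_, "excision", nm, fr$start)
      state <- .apply_edit(state, fr$start, fr$end - fr$start, "del")
      # the lifted feature now has zero length and was dropped by .apply_edit
    }
  } else if (rates$te_excise_rate > 0 && length(tes) && runif(1) < rates$te_excise_rate) {
    row <- sample(tes, 1L)
    fr <- state$truth$features[row, ]
    state$truth$events[nrow(state$truth$events) + 1L, ] <-
      list(state$leaf %||% NA_character_, "excision", fr$name, fr$start)
    state <- .apply_edit(state, fr$start, fr$end - fr$start, "del")
  }
  if (rates$te_insert_rate > 0) {
    n_new <- stats::rpois(1L, rates$te_insert_rate)
    gA <- state$truth$features[state$truth$features$type == "gene" &
                               state$truth$features$gene == "geneA", ]
    spec <- state$truth$params$spec
    for (i in seq_len(n_new)) {
      te <- lib[[sample.int(length(lib), 1L)]]
      b <- spec$te_bins[[sample.int(length(spec$te_bins), 1L)]]
      lo <- gA$start[1] + as.integer(b[1] * (gA$end[1] - gA$start[1]))
      hi <- gA$start[1] + as.integer(b[2] * (gA$end[1] - gA$start[1]))
      occupied <- state$truth$features[state$truth$features$type %in%
                                       c("repeat_region", "inverted_repeat"), ]
      for (try in 1:50) {
        pos <- lo + sample.int(max(1L, hi - lo), 1L) - 1L
        if (!any(occupied$start < pos + 20L & occupied$end > pos - 20L)) break
        pos <- NA_integer_
      }
      if (is.na(pos)) next
      nm <- sprintf("%s.new%d", te$id, nrow(state$truth$events) + i)
      state <- .apply_edit(state, pos, seq_len_bp(te), "ins", te$residues)
      state$truth$features[nrow(state$truth$features) + 1L, ] <-
        list("repeat_region", nm, "geneA", pos, pos + seq_len_bp(te), "+")
      state$truth$events[nrow(state$truth$events) + 1L, ] <-
        list(state$leaf %||% NA_character_, "insertion", nm, pos)
    }
  }
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evolve a root locus along a phylogeny
#'
#' Applies Jukes-Cantor point substitutions (probability
#' `3/4 (1 - exp(-4 d s / 3))` per site for branch length `d` and scale
#' `s`), geometric-length indels, and optional TE insertion/excision along
#' every branch of the tree. The conserved gene evolves at
#' `conserved_factor` times the divergent gene's rate. Truth coordinates
#' are lifted through every edit, so each leaf's truth stays internally
#' consistent. Per-branch RNG streams are derived by hashing the branch's
#' child node name with the seed, making leaves reproducible under tree
#' edits.
#'
#' @param root A `synthetic_locus` from [build_root_locus()], or a
#'   [dna_sequence()] (then `truth` must be supplied).
#' @param tree `ape::phylo` or newick string; branch lengths in expected
#'   substitutions per site.
#' @param rates List overriding any of `subst_rate_scale` (1),
#'   `indel_rate` (0.005 per site per unit distance),
#'   `indel_len_geom_p` (1/3, mean length 3), `te_insert_rate` (0,
#'   expected insertions per branch), `te_excise_rate` (0, per-branch
#'   probability).
#' @param seed Integer seed.
#' @param truth `synthetic_truth` when `root` is a bare sequence.
#' @param conserved_factor Rate multiplier for the conserved gene
#'   (default 0.3).
#' @param te_library Library used for insertions.
#' @param planted_excisions Named list leaf -> character vector of TE
#'   names excised on that leaf's terminal branch (deterministic planting
#'   of excision events).
#' @return Object of class `synthetic_cohort`: `leaves` (named list of
#'   `list(seq, truth)`), plus the tree, rates and seed.
#' @export
evolve_along_tree <- function(root, tree, rates = list(), seed, truth = NULL,
                              conserved_factor = 0.3, te_library = NULL,
                              planted_excisions = NULL) {
  if (inherits(root, "synthetic_locus")) {
    truth <- root$truth
    root_seq <- root$contig
  } else {
    stopifnot(inherits(root, "dna_sequence"), inherits(truth, "synthetic_truth"))
    root_seq <- root
  }
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), all(tree$edge.length >= 0))
  r <- utils::modifyList(.default_rates(), rates)
  lib <- te_library
  if (is.null(lib)) lib <- default_te_library()
  truth$params$rates <- r

  n_tip <- length(tree$tip.label)
  node_name <- function(v) {
    if (v <= n_tip) tree$tip.label[v] else paste0("node", v)
  }
  states <- list()
  root_node <- n_tip + 1L
  states[[as.character(root_node)]] <- list(res = root_seq$residues,
                                            truth = truth, leaf = NULL)
  edges <- tree$edge[order(tree$edge[, 1L]), , drop = FALSE]
  # preorder: parents always appear before children in ape's cladewise edges
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
  leaves <- list()
  for (e in seq_len(nrow(ord))) {
    parent <- ord[e, 1L]; child <- ord[e, 2L]
    ps <- states[[as.character(parent)]]
    nm <- node_name(child)
    ps$leaf <- if (child <= n_tip) nm else NULL
    exc <- character()
    if (!is.null(planted_excisions) && child <= n_tip &&
        nm %in% names(planted_excisions))
      exc <- planted_excisions[[nm]]
    cs <- with_seed(hash_seed(seed, nm), {
      .evolve_branch(ps, lens[e], r, conserved_factor, lib, exc)
    })
    if (child <= n_tip) {
      leaf_truth <- cs$truth
      leaf_truth$params$leaf <- nm
      leaves[[nm]] <- list(seq = dna_sequence(nm, cs$res,
                                              meta = c(taxon = nm)),
                           truth = leaf_truth)
    } else {
      states[[as.character(child)]] <- cs
    }
  }
  structure(list(leaves = leaves[tree$tip.label], tree = tree, rates = r,
                 seed = seed), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d leaves, seed %d\n", length(x$leaves),
              x$seed))
  invisible(x)
}

# --- truth serialization ----------------------------------------------------

#' Write planted truth to GFF3 + JSON sidecar
#'
#' Features and protection zones go to GFF3 (1-based inclusive, as the
#' format requires); parameters, rates, seed and the event log go to a
#' JSON sidecar. [read_truth()] reconstructs the object losslessly.
#'
#' @param truth A `synthetic_truth`.
#' @param gff_path,json_path Output paths.
#' @export
write_truth <- function(truth, gff_path, json_path) {
  f <- truth$features
  gr_f <- GenomicRanges::GRanges(
    seqnames = truth$contig_id,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = f$strand, type = f$type, Name = f$name, gene = f$gene)
  z <- truth$zones
  gr_z <- GenomicRanges::GRanges(
    seqnames = truth$contig_id,
    ranges = IRanges::IRanges(start = z$start + 1L, end = z$end),
    strand = "*", type = paste0("zone_", z$kind), Name = paste0("zone_", z$kind),
    gene = NA_character_)
  rtracklayer::export(c(gr_f, gr_z), gff_path, format = "gff3")
  jsonlite::write_json(list(contig_id = truth$contig_id,
                            params = truth$params, events = truth$events),
                       json_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(gff_path)
}

#' @rdname write_truth
#' @return `read_truth()` returns the reconstructed `synthetic_truth`.
#' @export
read_truth <- function(gff_path, json_path) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  type <- as.character(gr$type)
  is_zone <- startsWith(type, "zone_")
  f <- data.frame(type = type[!is_zone], name = gr$Name[!is_zone],
                  gene = gr$gene[!is_zone],
                  start = BiocGenerics::start(gr)[!is_zone] - 1L,
                  end = BiocGenerics::end(gr)[!is_zone],
                  strand = as.character(BiocGenerics::strand(gr))[!is_zone])
  z <- data.frame(kind = sub("^zone_", "", type[is_zone]),
                  start = BiocGenerics::start(gr)[is_zone] - 1L,
                  end = BiocGenerics::end(gr)[is_zone])
  ev <- meta$events
  if (is.null(ev) || !length(ev))
    ev <- data.frame(leaf = character(), event = character(),
                     name = character(), position = integer())
  ev <- as.data.frame(ev)
  structure(list(contig_id = meta$contig_id, features = f, zones = z,
                 events = ev, params = meta$params),
            class = "synthetic_truth")
}
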