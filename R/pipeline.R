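#' Pipeline configuration
#'
#' Builds the full configuration for [run_pipeline()] from defaults plus
#' overrides. Unknown keys are rejected (recursively), so typos fail at
#' startup rather than silently using defaults. The configuration
#' round-trips losslessly through YAML via [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param ... Named overrides of the defaults (nested lists merged
#'   key-by-key).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    out_dir = "lncortho_run",
    stages = list(simulate = TRUE, locate = TRUE, pas = TRUE, te = TRUE,
                  selfcomp = TRUE, motifs = TRUE, ani = TRUE,
                  archetypes = TRUE, ends = TRUE, promoter = TRUE),
    inputs = list(contigs_fasta = NULL, tree_newick = NULL,
                  te_library_fasta = NULL, pwm_file = NULL,
                  anchors_dir = NULL),
    simulate = list(tree = NULL, rates = list(subst_rate_scale = 1,
                                              indel_rate = 0.005,
                                              indel_len_geom_p = 1 / 3,
                                              te_insert_rate = 0,
                                              te_excise_rate = 0),
                    conserved_factor = 0.3, marsupial_pas = FALSE),
    align = list(word_size = 11L, min_pident = 60, min_len = 30L),
    locate = list(min_gene_len = 2000L, max_gene_len = 60000L,
                  max_chain_gap = 5000L),
    pas = list(window = 110L, alt_window = 600L, rescue = FALSE),
    te = list(min_len = 80L, min_pident = 80, min_coverage = 0.80,
              n_bins = 20L),
    selfcomp = list(min_len = 100L, min_pident = 80,
                    proximal_threshold = 2000L),
    motifs = list(query_motifs = c("GUGUGU", "UGUGUG", "UCUGUG", "CUGUGU"),
                  hexamer_bins = 10L, usage_bins = 20L),
    ani = list(min_hit_len = 100L, merge_overlaps = FALSE),
    archetypes = list(k = 3L),
    promoter = list(pthresh = 1e-4, window = 1000L, shared_fraction = 0.65))
  merge_cfg <- function(base, over, path = "") {
    for (nm in names(over)) {
      if (!nm %in% names(base))
        stop("unknown configuration key: ", paste0(path, nm))
      if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
          !is.null(names(base[[nm]])))
        base[[nm]] <- merge_cfg(base[[nm]], over[[nm]], paste0(path, nm, "."))
      else base[nm] <- over[nm]
    }
    base
  }
  cfg <- merge_cfg(defaults, list(...))
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

.write_models_gff <- function(models, path) {
  lines <- c("##gff-version 3")
  for (nm in names(models)) {
    m <- models[[nm]]
    if (is_no_call(m)) next
    row <- function(type, iv, name) {
      if (is.null(iv)) return(NULL)
      sprintf("%s\tlncortho\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s", m$contig_id,
              type, iv$start + 1L, iv$end, m$strand, paste0(nm, "_", type), name)
    }
    lines <- c(lines, row("gene", m$gene_iv, nm),
               row("TATA_box", m$tata_iv, paste0(nm, "_tata")),
               row("triple_helix", m$helix_iv, paste0(nm, "_helix")),
               row("tRNA_like", m$trna_like_iv, paste0(nm, "_trna")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Run the comparative-feature pipeline
#'
#' Executes the stages in dependency order (simulate, locate, pas, te,
#' selfcomp, motifs, ani/archetypes, ends, promoter), writing per-stage
#' TSV/GFF outputs plus a machine-readable JSON run summary into
#' `config$out_dir`. A stage failure is recorded in the summary, its
#' dependents are skipped, and the returned summary carries a non-zero
#' `status`. Identical configuration and seed reproduce identical outputs
#' (timestamps are confined to the log file).
#'
#' @param config A [pipeline_config()].
#' @return The run summary (list), invisibly; also written as
#'   `summary.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "pipeline.log")
  cat(sprintf("[%s] pipeline start\n", format(Sys.time())), file = logf)
  summary <- list(package_version = as.character(utils::packageVersion("lncortho")),
                  seed = config$seed, stages = list(), status = 0L)
  note <- function(stage, msg) {
    cat(sprintf("[%s] %s: %s\n", format(Sys.time()), stage, msg),
        file = logf, append = TRUE)
  }
  failed <- character()
  run_stage <- function(stage, deps, fun) {
    if (!isTRUE(config$stages[[stage]])) {
      summary$stages[[stage]] <<- list(status = "disabled")
      return(invisible())
    }
    if (any(deps %in% failed)) {
      summary$stages[[stage]] <<- list(status = "skipped",
                                       reason = paste("dependency failed:",
                                                      paste(intersect(deps, failed),
                                                            collapse = ",")))
      failed <<- c(failed, stage)
      return(invisible())
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) e)
    el <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      note(stage, paste("FAILED:", conditionMessage(res)))
      summary$stages[[stage]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      summary$status <<- 1L
      failed <<- c(failed, stage)
    } else {
      note(stage, sprintf("ok (%.2fs)", el))
      summary$stages[[stage]] <<- res
    }
    invisible()
  }
  env <- new.env()

  run_stage("simulate", character(), function() {
    tree <- config$simulate$tree %||% default_tree()
    spec <- synthetic_locus_spec(marsupial_pas = config$simulate$marsupial_pas)
    locus <- build_root_locus(spec, config$seed)
    cohort <- evolve_along_tree(locus, tree, rates = config$simulate$rates,
                                seed = config$seed,
                                conserved_factor = config$simulate$conserved_factor)
    env$anchors <- locus$anchors
    env$root <- locus
    env$cohort <- cohort
    env$contigs <- lapply(cohort$leaves, `[[`, "seq")
    env$tree <- tree
    for (nm in names(env$contigs))
      write_dna_fasta(env$contigs[[nm]],
                      file.path(config$out_dir, paste0(nm, ".fasta")))
    write_truth(locus$truth, file.path(config$out_dir, "root_truth.gff3"),
                file.path(config$out_dir, "root_truth.json"))
    list(status = "ok", n_leaves = length(env$contigs))
  })

  run_stage("locate", "simulate", function() {
    if (is.null(env$contigs)) {
      seqs <- read_dna_fasta(config$inputs$contigs_fasta)
      env$contigs <- seqs
    }
    ap <- config$align
    models_A <- list(); models_B <- list(); synteny <- list()
    for (nm in names(env$contigs)) {
      ct <- env$contigs[[nm]]
      anchor_iv <- locate_conserved_anchor(ct, env$anchors$geneA,
                                           word_size = ap$word_size,
                                           min_pident = ap$min_pident,
                                           min_len = ap$min_len)
      mA <- locate_gene(ct, NULL, env$anchors$geneA,
                        min_len = config$locate$min_gene_len,
                        max_len = config$locate$max_gene_len)
      mB <- locate_gene(ct, NULL, env$anchors$geneB,
                        min_len = config$locate$min_gene_len,
                        max_len = config$locate$max_gene_len)
      models_A[[nm]] <- mA; models_B[[nm]] <- mB
      if (!is_no_call(mA) && !is_no_call(mB))
        synteny[[nm]] <- check_synteny(mA, mB)
    }
    env$models_A <- models_A; env$models_B <- models_B
    env$genes_A <- list(); env$genes_B <- list()
    for (nm in names(models_A)) {
      if (!is_no_call(models_A[[nm]]))
        env$genes_A[[nm]] <- extract_gene_sequence(env$contigs[[nm]],
                                                   models_A[[nm]],
                                                   id = nm)
      if (!is_no_call(models_B[[nm]]))
        env$genes_B[[nm]] <- extract_gene_sequence(env$contigs[[nm]],
                                                   models_B[[nm]],
                                                   id = paste0(nm, "_B"))
    }
    .write_models_gff(models_A, file.path(config$out_dir, "geneA_models.gff3"))
    .write_models_gff(models_B, file.path(config$out_dir, "geneB_models.gff3"))
    syn <- data.frame(
      leaf = names(synteny),
      same_contig = vapply(synteny, `[[`, TRUE, "same_contig"),
      same_strand = vapply(synteny, `[[`, TRUE, "same_strand"),
      distance = vapply(synteny, `[[`, 0L, "intergenic_distance"))
    utils::write.table(syn, file.path(config$out_dir, "synteny.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(status = "ok", n_located = length(env$genes_A),
         n_nocall = sum(vapply(models_A, is_no_call, TRUE)))
  })

  run_stage("pas", "locate", function() {
    ref_nm <- names(env$genes_A)[1L]
    ref <- env$genes_A[[ref_nm]]
    ref_pas <- if (!is.null(env$root))
      truth_pas_offsets(env$root$truth)[1L] else NA_integer_
    rows <- list()
    env$pas <- list()
    for (nm in names(env$genes_A)) {
      g <- env$genes_A[[nm]]
      proj <- if (nm == ref_nm) ref_pas
              else project_reference_pas(g, ref, ref_pas)
      if (is_no_call(proj)) {
        if (isTRUE(config$pas$rescue)) {
          call <- call_rescue_pas(g)
        } else {
          rows[[nm]] <- data.frame(gene_id = nm, projected = NA, pas_pos = NA,
                                   kind = NA, offset = NA, status = "no_call",
                                   reason = "projection_failure")
          next
        }
      } else call <- call_main_pas(g, proj, window = config$pas$window)
      if (call$status == "called") {
        env$pas[[nm]] <- call
        alts <- find_alternative_pas(g, call, window = config$pas$alt_window)
        rows[[nm]] <- rbind(
          data.frame(gene_id = nm, projected = if (is_no_call(proj)) NA else proj,
                     pas_pos = call$position, kind = "main",
                     offset = call$offset_from_projection, status = "called",
                     reason = NA),
          if (nrow(alts)) data.frame(gene_id = nm, projected = NA,
                                     pas_pos = alts$position,
                                     kind = alts$kind, offset = alts$offset,
                                     status = "called", reason = NA))
      } else {
        rows[[nm]] <- data.frame(gene_id = nm,
                                 projected = if (is_no_call(proj)) NA else proj,
                                 pas_pos = NA, kind = "main", offset = NA,
                                 status = "no_call", reason = call$reason)
      }
    }
    tab <- do.call(rbind, rows)
    utils::write.table(tab, file.path(config$out_dir, "pas.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(status = "ok", n_called = length(env$pas))
  })

  run_stage("te", "locate", function() {
    lib <- if (!is.null(config$inputs$te_library_fasta))
      read_dna_fasta(config$inputs$te_library_fasta) else default_te_library()
    all_ann <- list(); prof <- NULL
    for (nm in names(env$genes_A)) {
      ann <- annotate_tes(env$genes_A[[nm]], lib,
                          min_len = config$te$min_len,
                          min_pident = config$te$min_pident,
                          min_coverage = config$te$min_coverage)
      all_ann[[nm]] <- ann
      p <- te_positional_profile(ann, seq_len_bp(env$genes_A[[nm]]),
                                 n_bins = config$te$n_bins)
      prof <- if (is.null(prof)) p$counts else prof + p$counts
    }
    env$te_annotations <- all_ann
    tab <- do.call(rbind, lapply(names(all_ann), function(nm) {
      a <- all_ann[[nm]]
      if (!nrow(a)) return(NULL)
      cbind(gene_id = nm, as.data.frame(a))
    }))
    if (is.null(tab)) tab <- data.frame()
    utils::write.table(tab, file.path(config$out_dir, "te_annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(bin = seq_along(prof) - 1L, count = prof),
                       file.path(config$out_dir, "te_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(status = "ok", n_te = sum(vapply(all_ann, nrow, 0L)))
  })

  run_stage("selfcomp", "locate", function() {
    tabs <- lapply(names(env$genes_A), function(nm) {
      find_self_complementary(env$genes_A[[nm]],
                              min_len = config$selfcomp$min_len,
                              min_pident = config$selfcomp$min_pident,
                              proximal_threshold = config$selfcomp$proximal_threshold)
    })
    tab <- do.call(rbind, tabs)
    write_selfcomp_table(tab, file.path(config$out_dir, "selfcomp.tsv"))
    list(status = "ok", n_regions = nrow(tab))
  })

  run_stage("motifs", "locate", function() {
    profiles <- lapply(env$genes_A, hexamer_profile,
                       query_motifs = config$motifs$query_motifs,
                       n_bins = config$motifs$hexamer_bins)
    shared <- shared_motifs(profiles)
    utils::write.table(head(shared, 50L),
                       file.path(config$out_dir, "shared_motifs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    g4 <- do.call(rbind, lapply(names(env$genes_A), function(nm) {
      h <- find_g4(env$genes_A[[nm]])
      if (nrow(h)) cbind(gene_id = nm, h) else NULL
    }))
    if (!is.null(g4))
      utils::write.table(g4, file.path(config$out_dir, "g4.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    usage <- t(vapply(env$genes_A,
                      function(g) nucleotide_usage(g)$overall, numeric(4L)))
    utils::write.table(data.frame(gene_id = rownames(usage), usage),
                       file.path(config$out_dir, "nucleotide_usage.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    env$shared <- shared
    list(status = "ok", n_shared_motifs = nrow(shared),
         n_g4 = if (is.null(g4)) 0L else nrow(g4))
  })

  run_stage("ani", "locate", function() {
    m <- ani_matrix(unname(env$genes_A), min_hit_len = config$ani$min_hit_len,
                    merge_overlaps = config$ani$merge_overlaps)
    env$ani <- m
    write_ani_matrix(m, file.path(config$out_dir, "ani_geneA.tsv"))
    if (length(env$genes_B) >= 2L) {
      mb <- ani_matrix(unname(env$genes_B), min_hit_len = config$ani$min_hit_len)
      write_ani_matrix(mb, file.path(config$out_dir, "ani_geneB.tsv"))
      env$ani_B <- mb
    }
    list(status = "ok", mean_offdiag = mean(m[upper.tri(m)]))
  })

  run_stage("archetypes", "ani", function() {
    k <- min(config$archetypes$k, nrow(env$ani))
    arch <- select_archetypes(env$ani, k)
    writeLines(arch, file.path(config$out_dir, "archetypes.txt"))
    list(status = "ok", archetypes = arch)
  })

  run_stage("ends", "locate", function() {
    layoutA <- end_structure_layout(
      env$anchors$geneA$end_fragment,
      helix_motif = env$anchors$geneA$end_layout$helix_motif,
      hairpin = env$anchors$geneA$end_layout$hairpin,
      linker = env$anchors$geneA$end_layout$linker,
      trna_like = env$anchors$geneA$end_layout$trna_like)
    rows <- list()
    for (nm in names(env$genes_A)) {
      # include the downstream tRNA-like element in the measured region
      ct <- env$contigs[[nm]]
      mdl <- env$models_A[[nm]]
      lo <- mdl$gene_iv$start
      hi <- min(seq_len_bp(ct), mdl$gene_iv$end + 80L)
      gplus <- subseq_dna(ct, lo, hi, id = nm)
      if (mdl$strand == "-") {
        gplus <- subseq_dna(ct, max(0L, mdl$gene_iv$start - 80L),
                            mdl$gene_iv$end, id = nm)
        gplus <- reverse_complement(gplus)
      }
      es <- extract_end_structures(gplus, NULL, layoutA)
      rows[[nm]] <- data.frame(gene_id = nm,
                               t(vapply(es, function(e) e$length, 0L)))
    }
    tab <- do.call(rbind, rows)
    utils::write.table(tab, file.path(config$out_dir, "end_structures.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(status = "ok", n_measured = nrow(tab))
  })

  run_stage("promoter", "locate", function() {
    pwms <- if (!is.null(config$inputs$pwm_file))
      read_pwms(config$inputs$pwm_file) else NULL
    if (is.null(pwms)) {
      summaryv <- list(status = "ok", note = "no PWM file configured",
                       n_shared_tfs = 0L)
      return(summaryv)
    }
    hits <- list()
    for (nm in names(env$models_A)) {
      mdl <- env$models_A[[nm]]
      if (is_no_call(mdl)) next
      ct <- env$contigs[[nm]]
      w <- config$promoter$window
      prom <- if (mdl$strand == "+") {
        subseq_dna(ct, max(0L, mdl$gene_iv$start - w), mdl$gene_iv$start,
                   id = nm)
      } else {
        p <- subseq_dna(ct, mdl$gene_iv$end,
                        min(seq_len_bp(ct), mdl$gene_iv$end + w), id = nm)
        reverse_complement(p)
      }
      hh <- do.call(rbind, lapply(pwms, function(p)
        scan_pwm(prom, p, pthresh = config$promoter$pthresh)))
      hits[[nm]] <- hh
    }
    shared <- shared_tfs(hits, fraction = config$promoter$shared_fraction)
    utils::write.table(shared, file.path(config$out_dir, "shared_tfs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(status = "ok", n_shared_tfs = nrow(shared))
  })

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  note("pipeline", sprintf("done, status %d", summary$status))
  invisible(summary)
}
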