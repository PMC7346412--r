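# End-to-end orchestration: structure -> annotation lift -> degradation scan
# -> paralog screen -> comparative statistics -> selection tests, with a
# checksummed, reproducible report bundle.

.md5_string <- function(x) {
  f <- tempfile()
  writeLines(x, f)
  unname(tools::md5sum(f))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full plastome degradation pipeline
#'
#' Orchestrates the package's stages over a focal genome and a panel of
#' related annotated genomes: quadripartite structure and genome summaries;
#' homology annotation lift (when the focal record carries no annotations);
#' the criteria-based degradation scan with hydrophobicity profiles;
#' coverage-based paralog classification and lesion screening (when contigs
#' are supplied); genome-size and read-fraction comparative tests; and
#' branch-specific dN/dS likelihood-ratio tests with Hochberg correction
#' for the flagged genes (when a tree is supplied). All outputs are written
#' to `out_dir` together with a machine-readable manifest recording the
#' package version, seed, configuration hash and input/output checksums.
#' Deterministic given identical inputs and seed.
#'
#' @param focal Focal [plastome_record()] (annotated or not).
#' @param panel Named list of annotated panel [plastome_record()]s.
#' @param out_dir Output directory (created if needed).
#' @param config A [scan_config()].
#' @param tree Optional `phylo` containing the focal id and panel ids as
#'   tips; enables the selection stage.
#' @param gene_alignments Optional named list (gene -> named aligned DNA
#'   vector) for the selection stage; when absent, per-gene matrices are
#'   built from the panel CDS plus the focal region via
#'   [prep_gene_matrix()].
#' @param contigs Optional list of [paralog_contig()]s.
#' @param organellar_coverage Plastid fold coverage for
#'   [classify_origin()] (required with `contigs`).
#' @param read_counts Optional list(focal = list(mapped_to_plastid,
#'   total_reads), panel = vector of panel percentages) for the
#'   read-fraction test.
#' @param selection_genes Genes to test for selection shifts; default: the
#'   scan's pseudogene verdicts.
#' @param min_remaining Minimum bases for a row to enter a gene matrix.
#' @param n_starts Optimizer starts per model fit.
#' @param seed Master seed, recorded in every report.
#' @return Invisible list with the in-memory results (`summaries`,
#'   `report`, `lrt`, `paralogs`, `stats`, `manifest`).
#' @export
run_pipeline <- function(focal, panel, out_dir, config = scan_config(),
                         tree = NULL, gene_alignments = NULL,
                         contigs = NULL, organellar_coverage = NULL,
                         read_counts = NULL, selection_genes = NULL,
                         min_remaining = 200, n_starts = 1, seed = 1) {
  stopifnot(inherits(focal, "plastome_record"), length(panel) >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(path) { written <<- c(written, path); path }
  stage <- "setup"
  result <- tryCatch({
    # ---- structure ------------------------------------------------------
    stage <- "structure"
    all_recs <- c(list(focal), unname(panel))
    summaries <- do.call(rbind, lapply(all_recs, function(r)
      genome_summary(r)))
    emit(.write_tsv(summaries, file.path(out_dir, "genome_summaries.tsv")))

    # ---- annotation lift ------------------------------------------------
    stage <- "annotate"
    if (!length(focal$features)) {
      focal <- annotate_by_homology(focal, panel[[1]], config)
      emit(.write_tsv(attr(focal, "lift"),
                      file.path(out_dir, "annotation_lift.tsv")))
    }

    # ---- degradation scan -----------------------------------------------
    stage <- "scan"
    report <- scan_genome(focal, panel, config)
    write_report(report, json_path = file.path(out_dir, "degradation.json"),
                 tsv_path = file.path(out_dir, "degradation.tsv"))
    emit(file.path(out_dir, "degradation.json"))
    emit(file.path(out_dir, "degradation.tsv"))
    if (!is.null(report$hydrophobicity))
      emit(.write_tsv(report$hydrophobicity,
                      file.path(out_dir, "hydrophobicity.tsv")))
    verdicts <- vapply(report$genes, `[[`, "", "verdict")
    flagged <- names(verdicts)[verdicts == "pseudogene"]

    # ---- paralogs -------------------------------------------------------
    stage <- "paralogs"
    paralogs <- NULL
    if (!is.null(contigs)) {
      if (is.null(organellar_coverage))
        stop("organellar_coverage required when contigs are given")
      rows <- list()
      for (cg in contigs) {
        cg <- classify_origin(cg, organellar_coverage)
        gene <- cg$best_hit_gene
        ev <- NULL
        if (!is.na(gene) && gene %in% names(report$genes)) {
          carriers <- which(vapply(panel, function(p)
            gene %in% .feature_names(p, "protein_coding"), TRUE))
          ref_cds <- extract_cds(panel[[carriers[1]]], gene)
          ev <- screen_paralog(cg, ref_cds,
                               plastid_events = report$genes[[gene]]$events,
                               config = config)
        }
        rows[[cg$id]] <- data.frame(
          contig = cg$id, gene = if (is.na(gene)) "" else gene,
          coverage = cg$kmer_coverage, classification = cg$classification,
          n_events = length(ev),
          event_kinds = paste(vapply(ev, `[[`, "", "kind"), collapse = ";"),
          stringsAsFactors = FALSE)
      }
      paralogs <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
      emit(.write_tsv(paralogs, file.path(out_dir, "paralogs.tsv")))
    }

    # ---- comparative statistics -----------------------------------------
    stage <- "stats"
    stats_out <- list(seed = seed)
    panel_lengths <- vapply(panel, `[[`, 1, "length")
    if (length(panel_lengths) >= 3 && stats::sd(panel_lengths) > 0) {
      gs <- one_tailed_t(panel_lengths, focal$length, "panel_mean_greater")
      stats_out$genome_size_test <- gs
    }
    if (!is.null(read_counts)) {
      focal_pct <- plastid_read_fraction(read_counts$focal)
      rf <- one_tailed_t(read_counts$panel, focal_pct, "panel_mean_greater")
      stats_out$read_fraction <- list(focal_percent = focal_pct,
                                      panel_mean = rf$panel_mean,
                                      p = rf$p)
    }
    jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
    emit(file.path(out_dir, "stats.json"))

    # ---- selection ------------------------------------------------------
    stage <- "selection"
    lrt_tab <- NULL
    if (!is.null(tree)) {
      if (is.null(selection_genes)) selection_genes <- sort(flagged)
      rows <- list()
      for (gene in selection_genes) {
        aln_seqs <- if (!is.null(gene_alignments)) gene_alignments[[gene]]
        else {
          carriers <- which(vapply(panel, function(p)
            gene %in% .feature_names(p, "protein_coding"), TRUE))
          plastid <- vapply(carriers, function(i)
            extract_cds(panel[[i]], gene), "")
          names(plastid) <- names(panel)[carriers]
          if (length(unique(nchar(plastid))) != 1)
            stop("panel CDS of '", gene, "' are not length-aligned")
          focal_row <- extract_cds(focal, gene)
          names(focal_row) <- focal$id
          prep_gene_matrix(plastid, as.list(focal_row),
                           min_remaining = min_remaining)
        }
        if (is.null(aln_seqs) || length(aln_seqs) < 3) next
        ambig <- mask_ambiguous_columns(aln_seqs)
        caln <- build_codon_alignment(aln_seqs, min_remaining = min_remaining,
                                      mask = ambig)
        if (!focal$id %in% caln$taxa) next  # focal copy too degraded to test
        shift <- test_branch_shift(caln, ape::keep.tip(tree, caln$taxa),
                                   focal$id, n_starts = n_starts,
                                   seed = seed)
        rows[[gene]] <- data.frame(
          gene = gene, lambda = shift$lrt$lambda, df = shift$lrt$df,
          p = shift$lrt$p, omega_focal = shift$omega_focal,
          omega_ancestral = shift$omega_ancestral,
          logL_full = shift$full$loglik,
          logL_constrained = shift$constrained$loglik,
          converged = shift$full$converged && shift$constrained$converged,
          stringsAsFactors = FALSE)
      }
      if (length(rows)) {
        lrt_tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
        lrt_tab$p_hochberg <- hochberg_adjust(lrt_tab$p)
        emit(.write_tsv(lrt_tab, file.path(out_dir, "selection_lrt.tsv")))
      }
    }

    # ---- manifest -------------------------------------------------------
    stage <- "manifest"
    cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                 digits = NA)
    manifest <- list(
      tool = "plastidDecay",
      version = as.character(utils::packageVersion("plastidDecay")),
      seed = seed,
      config_md5 = .md5_string(as.character(cfg_json)),
      inputs = c(stats::setNames(
        vapply(all_recs, function(r) .md5_string(r$sequence), ""),
        vapply(all_recs, `[[`, "", "id"))),
      outputs = as.list(stats::setNames(
        vapply(written, function(p) unname(tools::md5sum(p)), ""),
        basename(written))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)

    list(summaries = summaries, report = report, lrt = lrt_tab,
         paralogs = paralogs, stats = stats_out, manifest = manifest,
         focal = focal)
  }, error = function(e) {
    unlink(written)          # remove partial outputs
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' Verify a pipeline manifest
#'
#' Recomputes the checksum of every output file listed in a pipeline
#' manifest and reports mismatches.
#'
#' @param out_dir Pipeline output directory containing `manifest.json`.
#' @return Logical: all checksums match (with a warning naming mismatches
#'   otherwise).
#' @export
verify_manifest <- function(out_dir) {
  mf <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  bad <- character()
  for (f in names(mf$outputs)) {
    path <- file.path(out_dir, f)
    if (!file.exists(path) ||
        unname(tools::md5sum(path)) != mf$outputs[[f]])
      bad <- c(bad, f)
  }
  if (length(bad)) {
    warning("checksum mismatch: ", paste(bad, collapse = ", "))
    return(FALSE)
  }
  TRUE
}
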