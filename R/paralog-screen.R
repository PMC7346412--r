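# Candidate paralog contigs (e.g. nuclear plastid-derived copies, NUPTs):
# coverage-based origin classification and degradation screening against
# the plastid reference copy.

#' Construct a paralog contig
#'
#' @param id Contig identifier.
#' @param sequence DNA string.
#' @param kmer_coverage Assembler-reported fold coverage (>= 0).
#' @param best_hit_gene Optional gene assignment.
#' @return Object of class `paralog_contig`.
#' @export
paralog_contig <- function(id, sequence, kmer_coverage,
                           best_hit_gene = NA_character_) {
  stopifnot(kmer_coverage >= 0)
  structure(list(id = id, sequence = toupper(sequence),
                 kmer_coverage = kmer_coverage,
                 best_hit_gene = best_hit_gene,
                 classification = NA_character_),
            class = "paralog_contig")
}

#' Read contigs plus a coverage table
#'
#' @param fasta_path Contig FASTA.
#' @param coverage_path Two-column TSV (contig id, fold coverage), no
#'   header.
#' @return List of [paralog_contig()] objects.
#' @export
read_paralog_contigs <- function(fasta_path, coverage_path) {
  seqs <- read_fasta(fasta_path)
  cov <- utils::read.table(coverage_path, sep = "\t", header = FALSE,
                           col.names = c("id", "coverage"),
                           stringsAsFactors = FALSE)
  missing <- setdiff(names(seqs), cov$id)
  if (length(missing))
    stop("no coverage for contig(s): ", paste(missing, collapse = ", "))
  lapply(names(seqs), function(id)
    paralog_contig(id, seqs[[id]], cov$coverage[match(id, cov$id)]))
}

#' Classify a contig's genome of origin by relative coverage
#'
#' Nuclear plastid-derived fragments assemble at fold coverage orders of
#' magnitude below the organellar genomes; the contig is called `nuclear`
#' when its coverage is below `ratio_threshold` of the organellar coverage
#' (strict less-than), `organellar` at or above 0.5, and `ambiguous`
#' between. Scale-invariant in the pair of coverages.
#'
#' @param contig A [paralog_contig()] (or a bare coverage value).
#' @param organellar_coverage Fold coverage of the organellar genome (> 0).
#' @param ratio_threshold Nuclear call threshold (default 0.1).
#' @param organellar_threshold Organellar call threshold (default 0.5).
#' @return The contig with `classification` set (or the classification
#'   string if a bare value was given).
#' @export
classify_origin <- function(contig, organellar_coverage,
                            ratio_threshold = 0.1,
                            organellar_threshold = 0.5) {
  if (organellar_coverage <= 0) stop("organellar coverage must be positive")
  ck <- if (inherits(contig, "paralog_contig")) contig$kmer_coverage
        else contig
  ratio <- ck / organellar_coverage
  cls <- if (ratio < ratio_threshold) "nuclear"
         else if (ratio >= organellar_threshold) "organellar"
         else "ambiguous"
  if (inherits(contig, "paralog_contig")) {
    contig$classification <- cls
    contig
  } else cls
}

#' Screen a paralog contig for degradation events
#'
#' Aligns the contig to the reference CDS (global in the reference, local
#' in the contig) and reuses [detect_events()]; premature stops are
#' additionally labeled `shared` when they fall on the same aligned
#' reference column as a premature stop of the plastid copy, `novel`
#' otherwise.
#'
#' @param contig A [paralog_contig()] or DNA string.
#' @param reference_cds Intact reference coding sequence.
#' @param plastid_events Optional event list from the plastid copy of the
#'   same gene (as returned in a [scan_genome()] report) used for
#'   shared/novel labeling; sharing is assessed on the reference-CDS
#'   coordinate of each stop.
#' @param config A [scan_config()].
#' @param min_overlap Minimum aligned overlap (bp) with the reference gene.
#' @return List of degradation events, or `NULL` (with a warning) when the
#'   overlap is insufficient.
#' @export
screen_paralog <- function(contig, reference_cds, plastid_events = NULL,
                           config = scan_config(), min_overlap = 100) {
  seqn <- if (inherits(contig, "paralog_contig")) contig$sequence else contig
  idn <- if (inherits(contig, "paralog_contig")) contig$id else "contig"
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = config$match, mismatch = config$mismatch, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(seqn)),
    Biostrings::DNAString(toupper(reference_cds)),
    type = "local", substitutionMatrix = mat,
    gapOpening = config$gap_open, gapExtension = config$gap_extend)
  overlap <- Biostrings::nchar(Biostrings::subject(aln))
  if (overlap < min_overlap) {
    warning("contig '", idn, "' overlaps reference by only ", overlap,
            " bp (< ", min_overlap, "); skipped")
    return(NULL)
  }
  fa <- as.character(Biostrings::alignedPattern(aln))
  ra <- as.character(Biostrings::alignedSubject(aln))
  # reference-frame offset of the local alignment start
  ref_from <- Biostrings::start(Biostrings::subject(aln))
  ga <- structure(list(focal = fa, ref = ra, score = Biostrings::score(aln),
                       identity = mean(strsplit(fa, "")[[1]] ==
                                         strsplit(ra, "")[[1]])),
                  class = "gene_alignment")
  events <- detect_events(ga, config)
  if (!is.null(plastid_events)) {
    plastid_stops <- vapply(
      Filter(function(e) e$kind == "premature_stop", plastid_events),
      function(e) e$position, 1L)
    events <- lapply(events, function(e) {
      if (e$kind != "premature_stop") return(e)
      # map both to reference coordinates before comparing
      col <- e$position
      rv <- strsplit(ra, "")[[1]]
      refpos <- sum(rv[seq_len(col)] != "-") + ref_from - 1L
      shared <- any(abs(plastid_stops - refpos) <= 2)
      e$detail <- paste0(e$detail, if (shared) "; shared" else "; novel")
      e
    })
  }
  events
}

#' Mask ambiguously aligned regions of a gene matrix
#'
#' Flags columns lying in local windows where any row disagrees densely
#' with the column consensus -- the signature of unalignable or rearranged
#' sequence (e.g. an inverted segment) rather than point substitution.
#' Masking is codon-aware: if any column of a codon is flagged, the whole
#' codon is flagged, so downstream codon alignments keep their frame.
#'
#' @param alignment Named character vector of equal-length aligned in-frame
#'   sequences (length a multiple of 3).
#' @param window Sliding window width in bp.
#' @param threshold Local mismatch fraction (vs the column consensus) at or
#'   above which a window is considered ambiguous.
#' @return Logical vector over columns; `TRUE` = mask.
#' @export
mask_ambiguous_columns <- function(alignment, window = 15,
                                   threshold = 0.5) {
  stopifnot(length(unique(nchar(alignment))) == 1)
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  L <- ncol(mat)
  stopifnot(L %% 3 == 0)
  consensus <- apply(mat, 2, function(col) {
    col <- col[!col %in% c("-", "?", "N")]
    if (!length(col)) return(NA_character_)
    names(sort(table(col), decreasing = TRUE))[1]
  })
  mask <- rep(FALSE, L)
  half <- window %/% 2
  for (i in seq_len(nrow(mat))) {
    mm <- as.numeric(mat[i, ] != consensus & mat[i, ] != "-" &
                       !is.na(consensus))
    cum <- cumsum(c(0, mm))
    lo <- pmax(seq_len(L) - half, 1)
    hi <- pmin(seq_len(L) + half, L)
    frac <- (cum[hi + 1] - cum[lo]) / (hi - lo + 1)
    mask <- mask | frac >= threshold
  }
  # codon-aware: flag whole codons
  codon_flag <- colSums(matrix(mask, nrow = 3)) > 0
  rep(codon_flag, each = 3)
}

#' Prepare a per-gene matrix for tree building
#'
#' Contigs are mapped into the coordinate system of an existing gene
#' alignment (via pairwise alignment to its first, reference row), trimmed
#' to the aligned gene extent, masked columns are removed, and sequences
#' retaining fewer than `min_remaining` bases are dropped.
#'
#' @param gene_alignment Named character vector of equal-length aligned
#'   plastid gene sequences (first row = reference).
#' @param contigs List of [paralog_contig()] or named DNA strings.
#' @param min_remaining Minimum unmasked bases for retention (default 200).
#' @param mask Optional logical column mask (TRUE = remove).
#' @param config A [scan_config()] (alignment scoring).
#' @return Named character vector: the masked plastid rows plus one row per
#'   retained contig (padded with gaps outside its aligned extent). Warns
#'   and returns only the plastid rows when every contig is dropped.
#' @export
prep_gene_matrix <- function(gene_alignment, contigs, min_remaining = 200,
                             mask = NULL, config = scan_config()) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = config$match, mismatch = config$mismatch, baseOnly = FALSE)
  stopifnot(length(unique(nchar(gene_alignment))) == 1)
  ref_aln <- gene_alignment[[1]]
  ref_plain <- gsub("-", "", ref_aln)
  ncol_aln <- nchar(ref_aln)
  ref_cols <- which(strsplit(ref_aln, "")[[1]] != "-")  # ref pos -> column

  contig_rows <- list()
  for (i in seq_along(contigs)) {
    cg <- contigs[[i]]
    seqn <- if (inherits(cg, "paralog_contig")) cg$sequence else cg
    idn <- if (inherits(cg, "paralog_contig")) cg$id
           else names(contigs)[i]
    if (is.null(idn) || !nzchar(idn)) idn <- paste0("contig", i)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(toupper(seqn)),
      Biostrings::DNAString(toupper(ref_plain)), type = "local",
      substitutionMatrix = submat, gapOpening = config$gap_open,
      gapExtension = config$gap_extend)
    fa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    ra <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    ref_from <- Biostrings::start(Biostrings::subject(aln))
    row <- rep("-", ncol_aln)
    rp <- ref_from - 1L
    for (k in seq_along(fa)) {
      if (ra[k] != "-") {
        rp <- rp + 1L
        row[ref_cols[rp]] <- fa[k]
      }
      # contig insertions relative to the reference are dropped (trimming
      # to the aligned gene extent)
    }
    contig_rows[[idn]] <- paste(row, collapse = "")
  }
  out <- c(gene_alignment, unlist(contig_rows))
  if (!is.null(mask)) {
    stopifnot(length(mask) == ncol_aln)
    out <- vapply(out, function(s)
      paste(strsplit(s, "")[[1]][!mask], collapse = ""), "")
  }
  kept_bp <- vapply(out, function(s) sum(strsplit(s, "")[[1]] != "-"), 1)
  keep <- kept_bp >= min_remaining | names(out) %in% names(gene_alignment)
  contig_kept <- setdiff(names(out)[keep], names(gene_alignment))
  if (!length(contig_kept) && length(contigs))
    warning("all contigs dropped (fewer than ", min_remaining,
            " bp after trimming)")
  out[keep]
}
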