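# Criteria-based pseudogene detection: homology annotation lift, pairwise
# alignment of each focal gene to a reference ortholog, structural-lesion
# scanning (premature stops, frameshifts, lost canonical stops, large
# deletions, short inversions), and panel-context anomalies (novel
# terminations, length outliers, hydrophobicity outliers).

#' Scan configuration
#'
#' Thresholds and options for [scan_genome()] and friends.
#'
#' @param large_deletion_threshold Minimum single-gap length (bp) reported
#'   as a large deletion (default 100; the threshold is per gap, not
#'   cumulative).
#' @param min_identity_for_lift Minimum pairwise identity for transferring
#'   a gene model during annotation lift (default 0.70).
#' @param hydrophobic_residues Residue set counted as hydrophobic (default
#'   the positive Kyte-Doolittle hydropathy set A, C, F, I, L, M, V).
#' @param ci_level Confidence level for the panel hydrophobicity interval.
#' @param inversion_window Maximum span (bp) of a mismatch cluster tested
#'   for inversion (default 200).
#' @param inversion_identity_gain Minimum local identity gain after reverse
#'   complementing the cluster required to call an inversion (default 0.25).
#' @param stop_search_window Bases past the canonical stop searched before
#'   declaring the stop lost (default 30).
#' @param flank Downstream flank (bp) carried along for stop-site logic.
#' @param excluded_genes Genes excluded from novel pseudogene calls (IR
#'   boundary fragments and known angiosperm pseudogenes).
#' @param match,mismatch,gap_open,gap_extend Pairwise alignment scoring.
#' @return List of class `scan_config`.
#' @export
scan_config <- function(large_deletion_threshold = 100,
                        min_identity_for_lift = 0.70,
                        hydrophobic_residues = c("A", "C", "F", "I", "L",
                                                 "M", "V"),
                        ci_level = 0.95,
                        inversion_window = 200,
                        inversion_identity_gain = 0.25,
                        stop_search_window = 30,
                        flank = 200,
                        excluded_genes = c("ycf15", "ycf1", "ycf2"),
                        match = 2, mismatch = -3, gap_open = 10,
                        gap_extend = 0.5) {
  stopifnot(large_deletion_threshold > 0, min_identity_for_lift > 0,
            ci_level > 0, ci_level < 1, inversion_window > 0,
            inversion_identity_gain > 0, stop_search_window >= 0)
  structure(list(large_deletion_threshold = large_deletion_threshold,
                 min_identity_for_lift = min_identity_for_lift,
                 hydrophobic_residues = hydrophobic_residues,
                 ci_level = ci_level, inversion_window = inversion_window,
                 inversion_identity_gain = inversion_identity_gain,
                 stop_search_window = stop_search_window, flank = flank,
                 excluded_genes = excluded_genes, match = match,
                 mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "scan_config")
}

.event <- function(kind, position, detail = "") {
  list(kind = kind, position = as.integer(position),
       detail = as.character(detail))
}

#' Global pairwise alignment of a focal gene against a reference
#'
#' Deterministic affine-gap global (Needleman-Wunsch) alignment with the
#' package's documented scoring (match +2, mismatch -3, gap open -10, gap
#' extend -0.5 by default).
#'
#' @param focal,reference Non-empty DNA strings.
#' @param config A [scan_config()] (scoring parameters).
#' @return List of class `gene_alignment`: `focal`, `ref` (gapped strings of
#'   equal length), `score`, `identity` (matches / alignment columns).
#' @export
align_gene_to_reference <- function(focal, reference, config = scan_config()) {
  stopifnot(nzchar(focal), nzchar(reference))
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = config$match, mismatch = config$mismatch, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(focal)),
    Biostrings::DNAString(toupper(reference)),
    type = "global", substitutionMatrix = mat,
    gapOpening = config$gap_open, gapExtension = config$gap_extend)
  fa <- as.character(Biostrings::alignedPattern(aln))
  ra <- as.character(Biostrings::alignedSubject(aln))
  fv <- strsplit(fa, "")[[1]]; rv <- strsplit(ra, "")[[1]]
  structure(list(focal = fa, ref = ra, score = Biostrings::score(aln),
                 identity = mean(fv == rv & fv != "-")),
            class = "gene_alignment")
}

.mismatch_clusters <- function(mm_cols, max_gap, min_count, min_span,
                               max_span) {
  if (length(mm_cols) < min_count) return(list())
  breaks <- which(diff(mm_cols) > max_gap)
  starts <- c(1, breaks + 1)
  ends <- c(breaks, length(mm_cols))
  out <- list()
  for (k in seq_along(starts)) {
    cl <- mm_cols[starts[k]:ends[k]]
    span <- cl[length(cl)] - cl[1] + 1
    if (length(cl) >= min_count && span >= min_span && span <= max_span)
      out[[length(out) + 1]] <- c(from = cl[1], to = cl[length(cl)])
  }
  out
}

#' Detect degradation events on a gene alignment
#'
#' Applies the structural pseudogenization criteria to an alignment of a
#' focal coding region against an intact reference CDS (reference assumed
#' to end in its stop codon):
#' frameshifts (net indel offset not divisible by 3, reported at the first
#' offending indel), premature stop codons (in the focal reading frame,
#' strictly upstream of the column aligned to the reference stop), lost
#' canonical stop (no focal in-frame stop at or within
#' `stop_search_window` bp downstream of the reference stop position),
#' large deletions (any single focal gap at or above the threshold), short
#' inversions (a mismatch cluster whose reverse complement raises local
#' identity by at least `inversion_identity_gain`), and novel terminations
#' (first focal stop beyond the search window, with the extension length).
#'
#' @param alignment A [align_gene_to_reference()] result.
#' @param config A [scan_config()].
#' @param focal_flank DNA continuing downstream of the focal region in
#'   transcription direction (used for stop-site logic past the alignment).
#' @return List of degradation events (`kind`, `position` in alignment
#'   columns, `detail`).
#' @export
detect_events <- function(alignment, config = scan_config(),
                          focal_flank = "") {
  stopifnot(inherits(alignment, "gene_alignment"))
  fv <- strsplit(alignment$focal, "")[[1]]
  rv <- strsplit(alignment$ref, "")[[1]]
  n <- length(fv)
  events <- list()

  fgap <- fv == "-"
  rgap <- rv == "-"

  # ---- short inversions (first: their alignment artifacts must not count
  # as frameshifts) -------------------------------------------------------
  # candidate regions come from two signatures: (a) a dense mismatch
  # cluster (the aligner matched the inverted segment column by column);
  # (b) a paired focal-gap/reference-gap of similar length within the
  # window (the aligner rendered the inversion as deletion + insertion)
  candidates <- .mismatch_clusters(which(fv != rv), max_gap = 10,
                                   min_count = 6, min_span = 12,
                                   max_span = config$inversion_window)
  runs0 <- rle(ifelse(fgap, "D", ifelse(rgap, "I", "M")))
  rends <- cumsum(runs0$lengths)
  rstarts <- rends - runs0$lengths + 1
  didx <- which(runs0$values == "D" & runs0$lengths >= 4)
  iidx <- which(runs0$values == "I" & runs0$lengths >= 4)
  for (di in didx) {
    for (ii in iidx) {
      if (abs(runs0$lengths[di] - runs0$lengths[ii]) > 6) next
      lo <- min(rstarts[di], rstarts[ii]); hi <- max(rends[di], rends[ii])
      if (hi - lo + 1 > 2 * config$inversion_window) next
      candidates[[length(candidates) + 1]] <- c(from = lo, to = hi)
    }
  }
  inversion_spans <- list()
  for (cl in candidates) {
    cols <- cl["from"]:cl["to"]
    fseg <- paste(fv[cols][!fgap[cols]], collapse = "")
    rseg <- paste(rv[cols][!rgap[cols]], collapse = "")
    if (nchar(fseg) < 12 || nchar(rseg) < 12) next
    if (nchar(fseg) > 2 * config$inversion_window) next
    # aligned (not positional) identity: candidate regions include a few
    # flanking bases that would otherwise shift the reverse-complement
    # frame and mask the signal
    id0 <- .pair_identity(fseg, rseg, config)
    idr <- align_gene_to_reference(.revcomp(fseg), rseg, config)$identity
    if (idr - id0 >= config$inversion_identity_gain) {
      events[[length(events) + 1]] <-
        .event("short_inversion", cl["from"],
               sprintf("span %d bp; identity %.2f -> %.2f reverse-complemented",
                       length(cols), id0, idr))
      inversion_spans[[length(inversion_spans) + 1]] <- cl
    }
  }
  in_inversion <- function(col) {
    any(vapply(inversion_spans, function(cl)
      col >= cl["from"] && col <= cl["to"], TRUE))
  }

  # ---- indel walk: frameshift + large deletions -------------------------
  runs <- rle(ifelse(fgap, "D", ifelse(rgap, "I", "M")))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  cum <- 0L
  frameshift_done <- FALSE
  for (k in seq_along(runs$lengths)) {
    type <- runs$values[k]; len <- runs$lengths[k]
    if (type == "M") next
    if (in_inversion(starts[k]))  # alignment artifacts of the inversion
      next
    if (type == "D" && len >= config$large_deletion_threshold)
      events[[length(events) + 1]] <-
        .event("large_deletion", starts[k], len)
    prev <- cum
    cum <- cum + if (type == "I") len else -len
    if (!frameshift_done && prev %% 3L == 0L && cum %% 3L != 0L) {
      events[[length(events) + 1]] <-
        .event("frameshift", starts[k],
               sprintf("net shift %+d", ((cum %% 3L) + 3L) %% 3L))
      frameshift_done <- TRUE
    }
  }

  # ---- stop-site logic --------------------------------------------------
  fseq <- paste(fv[!fgap], collapse = "")
  ffull <- paste0(fseq, toupper(focal_flank))
  ref_len <- sum(!rgap)
  ref_stop <- substr(paste(rv[!rgap], collapse = ""), ref_len - 2, ref_len)
  if (ref_len >= 6 && ref_stop %in% .stop_codons) {
    # alignment column of the reference stop codon start
    ref_pos <- cumsum(!rgap)               # per column: ref bases so far
    ref_stop_col <- which(ref_pos == ref_len - 2 & !rgap)[1]
    focal_before <- cumsum(!fgap)
    canon_pos <- if (ref_stop_col > 1) focal_before[ref_stop_col - 1] else 0L
    # 0-based focal position aligned to the reference stop start
    ncod <- nchar(ffull) %/% 3
    if (ncod >= 1) {
      cods <- substring(ffull, seq(1, 3 * ncod - 2, 3), seq(3, 3 * ncod, 3))
      stop_pos <- 3L * (which(cods %in% .stop_codons) - 1L)  # 0-based
      col_of_focal <- function(p) {
        # alignment column holding focal base p (0-based); flank positions
        # report the last alignment column
        if (p >= nchar(fseq)) return(n)
        which(focal_before == p + 1 & !fgap)[1]
      }
      premature <- stop_pos[stop_pos < canon_pos & stop_pos < nchar(fseq)]
      if (length(premature))
        events[[length(events) + 1]] <-
          .event("premature_stop", col_of_focal(premature[1]),
                 sprintf("codon %d of %d; %d premature stop(s)",
                         premature[1] %/% 3 + 1, canon_pos %/% 3 + 1,
                         length(premature)))
      at_canon <- stop_pos[stop_pos >= canon_pos &
                             stop_pos <= canon_pos + config$stop_search_window]
      if (!length(at_canon))
        events[[length(events) + 1]] <-
          .event("lost_canonical_stop", ref_stop_col,
                 sprintf("no stop within %d bp of canonical site",
                         config$stop_search_window))
      beyond <- stop_pos[stop_pos > canon_pos + config$stop_search_window]
      if (!length(at_canon) && !length(premature) && length(beyond))
        events[[length(events) + 1]] <-
          .event("novel_termination", n,
                 sprintf("%d additional bp before a novel stop codon",
                         beyond[1] - canon_pos))
    }
  }

  events
}

.pair_identity <- function(a, b, config) {
  if (nchar(a) == nchar(b))
    return(mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]]))
  aln <- align_gene_to_reference(a, b, config)
  aln$identity
}

#' Fraction of hydrophobic residues in a protein
#'
#' @param protein Amino-acid string; stop (`*`) and ambiguous (`X`)
#'   residues are excluded from the denominator.
#' @param residue_set Residues counted as hydrophobic.
#' @return Fraction in \[0, 1\].
#' @export
hydrophobic_fraction <- function(protein,
                                 residue_set = scan_config()$hydrophobic_residues) {
  stopifnot(nzchar(protein))
  aa <- strsplit(toupper(protein), "")[[1]]
  aa <- aa[!aa %in% c("*", "X")]
  if (!length(aa)) stop("no countable residues")
  mean(aa %in% residue_set)
}

#' Student-t confidence interval for panel hydrophobicity
#'
#' `mean +/- t(1 - (1 - ci_level)/2, n - 1) * sd / sqrt(n)`.
#'
#' @param panel_fractions Numeric vector (n >= 3) of per-taxon fractions.
#' @param ci_level Confidence level in (0, 1).
#' @return Numeric `c(low, high)`.
#' @export
hydrophobicity_ci <- function(panel_fractions, ci_level = 0.95) {
  n <- length(panel_fractions)
  if (n < 3) stop("need at least 3 panel values")
  stopifnot(ci_level > 0, ci_level < 1)
  m <- mean(panel_fractions)
  se <- stats::sd(panel_fractions) / sqrt(n)
  half <- stats::qt(1 - (1 - ci_level) / 2, df = n - 1) * se
  c(m - half, m + half)
}

# ---- annotation lift -----------------------------------------------------

.locate_gene <- function(target_seq, ref_cds, config) {
  # seed-and-extend localization of a reference CDS on an unannotated
  # genome; returns NULL or list(start, end (0-based half-open), strand,
  # identity)
  L <- nchar(ref_cds)
  subj <- Biostrings::DNAString(target_seq)
  seed_len <- 24L
  offsets <- c(0L, 30L, 60L, 90L, max(0L, L - seed_len - 3L))
  offsets <- unique(offsets[offsets + seed_len <= L])
  window <- NULL
  strand <- NULL
  for (off in offsets) {
    seed <- substr(ref_cds, off + 1, off + seed_len)
    for (str in c("+", "-")) {
      pat <- if (str == "+") seed else .revcomp(seed)
      hits <- Biostrings::matchPattern(pat, subj, max.mismatch = 5)
      if (length(hits) >= 1) {
        h <- Biostrings::start(hits)[1]
        anchor <- if (str == "+") h - off else h - (L - off - seed_len)
        window <- c(max(1, anchor - 150), min(nchar(target_seq),
                                              anchor + L + 150))
        strand <- str
        break
      }
    }
    if (!is.null(window)) break
  }
  if (is.null(window)) return(NULL)
  wseq <- substr(target_seq, window[1], window[2])
  if (strand == "-") wseq <- .revcomp(wseq)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = config$match, mismatch = config$mismatch, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ref_cds), Biostrings::DNAString(wseq),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = config$gap_open, gapExtension = config$gap_extend)
  s <- Biostrings::start(Biostrings::subject(aln))
  e <- Biostrings::end(Biostrings::subject(aln))
  pa <- as.character(Biostrings::alignedPattern(aln))
  sa <- as.character(Biostrings::alignedSubject(aln))
  pv <- strsplit(pa, "")[[1]]; sv2 <- strsplit(sa, "")[[1]]
  identity <- mean(pv == sv2 & pv != "-")
  wlen <- nchar(wseq)
  if (strand == "+") {
    gstart <- window[1] - 1 + s - 1        # 0-based
    gend <- window[1] - 1 + e             # half-open
  } else {
    gstart <- window[1] - 1 + (wlen - e)
    gend <- window[1] - 1 + (wlen - s + 1)
  }
  list(start = gstart, end = gend, strand = strand, identity = identity)
}

#' Lift annotations from a reference genome by homology
#'
#' Each reference gene is located on the unannotated target by seeded
#' pairwise alignment; models whose best hit reaches
#' `min_identity_for_lift` are transferred with adjusted coordinates (as
#' single-segment models), others are recorded as missing. Per-gene lift
#' identity is attached as attribute `"lift"`.
#'
#' @param target A [plastome_record()] (annotations ignored/overwritten).
#' @param reference An annotated [plastome_record()].
#' @param config A [scan_config()].
#' @return Annotated copy of `target` with a `lift` attribute (data.frame:
#'   gene, kind, identity, status).
#' @export
annotate_by_homology <- function(target, reference, config = scan_config()) {
  stopifnot(inherits(target, "plastome_record"),
            inherits(reference, "plastome_record"))
  feats <- list()
  lift <- list()
  for (f in reference$features) {
    ref_cds <- extract_cds(reference, f$gene_name)
    loc <- .locate_gene(target$sequence, ref_cds, config)
    if (is.null(loc) || loc$identity < config$min_identity_for_lift) {
      lift[[length(lift) + 1]] <- data.frame(
        gene = f$gene_name, kind = f$kind,
        identity = if (is.null(loc)) NA_real_ else loc$identity,
        status = "missing", stringsAsFactors = FALSE)
      next
    }
    feats[[length(feats) + 1]] <- gene_model(
      f$gene_name, f$kind, matrix(c(loc$start, loc$end), ncol = 2),
      strand = loc$strand, codon_start_offset = f$codon_start_offset)
    lift[[length(lift) + 1]] <- data.frame(
      gene = f$gene_name, kind = f$kind, identity = loc$identity,
      status = "transferred", stringsAsFactors = FALSE)
  }
  out <- plastome_record(target$id, target$sequence, feats,
                         target$is_circular)
  attr(out, "lift") <- do.call(rbind, lift)
  out
}

# ---- whole-genome scan ---------------------------------------------------

.PRIMARY_KINDS <- c("premature_stop", "frameshift", "lost_canonical_stop",
                    "large_deletion")

.gene_flank <- function(record, gene, len) {
  f <- .get_feature(record, gene)
  segs <- f$segments
  end_pos <- if (f$strand == "+") segs[nrow(segs), 2]
             else segs[nrow(segs), 1] + 1L
  .downstream_flank(record$sequence, end_pos, f$strand, len, record$length)
}

.first_stop_codon <- function(cds) {
  ncod <- nchar(cds) %/% 3
  if (ncod < 1) return(NA_integer_)
  cods <- substring(cds, seq(1, 3 * ncod - 2, 3), seq(3, 3 * ncod, 3))
  w <- which(cods %in% .stop_codons)
  if (!length(w)) NA_integer_ else w[1]   # 1-based codon index
}

#' Scan a focal genome for pseudogenization against a panel
#'
#' For every protein-coding gene shared between the focal record and the
#' reference (the first panel member carrying the gene), the focal coding
#' region is aligned to the reference CDS and [detect_events()] applied;
#' panel context adds supporting events: `novel_termination` when the focal
#' predicted termination differs from every panel ortholog,
#' `length_anomaly` when the predicted protein length falls outside the
#' panel's observed range, and `hydrophobicity_outlier` when the focal
#' hydrophobic fraction falls outside the panel's Student-t confidence
#' interval. Genes listed in `config$excluded_genes` (IR-boundary
#' fragments, known angiosperm pseudogenes) are excluded from novel calls.
#'
#' Verdicts: `pseudogene` if at least one primary structural event
#' (premature stop, frameshift, lost canonical stop, large deletion) was
#' found; `anomalous` if only supporting events; `intact` otherwise.
#'
#' @param focal Annotated (or homology-lifted) [plastome_record()].
#' @param panel Non-empty list of annotated [plastome_record()]s.
#' @param config A [scan_config()].
#' @return Object of class `degradation_report`: `focal_id`, `genes`
#'   (per-gene list with `events`, `verdict`, `identity`), and
#'   `hydrophobicity` (per-gene profile rows).
#' @export
scan_genome <- function(focal, panel, config = scan_config()) {
  stopifnot(inherits(focal, "plastome_record"))
  if (!length(panel)) stop("empty panel")
  for (p in panel) stopifnot(inherits(p, "plastome_record"))

  focal_genes <- .feature_names(focal, "protein_coding")
  genes <- setdiff(focal_genes, config$excluded_genes)
  out <- list()
  hydro <- list()
  for (gene in genes) {
    carriers <- which(vapply(panel, function(p)
      gene %in% .feature_names(p, "protein_coding"), TRUE))
    if (!length(carriers)) next
    reference <- panel[[carriers[1]]]
    ref_cds <- extract_cds(reference, gene)
    focal_cds <- extract_cds(focal, gene)
    flank <- .gene_flank(focal, gene, config$flank)
    aln <- align_gene_to_reference(focal_cds, ref_cds, config)
    events <- detect_events(aln, config, focal_flank = flank)

    # panel context: terminations, protein lengths, hydrophobicity
    panel_cds <- lapply(carriers, function(i) extract_cds(panel[[i]], gene))
    focal_first_stop <- .first_stop_codon(paste0(focal_cds, flank))
    panel_first_stop <- vapply(panel_cds, .first_stop_codon, 1L)
    focal_len <- nchar(focal_cds) %/% 3L
    panel_len <- vapply(panel_cds, function(x) nchar(x) %/% 3L, 1L)
    kinds_so_far <- vapply(events, `[[`, "", "kind")
    if (!is.na(focal_first_stop) && !any(is.na(panel_first_stop)) &&
        !any(kinds_so_far %in% c("premature_stop", "frameshift")) &&
        !focal_first_stop %in% panel_first_stop &&
        focal_len %in% panel_len == FALSE &&
        !"novel_termination" %in% kinds_so_far &&
        focal_first_stop != focal_len) {
      events[[length(events) + 1]] <-
        .event("novel_termination", nchar(aln$focal),
               sprintf("terminates at codon %d; panel at %s",
                       focal_first_stop,
                       paste(sort(unique(panel_first_stop)), collapse = "/")))
    }
    if (length(panel_len) >= 2 &&
        (focal_len < min(panel_len) || focal_len > max(panel_len)) &&
        !any(kinds_so_far == "large_deletion")) {
      events[[length(events) + 1]] <-
        .event("length_anomaly", nchar(aln$focal),
               sprintf("predicted %d codons; panel range %d-%d", focal_len,
                       min(panel_len), max(panel_len)))
    }
    panel_h <- vapply(panel_cds, function(x)
      hydrophobic_fraction(translate_cds(x), config$hydrophobic_residues),
      1.0)
    focal_h <- hydrophobic_fraction(translate_cds(focal_cds),
                                    config$hydrophobic_residues)
    if (length(panel_h) >= 3 && stats::sd(panel_h) > 0) {
      ci <- hydrophobicity_ci(panel_h, config$ci_level)
      if (focal_h < ci[1] || focal_h > ci[2])
        events[[length(events) + 1]] <-
          .event("hydrophobicity_outlier", 0,
                 sprintf("%.3f outside panel CI [%.3f, %.3f]", focal_h,
                         ci[1], ci[2]))
      hydro[[gene]] <- data.frame(gene = gene, focal_fraction = focal_h,
                                  ci_low = ci[1], ci_high = ci[2],
                                  n_panel = length(panel_h),
                                  stringsAsFactors = FALSE)
    }
    kinds <- vapply(events, `[[`, "", "kind")
    verdict <- if (any(kinds %in% .PRIMARY_KINDS)) "pseudogene"
               else if (length(kinds)) "anomalous" else "intact"
    out[[gene]] <- list(events = events, verdict = verdict,
                        identity = aln$identity)
  }
  structure(list(focal_id = focal$id, genes = out,
                 hydrophobicity = do.call(rbind, hydro)),
            class = "degradation_report")
}

#' @export
print.degradation_report <- function(x, ...) {
  verdicts <- vapply(x$genes, `[[`, "", "verdict")
  cat(sprintf("degradation report for '%s': %d genes scanned\n", x$focal_id,
              length(verdicts)))
  cat(sprintf("  pseudogene: %d  anomalous: %d  intact: %d\n",
              sum(verdicts == "pseudogene"), sum(verdicts == "anomalous"),
              sum(verdicts == "intact")))
  flagged <- names(verdicts)[verdicts == "pseudogene"]
  if (length(flagged)) cat("  flagged:", paste(sort(flagged), collapse = ", "), "\n")
  invisible(x)
}
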