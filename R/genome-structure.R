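# Quadripartite plastome structure: inverted-repeat detection by
# seed-and-extend, SSC orientation standardization, and genome summaries.
#
# Intervals are 0-based half-open and may wrap the circular origin
# (start > end means the interval crosses position 0).

.interval_len <- function(iv, n) {
  if (iv[1] <= iv[2]) iv[2] - iv[1] else n - iv[1] + iv[2]
}

.comp_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Detect the inverted repeat and quadripartite structure
#'
#' Finds the longest pair of disjoint, mutually reverse-complementary
#' segments of at least `min_len` bases on the circular sequence, by exact
#' seed matching between the (virtually doubled) forward sequence and its
#' reverse complement followed by maximal symmetric extension under the
#' mismatch tolerance. The two single-copy arcs between the repeat copies
#' are labeled LSC (longer) and SSC (shorter); IRb is the copy adjacent to
#' the downstream end of the LSC.
#'
#' @param sequence Circular DNA string (or a [plastome_record()]).
#' @param min_len Minimum repeat length to report (default 1000 bp).
#' @param max_mismatch_frac Mismatch fraction tolerated during extension
#'   (default 0.01; 0 for exact repeats).
#' @param seed_len Exact seed k-mer length.
#' @return Object of class `quadripartite_structure` with fields `found`,
#'   `lsc`, `ssc`, `ira`, `irb` (0-based half-open intervals, possibly
#'   wrapping), and `ir_length`, `lsc_length`, `ssc_length`. When no repeat
#'   qualifies, `found` is `FALSE` and the intervals are `NULL`.
#' @export
detect_inverted_repeat <- function(sequence, min_len = 1000,
                                   max_mismatch_frac = 0.01, seed_len = 24) {
  if (inherits(sequence, "plastome_record")) sequence <- sequence$sequence
  sequence <- toupper(sequence)
  n <- as.integer(nchar(sequence))
  if (n <= 2 * min_len)
    stop("sequence length must exceed 2 * min_len")
  sv <- strsplit(sequence, "")[[1]]
  cv <- unname(.comp_base[sv])
  cv[is.na(cv)] <- "N"

  absent <- structure(list(found = FALSE, lsc = NULL, ssc = NULL,
                           ira = NULL, irb = NULL, ir_length = 0L,
                           lsc_length = NA_integer_, ssc_length = NA_integer_,
                           genome_length = n),
                      class = "quadripartite_structure")

  # seeds sampled densely enough that any repeat >= min_len contains one
  stride <- max(1L, as.integer(min_len - seed_len))
  starts <- unique(c(seq(1L, n - seed_len + 1L, by = stride), n - seed_len + 1L))
  subj <- Biostrings::DNAString(sequence)
  pairs <- list()
  for (st in starts) {
    seed <- substr(sequence, st, st + seed_len - 1L)
    if (grepl("[^ACGT]", seed)) next
    rc <- .revcomp(seed)
    hits <- Biostrings::matchPattern(rc, subj)
    for (h in seq_along(hits)) {
      hs <- Biostrings::start(hits)[h]
      # forward copy [st, st+k), partner [hs, hs+k) equals its revcomp
      if (hs == st) next
      a <- min(st, hs); b <- max(st, hs)
      pairs[[length(pairs) + 1L]] <- c(a, b)
    }
  }
  if (!length(pairs)) return(absent)
  pairs <- unique(pairs)
  # seed pairs arising from the same repeat share an anti-diagonal (a + b
  # constant, substitutions do not shift it): extend one seed per diagonal
  diags <- vapply(pairs, sum, 0)
  pairs <- pairs[!duplicated(diags)]

  wrap <- function(i) ((i - 1L) %% n) + 1L
  extend <- function(a, b) {
    # a..a+k-1 pairs with b..b+k-1 (reverse complementary): position a+i
    # matches complement of b+k-1-i. Extend left end of A with right end of
    # B, and right end of A with left end of B.
    k <- seed_len
    a1 <- a; a2 <- a + k - 1L; b1 <- b; b2 <- b + k - 1L
    mism <- 0L
    budget <- function(len) floor(max_mismatch_frac * len)
    # extend outward: A right / B left
    repeat {
      extended <- FALSE
      na2 <- wrap(a2 + 1L); nb1 <- wrap(b1 - 1L)
      len <- (a2 - a1 + 1L)
      if (na2 != b1 && wrap(b1 - 1L) != a2 && len < n %/% 2) {
        ok <- sv[na2] == cv[nb1]
        if (ok || mism + 1L <= budget(len + 1L)) {
          if (!ok) mism <- mism + 1L
          a2 <- a2 + 1L; b1 <- b1 - 1L
          extended <- TRUE
        }
      }
      na1 <- wrap(a1 - 1L); nb2 <- wrap(b2 + 1L)
      len <- (a2 - a1 + 1L)
      if (wrap(a1 - 1L) != b2 && wrap(b2 + 1L) != a1 && len < n %/% 2) {
        ok <- sv[na1] == cv[nb2]
        if (ok || mism + 1L <= budget(len + 1L)) {
          if (!ok) mism <- mism + 1L
          a1 <- a1 - 1L; b2 <- b2 + 1L
          extended <- TRUE
        }
      }
      if (!extended) break
    }
    c(a1 = a1, a2 = a2, b1 = b1, b2 = b2)
  }

  cands <- lapply(pairs, function(p) extend(as.integer(p[1]), as.integer(p[2])))
  lens <- vapply(cands, function(x) unname(x["a2"] - x["a1"] + 1L), 0)
  keep <- lens >= min_len
  if (!any(keep)) return(absent)
  cands <- cands[keep]; lens <- lens[keep]
  # deduplicate by extended coordinates (normalized mod n)
  key <- vapply(cands, function(x)
    paste(wrap(x["a1"]), wrap(x["b1"]), sep = ":"), "")
  first <- !duplicated(key)
  cands <- cands[first]; lens <- lens[first]
  best_len <- max(lens)
  best <- cands[lens == best_len]
  # collapse symmetric duplicates (A,B) vs (B,A-ish from other seed)
  norm <- unique(lapply(best, function(x) {
    iv <- rbind(c(wrap(x["a1"]), wrap(x["a2"])),
                c(wrap(x["b1"]), wrap(x["b2"])))
    iv[order(iv[, 1]), , drop = FALSE]
  }))
  if (length(norm) > 1)
    stop("multiple inverted-repeat pairs tie at length ", best_len,
         "; refusing to guess (candidate starts: ",
         paste(vapply(norm, function(m) m[1, 1], 1), collapse = ", "), ")")
  m <- norm[[1]]
  # 0-based half-open
  ivA <- c(m[1, 1] - 1L, m[1, 2])
  ivB <- c(m[2, 1] - 1L, m[2, 2])

  arc <- function(from_end, to_start) {
    s <- from_end %% n; e <- to_start %% n
    c(s, e)
  }
  arc1 <- arc(ivA[2], ivB[1])   # between A end and B start
  arc2 <- arc(ivB[2], ivA[1])   # between B end and A start (may wrap)
  l1 <- .interval_len(arc1, n); l2 <- .interval_len(arc2, n)
  if (l1 >= l2) {
    lsc <- arc1; ssc <- arc2; irb <- ivB; ira <- ivA
  } else {
    lsc <- arc2; ssc <- arc1; irb <- ivA; ira <- ivB
  }
  # IRb is the copy adjacent to the LSC's downstream end: the copy whose
  # start equals the LSC end -- enforced by construction above (lsc ends at
  # irb start)
  structure(list(found = TRUE,
                 lsc = as.integer(unname(lsc)), ssc = as.integer(unname(ssc)),
                 ira = as.integer(unname(ira)), irb = as.integer(unname(irb)),
                 ir_length = as.integer(best_len),
                 lsc_length = as.integer(.interval_len(lsc, n)),
                 ssc_length = as.integer(.interval_len(ssc, n)),
                 genome_length = n),
            class = "quadripartite_structure")
}

#' @export
print.quadripartite_structure <- function(x, ...) {
  if (!x$found) {
    cat("no inverted repeat found\n")
    return(invisible(x))
  }
  cat(sprintf("quadripartite structure: LSC %d bp | IR %d bp x2 | SSC %d bp (genome %d bp)\n",
              x$lsc_length, x$ir_length, x$ssc_length, x$genome_length))
  invisible(x)
}

.extract_interval <- function(sequence, iv) {
  n <- nchar(sequence)
  if (iv[1] <= iv[2]) substr(sequence, iv[1] + 1, iv[2])
  else paste0(substr(sequence, iv[1] + 1, n), substr(sequence, 1, iv[2]))
}

.in_interval <- function(pos, iv, n) {
  # pos 0-based; iv 0-based half-open possibly wrapping
  if (iv[1] <= iv[2]) pos >= iv[1] & pos < iv[2]
  else pos >= iv[1] | pos < iv[2]
}

#' Standardize the orientation of the SSC region
#'
#' Plastome assemblies occur with the small single-copy region in either
#' orientation; comparative work requires a consistent choice. If the anchor
#' gene (default `ndhF`) lies on the minus strand, the SSC segment is
#' reverse-complemented in place and the coordinates and strands of all
#' features inside the SSC are remapped. Idempotent.
#'
#' @param record A [plastome_record()].
#' @param structure A `quadripartite_structure` for `record`.
#' @param anchor_gene Gene whose plus-strand orientation defines the
#'   standard (must lie inside the SSC).
#' @return The (possibly reoriented) record.
#' @export
standardize_ssc_orientation <- function(record, structure,
                                        anchor_gene = "ndhF") {
  stopifnot(inherits(record, "plastome_record"),
            inherits(structure, "quadripartite_structure"))
  if (!structure$found) stop("no structure found; cannot standardize")
  n <- record$length
  f <- .get_feature(record, anchor_gene)
  inside <- all(.in_interval(as.vector(f$segments), structure$ssc, n) |
                  as.vector(f$segments) == structure$ssc[2])
  if (!inside)
    stop("anchor gene '", anchor_gene, "' does not lie within the SSC (",
         structure$ssc[1], "..", structure$ssc[2], ")")
  if (f$strand == "+") return(record)

  ssc <- structure$ssc
  if (ssc[1] > ssc[2])
    stop("SSC wraps the origin; rotate the record before standardizing")
  s <- ssc[1]; e <- ssc[2]
  seq <- record$sequence
  new_seq <- paste0(substr(seq, 1, s), .revcomp(substr(seq, s + 1, e)),
                    substr(seq, e + 1, n))
  feats <- lapply(record$features, function(g) {
    segs <- g$segments
    ins <- .in_interval(segs[, 1], ssc, n)
    if (!any(ins)) return(g)
    if (!all(ins))
      stop("feature '", g$gene_name, "' straddles the SSC boundary")
    ns <- s + e - segs[, 2]
    ne <- s + e - segs[, 1]
    g$segments <- matrix(as.integer(c(rev(ns), rev(ne))), ncol = 2,
                         dimnames = list(NULL, c("start", "end")))
    g$strand <- if (g$strand == "+") "-" else "+"
    g
  })
  plastome_record(record$id, new_seq, feats, record$is_circular)
}

#' Summarize a plastome record
#'
#' One table row of genome metrics: total length, IR/LSC/SSC lengths (from
#' [detect_inverted_repeat()] unless a structure is supplied) and counts of
#' distinct gene names by kind, excluding models flagged as pseudogene
#' annotations.
#'
#' @param record A [plastome_record()].
#' @param structure Optional precomputed `quadripartite_structure`.
#' @param ... Passed to [detect_inverted_repeat()].
#' @return A one-row data.frame.
#' @export
genome_summary <- function(record, structure = NULL, ...) {
  stopifnot(inherits(record, "plastome_record"))
  if (is.null(structure))
    structure <- tryCatch(detect_inverted_repeat(record$sequence, ...),
                          error = function(e) NULL)
  count_kind <- function(k) {
    length(unique(.feature_names(record, k)))
  }
  data.frame(
    id = record$id,
    total_length = record$length,
    ir_length = if (!is.null(structure) && structure$found)
      structure$ir_length else NA_integer_,
    lsc_length = if (!is.null(structure) && structure$found)
      structure$lsc_length else NA_integer_,
    ssc_length = if (!is.null(structure) && structure$found)
      structure$ssc_length else NA_integer_,
    protein_coding = count_kind("protein_coding"),
    tRNA = count_kind("tRNA"),
    rRNA = count_kind("rRNA"),
    pseudogene_annotation = count_kind("pseudogene_annotation"),
    stringsAsFactors = FALSE
  )
}
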