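# Annotated plastome records: a minimal single-record GenBank flat-file
# reader/writer, spliced CDS extraction with circular and strand semantics,
# FASTA round trips, and degradation-report serialization.
#
# Internal coordinates are 0-based half-open on the forward strand.
# Circularity is represented by allowing a feature's segment list to wrap
# the origin (a location crossing the origin becomes two segments); the
# sequence itself is never doubled.

#' Construct a gene model
#'
#' @param gene_name Non-empty gene name.
#' @param kind One of `"protein_coding"`, `"tRNA"`, `"rRNA"`,
#'   `"pseudogene_annotation"`.
#' @param segments Integer matrix with columns `start`, `end` (0-based,
#'   half-open), ordered in transcription direction.
#' @param strand `"+"` or `"-"`.
#' @param codon_start_offset 0, 1 or 2: bases to skip before the first
#'   complete codon.
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(gene_name, kind, segments, strand = "+",
                       codon_start_offset = 0L) {
  stopifnot(nzchar(gene_name),
            kind %in% c("protein_coding", "tRNA", "rRNA",
                        "pseudogene_annotation"),
            strand %in% c("+", "-"),
            codon_start_offset %in% 0:2)
  segments <- matrix(as.integer(segments), ncol = 2,
                     dimnames = list(NULL, c("start", "end")))
  if (any(segments[, 2] <= segments[, 1]))
    stop("gene model '", gene_name, "': empty or inverted segment")
  structure(list(gene_name = gene_name, kind = kind, segments = segments,
                 strand = strand,
                 codon_start_offset = as.integer(codon_start_offset)),
            class = "gene_model")
}

#' Construct a plastome record
#'
#' @param id Accession or name.
#' @param sequence IUPAC DNA string.
#' @param features List of [gene_model()] objects.
#' @param is_circular Logical topology flag.
#' @return Object of class `plastome_record` with fields `id`, `sequence`,
#'   `length`, `features`, `is_circular`.
#' @export
plastome_record <- function(id, sequence, features = list(),
                            is_circular = TRUE) {
  sequence <- toupper(as.character(sequence))
  len <- nchar(sequence)
  for (f in features) {
    stopifnot(inherits(f, "gene_model"))
    if (any(f$segments < 0) || any(f$segments > len))
      stop("feature '", f$gene_name, "' has endpoints outside [0, ", len, "]")
  }
  structure(list(id = id, sequence = sequence, length = len,
                 features = features, is_circular = isTRUE(is_circular)),
            class = "plastome_record")
}

#' @export
print.plastome_record <- function(x, ...) {
  kinds <- vapply(x$features, `[[`, "", "kind")
  cat(sprintf("plastome record '%s': %s bp (%s), %d features\n", x$id,
              format(x$length, big.mark = ","),
              if (x$is_circular) "circular" else "linear", length(kinds)))
  if (length(kinds)) print(table(kinds))
  invisible(x)
}

.feature_names <- function(record, kind = NULL) {
  f <- record$features
  if (!is.null(kind)) f <- Filter(function(g) g$kind %in% kind, f)
  vapply(f, `[[`, "", "gene_name")
}

.get_feature <- function(record, gene_name, kind = NULL) {
  nm <- .feature_names(record, kind)
  f <- record$features
  if (!is.null(kind)) f <- Filter(function(g) g$kind %in% kind, f)
  i <- which(nm == gene_name)
  if (!length(i))
    stop("gene '", gene_name, "' not found; available: ",
         paste(sort(unique(.feature_names(record))), collapse = ", "))
  f[[i[1]]]
}

# ---- GenBank location strings -------------------------------------------

.parse_span <- function(txt, len, circular) {
  txt <- gsub("[<>]", "", txt)
  if (grepl("\\.\\.", txt)) {
    ab <- suppressWarnings(as.numeric(strsplit(txt, "\\.\\.")[[1]]))
  } else {
    ab <- suppressWarnings(rep(as.numeric(txt), 2))
  }
  if (anyNA(ab)) stop("malformed location span '", txt, "'")
  a <- ab[1]; b <- ab[2]
  if (a <= b) return(matrix(c(a - 1, b), ncol = 2))
  if (!circular) stop("descending span '", txt, "' in a linear record")
  # single span crossing the origin -> two segments
  rbind(c(a - 1, len), c(0, b))
}

.parse_location <- function(loc, len, circular, feature_label) {
  loc <- gsub("\\s", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc)) {
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  }
  parts <- strsplit(loc, ",")[[1]]
  if (!length(parts) || any(!nzchar(parts)))
    stop("malformed location for feature '", feature_label, "'")
  segs <- do.call(rbind, lapply(parts, function(p) {
    tryCatch(.parse_span(p, len, circular),
             error = function(e) stop("feature '", feature_label, "': ",
                                      conditionMessage(e), call. = FALSE))
  }))
  if (strand == "-") segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
  list(segments = segs, strand = strand)
}

.format_location <- function(model, len) {
  segs <- model$segments
  if (model$strand == "-") segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
  # merge an origin wrap back into a descending single span when the two
  # parse-time halves are adjacent at the origin
  spans <- sprintf("%d..%d", segs[, 1] + 1, segs[, 2])
  body <- if (length(spans) > 1) paste0("join(", paste(spans, collapse = ","), ")")
          else spans
  if (model$strand == "-") paste0("complement(", body, ")") else body
}

# ---- GenBank flat file ---------------------------------------------------

#' Read a single-record GenBank flat file
#'
#' Parses the LOCUS line (length and circular/linear topology), the CDS,
#' tRNA and rRNA features (with `join`, `complement` and origin-spanning
#' locations) and the ORIGIN sequence. Coordinates are converted from the
#' file's 1-based inclusive dialect to the package's 0-based half-open
#' internal convention. Features flagged `/pseudo` become kind
#' `"pseudogene_annotation"`.
#'
#' @param path Path to a GenBank flat file containing exactly one record.
#' @return A [plastome_record()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines)
  if (length(locus) != 1)
    stop("expected exactly one record in '", path, "', found ",
         length(locus), " LOCUS lines")
  toks <- strsplit(trimws(lines[locus]), "\\s+")[[1]]
  id <- toks[2]
  len <- suppressWarnings(as.integer(toks[3]))
  circular <- "circular" %in% tolower(toks)
  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(ostart)) stop("no ORIGIN section in '", path, "'")
  seq_lines <- lines[(ostart[1] + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[0-9 ]", "", paste(seq_lines, collapse = "")))
  if (!is.na(len) && nchar(sequence) != len)
    stop("LOCUS length ", len, " != sequence length ", nchar(sequence))

  features <- list()
  if (length(fstart)) {
    flines <- lines[(fstart[1] + 1):(ostart[1] - 1)]
    is_key <- grepl("^ {2,10}\\S", flines) & !grepl("^ {12,}", flines)
    idx <- which(is_key)
    for (k in seq_along(idx)) {
      block <- flines[idx[k]:(if (k < length(idx)) idx[k + 1] - 1 else length(flines))]
      key <- sub("^\\s*(\\S+).*", "\\1", block[1])
      if (!key %in% c("CDS", "tRNA", "rRNA")) next
      body <- sub("^\\s*\\S+\\s*", "", block[1])
      rest <- trimws(block[-1])
      qual_at <- grepl("^/", rest)
      if (any(!qual_at) && length(rest))  # location continuation lines
        body <- paste0(body, paste(rest[!qual_at], collapse = ""))
      quals <- rest[qual_at]
      gene <- sub('^/gene="?([^"]*)"?$', "\\1",
                  grep("^/gene=", quals, value = TRUE)[1])
      if (is.na(gene))
        gene <- sub('^/locus_tag="?([^"]*)"?$', "\\1",
                    grep("^/locus_tag=", quals, value = TRUE)[1])
      if (is.na(gene) || !nzchar(gene)) next
      pseudo <- any(grepl("^/pseudo\\b", quals))
      cs <- grep("^/codon_start=", quals, value = TRUE)
      offset <- if (length(cs)) as.integer(sub("^/codon_start=", "", cs[1])) - 1L else 0L
      loc <- .parse_location(body, nchar(sequence), circular, gene)
      kind <- if (pseudo) "pseudogene_annotation"
              else switch(key, CDS = "protein_coding", tRNA = "tRNA",
                          rRNA = "rRNA")
      features[[length(features) + 1]] <-
        gene_model(gene, kind, loc$segments, loc$strand, offset)
    }
  }
  plastome_record(id, sequence, features, circular)
}

#' Write a plastome record as a GenBank flat file
#'
#' Inverse of [read_genbank()] for the feature types the package models;
#' `read_genbank(write_genbank(x))` reproduces `x`.
#'
#' @param record A [plastome_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  len <- record$length
  out <- c(sprintf("LOCUS       %s %d bp    DNA     %s PLN",
                   record$id, len,
                   if (record$is_circular) "circular" else "linear"),
           sprintf("DEFINITION  %s plastome record.", record$id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", len))
  for (f in record$features) {
    key <- switch(f$kind, protein_coding = "CDS",
                  pseudogene_annotation = "CDS", tRNA = "tRNA", rRNA = "rRNA")
    out <- c(out,
             sprintf("     %-16s%s", key, .format_location(f, len)),
             sprintf('                     /gene="%s"', f$gene_name))
    if (f$codon_start_offset > 0)
      out <- c(out, sprintf("                     /codon_start=%d",
                            f$codon_start_offset + 1L))
    if (f$kind == "pseudogene_annotation")
      out <- c(out, "                     /pseudo")
  }
  out <- c(out, "ORIGIN")
  s <- tolower(record$sequence)
  for (i in seq(1, len, 60)) {
    chunk <- substr(s, i, min(i + 59, len))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", i, paste(tens, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

# ---- sequence extraction -------------------------------------------------

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Extract the spliced coding sequence of a gene
#'
#' Concatenates the model's segments in transcription order,
#' reverse-complementing minus-strand segments, handles origin wraps, and
#' drops `codon_start_offset` leading bases.
#'
#' @param record A [plastome_record()].
#' @param gene_name Gene to extract.
#' @param kind Feature kinds to search (default: any).
#' @return DNA string (character scalar).
#' @export
extract_cds <- function(record, gene_name, kind = NULL) {
  f <- .get_feature(record, gene_name, kind)
  parts <- apply(f$segments, 1, function(seg)
    substr(record$sequence, seg[1] + 1, seg[2]))
  if (f$strand == "-") parts <- vapply(parts, .revcomp, "")
  cds <- paste(parts, collapse = "")
  if (f$codon_start_offset > 0)
    cds <- substr(cds, f$codon_start_offset + 1, nchar(cds))
  cds
}

#' Translate a coding sequence under the plastid/bacterial code
#'
#' Translation table 11 (configurable); codons containing ambiguity codes
#' translate to `"X"`; trailing incomplete codons are dropped.
#'
#' @param dna DNA string.
#' @param table Genetic code table identifier for
#'   [Biostrings::getGeneticCode()].
#' @return Amino-acid string (with `*` for stops).
#' @export
translate_cds <- function(dna, table = "11") {
  n <- nchar(dna) - nchar(dna) %% 3
  if (n < 3) return("")
  aa <- Biostrings::translate(Biostrings::DNAString(substr(dna, 1, n)),
                              genetic.code = Biostrings::getGeneticCode(table),
                              if.fuzzy.codon = "X")
  as.character(aa)
}

# ---- FASTA ---------------------------------------------------------------

#' Read/write FASTA sequences
#'
#' Thin wrappers over Biostrings giving named character vectors, round-trip
#' safe (`read_fasta(write_fasta(x)) == x`).
#'
#' @param x Named character vector of DNA sequences (write).
#' @param path File path.
#' @return `read_fasta`: named character vector; `write_fasta`: `path`,
#'   invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(is.character(x))
  if (length(x) && (is.null(names(x)) || any(!nzchar(names(x)))))
    stop("sequences must be named")
  set <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

# ---- reports -------------------------------------------------------------

#' Write a degradation report as JSON and TSV
#'
#' Serializes a [scan_genome()] report: a versioned JSON document plus a
#' per-gene TSV with one verdict row per gene mirroring the event table
#' layout (gene, verdict, event kind, position, detail).
#'
#' @param report A `degradation_report`.
#' @param json_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisible list of written paths.
#' @export
write_report <- function(report, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(report, "degradation_report"))
  written <- list()
  if (!is.null(json_path)) {
    doc <- list(schema = "plastidDecay/degradation-report/1",
                focal_id = report$focal_id,
                genes = lapply(report$genes, function(g)
                  list(verdict = g$verdict, events = g$events)))
    jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    written$json <- json_path
  }
  if (!is.null(tsv_path)) {
    tab <- report_table(report)
    utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written$tsv <- tsv_path
  }
  invisible(written)
}

#' Tabulate a degradation report
#'
#' @param report A `degradation_report`.
#' @return data.frame with columns gene, verdict, n_events, event_kinds,
#'   positions, details (one row per gene).
#' @export
report_table <- function(report) {
  stopifnot(inherits(report, "degradation_report"))
  rows <- lapply(names(report$genes), function(g) {
    gg <- report$genes[[g]]
    ev <- gg$events
    data.frame(gene = g, verdict = gg$verdict, n_events = length(ev),
               event_kinds = paste(vapply(ev, `[[`, "", "kind"),
                                   collapse = ";"),
               positions = paste(vapply(ev, function(e)
                 as.character(e$position), ""), collapse = ";"),
               details = paste(vapply(ev, `[[`, "", "detail"),
                               collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
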