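# Alignment summary statistics and the comparative tests: one-sample
# one-tailed t of a focal value against a panel, and plastid read-fraction
# computation from mapped-read summaries.

#' Alignment summary statistics
#'
#' Length, gap fraction, and the number of parsimony-informative columns.
#' A column is parsimony-informative iff at least two distinct non-gap,
#' non-ambiguous nucleotide states each occur in at least two sequences;
#' gaps (`-`, `?`) are treated as missing and IUPAC ambiguity codes are
#' excluded from state counts.
#'
#' @param alignment Named character vector of equal-length aligned
#'   sequences, or a path to an aligned FASTA file.
#' @return List of class `alignment_stats`: `length`, `n_seq`,
#'   `gap_fraction`, `parsimony_informative`.
#' @export
alignment_stats <- function(alignment) {
  if (length(alignment) == 1 && nchar(alignment[[1]]) < 500 &&
      file.exists(alignment[[1]]))
    alignment <- read_fasta(alignment[[1]])
  lens <- unique(nchar(alignment))
  if (length(lens) != 1) stop("ragged alignment: row lengths ",
                              paste(lens, collapse = ", "))
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  gapset <- c("-", "?")
  gap_fraction <- mean(mat %in% gapset)
  good <- c("A", "C", "G", "T")
  informative <- 0L
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    col <- col[col %in% good]
    if (length(col) < 4) next
    tab <- table(col)
    if (sum(tab >= 2) >= 2) informative <- informative + 1L
  }
  structure(list(length = lens, n_seq = nrow(mat),
                 gap_fraction = gap_fraction,
                 parsimony_informative = informative),
            class = "alignment_stats")
}

#' @export
print.alignment_stats <- function(x, ...) {
  cat(sprintf("alignment: %d seqs x %d columns; gap fraction %.3f; %d parsimony-informative\n",
              x$n_seq, x$length, x$gap_fraction, x$parsimony_informative))
  invisible(x)
}

#' One-tailed one-sample t-test of a panel against a focal value
#'
#' Compares the mean of a panel of species-level values with a single focal
#' genome's value (a two-sample test with n = 1 on one side is undefined):
#' `t = (mean(panel) - focal) / (sd(panel)/sqrt(n))` referred to the t
#' distribution with n - 1 degrees of freedom, one-tailed in the stated
#' direction.
#'
#' @param panel_values Numeric vector, n >= 3, non-zero variance.
#' @param focal_value Focal scalar.
#' @param alternative `"panel_mean_greater"` (panel mean exceeds the focal
#'   value) or `"panel_mean_less"`.
#' @return List: `t`, `df`, `p`, `panel_mean`.
#' @export
one_tailed_t <- function(panel_values, focal_value,
                         alternative = c("panel_mean_greater",
                                         "panel_mean_less")) {
  alternative <- match.arg(alternative)
  n <- length(panel_values)
  if (n < 3) stop("need at least 3 panel values")
  s <- stats::sd(panel_values)
  if (s == 0) stop("zero panel variance")
  t <- (mean(panel_values) - focal_value) / (s / sqrt(n))
  p <- if (alternative == "panel_mean_greater")
    stats::pt(t, df = n - 1, lower.tail = FALSE)
  else stats::pt(t, df = n - 1, lower.tail = TRUE)
  list(t = t, df = n - 1L, p = p, panel_mean = mean(panel_values))
}

#' Percent of reads mapping to the plastid genome
#'
#' An indirect measure of plastid genome copy number relative to background
#' (mostly nuclear) DNA. Accepts either precomputed counts or a SAM file;
#' for SAM input, mapped reads are primary alignments with the unmapped
#' flag clear (secondary and supplementary records are excluded from both
#' numerator and denominator).
#'
#' @param counts List with `mapped_to_plastid` and `total_reads`, or `NULL`
#'   when `sam_path` is given.
#' @param sam_path Path to a SAM file of reads mapped to the plastid
#'   assembly.
#' @return Percent (0-100).
#' @export
plastid_read_fraction <- function(counts = NULL, sam_path = NULL) {
  if (is.null(counts)) {
    stopifnot(!is.null(sam_path))
    bam <- Rsamtools::asBam(sam_path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
    flags <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
      what = "flag",
      flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE)))[[1]]$flag
    total <- length(flags)
    mapped <- sum(bitwAnd(flags, 4L) == 0L)
    counts <- list(mapped_to_plastid = mapped, total_reads = total)
  }
  if (counts$total_reads <= 0) stop("total read count must be positive")
  100 * counts$mapped_to_plastid / counts$total_reads
}
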