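# Codon-state machinery shared by the likelihood, the simulator and F3x4.
# State space: the 61 sense codons of the plastid/bacterial genetic code
# (translation table 11), in fixed T/C/A/G-major enumeration order.

.pd_env <- new.env(parent = emptyenv())

.CODON_BASES <- c("T", "C", "A", "G")

#' Codon state kit for the plastid genetic code
#'
#' Returns the fixed enumeration of the 61 sense codons (translation table
#' 11), their amino acids, and 0/1 pair-classification matrices used to build
#' the Goldman-Yang rate matrix: single-nucleotide synonymous/nonsynonymous
#' transitions and transversions.
#'
#' @return A list with elements `codons` (character 61), `aa` (character 61),
#'   and 61 x 61 indicator matrices `syn_ts`, `syn_tv`, `non_ts`, `non_tv`.
#' @export
codon_kit <- function() {
  if (!is.null(.pd_env$kit)) return(.pd_env$kit)
  all64 <- apply(expand.grid(.CODON_BASES, .CODON_BASES, .CODON_BASES,
                             stringsAsFactors = FALSE)[, 3:1], 1, paste0,
                 collapse = "")
  code <- Biostrings::getGeneticCode("11")
  aa <- unname(code[all64])
  sense <- aa != "*"
  codons <- all64[sense]
  aa <- aa[sense]
  n <- length(codons)
  stopifnot(n == 61L)
  cmat <- do.call(rbind, strsplit(codons, ""))
  syn_ts <- syn_tv <- non_ts <- non_tv <- matrix(0, n, n)
  is_ts <- function(a, b) (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
  for (i in seq_len(n)) {
    diffs <- sweep(cmat, 2, cmat[i, ], FUN = "!=")
    ndiff <- rowSums(diffs)
    for (j in which(ndiff == 1L)) {
      pos <- which(diffs[j, ])
      ts <- is_ts(cmat[i, pos], cmat[j, pos])
      syn <- aa[i] == aa[j]
      if (syn && ts) syn_ts[i, j] <- 1
      else if (syn) syn_tv[i, j] <- 1
      else if (ts) non_ts[i, j] <- 1
      else non_tv[i, j] <- 1
    }
  }
  dimnames(syn_ts) <- dimnames(syn_tv) <- dimnames(non_ts) <-
    dimnames(non_tv) <- list(codons, codons)
  .pd_env$kit <- list(codons = codons, aa = aa, syn_ts = syn_ts,
                      syn_tv = syn_tv, non_ts = non_ts, non_tv = non_tv)
  .pd_env$kit
}

#' Goldman-Yang codon rate matrix
#'
#' Builds the 61 x 61 instantaneous rate matrix with q(i->j) proportional to
#' kappa * pi_j for synonymous transitions, pi_j for synonymous
#' transversions, omega * kappa * pi_j for nonsynonymous transitions and
#' omega * pi_j for nonsynonymous transversions; zero for multi-nucleotide
#' changes. Rows are normalized (when `normalize = TRUE`) so that one unit of
#' branch length equals one expected substitution per codon.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega dN/dS ratio (>= 0).
#' @param pi Codon frequency vector of length 61 summing to 1.
#' @param normalize Scale so that -sum(pi * diag(Q)) == 1.
#' @return 61 x 61 rate matrix with row names in `codon_kit()` order.
#' @export
codon_rate_matrix <- function(kappa, omega, pi, normalize = TRUE) {
  stopifnot(kappa > 0, omega >= 0, length(pi) == 61L, all(pi >= 0))
  kit <- codon_kit()
  M <- kappa * (kit$syn_ts + omega * kit$non_ts) +
    (kit$syn_tv + omega * kit$non_tv)
  Q <- sweep(M, 2, pi, `*`)
  diag(Q) <- -rowSums(Q)
  if (normalize) {
    rate <- -sum(pi * diag(Q))
    if (rate <= 0) stop("degenerate rate matrix: zero total rate")
    Q <- Q / rate
  }
  dimnames(Q) <- list(kit$codons, kit$codons)
  Q
}

#' Codon transition probability matrix
#'
#' `P(t) = exp(Q t)` computed through the symmetric eigendecomposition that
#' time reversibility of the model affords.
#'
#' @inheritParams codon_rate_matrix
#' @param t Branch length in expected substitutions per codon (>= 0).
#' @return 61 x 61 stochastic matrix.
#' @export
codon_P_matrix <- function(kappa, omega, pi, t) {
  stopifnot(t >= 0)
  Q <- codon_rate_matrix(kappa, omega, pi)
  sp <- sqrt(pi)
  S <- Q * outer(sp, 1 / sp)         # symmetric by reversibility
  S <- (S + t(S)) / 2                # guard rounding
  e <- eigen(S, symmetric = TRUE)
  P <- outer(1 / sp, sp) * (e$vectors %*% (exp(e$values * t) * t(e$vectors)))
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Empirical F3x4 codon frequencies
#'
#' Position-specific nucleotide frequencies are estimated from the observed
#' codons; each codon frequency is the product of its three positional
#' nucleotide frequencies, stop codons are dropped and the remainder
#' renormalized over the 61 sense codons.
#'
#' @param codon_states Integer matrix of codon states (1..61, NA = missing),
#'   as produced by [build_codon_alignment()], or a character vector of
#'   gapless in-frame DNA sequences.
#' @return Numeric vector of 61 codon frequencies summing to 1.
#' @export
f3x4_frequencies <- function(codon_states) {
  kit <- codon_kit()
  if (is.character(codon_states)) {
    cods <- unlist(lapply(codon_states, function(s) {
      s <- toupper(s)
      substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
    }))
    idx <- match(cods, kit$codons)
    idx <- idx[!is.na(idx)]
  } else {
    idx <- as.vector(codon_states)
    idx <- idx[!is.na(idx)]
  }
  if (!length(idx)) stop("no usable codons for F3x4 estimation")
  counts <- tabulate(idx, nbins = 61L)
  cmat <- do.call(rbind, strsplit(kit$codons, ""))
  f <- matrix(0, 3, 4, dimnames = list(NULL, .CODON_BASES))
  for (pos in 1:3) {
    for (b in .CODON_BASES) f[pos, b] <- sum(counts[cmat[, pos] == b])
  }
  f <- f / rowSums(f)
  # small floor keeps unseen states reachable (sparse alignments)
  f <- pmax(f, 1e-4)
  f <- f / rowSums(f)
  pi <- f[1, cmat[, 1]] * f[2, cmat[, 2]] * f[3, cmat[, 3]]
  unname(pi / sum(pi))
}
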