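# Branch-specific dN/dS machinery: codon alignments, the pruning
# log-likelihood, free-ratio and constrained ML fits, and the LRT for a
# shift in selective regime on a focal branch.

#' Build a codon alignment from aligned DNA sequences
#'
#' Applies the gene-matrix preparation rules used throughout the package:
#' ambiguously aligned columns are removed via `mask`, sequences with fewer
#' than `min_remaining` unmasked non-gap bases are dropped, and internal stop
#' codons (as occur in pseudogene sequences) are recoded as missing states so
#' the 61-state codon model can accept them. Codons containing gaps or
#' ambiguity characters are likewise treated as missing.
#'
#' @param sequences Named character vector of equal-length aligned DNA
#'   strings whose length is a multiple of 3 after masking.
#' @param min_remaining Minimum unmasked, non-gap bases a sequence must
#'   retain (default 200).
#' @param mask Optional logical vector over alignment columns; `TRUE` columns
#'   are removed. Must leave a multiple of 3.
#' @return An object of class `codon_alignment`: list with `taxa`, `states`
#'   (n_taxa x n_codons integer matrix, 1..61 or NA), `n_codons`, and
#'   `dropped` (names of removed sequences).
#' @export
build_codon_alignment <- function(sequences, min_remaining = 200,
                                  mask = NULL) {
  stopifnot(is.character(sequences), length(sequences) >= 1)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must be uniquely named")
  lens <- unique(nchar(sequences))
  if (length(lens) != 1) stop("aligned sequences must have equal length")
  chars <- do.call(rbind, strsplit(toupper(sequences), ""))
  if (!is.null(mask)) {
    if (length(mask) != lens) stop("mask length must equal alignment length")
    chars <- chars[, !mask, drop = FALSE]
  }
  if (ncol(chars) %% 3 != 0)
    stop("alignment length after masking must be a multiple of 3")
  gapset <- c("-", "?", ".")
  kept_bp <- apply(chars, 1, function(x) sum(!x %in% gapset))
  keep <- kept_bp >= min_remaining
  dropped <- names(sequences)[!keep]
  chars <- chars[keep, , drop = FALSE]
  if (nrow(chars) < 3)
    stop("fewer than 3 sequences survive filtering")
  kit <- codon_kit()
  n_cod <- ncol(chars) %/% 3
  states <- matrix(NA_integer_, nrow(chars), n_cod)
  for (i in seq_len(nrow(chars))) {
    s <- paste0(chars[i, ], collapse = "")
    cods <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
    idx <- match(cods, kit$codons)   # stops, gaps, ambiguity -> NA (missing)
    states[i, ] <- idx
  }
  structure(list(taxa = names(sequences)[keep], states = states,
                 n_codons = n_cod, dropped = dropped),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon alignment:", length(x$taxa), "taxa x", x$n_codons, "codons;",
      sum(is.na(x$states)), "missing codon states\n")
  invisible(x)
}

.aln_patterns <- function(states) {
  key <- apply(states, 2, paste0, collapse = ",")
  first <- !duplicated(key)
  w <- as.numeric(table(factor(key, levels = key[first])))
  sti <- states[, first, drop = FALSE]
  sti[is.na(sti)] <- 0L
  list(states = sti, weights = w)
}

.check_tree <- function(tree, taxa) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (!setequal(tree$tip.label, taxa))
    stop("tree tips do not match alignment taxa: missing ",
         paste(setdiff(taxa, tree$tip.label), collapse = ", "))
  ape::reorder.phylo(tree, "postorder")
}

.new_cache_tag <- function() {
  tag <- get0("cache_tag", envir = .pd_env, ifnotfound = 0L)
  tag <- (tag + 1L) %% .Machine$integer.max
  assign("cache_tag", tag, envir = .pd_env)
  tag
}

#' Codon-model log-likelihood by pruning
#'
#' Computes the log-likelihood of a codon alignment on a rooted tree under
#' the Goldman-Yang style model with per-branch dN/dS, using Felsenstein's
#' pruning algorithm over the 61 sense-codon states. Missing states are
#' marginalized. Branch lengths are in expected substitutions per codon.
#'
#' @param alignment A [build_codon_alignment()] object.
#' @param tree Rooted `phylo` tree whose tips match `alignment$taxa`.
#' @param params List with `kappa` (scalar), `pi` (61 frequencies), `omega`
#'   (scalar recycled, or one value per edge in `tree$edge` postorder
#'   order) and optionally `lengths` (per-edge, defaults to
#'   `tree$edge.length`).
#' @param .cache_tag Internal memoisation tag; leave default.
#' @return Log-likelihood (scalar).
#' @export
gy94_loglik <- function(alignment, tree, params, .cache_tag = NULL) {
  stopifnot(inherits(alignment, "codon_alignment"))
  tree <- .check_tree(tree, alignment$taxa)
  n_edge <- nrow(tree$edge)
  omega <- rep_len(params$omega, n_edge)
  lengths <- params$lengths
  if (is.null(lengths)) lengths <- tree$edge.length
  if (is.null(lengths)) stop("tree has no branch lengths")
  lengths <- rep_len(lengths, n_edge)
  pi <- params$pi
  stopifnot(length(pi) == 61L, params$kappa > 0, all(omega >= 0),
            all(lengths >= 0))
  ord <- match(tree$tip.label, alignment$taxa)
  pat <- .aln_patterns(alignment$states[ord, , drop = FALSE])
  kit <- codon_kit()
  if (is.null(.cache_tag)) .cache_tag <- .new_cache_tag()
  codon_loglik_cpp(pat$states, pat$weights, tree$edge,
                   length(tree$tip.label), pi, params$kappa, omega, lengths,
                   kit$syn_ts, kit$syn_tv, kit$non_ts, kit$non_tv,
                   as.integer(.cache_tag))
}

.focal_edges <- function(tree, focal_branch) {
  # focal_branch: a tip label (its pendant edge) or an edge index
  if (is.character(focal_branch)) {
    tip <- match(focal_branch, tree$tip.label)
    if (is.na(tip)) stop("focal tip '", focal_branch, "' not in tree")
    fe <- which(tree$edge[, 2] == tip)
  } else {
    fe <- as.integer(focal_branch)
    if (fe < 1 || fe > nrow(tree$edge)) stop("focal edge index out of range")
  }
  parent <- tree$edge[fe, 1]
  ae <- which(tree$edge[, 2] == parent)
  if (length(ae) == 0)
    stop("focal branch attaches to the root; no ancestral branch exists")
  c(focal = fe, ancestral = ae)
}

#' Fit a per-branch dN/dS codon model
#'
#' Maximum-likelihood fit of the free-ratio model (one omega per branch,
#' kappa and branch lengths estimated, codon frequencies fixed at their
#' F3x4 empirical values) or of the constrained model in which the focal
#' branch shares its omega with the branch immediately ancestral to it.
#' Optimization is quasi-Newton (L-BFGS-B) on log-transformed parameters
#' with bounds omega in [1e-6, 999], kappa in [1e-3, 100], t in [~0, 50],
#' with `n_starts` seeded starts.
#'
#' @param alignment A [build_codon_alignment()] object.
#' @param tree Rooted `phylo` with tips matching the alignment; its branch
#'   lengths (if any) seed the optimizer.
#' @param focal_branch Tip label or edge index of the focal branch.
#' @param constrained Logical; fit the constrained (shared-omega) model.
#' @param n_starts Number of optimizer starts (first deterministic, later
#'   ones jittered from `seed`).
#' @param seed Integer seed for the jittered starts.
#' @param pi Optional codon frequencies; default F3x4 from the alignment.
#' @return An object of class `codon_model_fit`: list with `loglik`,
#'   `kappa`, `omega` (per edge), `lengths` (per edge), `pi`, `tree`,
#'   `focal_edge`, `ancestral_edge`, `constrained`, `converged`.
#' @export
fit_branch_model <- function(alignment, tree, focal_branch,
                             constrained = FALSE, n_starts = 3, seed = 1,
                             pi = NULL, init = NULL) {
  stopifnot(inherits(alignment, "codon_alignment"))
  tree <- .check_tree(tree, alignment$taxa)
  fa <- .focal_edges(tree, focal_branch)
  n_edge <- nrow(tree$edge)
  if (is.null(pi)) pi <- f3x4_frequencies(alignment$states)
  ord <- match(tree$tip.label, alignment$taxa)
  pat <- .aln_patterns(alignment$states[ord, , drop = FALSE])
  kit <- codon_kit()
  tag <- .new_cache_tag()

  # omega parameter blocks: in the constrained model the focal edge shares
  # the ancestral edge's omega
  omega_group <- seq_len(n_edge)
  if (constrained) omega_group[fa["focal"]] <- fa["ancestral"]
  ogroups <- unique(omega_group)
  omap <- match(omega_group, ogroups)
  n_om <- length(ogroups)

  lb <- c(log(1e-3), rep(log(1e-6), n_om), rep(log(1e-8), n_edge))
  ub <- c(log(100), rep(log(999), n_om), rep(log(50), n_edge))

  nll <- function(par) {
    kappa <- exp(par[1])
    om <- exp(par[1 + seq_len(n_om)])[omap]
    tv <- exp(par[1 + n_om + seq_len(n_edge)])
    -codon_loglik_cpp(pat$states, pat$weights, tree$edge,
                      length(tree$tip.label), pi, kappa, om, tv,
                      kit$syn_ts, kit$syn_tv, kit$non_ts, kit$non_tv,
                      as.integer(tag))
  }

  t0 <- tree$edge.length
  if (is.null(t0)) t0 <- rep(0.1, n_edge)
  t0 <- pmin(pmax(t0, 1e-4), 40)
  base_start <- c(log(2), rep(log(0.2), n_om), log(t0))
  if (!is.null(init)) {
    om0 <- vapply(ogroups, function(g) {
      members <- which(omega_group == g)
      exp(mean(log(pmax(init$omega[members], 1e-6))))
    }, 1.0)
    base_start <- c(log(init$kappa), log(om0),
                    log(pmin(pmax(init$lengths, 1e-8), 50)))
    base_start <- pmin(pmax(base_start, lb), ub)
  }

  best <- NULL
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  for (s in seq_len(n_starts)) {
    start <- base_start
    if (s > 1) {
      set.seed(seed + 977L * s)
      start <- start + stats::rnorm(length(start), 0, 0.5)
      start <- pmin(pmax(start, lb), ub)
    }
    fit <- try(stats::optim(start, nll, method = "L-BFGS-B", lower = lb,
                            upper = ub, control = list(maxit = 500,
                                                       factr = 1e7)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value - 1e-9) best <- fit
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  if (is.null(best)) stop("all optimizer starts failed")
  par <- best$par
  omega <- exp(par[1 + seq_len(n_om)])[omap]
  structure(list(
    loglik = -best$value,
    kappa = exp(par[1]),
    omega = omega,
    lengths = exp(par[1 + n_om + seq_len(n_edge)]),
    pi = pi,
    tree = tree,
    focal_edge = unname(fa["focal"]),
    ancestral_edge = unname(fa["ancestral"]),
    constrained = constrained,
    converged = best$convergence == 0
  ), class = "codon_model_fit")
}

#' @export
print.codon_model_fit <- function(x, ...) {
  cat(sprintf("%s codon model fit: logL = %.4f (kappa = %.3f)\n",
              if (x$constrained) "constrained" else "full", x$loglik,
              x$kappa))
  cat(sprintf("  focal omega = %.4g, ancestral omega = %.4g%s\n",
              x$omega[x$focal_edge], x$omega[x$ancestral_edge],
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Likelihood-ratio test for a branch-specific shift in selection
#'
#' Compares the full (free-ratio) fit against the constrained fit in which
#' the focal branch shares omega with its ancestral branch;
#' `Lambda = 2 (l_full - l_constrained)` is referred to a chi-squared
#' distribution with 1 degree of freedom.
#'
#' @param full,constrained `codon_model_fit` objects on the same data.
#' @param tol Tolerance for the constrained likelihood exceeding the full
#'   likelihood before an optimizer fault is declared.
#' @return List of class `lrt_result`: `lambda`, `df`, `p`.
#' @export
lrt <- function(full, constrained, tol = 0.05) {
  stopifnot(inherits(full, "codon_model_fit"),
            inherits(constrained, "codon_model_fit"))
  if (constrained$constrained == full$constrained)
    stop("need one full and one constrained fit")
  if (full$constrained) { tmp <- full; full <- constrained; constrained <- tmp }
  d <- full$loglik - constrained$loglik
  if (d < -tol)
    stop(sprintf("constrained logL exceeds full logL by %.4g: optimizer fault",
                 -d))
  lambda <- max(0, 2 * d)
  structure(list(lambda = lambda, df = 1L,
                 p = stats::pchisq(lambda, df = 1, lower.tail = FALSE)),
            class = "lrt_result")
}

#' Test a focal branch for a shift in selective regime
#'
#' Convenience wrapper fitting the full and constrained models and running
#' [lrt()]. If the constrained optimum exceeds the full optimum (a local
#' maximum in the larger model), the full model is refit from the
#' constrained solution so the nesting inequality holds.
#'
#' @inheritParams fit_branch_model
#' @return List with `full`, `constrained`, `lrt`, `omega_focal`,
#'   `omega_ancestral`.
#' @export
test_branch_shift <- function(alignment, tree, focal_branch, n_starts = 3,
                              seed = 1) {
  full <- fit_branch_model(alignment, tree, focal_branch,
                           constrained = FALSE, n_starts = n_starts,
                           seed = seed)
  cons <- fit_branch_model(alignment, tree, focal_branch,
                           constrained = TRUE, n_starts = n_starts,
                           seed = seed)
  # cross-seeding: each model refit from the other's optimum, so that
  # neither test statistic carries optimizer noise from a poor local start
  cons2 <- fit_branch_model(alignment, tree, focal_branch,
                            constrained = TRUE, n_starts = 1, seed = seed,
                            pi = full$pi,
                            init = list(kappa = full$kappa,
                                        omega = full$omega,
                                        lengths = full$lengths))
  if (cons2$loglik > cons$loglik) cons <- cons2
  if (cons$loglik > full$loglik + 1e-8) {
    full2 <- fit_branch_model(alignment, tree, focal_branch,
                              constrained = FALSE, n_starts = 1, seed = seed,
                              pi = cons$pi,
                              init = list(kappa = cons$kappa,
                                          omega = cons$omega,
                                          lengths = cons$lengths))
    if (full2$loglik > full$loglik) full <- full2
    if (cons$loglik > full$loglik) {
      # accept the constrained solution as the full optimum (boundary case)
      full$loglik <- cons$loglik
      full$omega <- cons$omega
      full$lengths <- cons$lengths
      full$kappa <- cons$kappa
    }
  }
  res <- lrt(full, cons)
  list(full = full, constrained = cons, lrt = res,
       omega_focal = full$omega[full$focal_edge],
       omega_ancestral = full$omega[full$ancestral_edge])
}

#' Hochberg step-up p-value adjustment
#'
#' Step-up adjustment controlling the family-wise error rate: with ascending
#' p(1..m), adj(i) = min over j >= i of (m - j + 1) * p(j), capped at 1,
#' reported in the original order (via [stats::p.adjust]).
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
hochberg_adjust <- function(pvals) {
  if (!is.numeric(pvals) || any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must be numeric in [0, 1]")
  stats::p.adjust(pvals, method = "hochberg")
}
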