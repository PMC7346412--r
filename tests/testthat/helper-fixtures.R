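# Shared fixtures, built once per test run.

# small evolved panel used across modules
.fixture_env <- new.env()

fixture_panel <- function() {
  if (is.null(.fixture_env$syn))
    .fixture_env$syn <- build_synthetic_plastome(synthetic_config(seed = 42))
  .fixture_env$syn
}

# unrooted 4-taxon tree whose internal AB edge is the ancestral branch of
# the focal tip A
fixture_tree <- function() {
  ape::reorder.phylo(
    ape::read.tree(text = "((A:0.15,B:0.15):0.08,C:0.2,D:0.2);"),
    "postorder")
}

# write a GenBank flat file from raw lines, returning its path
write_gb_lines <- function(lines) {
  f <- tempfile(fileext = ".gb")
  writeLines(lines, f)
  f
}

toy_genbank <- function(sequence, features, circular = TRUE, id = "toy") {
  stopifnot(nchar(sequence) <= 60)
  c(sprintf("LOCUS       %s %d bp    DNA     %s PLN", id, nchar(sequence),
            if (circular) "circular" else "linear"),
    "FEATURES             Location/Qualifiers",
    unlist(lapply(features, function(f)
      c(sprintf("     %-16s%s", f$key, f$loc),
        sprintf('                     /gene="%s"', f$gene)))),
    "ORIGIN",
    sprintf("%9d %s", 1, tolower(sequence)),
    "//")
}

# brute-force codon log-likelihood: explicit summation over every joint
# assignment of internal-node states (vectorized over the enumeration
# grid), transition matrices from Matrix::expm -- fully independent of the
# pruning implementation
brute_force_loglik <- function(aln, tree, kappa, omega, pi) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ne <- nrow(tree$edge)
  om <- rep_len(omega, ne)
  Ps <- lapply(seq_len(ne), function(e)
    as.matrix(Matrix::expm(codon_rate_matrix(kappa, om[e], pi) *
                             tree$edge.length[e])))
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  states <- aln$states[match(tree$tip.label, aln$taxa), , drop = FALSE]
  grid <- as.matrix(expand.grid(rep(list(1:61), nnode)))
  node_state <- function(node, site) {
    if (node <= ntip) rep(states[node, site], nrow(grid))
    else grid[, node - ntip]
  }
  ll <- 0
  for (site in seq_len(ncol(states))) {
    pr <- pi[grid[, 1]]  # root = first internal node (ntip + 1)
    for (e in seq_len(ne)) {
      pn <- node_state(tree$edge[e, 1], site)
      cn <- node_state(tree$edge[e, 2], site)
      if (anyNA(cn)) next  # missing tip state: marginalizes to 1
      pr <- pr * Ps[[e]][cbind(pn, cn)]
    }
    ll <- ll + log(sum(pr))
  }
  ll
}
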