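test_that("codon alignments mask, drop short rows, and recode internal stops as missing", {
  syn <- fixture_panel()
  seqs <- vapply(names(syn$panel), function(nm)
    extract_cds(syn$panel[[nm]], "rbcL"), "")
  aln <- build_codon_alignment(seqs, min_remaining = 100)
  expect_s3_class(aln, "codon_alignment")
  expect_equal(length(aln$taxa), length(seqs))
  expect_equal(aln$n_codons, nchar(seqs[[1]]) / 3)

  # one row reduced below the threshold by masking is dropped
  n <- nchar(seqs[[1]])
  short <- seqs
  short[2] <- paste0(substr(short[2], 1, 150), strrep("-", n - 150))
  aln2 <- build_codon_alignment(short, min_remaining = 200)
  expect_false(names(seqs)[2] %in% aln2$taxa)
  expect_equal(aln2$dropped, names(seqs)[2])

  # internal stops become missing states, the row is retained
  stopped <- seqs
  substr(stopped[3], 31, 33) <- "TAA"
  substr(stopped[3], 61, 63) <- "TGA"
  aln3 <- build_codon_alignment(stopped, min_remaining = 100)
  expect_true(names(seqs)[3] %in% aln3$taxa)
  row <- match(names(seqs)[3], aln3$taxa)
  expect_true(is.na(aln3$states[row, 11]))
  expect_true(is.na(aln3$states[row, 21]))
  # the injected stops plus the terminal stop codon are all missing states
  expect_equal(sum(is.na(aln3$states[row, ])), 3)

  expect_error(build_codon_alignment(c(a = "ATGTAA", b = "ATGTAA"),
                                     min_remaining = 3),
               "fewer than 3")
})

test_that("zero branch lengths give the closed-form likelihood", {
  tr <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  set.seed(2)
  pi <- rexp(61); pi <- pi / sum(pi)
  kit <- codon_kit()
  states <- matrix(rep(sample.int(61, 20, TRUE, prob = pi), each = 3), 3)
  seqs <- apply(states, 1, function(s) paste(kit$codons[s], collapse = ""))
  names(seqs) <- c("A", "B", "C")
  aln <- build_codon_alignment(seqs, min_remaining = 1)
  ll <- gy94_loglik(aln, tr, list(kappa = 2, pi = pi, omega = 0.5))
  expect_equal(ll, sum(log(pi[states[1, ]])), tolerance = 1e-8)
})

test_that("pruning equals a 2-taxon matrix-exponential oracle to 1e-8", {
  set.seed(1)
  pi <- rexp(61); pi <- pi / sum(pi)
  kappa <- 2.5; om <- 0.4
  tr <- ape::read.tree(text = "(A:0.3,B:0.1);")
  kit <- codon_kit()
  for (s in list(c(5L, 17L), c(33L, 33L), c(61L, 1L))) {
    aln <- structure(list(taxa = c("A", "B"),
                          states = matrix(s, nrow = 2), n_codons = 1L),
                     class = "codon_alignment")
    ll <- gy94_loglik(aln, tr, list(kappa = kappa, pi = pi, omega = om))
    P1 <- as.matrix(Matrix::expm(codon_rate_matrix(kappa, om, pi) * 0.3))
    P2 <- as.matrix(Matrix::expm(codon_rate_matrix(kappa, om, pi) * 0.1))
    oracle <- log(sum(pi * P1[, s[1]] * P2[, s[2]]))
    expect_equal(ll, oracle, tolerance = 1e-8)
  }
})

test_that("pruning equals brute-force summation over internal states to 1e-8", {
  pi <- rep(1 / 61, 61)
  tr <- fixture_tree()
  sim <- simulate_codon_evolution(tr, list(kappa = 2, omega = 0.3, pi = pi),
                                  n_codons = 5, seed = 5)
  aln <- build_codon_alignment(sim$sequences, min_remaining = 1)
  ll <- gy94_loglik(aln, tr, list(kappa = 2, pi = pi, omega = 0.3))
  llb <- brute_force_loglik(aln, tr, 2, 0.3, pi)
  expect_equal(ll, llb, tolerance = 1e-8)

  # with per-branch omega and missing data
  aln$states[2, 2] <- NA
  om <- c(0.1, 0.5, 1.2, 0.3, 0.8)
  ll2 <- gy94_loglik(aln, tr, list(kappa = 3, pi = pi, omega = om))
  llb2 <- brute_force_loglik(aln, tr, 3, om, pi)
  expect_equal(ll2, llb2, tolerance = 1e-8)
})

test_that("the likelihood is invariant to root placement on random 5-taxon trees", {
  pi <- rep(1 / 61, 61)
  for (rep_i in 1:3) {
    set.seed(rep_i * 17)
    tr <- ape::rtree(5, rooted = TRUE)
    tr$tip.label <- paste0("t", 1:5)
    tr$edge.length <- runif(nrow(tr$edge), 0.02, 0.3)
    sim <- simulate_codon_evolution(tr, list(kappa = 2, omega = 0.4, pi = pi),
                                    n_codons = 30, seed = rep_i)
    aln <- build_codon_alignment(sim$sequences, min_remaining = 1)
    ll0 <- gy94_loglik(aln, tr, list(kappa = 2, pi = pi, omega = 0.4))
    ur <- ape::unroot(tr)
    for (node in c("t3", "t5")) {
      rr <- ape::root(ur, outgroup = node, resolve.root = FALSE)
      ll <- gy94_loglik(aln, rr, list(kappa = 2, pi = pi, omega = 0.4))
      expect_equal(ll, ll0, tolerance = 1e-6)
    }
  }
})

test_that("the LRT behaves at its trivial points and matches the chi-square oracle", {
  f1 <- structure(list(loglik = -100, constrained = FALSE), class = "codon_model_fit")
  f0 <- structure(list(loglik = -100, constrained = TRUE), class = "codon_model_fit")
  r <- lrt(f1, f0)
  expect_equal(r$lambda, 0)
  expect_equal(r$p, 1)
  f0b <- structure(list(loglik = -100 - 3.841459 / 2, constrained = TRUE),
                   class = "codon_model_fit")
  r2 <- lrt(f1, f0b)
  expect_equal(r2$p, 0.05, tolerance = 1e-4)
  f0c <- structure(list(loglik = -90, constrained = TRUE),
                   class = "codon_model_fit")
  expect_error(lrt(f1, f0c), "optimizer fault")
})

test_that("a strong simulated shift in omega is estimated and detected", {
  tr <- fixture_tree()
  pi <- rep(1 / 61, 61)
  fe <- which(tr$edge[, 2] == which(tr$tip.label == "A"))
  om <- rep(0.1, nrow(tr$edge)); om[fe] <- 5
  sim <- simulate_codon_evolution(tr, list(kappa = 2, omega = om, pi = pi),
                                  n_codons = 500, seed = 3)
  aln <- build_codon_alignment(sim$sequences, min_remaining = 1)
  shift <- test_branch_shift(aln, tr, "A", n_starts = 1, seed = 1)
  expect_gt(shift$omega_focal, shift$omega_ancestral)
  expect_gt(shift$lrt$lambda, 3.84)
  expect_lt(shift$lrt$p, 0.05)
})

test_that("under the null the constrained and full fits nearly coincide", {
  tr <- fixture_tree()
  pi <- rep(1 / 61, 61)
  sim <- simulate_codon_evolution(tr, list(kappa = 2, omega = 0.2, pi = pi),
                                  n_codons = 300, seed = 21)
  aln <- build_codon_alignment(sim$sequences, min_remaining = 1)
  shift <- test_branch_shift(aln, tr, "A", n_starts = 1, seed = 2)
  expect_lt(shift$lrt$lambda, qchisq(0.999, 1))
  expect_gte(shift$full$loglik, shift$constrained$loglik - 1e-6)
})

test_that("Hochberg adjustment matches hand-computed step-up values", {
  expect_equal(hochberg_adjust(0.03), 0.03)
  expect_equal(hochberg_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(hochberg_adjust(rep(0.05, 3)), rep(0.05, 3))
  # hand computation: ascending p = (.01,.02,.30); adj3 = .30,
  # adj2 = min(2*.02, .30) = .04, adj1 = min(3*.01, .04) = .03
  expect_equal(hochberg_adjust(c(0.30, 0.01, 0.02)), c(0.30, 0.03, 0.04))
  expect_true(all(hochberg_adjust(c(0.9, 0.95, 0.99)) <= 1))
  expect_error(hochberg_adjust(c(0.5, 1.2)), "in \\[0, 1\\]")
  p <- c(0.2, 0.01, 0.7)
  expect_true(all(hochberg_adjust(p) >= p))
})
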