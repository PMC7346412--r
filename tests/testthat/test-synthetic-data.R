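test_that("the simulator is deterministic and honors its degenerate limits", {
  tr <- fixture_tree()
  pi <- rep(1 / 61, 61)
  s1 <- simulate_codon_evolution(tr, list(kappa = 2, omega = 0.3, pi = pi),
                                 50, seed = 9)
  s2 <- simulate_codon_evolution(tr, list(kappa = 2, omega = 0.3, pi = pi),
                                 50, seed = 9)
  expect_identical(s1$sequences, s2$sequences)

  # omega = 0: no nonsynonymous events anywhere
  s0 <- simulate_codon_evolution(tr, list(kappa = 2, omega = 0, pi = pi),
                                 100, seed = 4)
  expect_equal(sum(s0$counts$n_nonsyn), 0)
  expect_gt(sum(s0$counts$n_syn), 0)

  # t = 0: all tips identical to each other (and no events)
  tr0 <- tr; tr0$edge.length[] <- 0
  sz <- simulate_codon_evolution(tr0, list(kappa = 2, omega = 0.3, pi = pi),
                                 40, seed = 4)
  expect_equal(length(unique(sz$sequences)), 1)
  expect_equal(sum(sz$counts$n_events), 0)
})

test_that("per-branch substitution counts track branch lengths", {
  # branch length is expected substitutions per codon; averaged over sites
  # and replicates the realized count should match within 3 standard errors
  tr <- fixture_tree()
  pi <- rep(1 / 61, 61)
  n_codons <- 400; reps <- 12
  per_edge <- matrix(0, reps, nrow(tr$edge))
  for (r in 1:reps) {
    s <- simulate_codon_evolution(tr, list(kappa = 2, omega = 0.25, pi = pi),
                                  n_codons, seed = 300 + r)
    per_edge[r, ] <- s$counts$n_events / n_codons
  }
  for (e in seq_len(nrow(tr$edge))) {
    m <- mean(per_edge[, e])
    se <- sd(per_edge[, e]) / sqrt(reps)
    expect_lt(abs(m - tr$edge.length[e]), 3 * se + 0.01,
              label = paste("edge", e))
  }
})

test_that("a long branch reaches stationarity in codon frequencies", {
  tr <- ape::read.tree(text = "(A:40,B:40);")
  set.seed(10)
  pi <- rexp(61) + 0.2; pi <- pi / sum(pi)
  s <- simulate_codon_evolution(tr, list(kappa = 2, omega = 1, pi = pi),
                                1500, seed = 12)
  counts <- tabulate(s$states[1, ], nbins = 61)
  gof <- suppressWarnings(chisq.test(counts, p = pi))  # sparse cells expected
  expect_gt(gof$p.value, 0.01)
})

test_that("synthetic plastome panels are seed-deterministic with planted structure", {
  cfg <- synthetic_config(seed = 123, n_taxa = 4)
  a <- build_synthetic_plastome(cfg)
  b <- build_synthetic_plastome(synthetic_config(seed = 123, n_taxa = 4))
  expect_identical(vapply(a$panel, `[[`, "", "sequence"),
                   vapply(b$panel, `[[`, "", "sequence"))
  expect_false(identical(
    a$panel[[1]]$sequence,
    build_synthetic_plastome(synthetic_config(seed = 124,
                                              n_taxa = 4))$panel[[1]]$sequence))
  st <- detect_inverted_repeat(a$panel[[1]]$sequence, max_mismatch_frac = 0)
  expect_equal(st$ir_length, cfg$ir_length)
  expect_equal(st$irb, a$structures[[1]]$irb)
  s <- genome_summary(a$panel[[1]], structure = st)
  expect_equal(s$protein_coding, nrow(cfg$genes))
})

test_that("injection ledgers record each event once and empty specs are no-ops", {
  syn <- fixture_panel()
  focal <- syn$panel[[3]]
  out0 <- inject_degradation(focal, NULL)
  expect_identical(out0$record$sequence, focal$sequence)
  expect_equal(nrow(out0$truth), 0)

  spec <- data.frame(gene = c("rbcL", "atpB"),
                     kind = c("large_deletion", "frameshift"),
                     len = c(150, 2))
  out <- inject_degradation(focal, spec, seed = 6)
  expect_equal(nrow(out$truth), 2)
  expect_equal(out$truth$gene, c("rbcL", "atpB"))
  expect_equal(nchar(out$record$sequence),
               nchar(focal$sequence) - 150 + 2)
  # downstream features shifted consistently: every CDS still extractable
  for (g in c("rbcL", "atpB", "ndhF"))
    expect_silent(extract_cds(out$record, g))
  # unknown kinds and genes error
  expect_error(inject_degradation(focal, data.frame(gene = "rbcL",
                                                    kind = "meteor")),
               "unknown injection kind")
  expect_error(inject_degradation(focal, data.frame(gene = "nope",
                                                    kind = "frameshift")),
               "not found")
})

test_that("each injected lesion is recovered by the scan with the correct kind", {
  syn <- fixture_panel()
  panel <- syn$panel[-2]
  focal <- syn$panel[[2]]
  expected_kind <- c(premature_stop = "premature_stop",
                     frameshift = "frameshift",
                     large_deletion = "large_deletion",
                     short_inversion = "short_inversion",
                     lost_stop = "lost_canonical_stop")
  genes <- c("ndhA", "ndhB", "ndhD", "ndhF", "ccsA")
  for (i in seq_along(expected_kind)) {
    kind <- names(expected_kind)[i]
    spec <- data.frame(gene = genes[i], kind = kind,
                       len = if (kind == "large_deletion") 150 else
                         if (kind == "short_inversion") 60 else
                           if (kind == "frameshift") 1 else NA)
    inj <- inject_degradation(focal, spec, seed = 40 + i)
    rep <- scan_genome(inj$record, panel)
    kinds <- vapply(rep$genes[[genes[i]]]$events, `[[`, "", "kind")
    expect_true(expected_kind[i] %in% kinds,
                label = paste(kind, "detected as", expected_kind[i]))
  }
})

test_that("random quadripartite fixtures satisfy their own construction", {
  g <- random_quadripartite(seed = 77, ir_length = 800, lsc_length = 4000,
                            ssc_length = 1200)
  expect_equal(nchar(g$sequence), 4000 + 1200 + 1600)
  irb <- substr(g$sequence, g$structure$irb[1] + 1, g$structure$irb[2])
  ira <- substr(g$sequence, g$structure$ira[1] + 1, g$structure$ira[2])
  expect_identical(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(irb))),
    ira)
})
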