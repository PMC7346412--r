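test_that("pairwise alignment is gapless on identical sequences and places single gaps correctly", {
  s <- "ATGAAACCCGGGTGGTAA"
  a0 <- align_gene_to_reference(s, s)
  expect_equal(a0$identity, 1)
  expect_false(grepl("-", a0$focal))

  ref <- paste0("ATG", strrep("AAACCCGGGTGG", 4), "TAA")
  foc3 <- paste0(substr(ref, 1, 12), substr(ref, 16, nchar(ref)))
  a3 <- align_gene_to_reference(foc3, ref)
  gaps <- gregexpr("-+", a3$focal)[[1]]
  expect_equal(length(gaps), 1)
  expect_equal(attr(gaps, "match.length"), 3)

  foc1 <- paste0(substr(ref, 1, 12), substr(ref, 14, nchar(ref)))
  a1 <- align_gene_to_reference(foc1, ref)
  gaps1 <- gregexpr("-+", a1$focal)[[1]]
  expect_equal(attr(gaps1, "match.length"), 1)
  n <- nchar(ref)
  expect_equal(a1$identity, (n - 1) / n)
})

test_that("a 1 bp deletion is reported as a frameshift with downstream stop loss", {
  ref <- "ATGAAACCCGGGTGGTAA"
  foc <- "ATGAAACCGGGTGGTAA"   # one C of codon 3 deleted
  aln <- align_gene_to_reference(foc, ref)
  ev <- detect_events(aln)
  kinds <- vapply(ev, `[[`, "", "kind")
  expect_true("frameshift" %in% kinds)
  expect_true("lost_canonical_stop" %in% kinds)
  fs <- ev[[which(kinds == "frameshift")[1]]]
  expect_true(fs$position >= 7 && fs$position <= 10)
})

test_that("identical focal and reference yield no events", {
  syn <- fixture_panel()
  cds <- extract_cds(syn$panel[[1]], "rbcL")
  expect_length(detect_events(align_gene_to_reference(cds, cds)), 0)
})

test_that("frameshift calls agree with construction truth on random indel fixtures", {
  syn <- fixture_panel()
  cds <- extract_cds(syn$panel[[1]], "ndhB")
  set.seed(99)
  n_checked <- 0
  for (i in 1:60) {
    k <- sample(1:6, 1)
    insert <- sample(c(TRUE, FALSE), 1)
    pos <- sample(30:(nchar(cds) - 60), 1)
    foc <- if (insert)
      paste0(substr(cds, 1, pos),
             paste(sample(c("A", "C", "G", "T"), k, TRUE), collapse = ""),
             substr(cds, pos + 1, nchar(cds)))
    else paste0(substr(cds, 1, pos), substr(cds, pos + k + 1, nchar(cds)))
    ev <- detect_events(align_gene_to_reference(foc, cds))
    kinds <- vapply(ev, `[[`, "", "kind")
    expect_equal("frameshift" %in% kinds, k %% 3 != 0,
                 info = sprintf("i=%d k=%d insert=%d pos=%d", i, k, insert, pos))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 60)
})

test_that("large deletions are reported per gap with their length", {
  syn <- fixture_panel()
  cds <- extract_cds(syn$panel[[1]], "ndhF")
  foc <- paste0(substr(cds, 1, 90), substr(cds, 240 + 1, nchar(cds)))
  ev <- detect_events(align_gene_to_reference(foc, cds))
  kinds <- vapply(ev, `[[`, "", "kind")
  expect_true("large_deletion" %in% kinds)
  del <- ev[[which(kinds == "large_deletion")[1]]]
  expect_equal(del$detail, "150")
  expect_false("frameshift" %in% kinds)  # 150 is frame-neutral
  # two 60 bp gaps do not sum to a large deletion (per-gap threshold)
  foc2 <- paste0(substr(cds, 1, 90), substr(cds, 151, 300),
                 substr(cds, 361, nchar(cds)))
  ev2 <- detect_events(align_gene_to_reference(foc2, cds))
  expect_false("large_deletion" %in% vapply(ev2, `[[`, "", "kind"))
})

test_that("a point-mutation stop is called premature without frameshift", {
  syn <- fixture_panel()
  focal <- syn$panel[[2]]
  inj <- inject_degradation(focal,
                            data.frame(gene = "ndhB",
                                       kind = "premature_stop"), seed = 5)
  ref_cds <- extract_cds(syn$panel[[1]], "ndhB")
  foc_cds <- extract_cds(inj$record, "ndhB")
  ev <- detect_events(align_gene_to_reference(foc_cds, ref_cds))
  kinds <- vapply(ev, `[[`, "", "kind")
  expect_true("premature_stop" %in% kinds)
  expect_false("frameshift" %in% kinds)
})

test_that("hydrophobic fraction is correct and order-invariant", {
  expect_equal(hydrophobic_fraction("LLLL"), 1.0)
  expect_equal(hydrophobic_fraction("KRKR"), 0.0)
  expect_equal(hydrophobic_fraction("LKLK"), 0.5)
  # stops and X excluded from the denominator
  expect_equal(hydrophobic_fraction("LKX*"), 0.5)
  expect_error(hydrophobic_fraction("X*"), "countable")
  set.seed(7)
  for (i in 1:20) {
    aa <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                       30, TRUE), collapse = "")
    perm <- paste(sample(strsplit(aa, "")[[1]]), collapse = "")
    expect_equal(hydrophobic_fraction(aa), hydrophobic_fraction(perm))
  }
})

test_that("hydrophobicity CI matches the t-quantile oracle and widens with level", {
  expect_equal(hydrophobicity_ci(c(0.5, 0.5, 0.5)), c(0.5, 0.5))
  ci <- hydrophobicity_ci(c(0.50, 0.52, 0.54), 0.95)
  expect_equal(ci, c(0.4703, 0.5697), tolerance = 1e-4)
  ci99 <- hydrophobicity_ci(c(0.50, 0.52, 0.54), 0.99)
  expect_lt(ci99[1], ci[1])
  expect_gt(ci99[2], ci[2])
  expect_error(hydrophobicity_ci(c(0.5, 0.6)), "at least 3")
})

test_that("annotation lift transfers genes with a constructed coordinate shift", {
  syn <- fixture_panel()
  ref <- syn$panel[[1]]
  # identical target: identical coordinates
  bare <- plastome_record("t0", ref$sequence)
  lifted <- annotate_by_homology(bare, ref)
  expect_equal(length(lifted$features), length(ref$features))
  for (i in seq_along(ref$features))
    expect_identical(lifted$features[[i]]$segments,
                     ref$features[[i]]$segments)
  # 500 bp inserted upstream of everything: every model shifts by +500
  shifted <- plastome_record("t5", paste0(strrep("ACGTT", 100),
                                          ref$sequence))
  lifted5 <- annotate_by_homology(shifted, ref)
  tab <- attr(lifted5, "lift")
  expect_true(all(tab$status == "transferred"))
  for (i in seq_along(ref$features))
    expect_identical(lifted5$features[[i]]$segments,
                     ref$features[[i]]$segments + 500L)
  # a diverged panel genome: all genes transferred at identity >= 0.70
  other <- plastome_record("t2", syn$panel[[4]]$sequence)
  lifted2 <- annotate_by_homology(other, ref)
  tab2 <- attr(lifted2, "lift")
  expect_true(all(tab2$status == "transferred"))
  expect_true(all(tab2$identity >= 0.70))
})

test_that("scan_genome flags exactly the injected genes and nothing else", {
  syn <- fixture_panel()
  focal <- syn$panel[[2]]
  panel <- syn$panel[-2]

  clean <- scan_genome(focal, panel)
  verdicts <- vapply(clean$genes, `[[`, "", "verdict")
  expect_equal(sum(verdicts == "pseudogene"), 0)
  structural <- c("premature_stop", "frameshift", "lost_canonical_stop",
                  "large_deletion", "short_inversion")
  for (g in names(clean$genes)) {
    kinds <- vapply(clean$genes[[g]]$events, `[[`, "", "kind")
    expect_length(intersect(kinds, structural), 0)
  }

  spec <- data.frame(
    gene = c("ndhA", "ndhB", "ndhD", "ndhF", "ndhK", "ccsA", "cemA"),
    kind = c("frameshift", "premature_stop", "large_deletion", "frameshift",
             "short_inversion", "frameshift", "large_deletion"),
    len = c(1, NA, 150, 2, 60, 1, 120))
  inj <- inject_degradation(focal, spec, seed = 11)
  rep1 <- scan_genome(inj$record, panel)
  v1 <- vapply(rep1$genes, `[[`, "", "verdict")
  expect_setequal(names(v1)[v1 == "pseudogene"],
                  c("ndhA", "ndhB", "ndhD", "ndhF", "ndhK", "ccsA", "cemA"))
  expect_error(scan_genome(focal, list()), "empty panel")
})

test_that("excluded boundary genes are not scanned for novel calls", {
  syn <- fixture_panel()
  cfg <- scan_config(excluded_genes = c("rbcL"))
  rep <- scan_genome(syn$panel[[2]], syn$panel[-2], cfg)
  expect_false("rbcL" %in% names(rep$genes))
})
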