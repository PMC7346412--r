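test_that("coverage classification encodes the orders-of-magnitude rule", {
  expect_equal(classify_origin(3, 500), "nuclear")
  expect_equal(classify_origin(500, 500), "organellar")
  expect_equal(classify_origin(50, 500), "ambiguous")    # exactly 0.1: strict
  expect_equal(classify_origin(0.1 * 500, 500), "ambiguous")
  expect_equal(classify_origin(49.99, 500), "nuclear")
  expect_error(classify_origin(3, 0), "positive")
  cg <- classify_origin(paralog_contig("c1", "ACGT", 2), 800)
  expect_s3_class(cg, "paralog_contig")
  expect_equal(cg$classification, "nuclear")
})

test_that("classification is scale-invariant", {
  set.seed(4)
  for (i in 1:25) {
    ck <- runif(1, 0, 2000); oc <- runif(1, 1, 2000)
    base <- classify_origin(ck, oc)
    for (s in c(0.01, 3, 1000))
      expect_equal(classify_origin(ck * s, oc * s), base)
  }
})

test_that("paralog screening labels stops shared with the plastid copy vs novel", {
  syn <- fixture_panel()
  focal <- syn$panel[[2]]
  inj <- inject_degradation(focal, data.frame(gene = "ndhB",
                                              kind = "premature_stop"),
                            seed = 5)
  ref_cds <- extract_cds(syn$panel[[1]], "ndhB")
  plastid_cds <- extract_cds(inj$record, "ndhB")
  plastid_events <- detect_events(align_gene_to_reference(plastid_cds,
                                                          ref_cds))

  # intact contig: no events
  expect_length(screen_paralog(ref_cds, ref_cds), 0)

  # contig carrying the same lesion as the plastid copy
  ev_shared <- screen_paralog(plastid_cds, ref_cds,
                              plastid_events = plastid_events)
  k <- vapply(ev_shared, `[[`, "", "kind")
  expect_true(any(k == "premature_stop"))
  expect_match(ev_shared[[which(k == "premature_stop")[1]]]$detail, "shared")

  # contig with a different stop
  other <- ref_cds
  ncod <- nchar(other) / 3
  ci <- ncod - 12
  substr(other, 3 * ci - 2, 3 * ci) <- "TAA"
  ev_novel <- screen_paralog(other, ref_cds, plastid_events = plastid_events)
  k2 <- vapply(ev_novel, `[[`, "", "kind")
  expect_true(any(k2 == "premature_stop"))
  expect_match(ev_novel[[which(k2 == "premature_stop")[1]]]$detail, "novel")

  # insufficient overlap is skipped with a diagnostic
  expect_warning(out <- screen_paralog(substr(ref_cds, 1, 60), ref_cds),
                 "skipped")
  expect_null(out)
})

test_that("screening the plastid copy itself reproduces the scan's structural events", {
  syn <- fixture_panel()
  focal <- syn$panel[[2]]
  inj <- inject_degradation(focal, data.frame(gene = "ndhD",
                                              kind = "large_deletion",
                                              len = 150), seed = 2)
  rep <- scan_genome(inj$record, syn$panel[-2])
  scan_kinds <- sort(vapply(rep$genes$ndhD$events, `[[`, "", "kind"))
  scan_kinds <- setdiff(scan_kinds, c("hydrophobicity_outlier",
                                      "length_anomaly", "novel_termination"))
  ref_cds <- extract_cds(syn$panel[[1]], "ndhD")
  ev <- screen_paralog(extract_cds(inj$record, "ndhD"), ref_cds)
  expect_setequal(vapply(ev, `[[`, "", "kind"), scan_kinds)
})

test_that("gene matrices trim contigs to the gene extent and drop short rows", {
  syn <- fixture_panel()
  plastid <- vapply(names(syn$panel), function(nm)
    extract_cds(syn$panel[[nm]], "ndhK"), "")
  full <- extract_cds(syn$panel[[1]], "ndhK")

  m <- prep_gene_matrix(plastid, list(full_contig = full))
  expect_equal(length(m), length(plastid) + 1)
  expect_equal(unique(nchar(m)), nchar(plastid[[1]]))
  expect_equal(m[["full_contig"]], plastid[[1]])

  # contig spanning 150 bp is dropped at the 200 bp rule
  short <- substr(full, 1, 150)
  expect_warning(m2 <- prep_gene_matrix(plastid, list(sc = short)),
                 "dropped")
  expect_false("sc" %in% names(m2))

  # 4 divergent paralog lineages all retained
  set.seed(8)
  paras <- lapply(1:4, function(i) {
    v <- strsplit(full, "")[[1]]
    mut <- sample(seq_along(v), round(0.1 * length(v)))
    v[mut] <- vapply(v[mut], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(v, collapse = "")
  })
  names(paras) <- paste0("para", 1:4)
  m3 <- prep_gene_matrix(plastid, paras)
  expect_true(all(paste0("para", 1:4) %in% names(m3)))

  # masked columns are removed from every row
  mask <- rep(FALSE, nchar(plastid[[1]])); mask[1:30] <- TRUE
  m4 <- prep_gene_matrix(plastid, list(full_contig = full), mask = mask)
  expect_equal(unique(nchar(m4)), nchar(plastid[[1]]) - 30)
})

test_that("ambiguous-region masking flags rearranged blocks, codon-aware", {
  syn <- fixture_panel()
  rows <- vapply(names(syn$panel)[1:4], function(nm)
    extract_cds(syn$panel[[nm]], "ndhB"), "")
  m0 <- mask_ambiguous_columns(rows)
  expect_false(any(m0))  # point substitutions alone are not ambiguous
  # scramble (reverse-complement) a 30 bp block of one row
  bad <- rows
  seg <- substr(bad[2], 91, 120)
  substr(bad[2], 91, 120) <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seg)))
  m1 <- mask_ambiguous_columns(bad)
  expect_true(any(m1[91:120]))
  expect_false(any(m1[1:60]))
  expect_false(any(m1[180:length(m1)]))
  # whole codons are masked
  flag <- colSums(matrix(m1, nrow = 3))
  expect_true(all(flag %in% c(0, 3)))
})

test_that("contig FASTA + coverage TSV round trips", {
  f <- tempfile(fileext = ".fa"); cv <- tempfile(fileext = ".tsv")
  write_fasta(c(c1 = "ACGTACGTACGT", c2 = "TTTTCCCCGGGG"), f)
  writeLines(c("c1\t3.5", "c2\t800"), cv)
  contigs <- read_paralog_contigs(f, cv)
  expect_length(contigs, 2)
  expect_equal(contigs[[1]]$kmer_coverage, 3.5)
  writeLines(c("c1\t3.5"), cv)
  expect_error(read_paralog_contigs(f, cv), "c2")
})
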