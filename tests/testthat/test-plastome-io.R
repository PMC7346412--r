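test_that("GenBank coordinates convert to 0-based half-open internally", {
  seq30 <- "ATGAAATAGCCCCCCCCCCCCCCCCCATG"
  f <- write_gb_lines(toy_genbank(
    paste0(seq30, "A"),
    list(list(key = "CDS", loc = "join(4..9)", gene = "g1"))))
  rec <- read_genbank(f)
  expect_equal(rec$length, 30)
  g <- rec$features[[1]]
  expect_equal(unname(g$segments[1, ]), c(3L, 9L))
  expect_equal(g$strand, "+")
})

test_that("origin-spanning join yields a wrapping segment list with the right spliced length", {
  # 30 bp circular toy; CDS = join(28..30,1..6), spliced length 9
  seqn <- "ATGAAATAGCCCCCCCCCCCCCCCCCCAT"
  seqn <- paste0(seqn, "G")  # positions 28..30 = "ATG"
  f <- write_gb_lines(toy_genbank(
    seqn, list(list(key = "CDS", loc = "join(28..30,1..6)", gene = "wrap"))))
  rec <- read_genbank(f)
  g <- rec$features[[1]]
  expect_equal(nrow(g$segments), 2)
  expect_equal(sum(g$segments[, 2] - g$segments[, 1]), 9)
  cds <- extract_cds(rec, "wrap")
  expect_equal(nchar(cds), 9)
  expect_equal(cds, "ATGATGAAA")
})

test_that("descending single-span locations wrap the origin on circular records", {
  seqn <- paste0(strrep("C", 27), "ATG")
  f <- write_gb_lines(toy_genbank(
    seqn, list(list(key = "CDS", loc = "28..3", gene = "w2"))))
  rec <- read_genbank(f)
  expect_equal(extract_cds(rec, "w2"), "ATGCCC")
})

test_that("multi-record files and malformed locations are rejected", {
  one <- toy_genbank("ATGAAATAG",
                     list(list(key = "CDS", loc = "1..9", gene = "g")))
  f2 <- write_gb_lines(c(one, one))
  expect_error(read_genbank(f2), "exactly one record")
  fbad <- write_gb_lines(toy_genbank(
    "ATGAAATAG", list(list(key = "CDS", loc = "x..y", gene = "bad"))))
  expect_error(read_genbank(fbad), "bad")
})

test_that("extract_cds handles strand, offsets, and unknown genes", {
  rec <- plastome_record("t", "ATGAAATAG", list(
    gene_model("fwd", "protein_coding", matrix(c(0, 9), ncol = 2), "+")))
  expect_equal(extract_cds(rec, "fwd"), "ATGAAATAG")
  rec2 <- plastome_record("t", "CTATTTCAT", list(
    gene_model("neg", "protein_coding", matrix(c(0, 9), ncol = 2), "-")))
  expect_equal(extract_cds(rec2, "neg"), "ATGAAATAG")
  expect_error(extract_cds(rec, "nope"), "available: fwd")
  rec3 <- plastome_record("t", "GGATGAAATAG", list(
    gene_model("off", "protein_coding", matrix(c(0, 11), ncol = 2), "+",
               codon_start_offset = 2L)))
  expect_equal(extract_cds(rec3, "off"), "ATGAAATAG")
})

test_that("GenBank -> internal -> GenBank round trip is identity on join/complement/wrap fixtures", {
  seqn <- paste(rep("ACGTTGCA", 6), collapse = "")  # 48 bp
  feats <- list(
    gene_model("a", "protein_coding", matrix(c(3, 9), ncol = 2), "+"),
    gene_model("b", "protein_coding",
               matrix(c(12, 18, 21, 27), ncol = 2, byrow = TRUE), "+"),
    gene_model("c", "tRNA", matrix(c(30, 36), ncol = 2), "-"),
    gene_model("d", "protein_coding",
               matrix(c(0, 6, 45, 48), ncol = 2, byrow = TRUE), "-"),
    gene_model("e", "rRNA", matrix(c(37, 43), ncol = 2), "+"))
  rec <- plastome_record("rt", seqn, feats, is_circular = TRUE)
  f <- tempfile(fileext = ".gb")
  write_genbank(rec, f)
  rec2 <- read_genbank(f)
  expect_identical(rec2$sequence, rec$sequence)
  expect_identical(rec2$is_circular, TRUE)
  expect_equal(length(rec2$features), length(feats))
  for (i in seq_along(feats)) {
    expect_identical(rec2$features[[i]]$segments, feats[[i]]$segments,
                     info = feats[[i]]$gene_name)
    expect_identical(rec2$features[[i]]$strand, feats[[i]]$strand)
    expect_identical(rec2$features[[i]]$kind, feats[[i]]$kind)
  }
  # and a second round trip is byte-stable
  f2 <- tempfile(fileext = ".gb")
  write_genbank(rec2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("synthetic panel round trips through GenBank and all CDS are intact", {
  syn <- fixture_panel()
  rec <- syn$panel[[1]]
  f <- tempfile(fileext = ".gb")
  write_genbank(rec, f)
  rec2 <- read_genbank(f)
  expect_identical(rec2$sequence, rec$sequence)
  pc <- vapply(Filter(function(x) x$kind == "protein_coding",
                      rec2$features), `[[`, "", "gene_name")
  for (g in pc) {
    cds <- extract_cds(rec2, g)
    expect_equal(nchar(cds) %% 3, 0)
    prot <- translate_cds(cds)
    expect_false(grepl("\\*", substr(prot, 1, nchar(prot) - 1)),
                 label = paste("internal stop in", g))
    expect_equal(substr(prot, nchar(prot), nchar(prot)), "*")
  }
})

test_that("FASTA write/read round trips, including the empty set", {
  x <- c(s1 = "ATGAAATAG", s2 = "GGGCCCAAATTT")
  f <- tempfile(fileext = ".fa")
  write_fasta(x, f)
  expect_identical(read_fasta(f), x)
  f0 <- tempfile(fileext = ".fa")
  write_fasta(character(), f0)
  expect_length(read_fasta(f0), 0)
})

test_that("translation uses the plastid code and maps ambiguous codons to X", {
  expect_equal(translate_cds("ATGAAATAG"), "MK*")
  expect_equal(translate_cds("ATGANATAG"), "MX*")
})

test_that("degradation reports serialize to JSON and one TSV row per gene", {
  syn <- fixture_panel()
  focal <- syn$panel[[2]]
  spec <- data.frame(
    gene = c("ndhA", "ndhB", "ndhD", "ndhF", "ndhK", "ccsA", "cemA"),
    kind = c("frameshift", "premature_stop", "large_deletion", "frameshift",
             "short_inversion", "frameshift", "large_deletion"),
    len = c(1, NA, 150, 2, 60, 1, 120))
  inj <- inject_degradation(focal, spec, seed = 3)
  rep <- scan_genome(inj$record, syn$panel[-2])
  tab <- report_table(rep)
  verdicts <- vapply(rep$genes, `[[`, "", "verdict")
  expect_equal(sum(tab$verdict == "pseudogene"), 7)
  jf <- tempfile(fileext = ".json"); tf <- tempfile(fileext = ".tsv")
  write_report(rep, jf, tf)
  doc <- jsonlite::read_json(jf)
  expect_equal(doc$schema, "plastidDecay/degradation-report/1")
  expect_equal(length(doc$genes), length(rep$genes))
  tsv <- utils::read.table(tf, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  expect_equal(nrow(tsv), length(rep$genes))
  expect_equal(sum(tsv$verdict == "pseudogene"), 7)
})
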