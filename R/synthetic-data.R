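# Seeded synthetic plastomes: codon-model sequence evolution along a tree,
# assembly of panels of circular quadripartite genomes, and injection of
# degradation events with a ground-truth ledger.
#
# All randomness flows from one master seed through deterministically
# derived per-component seeds, so adding a gene or a genome does not perturb
# the draws of the others.

.derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(seed %% 1000003L)
  for (i in idx) x <- (x * 2039 + as.double(i) * 7919 + 1) %% 2147483629
  as.integer(x) + 1L
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  eval.parent(substitute(expr))
}

.random_dna <- function(n, gc = 0.37) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Synthetic plastome panel configuration
#'
#' Defines the study conditions the simulator emulates: a panel of related
#' circular plastomes with canonical quadripartite structure, conserved
#' intact protein-coding genes evolved under a codon model, plastome-like
#' spacer GC content, and an inverted repeat of configurable length.
#'
#' @param seed Master seed (mandatory; all stochastic output derives from
#'   it).
#' @param n_taxa Number of panel genomes (tips of the tree).
#' @param tree Optional `phylo`; default: a seeded random topology with
#'   depth scaled to `divergence`.
#' @param genes data.frame with columns `gene`, `codons` (length in codons
#'   including start and stop), `region` ("LSC"/"SSC") and `strand`;
#'   default: an 11-gene plastome-like set.
#' @param spacer_range Intergenic spacer length range in bp.
#' @param ir_length Inverted repeat length in bp.
#' @param divergence Mean root-to-tip distance in substitutions per site.
#' @param kappa,omega Codon model parameters used to evolve the genes.
#' @param gc Spacer GC target (default 0.37, plastome-like).
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(seed, n_taxa = 6, tree = NULL, genes = NULL,
                             spacer_range = c(100, 300), ir_length = 1500,
                             divergence = 0.05, kappa = 2, omega = 0.2,
                             gc = 0.37) {
  if (missing(seed)) stop("a seed is mandatory")
  if (is.null(genes)) {
    genes <- data.frame(
      gene = c("psbA", "matK", "atpB", "rbcL", "cemA", "ccsA", "ndhB",
               "ndhK", "ndhA", "ndhD", "ndhF"),
      codons = c(120, 150, 130, 140, 160, 110, 170, 90, 130, 170, 240),
      region = c(rep("LSC", 8), rep("SSC", 3)),
      strand = c("-", "+", "+", "+", "+", "+", "+", "+", "+", "+", "-"),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("gene", "codons", "region", "strand") %in% names(genes)),
            all(genes$codons > 10), ir_length > 0, n_taxa >= 3)
  structure(list(seed = as.integer(seed), n_taxa = n_taxa, tree = tree,
                 genes = genes, spacer_range = spacer_range,
                 ir_length = ir_length, divergence = divergence,
                 kappa = kappa, omega = omega, gc = gc),
            class = "synthetic_config")
}

.synthetic_tree <- function(config) {
  if (!is.null(config$tree)) return(ape::reorder.phylo(config$tree, "postorder"))
  tr <- .with_seed(.derive_seed(config$seed, 1), {
    t0 <- ape::rtree(config$n_taxa, rooted = TRUE)
    t0$tip.label <- paste0("tax", seq_len(config$n_taxa))
    t0
  })
  depth <- mean(ape::node.depth.edgelength(tr)[seq_len(config$n_taxa)])
  tr$edge.length <- tr$edge.length / depth * config$divergence
  ape::reorder.phylo(tr, "postorder")
}

#' Simulate codon evolution along a tree
#'
#' Gillespie simulation of the Goldman-Yang style codon process used by
#' [gy94_loglik()]: root codons are drawn from `pi`, substitutions occur
#' along each branch at the normalized instantaneous rates, and the actual
#' per-branch substitution counts are retained so simulator and likelihood
#' can be cross-checked. Branch lengths are expected substitutions per
#' codon.
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param params List with `kappa`, `pi` (61 frequencies; default uniform)
#'   and `omega` (scalar or per postorder edge).
#' @param n_codons Number of codon sites.
#' @param seed Integer seed.
#' @return List with `sequences` (named DNA strings, tips only), `states`
#'   (tip codon-state matrix), and `counts` (per-edge data.frame: parent,
#'   child, length, n_events, n_syn, n_nonsyn).
#' @export
simulate_codon_evolution <- function(tree, params, n_codons, seed) {
  kit <- codon_kit()
  tree <- ape::reorder.phylo(tree, "postorder")
  n_edge <- nrow(tree$edge)
  n_tips <- length(tree$tip.label)
  pi <- params$pi
  if (is.null(pi)) pi <- rep(1 / 61, 61)
  omega <- rep_len(params$omega, n_edge)
  kappa <- params$kappa

  .with_seed(seed, {
    n_nodes <- n_tips + tree$Nnode
    states <- matrix(NA_integer_, n_nodes, n_codons)
    root <- n_tips + 1L
    states[root, ] <- sample.int(61, n_codons, replace = TRUE, prob = pi)
    counts <- data.frame(parent = tree$edge[, 1], child = tree$edge[, 2],
                         length = tree$edge.length, n_events = 0L,
                         n_syn = 0L, n_nonsyn = 0L)
    # preorder = reversed postorder
    for (e in rev(seq_len(n_edge))) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      t <- tree$edge.length[e]
      Q <- codon_rate_matrix(kappa, omega[e], pi)
      rate <- -diag(Q)
      J <- Q; diag(J) <- 0
      J <- J / pmax(rowSums(J), .Machine$double.eps)
      st <- states[p, ]
      tleft <- rep(t, n_codons)
      active <- which(rate[st] > 0)
      nev <- nsyn <- nnon <- 0L
      while (length(active)) {
        w <- stats::rexp(length(active), rate[st[active]])
        tleft[active] <- tleft[active] - w
        alive <- tleft[active] > 0
        active <- active[alive]
        for (i in active) {
          new <- sample.int(61, 1, prob = J[st[i], ])
          nev <- nev + 1L
          if (kit$aa[st[i]] == kit$aa[new]) nsyn <- nsyn + 1L
          else nnon <- nnon + 1L
          st[i] <- new
        }
        if (length(active)) active <- active[rate[st[active]] > 0]
      }
      states[ch, ] <- st
      counts$n_events[e] <- nev
      counts$n_syn[e] <- nsyn
      counts$n_nonsyn[e] <- nnon
    }
    tip_states <- states[seq_len(n_tips), , drop = FALSE]
    seqs <- apply(tip_states, 1, function(s)
      paste(kit$codons[s], collapse = ""))
    names(seqs) <- tree$tip.label
    list(sequences = seqs, states = tip_states, counts = counts)
  })
}

# ensure the planted repeat is maximal: the single-copy bases flanking the
# two IR copies must not extend the repeat by chance complementarity
.fix_ir_flanks <- function(seqs, ir) {
  # seqs: list(lsc =, irb =, ssc =); genome = lsc | irb | ssc | revcomp(irb)
  pick_noncomp <- function(partner) {
    cand <- setdiff(c("A", "C", "G", "T"), .comp_base[partner])
    cand[1]
  }
  # extension A-right/B-left compares first base of SSC with complement of
  # last base of SSC
  first_ssc <- substr(seqs$ssc, 1, 1)
  last_ssc <- substr(seqs$ssc, nchar(seqs$ssc), nchar(seqs$ssc))
  if (first_ssc == .comp_base[last_ssc])
    substr(seqs$ssc, 1, 1) <- pick_noncomp(last_ssc)
  # extension A-left/B-right compares last base of LSC with complement of
  # first base of LSC (wrap through the origin)
  first_lsc <- substr(seqs$lsc, 1, 1)
  last_lsc <- substr(seqs$lsc, nchar(seqs$lsc), nchar(seqs$lsc))
  if (last_lsc == .comp_base[first_lsc]) {
    nl <- nchar(seqs$lsc)
    substr(seqs$lsc, nl, nl) <- pick_noncomp(first_lsc)
  }
  seqs
}

#' Build a panel of synthetic plastomes
#'
#' Assembles, for every tip of the configuration's tree, a circular genome
#' laid out as LSC genes and spacers, IRb, SSC genes and spacers, and
#' IRa = reverse complement of IRb. Gene coding sequences are evolved along
#' the tree under the codon model; spacers are regenerated per genome
#' (modeling unalignable intergenic turnover); the IR accumulates point
#' mutations with root-to-tip divergence but stays identical between its
#' two copies within a genome. Annotations are attached, and the planted
#' structure boundaries are returned as ground truth.
#'
#' @param config A [synthetic_config()].
#' @return List with `panel` (named list of [plastome_record()]),
#'   `tree`, `structures` (per-genome list of planted `lsc`, `irb`, `ssc`,
#'   `ira` intervals, 0-based half-open), `gene_alignments` (per-gene named
#'   codon-aligned tip sequences), and `config`.
#' @export
build_synthetic_plastome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  tree <- .synthetic_tree(config)
  genes <- config$genes
  n_tips <- length(tree$tip.label)

  # evolve each gene independently (seed split per gene)
  gene_seqs <- list()
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    n_internal <- g$codons - 2L
    root_cds <- .with_seed(.derive_seed(config$seed, 100, gi), {
      kit <- codon_kit()
      internal <- sample(setdiff(kit$codons, "ATG"), n_internal,
                         replace = TRUE)
      c(start = "ATG", internal, stop = "TAA")
    })
    sim <- simulate_codon_evolution(
      tree, list(kappa = config$kappa, omega = config$omega,
                 pi = rep(1 / 61, 61)),
      n_codons = n_internal, seed = .derive_seed(config$seed, 200, gi))
    gene_seqs[[g$gene]] <- vapply(tree$tip.label, function(tip)
      paste0("ATG", sim$sequences[[tip]], "TAA"), "")
  }

  # IR: root sequence mutated per tip at its root-to-tip depth
  ir_root <- .with_seed(.derive_seed(config$seed, 3),
                        .random_dna(config$ir_length, config$gc))
  depths <- ape::node.depth.edgelength(tree)[seq_len(n_tips)]

  panel <- list()
  structures <- list()
  for (ti in seq_len(n_tips)) {
    tip <- tree$tip.label[ti]
    sd_g <- .derive_seed(config$seed, 400, ti)
    rec <- .with_seed(sd_g, {
      spacer <- function() .random_dna(
        sample(seq(config$spacer_range[1], config$spacer_range[2]), 1),
        config$gc)
      irb <- ir_root
      p <- min(0.75 * depths[ti], 0.4)
      if (p > 0) {
        muts <- which(stats::runif(config$ir_length) < p)
        if (length(muts)) {
          v <- strsplit(irb, "")[[1]]
          v[muts] <- vapply(v[muts], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
          irb <- paste(v, collapse = "")
        }
      }
      build_region <- function(region_genes) {
        seq <- spacer()
        feats <- list()
        for (gi in seq_len(nrow(region_genes))) {
          g <- region_genes[gi, ]
          cds <- gene_seqs[[g$gene]][[tip]]
          ins <- if (g$strand == "+") cds else .revcomp(cds)
          start <- nchar(seq)
          seq <- paste0(seq, ins, spacer())
          feats[[gi]] <- list(gene = g$gene, start = start,
                              end = start + nchar(ins), strand = g$strand)
        }
        list(seq = seq, feats = feats)
      }
      lsc <- build_region(genes[genes$region == "LSC", ])
      ssc <- build_region(genes[genes$region == "SSC", ])
      parts <- .fix_ir_flanks(list(lsc = lsc$seq, irb = irb, ssc = ssc$seq))
      lsc_len <- nchar(parts$lsc); ssc_len <- nchar(parts$ssc)
      irl <- as.integer(config$ir_length)
      genome <- paste0(parts$lsc, parts$irb, parts$ssc, .revcomp(parts$irb))
      offs <- c(LSC = 0L, SSC = lsc_len + irl)
      feats <- lapply(c(lapply(lsc$feats, c, region = "LSC"),
                        lapply(ssc$feats, c, region = "SSC")), function(f) {
        off <- offs[[f$region]]
        gene_model(f$gene, "protein_coding",
                   matrix(c(f$start + off, f$end + off), ncol = 2),
                   strand = f$strand)
      })
      list(record = plastome_record(tip, genome, feats, is_circular = TRUE),
           structure = list(
             lsc = c(0L, lsc_len),
             irb = c(lsc_len, lsc_len + irl),
             ssc = c(lsc_len + irl, lsc_len + irl + ssc_len),
             ira = c(lsc_len + irl + ssc_len,
                     lsc_len + 2L * irl + ssc_len)))
    })
    panel[[tip]] <- rec$record
    structures[[tip]] <- rec$structure
  }

  list(panel = panel, tree = tree, structures = structures,
       gene_alignments = gene_seqs, config = config)
}

#' Flip the SSC region of a synthetic record
#'
#' Returns the record with its SSC segment reverse-complemented in place and
#' SSC feature coordinates/strands remapped; used to generate fixtures in
#' the non-standard orientation.
#'
#' @param record A [plastome_record()].
#' @param ssc Planted SSC interval (0-based half-open, non-wrapping).
#' @return A [plastome_record()].
#' @export
flip_ssc <- function(record, ssc) {
  s <- ssc[1]; e <- ssc[2]
  n <- record$length
  stopifnot(s < e, e <= n)
  new_seq <- paste0(substr(record$sequence, 1, s),
                    .revcomp(substr(record$sequence, s + 1, e)),
                    substr(record$sequence, e + 1, n))
  feats <- lapply(record$features, function(g) {
    if (!all(g$segments[, 1] >= s & g$segments[, 2] <= e)) return(g)
    ns <- s + e - g$segments[, 2]
    ne <- s + e - g$segments[, 1]
    g$segments <- matrix(as.integer(c(rev(ns), rev(ne))), ncol = 2,
                         dimnames = list(NULL, c("start", "end")))
    g$strand <- if (g$strand == "+") "-" else "+"
    g
  })
  plastome_record(record$id, new_seq, feats, record$is_circular)
}

#' Generate a single random quadripartite genome
#'
#' A lightweight construction-oracle fixture: uniform-random single-copy
#' regions around a planted inverted repeat (IRa = reverse complement of
#' IRb), with the repeat-flanking bases adjusted so the planted repeat is
#' maximal. Used for boundary-recovery studies where a full evolved panel
#' is unnecessary.
#'
#' @param seed Integer seed.
#' @param ir_length,lsc_length,ssc_length Region lengths in bp
#'   (`lsc_length` must be >= `ssc_length`).
#' @param gc GC content target.
#' @return List with `sequence` and `structure` (planted `lsc`, `irb`,
#'   `ssc`, `ira` 0-based half-open intervals).
#' @export
random_quadripartite <- function(seed, ir_length = 1500, lsc_length = 5000,
                                 ssc_length = 2000, gc = 0.37) {
  stopifnot(lsc_length >= ssc_length, ir_length > 0)
  ir_length <- as.integer(ir_length)
  lsc_length <- as.integer(lsc_length)
  ssc_length <- as.integer(ssc_length)
  .with_seed(seed, {
    parts <- .fix_ir_flanks(list(lsc = .random_dna(lsc_length, gc),
                                 irb = .random_dna(ir_length, gc),
                                 ssc = .random_dna(ssc_length, gc)))
    seqn <- paste0(parts$lsc, parts$irb, parts$ssc, .revcomp(parts$irb))
    list(sequence = seqn,
         structure = list(
           lsc = c(0L, lsc_length),
           irb = c(lsc_length, lsc_length + ir_length),
           ssc = c(lsc_length + ir_length,
                   lsc_length + ir_length + ssc_length),
           ira = c(lsc_length + ir_length + ssc_length,
                   lsc_length + 2L * ir_length + ssc_length)))
  })
}

# ---- degradation injection ----------------------------------------------

.stop_codons <- c("TAA", "TAG", "TGA")

.one_sub_to_stop <- function(codon) {
  # returns list(stop, pos) for the first stop reachable by one substitution
  for (s in .stop_codons) {
    d <- which(strsplit(codon, "")[[1]] != strsplit(s, "")[[1]])
    if (length(d) == 1) return(list(stop = s, pos = d))
  }
  NULL
}

# Map position j (1-based) of the downstream flank -- the spacer continuing
# past the gene in transcription direction -- to a 1-based genome position.
# `end_pos` is the last transcribed base (1-based) for "+" strand genes, the
# first genome base of the gene for "-" strand genes.
.flank_genome_pos <- function(end_pos, strand, j, n) {
  p <- if (strand == "+") end_pos + j else end_pos - j
  ((p - 1) %% n) + 1
}

.downstream_flank <- function(genome, end_pos, strand, len, n) {
  chars <- strsplit(genome, "")[[1]]
  idx <- vapply(seq_len(len), function(j)
    .flank_genome_pos(end_pos, strand, j, n), 1)
  out <- chars[idx]
  if (strand == "-") out <- unname(.comp_base[out])
  paste(out, collapse = "")
}

.edit_flank_base <- function(genome, end_pos, strand, j, base, n) {
  gpos <- .flank_genome_pos(end_pos, strand, j, n)
  if (strand == "-") base <- unname(.comp_base[[base]])
  substr(genome, gpos, gpos) <- base
  genome
}

.scrub_frame_stops <- function(genome, end_pos, strand, n, window) {
  # remove in-frame stop codons from the downstream spacer so injected
  # stop-loss events are unambiguous; codon frame continues the CDS frame
  ncod <- window %/% 3
  if (ncod < 1) return(genome)
  for (ci in seq_len(ncod)) {
    flank <- .downstream_flank(genome, end_pos, strand, window, n)
    cod <- substr(flank, 3 * ci - 2, 3 * ci)
    if (cod %in% .stop_codons) {
      # mutate the middle base to C: TAA->TCA, TAG->TCG, TGA->TCA (all sense)
      genome <- .edit_flank_base(genome, end_pos, strand, 3 * ci - 1, "C", n)
    }
  }
  genome
}

#' Inject degradation events into a plastome record
#'
#' Applies the specified lesions to intact genes and returns both the
#' mutated record and a ground-truth ledger. Supported kinds:
#' `premature_stop` (single substitution creating an in-frame stop),
#' `frameshift` (1-2 bp indel), `large_deletion` (in-gene deletion of
#' `len` bp), `short_inversion` (in-place reverse complement of `len` bp),
#' `lost_stop` (substitution destroying the canonical stop, downstream
#' spacer scrubbed of in-frame stops within the search window), and
#' `novel_termination` (stop destroyed and a new in-frame stop planted
#' `ext` bp downstream). Feature coordinates downstream of indels are
#' updated.
#'
#' @param record An annotated [plastome_record()] with intact target genes.
#' @param truth_spec data.frame with columns `gene`, `kind` and optionally
#'   `len` (deletion/inversion/indel length), `ext` (termination shift) and
#'   `at` (target position within the CDS: codon index for premature stops,
#'   0-based bp offset otherwise; defaults to mid-gene).
#' @param seed Integer seed (used for random indel bases).
#' @return List with `record` (mutated) and `truth` (data.frame ledger:
#'   gene, kind, position in CDS coordinates, payload).
#' @export
inject_degradation <- function(record, truth_spec, seed = 1) {
  stopifnot(inherits(record, "plastome_record"))
  if (is.null(truth_spec) || nrow(as.data.frame(truth_spec)) == 0)
    return(list(record = record,
                truth = data.frame(gene = character(), kind = character(),
                                   position = integer(), payload = integer())))
  truth_spec <- as.data.frame(truth_spec, stringsAsFactors = FALSE)
  ledger <- list()
  rec <- record
  for (i in seq_len(nrow(truth_spec))) {
    gene <- truth_spec$gene[i]
    kind <- truth_spec$kind[i]
    len <- if ("len" %in% names(truth_spec)) truth_spec$len[i] else NA
    ext <- if ("ext" %in% names(truth_spec)) truth_spec$ext[i] else NA
    at <- if ("at" %in% names(truth_spec)) truth_spec$at[i] else NA
    f <- .get_feature(rec, gene)
    if (nrow(f$segments) != 1)
      stop("inject_degradation supports single-segment genes (", gene, ")")
    cds <- extract_cds(rec, gene)
    n_cod <- nchar(cds) %/% 3
    if (n_cod < 8) stop("gene '", gene, "' too short for injection")
    sd_i <- .derive_seed(seed, 500, i)
    new_cds <- cds
    position <- NA_integer_
    payload <- NA_integer_
    post_edit <- NULL

    if (kind == "premature_stop") {
      mid <- if (!is.na(at)) as.integer(at) else n_cod %/% 2
      mid <- min(max(mid, 3L), n_cod - 2L)
      order_try <- mid + c(0, as.vector(rbind(seq_len(n_cod), -seq_len(n_cod))))
      order_try <- order_try[order_try >= 3 & order_try <= n_cod - 2]
      done <- FALSE
      for (ci in order_try) {
        cod <- substr(cds, 3 * ci - 2, 3 * ci)
        hit <- .one_sub_to_stop(cod)
        if (!is.null(hit)) {
          substr(new_cds, 3 * ci - 3 + hit$pos, 3 * ci - 3 + hit$pos) <-
            substr(hit$stop, hit$pos, hit$pos)
          position <- 3L * (ci - 1L)
          payload <- 1L
          done <- TRUE
          break
        }
      }
      if (!done) stop("no codon mutable to a stop by one substitution in '",
                      gene, "'")
    } else if (kind == "frameshift") {
      if (is.na(len)) len <- 1L
      stopifnot(abs(len) %in% 1:2)
      pos <- if (!is.na(at)) as.integer(at) else 3 * (n_cod %/% 2)
      pos <- min(max(pos, 9L), nchar(cds) - 9L)
      if (len > 0) {
        insert <- .with_seed(sd_i, .random_dna(len, 0.5))
        new_cds <- paste0(substr(cds, 1, pos), insert,
                          substr(cds, pos + 1, nchar(cds)))
      } else {
        new_cds <- paste0(substr(cds, 1, pos),
                          substr(cds, pos - len + 1, nchar(cds)))
      }
      position <- pos
      payload <- as.integer(len)
    } else if (kind == "large_deletion") {
      if (is.na(len)) len <- 150L
      len <- as.integer(len)
      start <- if (!is.na(at)) as.integer(at)
               else max(4L, (nchar(cds) - len) %/% 2)
      start <- min(max(start, 4L), nchar(cds) - len - 6L)
      if (start + len > nchar(cds) - 6)
        stop("gene '", gene, "' too short for a ", len, " bp deletion")
      new_cds <- paste0(substr(cds, 1, start),
                        substr(cds, start + len + 1, nchar(cds)))
      position <- start
      payload <- len
    } else if (kind == "short_inversion") {
      if (is.na(len)) len <- 60L
      len <- as.integer(len)
      mid <- if (!is.na(at)) as.integer(at)
             else max(4L, (nchar(cds) - len) %/% 2)
      mid <- min(max(mid - mid %% 3L, 3L), nchar(cds) - len - 6L)
      if (mid + len > nchar(cds) - 6)
        stop("gene '", gene, "' too short for a ", len, " bp inversion")
      # prefer an inversion site whose reverse complement carries an
      # in-frame stop (the usual way a short inversion disables a gene)
      cand <- mid + 3L * c(0L, as.vector(rbind(1:20, -(1:20))))
      cand <- cand[cand >= 3 & cand + len <= nchar(cds) - 6]
      start <- cand[1]
      for (cs in cand) {
        seg_rc <- .revcomp(substr(cds, cs + 1, cs + len))
        ncd <- nchar(seg_rc) %/% 3
        cods <- substring(seg_rc, seq(1, 3 * ncd - 2, 3), seq(3, 3 * ncd, 3))
        if (any(cods %in% .stop_codons)) { start <- cs; break }
      }
      seg <- substr(cds, start + 1, start + len)
      new_cds <- paste0(substr(cds, 1, start), .revcomp(seg),
                        substr(cds, start + len + 1, nchar(cds)))
      position <- start
      payload <- len
    } else if (kind %in% c("lost_stop", "novel_termination")) {
      stop_cod <- substr(cds, nchar(cds) - 2, nchar(cds))
      if (!stop_cod %in% .stop_codons)
        stop("gene '", gene, "' has no canonical stop to destroy")
      # one substitution to a sense codon: TAA->TAC, TAG->TAC, TGA->GGA
      new_stop <- if (stop_cod == "TGA") "GGA" else
        paste0(substr(stop_cod, 1, 2), "C")
      new_cds <- paste0(substr(cds, 1, nchar(cds) - 3), new_stop)
      position <- nchar(cds) - 3L
      payload <- if (kind == "novel_termination") {
        if (is.na(ext)) ext <- 99L
        as.integer(ext)
      } else 0L
      post_edit <- kind
    } else stop("unknown injection kind '", kind, "'")

    # splice the edited CDS back into the genome
    seg <- f$segments[1, ]
    ins <- if (f$strand == "+") new_cds else .revcomp(new_cds)
    genome <- paste0(substr(rec$sequence, 1, seg[1]), ins,
                     substr(rec$sequence, seg[2] + 1, rec$length))
    delta <- nchar(new_cds) - nchar(cds)
    feats <- lapply(rec$features, function(g) {
      shift <- g$segments[, 1] >= seg[2]
      g$segments[shift, ] <- g$segments[shift, , drop = FALSE] + delta
      if (g$gene_name == gene)
        g$segments[1, 2] <- g$segments[1, 2] + delta
      g
    })
    rec <- plastome_record(rec$id, genome, feats, rec$is_circular)

    if (!is.null(post_edit)) {
      f2 <- .get_feature(rec, gene)
      end_pos <- if (f2$strand == "+") f2$segments[1, 2]
                 else f2$segments[1, 1] + 1L
      n2 <- rec$length
      # scrub downstream in-frame stops: over the canonical-stop search
      # window (lost_stop) or up to just before the planted stop
      # (novel_termination, ext measured from the destroyed stop start)
      scrub_window <- if (post_edit == "lost_stop") 33L else payload - 3L
      genome2 <- .scrub_frame_stops(rec$sequence, end_pos, f2$strand, n2,
                                    scrub_window)
      if (post_edit == "novel_termination") {
        fo <- payload - 3L  # 0-based flank offset of the planted stop codon
        stopifnot(fo %% 3L == 0L, fo >= 0L)
        for (b in 1:3)
          genome2 <- .edit_flank_base(genome2, end_pos, f2$strand, fo + b,
                                      substr("TAA", b, b), n2)
      }
      rec <- plastome_record(rec$id, genome2, rec$features, rec$is_circular)
    }

    ledger[[i]] <- data.frame(gene = gene, kind = kind,
                              position = position, payload = payload,
                              stringsAsFactors = FALSE)
  }
  list(record = rec, truth = do.call(rbind, ledger))
}
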