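---
title: "Detecting plastid genome degradation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting plastid genome degradation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidDecay)
```

## The problem

Land-plant plastomes are among the most conserved genomes known: a circular
molecule of 120–170 kb with a quadripartite layout — a large single-copy
region (LSC) and a small single-copy region (SSC) separated by two identical
inverted-repeat copies (IRa/IRb) — carrying a nearly fixed complement of
protein-coding, tRNA and rRNA genes. Against that background, loss or
pseudogenization of photosynthesis genes in a *fully photosynthetic* lineage
is a strong signal: it has been reported repeatedly for the *ndh* complex
(photooxidative protection) in aquatic and otherwise habitat-specialized
plants, and only rarely for genes closer to the photosynthetic core such as
*cemA* (carbon uptake) and *ccsA* (cytochrome c heme attachment).

`plastidDecay` implements the comparative workflow such a claim requires,
end to end and testable without any external downloads:

1. structural characterization (IR detection, SSC orientation, genome
   summaries),
2. criteria-based pseudogene detection of a focal genome against a panel of
   related genomes,
3. screening of putative nuclear paralogs (NUPTs) by assembler coverage and
   by the same lesion criteria,
4. comparative statistics (alignment summaries, one-tailed t-tests for
   genome size and plastid read fraction), and
5. branch-specific dN/dS likelihood-ratio tests for shifts in selective
   regime on the focal branch.

A seeded synthetic-plastome simulator with a ground-truth event ledger makes
every stage verifiable: the package's tests measure sensitivity and
specificity against lesions it injected itself.

## Pseudogene criteria

A gene in the focal genome is compared with an intact ortholog from the
panel by deterministic affine-gap global alignment (match +2, mismatch −3,
gap open −10, gap extension −0.5; `Biostrings::pairwiseAlignment`). The
primary structural criteria, any one of which yields a `pseudogene`
verdict, are:

* **premature stop codon** — an in-frame stop in the focal reading frame
  strictly upstream of the column aligned to the reference stop, with the
  frame tracked through indels;
* **frameshift** — a prefix of the alignment in which focal insertions
  minus deletions are not divisible by three, reported at the first
  offending indel;
* **lost canonical stop** — no focal in-frame stop at, or within 30 bp
  downstream of, the reference stop position;
* **large deletion** — any *single* alignment gap of ≥ 100 bp in the focal
  sequence. The threshold is per gap, not cumulative, because scattered
  small indels in otherwise-intact genes are common and not diagnostic.

Two further signals are treated as *supporting* evidence only, yielding an
`anomalous` verdict when unaccompanied by a structural lesion:

* **novel termination / length anomaly** — a predicted protein whose
  termination site or length falls outside everything observed in the
  panel (a stop found > 30 bp past the canonical site is reported with its
  extension length);
* **hydrophobicity outlier** — a hydrophobic-residue fraction outside the
  panel's Student-t confidence interval of the mean,
  `mean ± t(1−α/2, n−1)·sd/√n`. We interpret the interval as a CI of the
  panel mean (not a prediction interval) because that is the quantity a
  panel of orthologs estimates; with membrane proteins whose hydrophobic
  fraction is tightly conserved, a focal value outside even this narrow
  band is informative. The residue set is configurable and defaults to the
  positive Kyte–Doolittle hydropathy set {A, C, F, I, L, M, V}, since
  "hydrophobic" has no single canonical definition.

**Short inversions** get special treatment. A linear aligner renders an
inverted segment either as a dense mismatch block or — more often — as a
paired deletion and insertion of similar length bracketing it, which
would masquerade as frameshifts. `detect_events()` therefore collects
inversion candidates *first*, from both signatures: mismatch/gap clusters
(difference columns separated by ≤ 10 matching columns, span 12–200 bp)
and focal-gap/reference-gap pairs of similar length (≥ 4 bp each, within
the window). A candidate whose reverse complement raises its *aligned*
local identity against the reference segment by ≥ 0.25 is reported as
`short_inversion` (aligned rather than positional identity, because a few
flanking bases inside the candidate would otherwise shift the
reverse-complement frame and mask the signal), and indels inside its span
are excluded from the frameshift walk. An inversion that introduces an
in-frame stop still (correctly) yields `premature_stop`, which is what
makes such genes pseudogenes; an inversion alone is `anomalous`.

Genes known to be pseudogenized by IR boundary effects across angiosperms
(*ycf1*, *ycf2* fragments, *ycf15*) are excluded from novel calls by
default (`scan_config(excluded_genes = ...)`).

## Annotation lift

Unannotated assemblies are annotated by homology against a reference
genome: each reference CDS is located by exact 24-mer seeding (tried at
several offsets, both strands, up to 5 mismatches) followed by global–local
alignment of the CDS into the candidate window. Models are transferred when
alignment identity reaches 0.70 — a deliberately permissive cutoff so that
*degraded* copies are still annotated and then flagged by the scan, rather
than silently dropped. Genes that cannot be located are recorded as missing
rather than raising an error.

## The codon model

Selection tests use a Goldman–Yang style codon substitution model over the
61 sense codons of the plastid/bacterial genetic code (translation table
11). The instantaneous rate from codon *i* to *j* is 0 for multi-nucleotide
changes and otherwise proportional to

| change | rate |
|---|---|
| synonymous transversion | $\pi_j$ |
| synonymous transition | $\kappa \pi_j$ |
| nonsynonymous transversion | $\omega_b \pi_j$ |
| nonsynonymous transition | $\omega_b \kappa \pi_j$ |

with $\omega_b$ = dN/dS on branch *b*. Each branch's generator is rescaled
so branch lengths are expected substitutions per codon. Codon frequencies
$\pi$ use the F3x4 parameterization (products of position-specific
nucleotide frequencies, stops removed and renormalized, floored at $10^{-4}$
so unobserved states remain reachable). The log-likelihood is computed by
Felsenstein pruning over the 61 states in compiled code; time reversibility
allows diagonalizing a symmetrized generator, and the (κ, ω) → eigensystem
and (κ, ω, t) → P(t) maps are memoised because quasi-Newton optimization
revisits parameter points that differ in one coordinate.

**The test.** Following the standard branch-model recipe, the *full* model
gives every branch its own ω (free-ratio) with κ and all branch lengths
estimated; the *constrained* model is identical except that the focal
branch shares ω with the branch immediately ancestral to it. Twice the
log-likelihood difference is referred to χ²₁ (the models differ by exactly
one parameter), and p-values across genes are corrected by the Hochberg
step-up rule (`stats::p.adjust`). Internal stop codons in pseudogene
sequences — which a sense-codon model cannot represent — are recoded as
missing data and marginalized, as are codons containing gaps or ambiguity
codes. Rows retaining fewer than 200 unmasked bases are dropped entirely,
the same rule used when trimming paralog contigs into gene matrices.

**Optimization.** L-BFGS-B on log-transformed parameters with bounds
ω ∈ [10⁻⁶, 999], κ ∈ [10⁻³, 100], t ∈ [~0, 50]; by default three starts
(the first from κ=2, ω=0.2 and the input branch lengths; later starts
jittered under a fixed seed); convergence at |Δℓ| below ~10⁻⁶. After
fitting, the constrained model is refit once from the full model's optimum
(and vice versa when the inequality ℓ_constrained ≤ ℓ_full is violated), so
the test statistic does not inherit optimizer noise from a poor start. A
non-convergent fit is flagged, not raised.

**Tree shape matters.** On a rooted binary tree the two edges meeting at
the root are confounded under a reversible model, so an "ancestral branch"
adjacent to the root is weakly identified and the test loses meaning. The
test expects the focal branch's ancestral edge to be a genuine internal
edge — in practice we fit on unrooted (trifurcating-root) topologies, which
is also how the calibration studies are set up.

## The synthetic data generator

`build_synthetic_plastome()` emulates the study conditions the package is
designed for: a panel of related plastomes (default 6 taxa on a seeded
random topology with mean root-to-tip divergence 0.05 substitutions/site —
the within-family range over which such comparative panels are built), each
assembled as LSC genes+spacers | IRb | SSC genes+spacers | IRa =
revcomp(IRb). The default gene set is 11 plastome-like genes (90–240
codons, two on the minus strand, *ndh* genes in the SSC) evolved under the
same Gillespie process the likelihood describes (κ = 2, ω = 0.2 —
purifying selection typical of plastid genes); the realized per-branch
substitution counts are retained so simulator and likelihood can be
cross-checked. Spacers are uniform-random at GC 0.37 (plastome-like) and
are regenerated per genome, modeling unalignable intergenic turnover; the
IR accumulates point mutations with divergence but stays identical between
its two copies within a genome, as in real plastomes where the copies are
homogenized.

Two deliberate construction details:

* **Planted-IR maximality.** "Recover the planted boundaries exactly" is
  only well-posed if the planted repeat *is* the maximal repeat, so the
  generator rejection-samples the four single-copy bases flanking the IR
  copies to break chance complementarity that would extend the true
  maximal repeat past the planted one.
* **Seed splitting.** All randomness flows from one master seed through
  deterministically derived per-component seeds (an integer-hash stream
  split), so adding a gene or genome does not perturb the other
  components' draws.

`inject_degradation()` plants the five lesion classes (point-mutation
stops, 1–2 bp frameshifting indels, ≥ 100 bp deletions, short in-place
inversions, destroyed stop codons with or without a planted downstream
stop) into named genes at controllable positions, updates all downstream
feature coordinates, and returns a ledger that the scan is scored against.
Inversion sites are chosen, where possible, so the reverse-complemented
segment carries an in-frame stop — the usual mechanism by which a short
inversion disables a gene. For destroyed-stop lesions the downstream spacer
is scrubbed of chance in-frame stops inside the search window, so the
ledger's expected detection is unambiguous.

What the generator does **not** emulate: introns and trans-splicing, RNA
editing, codon-usage heterogeneity along genes, IR boundary shifts,
heteroplasmy, or read-level sequencing error. Passing the round-trip tests
therefore demonstrates the detector logic is correct for clean assemblies
with single-exon gene models, not that annotation of intron-rich real
genomes is solved.

## What the structure detector assumes

`detect_inverted_repeat()` uses exact 24-mer seeds sampled at a stride just
under `min_len`, guaranteeing that any repeat of at least `min_len` bp
contains a sampled seed; seed pairs are extended symmetrically, tolerating
mismatches up to `max_mismatch_frac` of the current length (0 = exact). The
longest disjoint pair wins; an exact tie between distinct pairs raises an
error rather than guessing. Repeat copies that themselves span the
sequence origin are not seeded (the single-copy regions may wrap; the
copies may not) — rotate such assemblies first, which is also the usual
convention for deposited plastomes.

## Numerical and edge-case choices

* Internal coordinates are 0-based half-open on the forward strand;
  circularity is a wrapping segment list, never sequence doubling.
* Ambiguity codes are preserved through I/O; codons containing them
  translate to `X` and are excluded from hydrophobicity denominators.
* The genome-size and read-fraction comparisons use a one-sample t of the
  panel against the focal value (a two-sample test with n = 1 on one side
  is undefined); the direction of the alternative is always explicit.
* `classify_origin()` encodes "orders of magnitude lower coverage" as a
  ratio below 0.1 of the organellar coverage for `nuclear` (strictly
  less), at or above 0.5 for `organellar`, `ambiguous` between; both
  thresholds configurable, and the classification is scale-invariant.
* Zero-length branches, identical sequences, all-equal panels and other
  degenerate inputs are exercised in the test suite; single-site
  alignments converge with ω at a bound and are reported as such.

## Problem sizes in the validation studies

The shipped studies are sized to run on a laptop-class machine: 100 random
genomes (IR 500–30,000 bp) for boundary recovery; 50 seeded injections per
lesion class for the scan round trip; pruning-versus-enumeration likelihood
checks on trees of up to 5 taxa and 6 codons (the largest exhaustive
enumeration that stays exact); 300 null replicates of 300 codons on a
4-taxon unrooted tree for LRT calibration, and 50 replicates of 500 codons
at true focal ω = 0.03 for recovery of strongly purifying dN/dS. The same
studies are recomputed from scratch by `scripts/acceptance.R`.

## Known limitations

* The annotation lift transfers single-segment models only; spliced genes
  on real genomes need upstream annotation.
* The free-ratio model estimates one ω per branch from one gene at a time;
  with few taxa and short genes, per-branch ω estimates other than the
  focal contrast are noisy (only the focal-vs-ancestral contrast is
  interpreted).
* The inversion detector requires the inverted segment to sit inside a
  single alignment neighborhood (span ≤ 200 bp by default); larger
  rearrangements are out of scope.
* Hochberg correction assumes the per-gene tests are non-negatively
  dependent, the standard assumption when the same tree underlies all
  genes.
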