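---
title: "Detecting gene loss and testing relaxed selection with genedecay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene loss and testing relaxed selection with genedecay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genedecay)
```

## The problem

When a protein-coding gene stops mattering to an organism, its sequence
decays: frameshifting indels accumulate, premature stop codons appear,
splice sites drift away from the canonical `gt..ag`, and eventually whole
exons or the whole locus can be deleted.  Establishing that a gene has been
lost in some lineages — and dating the loss relative to speciation events —
takes two complementary lines of evidence:

1. **Structural**: reconstruct the gene copy in each species from genomic
   sequence, catalogue every open-reading-frame (ORF) disrupting mutation,
   and place mutations shared by several species on the branches of the
   species tree.  Where no gene copy is found at all, whole-genome-shotgun
   (WGS) reads mapped to a reference locus distinguish a true genomic
   deletion from missing data.
2. **Statistical**: fit codon substitution models in which the
   nonsynonymous/synonymous rate ratio $\omega = d_N/d_S$ differs between
   prespecified branch classes, and compare nested models by likelihood
   ratio tests (LRTs).  Purifying selection keeps $\omega \ll 1$; relaxed
   selection pushes $\omega$ toward 1 on the branches where the gene no
   longer functions.

`genedecay` implements both lines as a tested, reusable pipeline, together
with a synthetic-data module that generates every input class with known
ground truth.

## The codon model

Substitution follows the Goldman–Yang codon model on the 61 sense codons of
the standard genetic code.  The instantaneous rate from codon $i$ to codon
$j$ is

$$ q_{ij} = \begin{cases}
0 & \text{more than one position differs} \\
\pi_j & \text{synonymous transversion} \\
\kappa \pi_j & \text{synonymous transition} \\
\omega \pi_j & \text{nonsynonymous transversion} \\
\omega \kappa \pi_j & \text{nonsynonymous transition,}
\end{cases} $$

with equilibrium codon frequencies $\pi$, transition/transversion ratio
$\kappa$, and $\omega$ taken from the branch's class.  $Q$ is rescaled so
that $-\sum_i \pi_i q_{ii} = 1$, making branch lengths expected
substitutions per codon.  The default frequency model is F3x4
(position-specific nucleotide frequencies multiplied and renormalized over
sense codons); F61 and F1x4 are available.

Likelihoods are computed by Felsenstein pruning over the 61 states in
compiled code.  Because the chain is reversible ($\pi_i q_{ij} = \pi_j
q_{ji}$ by construction), the likelihood is invariant to root placement;
trees may be rooted or unrooted, and the shipped example topologies are
unrooted so that parameter counts equal `2n - 3` branch lengths plus
$\kappa$ plus the free $\omega$ classes.  Transition matrices are obtained
by eigendecomposition of the $\pi^{1/2}$-symmetrized generator — stable,
and reusable across all branches of one $\omega$ class.

```{r quick-model}
pi <- rep(1 / 61, 61)
Q <- codon_rate_matrix(kappa = 2, omega = 0.5, pi = pi)
# synonymous transition vs nonsynonymous transversion: kappa / omega
Q["TTT", "TTC"] / Q["TTT", "TTA"]
```

### Fitting and testing

`fit_codon_model()` maximizes the likelihood over $\kappa$, the free
$\omega$ classes and all branch lengths with log-transformed
box-constrained quasi-Newton iterations (`nlminb`), starting from
$\kappa = 2$, $\omega = 0.4$, branch lengths 0.1 (or the tree's lengths),
with up to three jittered starts ($\times 0.5, 1, 2$).  Classes may be
pinned (`fixed = c("1" = 1)` encodes the "relaxed to neutrality" null) and
`free_ratio = TRUE` gives every branch its own $\omega$.  `lrt()` compares
nested fits: $2\Delta\ln L$ against $\chi^2_{df}$ with $df$ equal to the
parameter-count difference.  No boundary-mixture correction is applied even
when $\omega$ is fixed at 1 — this matches how published branch-model
tables report $df$ and $P$.  The upper tail is `pchisq(..., lower.tail =
FALSE)`, accurate to the smallest representable p-values.

Model batteries are declarative JSON files naming branch sets by tip-set
descriptors (`terminal`, `clade` with or without its stem, `stem`), so the
same battery runs on any tree containing those taxa; see
`inst/extdata/battery_catarrhine.json` (models A–L) and
`battery_whale.json` (models A–G), which encode the canonical comparisons
for a 13-taxon primate dataset and an 8-taxon whale/cow/pig dataset.  The
printed maximum-likelihood summaries for those two datasets ship as plain
tables (`model_table()`) so that the LRT arithmetic can be reproduced from
printed values alone.

## The structural pipeline

**Exon mapping** (`map_exons()`): each reference exon is located by local
alignment (match +1, mismatch −1, gap open −4, extend −1), searched
left-to-right so hits stay ordered and non-overlapping.  Boundaries are
refined toward canonical splice sites within a 50-nt window.  Two details
matter and are deliberate:

* the *unrefined* alignment boundary always stays a candidate, ranked by
  identity — so a genuinely mutated splice site is not dragged onto a
  spurious canonical site nearby;
* candidate identity is matches over *alignment columns*, not over the
  reference length; otherwise extending an exon into random intron sequence
  could only gain matches and over-long intervals would win.  Ties go to
  the smallest coordinate shift.  Unaligned reference tails longer than
  6 nt are left to refinement rather than blindly re-covered, because a
  long tail is the signature of an indel near the exon edge.

**Annotation** (`annotate_gene()` and friends): indels come from global
per-exon alignment, one record per maximal gap run, frameshift iff length
mod 3 ≠ 0.  Premature stops are scanned in the *reference* codon frame by
projecting reference codons through the per-exon alignments: a stop that
exists only because of an upstream frameshift is a consequence of that
frameshift, not an independent mutation, and is never double-counted — the
catalogue style used in curated mutation tables.  The functional call
applies the precedence `gene_absent > pseudogene > altered_Cterm > intact`;
`altered_Cterm` covers the special case of a frameshift confined to the
last exon, which truncates the C-terminus (losing, e.g., a GPI-anchor
signal) while leaving the upstream ORF intact.  Protein lengths are
translations to the first stop in the species frame.

**Dollo placement** (`assign_mutations_to_tree()`): an identical event
(same kind, exon, position, length, allele) observed in a species set is
assigned once to the branch above the set's MRCA *iff* the set is exactly
the MRCA's tip set among sampled species; anything else becomes independent
terminal-branch events.  This is the parsimony logic that puts a deletion
shared by all toothed whales on the toothed-whale stem while refusing to
infer a single loss for a paraphyletic pattern.

**Presence/absence from reads** (`match_reads()`, `call_deletion()`):
reads are seeded with exact 16-mers and extended ungapped; identity is
computed within the best locally maximal-scoring segment (+1/−1) and query
coverage as that segment's length over the read length.  A read is retained
only if identity ≥ 0.90 *and* coverage ≥ 0.90 — the classic BLAST-style
match rule.  These HSP semantics are what make the deletion call exact: a
read straddling a deletion breakpoint either fails coverage or has its
aligned segment confined to the flank, so a truly deleted target interval
stays at coverage zero.  `call_deletion()` then requires a bare target with
both flanks at mean coverage ≥ 5 (a threshold chosen so a depth-20
simulation is decisive; the original analyses judged such plots by eye, so
the numeric criterion is this package's own, exposed as a parameter).

## The synthetic world

`make_locus()` generates multi-exon loci: i.i.d. codons at a target GC
(default 0.45, a typical mammalian exome value), ATG start, single terminal
stop, canonical `gt..ag` introns, uppercase exons / lowercase introns.  The
default spec is 13 exons totalling 1857 coding nt — a 618-residue product,
the shape of the monooxygenase gene this machinery was built around.
`plant_mutations()` applies any combination of the nine disruption kinds
with full ground truth; `gene_deletion` replaces the locus with a
non-homologous random segment (no repeat model — repeat content is
irrelevant to identity/coverage thresholding).  `make_reads()` draws
uniform starts, fixed length, i.i.d. substitution errors, no indels and no
quality model.  `simulate_codon_alignment()` evolves codons down a labeled
tree from a $\pi$-distributed root.  Everything is a pure function of its
seed.

What a green test establishes, and what it does not: the generator's world
has no repeats, no paralogs, no alignment uncertainty, no sequencing
indels, and no rate variation across sites.  Green planted-truth recovery
therefore validates the *bookkeeping* (frame tracking, boundary logic,
catalogue identity, threshold behaviour) and the *statistics* (likelihood
correctness against enumeration, parameter recovery, null calibration of
the LRT at the nominal 5% level), not robustness to genomic complexity
that the world does not contain.

## Numerical and design choices

* **Coordinates** are 1-based inclusive throughout the R API (the
  R/Bioconductor idiom); BED I/O converts to and from 0-based half-open at
  the file boundary.  This replaces the usual "0-based internally" split
  convention — in R, 1-based internals remove a whole class of off-by-one
  translations.
* **Alignment scoring**: Biostrings charges a length-$L$ gap
  `gapOpening + L * gapExtension`; with `gapOpening = 3, gapExtension = 1`
  the first gap base costs 4 and each further base 1, i.e. the stated
  "open −4 / extend −1" schedule under the convention that opening includes
  the first base.
* **Missing data**: codons containing `-`, `N`, anything non-ACGT, or a
  stop codon are missing (all-ones partials), not deleted columns —
  disrupted positions are expected to have been excluded upstream by
  `prepare_dataset()`, so remaining gaps are padding.
* **Optimizer**: convergence at `rel.tol = 1e-10`; bulk experiments (the
  200-replicate null calibration) use a single start because these
  branch-model surfaces are unimodal in practice and multi-start triples
  runtime for identical optima; the user-facing default remains 3 starts.
* **Degenerate inputs**: zero-length branches are legal (identity
  transition matrix); a site with zero likelihood raises an error naming
  the site; `f61_frequencies()` floors unobserved codons at $10^{-6}$ so
  the symmetrized eigensolver stays defined.
* **In-frame insertions** have no kind in the nine-kind mutation
  vocabulary and are not ORF-disrupting; the annotator skips them.
  In-frame deletions are catalogued (`inframe_deletion`) but do not count
  toward the pseudogene call.

## Limitations

The exon mapper is a single-gene spliced aligner, not a genome aligner: no
paralog disambiguation beyond best-in-order hits, no chaining across
rearrangements.  The read matcher has no mapping-quality model and no
paired-end geometry (pairs are treated as independent reads).  Site models,
branch-site models and gamma rate variation are out of scope — branch
models only.  Reproducing the printed likelihood values for the original
datasets requires the original supplementary alignment/tree bundles, which
cannot be redistributed here; the acceptance tests for those values look
for the files under `inst/extdata/supplementary/` and fail with
instructions when absent.
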