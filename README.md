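# genedecay

Tools for studying the loss and decay of a protein-coding gene across
species.  The package grew out of comparative analyses of pseudogenization —
the kind of study that asks "in which lineages did this gene die, when, and
was selection already relaxed before it did?" — and packages the full
inference chain:

* **exon reconstruction**: locate each reference exon in a species' genomic
  sequence by local alignment with canonical (`gt..ag`) splice-site boundary
  refinement, and concatenate the hits into a *virtual cDNA*
  (`map_exons()`, `build_virtual_cdna()`, `translate_cds()`);
* **mutation cataloguing**: frameshift indels, premature stop codons
  (scanned in the reference frame, so stops caused by an upstream frameshift
  are not double-counted), start-codon loss, non-canonical splice sites,
  exon and whole-gene deletions; functional classification
  (`intact` / `altered_Cterm` / `pseudogene` / `gene_absent`) and
  Dollo-parsimony placement of shared mutations on a species tree
  (`annotate_gene()`, `classify_gene()`, `assign_mutations_to_tree()`);
* **presence/absence from WGS reads**: BLAST-style matching (identity >= 90%
  and query coverage >= 90%) against a reference locus, coverage tracks,
  and a deletion call that demands a bare target interval between
  well-covered flanks (`match_reads()`, `call_deletion()`, `dot_matrix()`);
* **branch-model dN/dS**: Goldman–Yang codon model over the 61 sense codons
  with branch-specific omega classes, likelihood by Felsenstein pruning in
  compiled code, constrained maximum-likelihood fitting, declarative model
  batteries, and chi-square likelihood-ratio tests
  (`fit_codon_model()`, `model_battery()`, `lrt()`);
* **synthetic data with known truth** for every input class: multi-exon
  loci with planted disruptions, shotgun read sets, and codon alignments
  evolved under known branch-specific omega (`make_locus()`,
  `plant_mutations()`, `make_reads()`, `simulate_codon_alignment()`).

The rate matrix is the GY94 parameterization: `q_ij = 0` unless codons `i`
and `j` differ at one position, otherwise `pi_j` times `kappa` for
transitions and `omega` for nonsynonymous changes, rescaled so branch
lengths are substitutions/codon.  Nested branch models are compared with
`2*dlnL ~ chisq(df = np_alt - np_null)`.

## Worked example

Build a five-exon synthetic locus, plant three disruptive mutations, and
let the annotator recover them:

```r
library(genedecay)

loc <- make_locus(locus_spec(n_exons = 5,
                             exon_lengths = c(120, 150, 90, 120, 120),
                             intron_lengths = 60, seed = 42))
pm <- plant_mutations(loc$genomic, loc$model, list(
  list(kind = "frameshift_deletion", exon = 2, offset = 31, length = 4),
  list(kind = "splice_donor", exon = 3),
  list(kind = "nonsense", exon = 4, offset = 13)), species = "whale_like")

ann <- annotate_gene(pm$genomic, loc$model, species = "whale_like")
format_mutations(ann$records)
#> exon 2: 4-nt deletion; exon 3: splice donor mutation (GT to GA); exon 4: nonsense codon
ann$call
#> functional call: pseudogene (58 aa)
```

The catalogue string is the standard mutation-table grammar; the 58-aa
product is the translation of the species-frame ORF up to the first stop
(the reference product is 199 aa), which is what the frameshift in exon 2
does to it.

Likelihood-ratio arithmetic from a published model-summary table (shipped
under `inst/extdata/`; `B` is the one-ratio model with omega fixed at 1,
`A` the free one-ratio model, `C`/`D` two-ratio models for the whale
branches):

```r
lrt_from_table(model_table("whale"), "B", "A")
#> B vs A: 2dlnL = 149.8160, df = 1, P = 1.902e-34 ***
lrt_from_table(model_table("whale"), "D", "C")
#> D vs C: 2dlnL = 3.9048, df = 1, P = 0.04815 *
```

The first row rejects strict neutrality for the whole tree (strong
purifying selection on average); the second shows the data are only
marginally distinguishable from omega = 1 on the whale branches — relaxed
selection after the whale lineages' gene copies were disrupted.

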