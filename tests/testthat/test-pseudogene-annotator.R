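test_that("detect_exon_indels records maximal gap runs with frame flags", {
  loc <- fixture_locus()
  refs <- ref_exon_seqs(loc)
  # killer-whale-like 4-nt deletion
  sp <- paste0(substr(refs[2L], 1L, 30L), substr(refs[2L], 35L, 150L))
  rec <- detect_exon_indels(sp, refs[2L], "killer_whale", 2L)
  expect_identical(rec$kind, "frameshift_deletion")
  expect_identical(rec$length, 4L)
  expect_identical(rec$exon, 2L)
  expect_identical(format_mutations(rec), "exon 2: 4-nt deletion")

  # cercopithecine-like 13-nt deletion in the last exon
  sp13 <- paste0(substr(refs[5L], 1L, 50L), substr(refs[5L], 64L, 120L))
  rec13 <- detect_exon_indels(sp13, refs[5L], "rhesus", 5L)
  expect_identical(rec13$kind, "frameshift_deletion")
  expect_identical(rec13$length, 13L)

  expect_identical(nrow(detect_exon_indels(refs[1L], refs[1L])), 0L)
  # in-frame deletion is catalogued but typed inframe
  sp3 <- paste0(substr(refs[3L], 1L, 20L), substr(refs[3L], 27L, 90L))
  expect_identical(detect_exon_indels(sp3, refs[3L])$kind, "inframe_deletion")
})

test_that("reference-frame stop/start scan finds planted events only", {
  loc <- fixture_locus()
  pm <- plant_mutations(loc$genomic, loc$model, list(
    list(kind = "nonsense", exon = 2L, offset = 13L, payload = "TAA"),
    list(kind = "start_loss", exon = 1L, offset = 1L, payload = "G")))
  ann <- annotate_gene(pm$genomic, loc$model, species = "baiji_like")
  expect_setequal(ann$records$kind, c("nonsense", "start_loss"))
  expect_identical(ann$records$detail[ann$records$kind == "start_loss"],
                   "ATG to GTG")

  # intact ortholog: no records at all
  ann0 <- annotate_gene(loc$genomic, loc$model)
  expect_identical(nrow(ann0$records), 0L)
  expect_identical(ann0$call$status, "intact")

  # stops arising downstream of a frameshift are consequences, not events:
  # the only catalogued record is the frameshift itself
  pm2 <- plant_mutations(loc$genomic, loc$model, list(
    list(kind = "frameshift_deletion", exon = 2L, offset = 31L,
         length = 4L)))
  ann2 <- annotate_gene(pm2$genomic, loc$model)
  expect_identical(ann2$records$kind, "frameshift_deletion")
  # ...while the species-frame ORF really is truncated
  expect_lt(ann2$call$protein_length, nchar(loc$cdna[[1L]]) / 3 - 1)
})

test_that("splice-site checks attribute donors upstream, acceptors downstream", {
  loc <- fixture_locus()
  pm <- plant_mutations(loc$genomic, loc$model, list(
    list(kind = "splice_donor", exon = 3L, payload = "ga"),
    list(kind = "splice_acceptor", exon = 4L, payload = "gg")))
  ann <- annotate_gene(pm$genomic, loc$model)
  don <- ann$records[ann$records$kind == "splice_donor", ]
  acc <- ann$records[ann$records$kind == "splice_acceptor", ]
  expect_identical(don$exon, 3L)
  expect_identical(don$detail, "GT to GA")
  expect_identical(acc$exon, 4L)
  expect_identical(acc$detail, "AG to GG")
  expect_identical(format_mutations(don), "exon 3: splice donor mutation (GT to GA)")

  expect_identical(nrow(check_splice_sites(loc$genomic,
    map_exons(loc$genomic, ref_exon_seqs(loc)))), 0L)
})

test_that("classify_gene applies its precedence and is monotone", {
  loc <- fixture_locus()
  hits <- map_exons(loc$genomic, ref_exon_seqs(loc))
  none <- mutation_record(character(), character())
  vc <- build_virtual_cdna(hits, loc$genomic)
  expect_identical(classify_gene(none, hits, loc$model,
                                 virtual_cdna = vc)$status, "intact")

  # last-exon frameshift only -> altered C-terminus, shorter product,
  # and no nonsense records in earlier exons
  pm <- plant_mutations(loc$genomic, loc$model, list(
    list(kind = "frameshift_deletion", exon = 5L, offset = 40L,
         length = 13L)))
  ann <- annotate_gene(pm$genomic, loc$model)
  expect_identical(ann$call$status, "altered_Cterm")
  expect_false(any(ann$records$kind == "nonsense"))
  expect_lt(ann$call$protein_length, nchar(loc$cdna[[1L]]) / 3 - 1)

  # adding a disruptive record never moves the call toward intact
  order_of <- function(s) match(s, c("intact", "altered_Cterm",
                                     "pseudogene", "gene_absent"))
  extra <- list(mutation_record("q", "nonsense", 2L, position = 4L),
                mutation_record("q", "splice_donor", 1L, detail = "GT to GC"),
                mutation_record("q", "gene_deletion"))
  recs <- ann$records
  prev <- ann$call$status
  for (e in extra) {
    recs <- .bind_records_for_test(recs, e)
    now <- classify_gene(recs, hits, loc$model, virtual_cdna = vc)$status
    expect_gte(order_of(now), order_of(prev))
    prev <- now
  }

  # read-based deletion call dominates everything
  expect_identical(classify_gene(none, hits, loc$model,
                                 deletion_call = "deleted")$status,
                   "gene_absent")
})

test_that("Dollo assignment places shared events on stems only when exact", {
  phy <- ape::read.tree(text = paste0(
    "(((killer_whale,dolphin),(porpoise,baiji)),(minke,fin),cow);"))
  recs <- .bind_records_for_test(
    mutation_record(c("killer_whale", "dolphin", "porpoise", "baiji"),
                    "frameshift_deletion", 2L, position = 31L, length = 4L),
    mutation_record(c("minke", "fin"), "nonsense", 2L, position = 55L,
                    detail = "TAA"),
    mutation_record("baiji", "start_loss", 1L, position = 1L,
                    detail = "ATG to GTG"),
    # present in a set that is NOT a full clade (killer_whale + minke)
    mutation_record(c("killer_whale", "minke"), "nonsense", 7L,
                    position = 10L, detail = "TGA"))
  placed <- assign_mutations_to_tree(recs, phy)

  toothed <- placed[placed$kind == "frameshift_deletion", ]
  expect_true(toothed$shared)
  expect_identical(toothed$node,
                   ape::getMRCA(phy, c("killer_whale", "baiji")))
  baleen <- placed[placed$kind == "nonsense" & placed$exon == 2L, ]
  expect_true(baleen$shared)
  expect_identical(baleen$node, ape::getMRCA(phy, c("minke", "fin")))
  single <- placed[placed$kind == "start_loss", ]
  expect_false(single$shared)
  expect_identical(single$branch_label, "baiji")
  # non-clade sharing falls back to independent terminal events
  conv <- placed[placed$kind == "nonsense" & placed$exon == 7L, ]
  expect_identical(nrow(conv), 2L)
  expect_false(any(conv$shared))
  # nothing lands on the whale stem
  whale_stem <- ape::getMRCA(phy, c("killer_whale", "fin"))
  expect_false(whale_stem %in% placed$node)

  expect_error(assign_mutations_to_tree(
    mutation_record("sperm_whale", "gene_deletion"), phy), "not in tree")
})
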