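test_that("make_locus builds a consistent locus and is seed-deterministic", {
  spec <- locus_spec(n_exons = 3L, exon_lengths = c(9L, 12L, 9L),
                     intron_lengths = 30L, seed = 1L)
  loc <- make_locus(spec)
  expect_identical(nchar(loc$cdna[[1L]]), 30L)
  expect_identical(nchar(translate_cds(loc$cdna)[[1L]]), 9L)  # 30/3 - 1

  # concatenated exons reproduce the cDNA; introns are canonical gt..ag
  g <- loc$genomic[[1L]]
  ex <- loc$model$exons
  expect_identical(paste0(substring(g, ex$start, ex$end), collapse = ""),
                   loc$cdna[[1L]])
  for (i in seq_len(nrow(ex) - 1L)) {
    intron <- substr(g, ex$end[i] + 1L, ex$start[i + 1L] - 1L)
    expect_identical(substr(intron, 1L, 2L), "gt")
    expect_identical(substr(intron, nchar(intron) - 1L, nchar(intron)), "ag")
  }
  aa <- translate_cds(loc$cdna)[[1L]]
  expect_false(grepl("*", aa, fixed = TRUE))  # no internal stop
  expect_identical(substr(loc$cdna[[1L]], 1L, 3L), "ATG")

  expect_identical(make_locus(spec), loc)  # pure function of the spec
  expect_error(locus_spec(3L, c(9L, 12L, 8L), 30L), "divisible by 3")
  expect_error(locus_spec(3L, c(9L, 12L, 9L), 10L), ">= 20")
})

test_that("the default 13-exon locus translates to 618 residues", {
  loc <- make_locus(locus_spec(seed = 7L))
  expect_identical(sum(nchar(ref_exon_seqs(loc))), 1857L)
  expect_identical(nchar(translate_cds(loc$cdna)[[1L]]), 618L)
})

test_that("plant_mutations applies each edit kind and records truth", {
  loc <- fixture_locus()
  g0 <- loc$genomic[[1L]]
  ex <- loc$model$exons

  # nonsense at an in-frame offset of exon 2 (cdna offset 120 -> frame 0)
  pm <- plant_mutations(loc$genomic, loc$model,
                        list(list(kind = "nonsense", exon = 2L, offset = 13L,
                                  payload = "TGA")))
  p <- ex$start[2L] + 12L
  expect_identical(substr(pm$genomic[[1L]], p, p + 2L), "TGA")
  expect_identical(pm$truth$kind, "nonsense")

  pm <- plant_mutations(loc$genomic, loc$model,
                        list(list(kind = "frameshift_deletion", exon = 2L,
                                  offset = 31L, length = 4L)))
  expect_identical(nchar(pm$genomic[[1L]]), nchar(g0) - 4L)

  pm <- plant_mutations(loc$genomic, loc$model,
                        list(list(kind = "start_loss", exon = 1L,
                                  offset = 1L, payload = "G")))
  expect_identical(substr(pm$genomic[[1L]], ex$start[1L], ex$start[1L] + 2L),
                   "GTG")
  expect_identical(pm$truth$detail, "ATG to GTG")

  # same seed twice -> identical bytes
  muts <- list(list(kind = "frameshift_insertion", exon = 3L, offset = 20L,
                    length = 2L))
  expect_identical(plant_mutations(loc$genomic, loc$model, muts, seed = 5L),
                   plant_mutations(loc$genomic, loc$model, muts, seed = 5L))

  expect_error(plant_mutations(loc$genomic, loc$model, list(
    list(kind = "frameshift_deletion", exon = 2L, offset = 10L, length = 4L),
    list(kind = "frameshift_insertion", exon = 2L, offset = 12L,
         length = 1L))), "overlapping")
  expect_error(plant_mutations(loc$genomic, loc$model, list(
    list(kind = "nonsense", exon = 2L, offset = 14L))), "codon boundary")
  expect_error(plant_mutations(loc$genomic, loc$model, list(
    list(kind = "start_loss", exon = 2L, offset = 1L))), "exon 1")
})

test_that("make_reads hits its coverage target and is exact at error 0", {
  loc <- fixture_locus()
  rs <- make_reads(loc$genomic, length = 80L, depth = 20, error_rate = 0,
                   seed = 2L)
  g <- toupper(loc$genomic[[1L]])
  # binomial/Poisson oracle: mean coverage ~ depth within sampling noise
  cov <- coverage_track(data.frame(read = names(rs$reads), start = rs$start,
                                   end = rs$start + rs$length - 1L,
                                   identity = 1, qcov = 1), nchar(g))
  expect_lt(abs(mean(cov) - 20), 3)
  # every read an exact substring
  expect_true(all(vapply(seq_along(rs$reads), function(i)
    substr(g, rs$start[i], rs$start[i] + rs$length - 1L) == rs$reads[[i]],
    TRUE)))
  expect_identical(make_reads(loc$genomic, 80L, 20, 0, seed = 2L), rs)
  expect_error(make_reads(loc$genomic, 80L, depth = 0), "depth")
  expect_error(make_reads(loc$genomic, nchar(g) + 1L, 5), "exceeds")
})

test_that("codon simulation is stationary and degenerate cases behave", {
  lt <- read_newick_labeled(text = "(A:0,B:0,C:0);")
  aln <- simulate_codon_alignment(lt, list(kappa = 2, omega = 0.5), 50L,
                                  seed = 3L)
  m <- unclass(aln)
  expect_true(all(m[1L, ] == m[2L, ]) && all(m[1L, ] == m[3L, ]))

  # one long branch: terminal distribution converges to pi
  lt2 <- read_newick_labeled(text = "(A:0.01,B:50);")
  set.seed(4)
  pi <- {x <- rgamma(61, 5); x / sum(x)}
  aln2 <- simulate_codon_alignment(lt2, list(kappa = 2, omega = 0.3,
                                             pi = pi), 5000L, seed = 4L)
  counts <- tabulate(unclass(aln2)["B", ], nbins = 61L)
  gof <- suppressWarnings(stats::chisq.test(counts, p = pi))
  expect_gt(gof$p.value, 0.01)

  expect_identical(simulate_codon_alignment(lt, list(kappa = 2, omega = 1),
                                            10L, seed = 9L),
                   simulate_codon_alignment(lt, list(kappa = 2, omega = 1),
                                            10L, seed = 9L))
  expect_error(simulate_codon_alignment(lt, list(kappa = 2, omega = 1,
                                                 pi = rep(0, 61)), 5L),
               "frequencies")
})
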