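# shared fixture: a locus embedded in random flanks, plus a version with the
# gene segment replaced by non-homologous sequence
presence_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    loc <- make_locus(locus_spec(n_exons = 4L,
                                 exon_lengths = c(120L, 120L, 120L, 120L),
                                 intron_lengths = 300L, seed = 9L))
    set.seed(99)
    flankL <- genedecay:::.random_bases(2000L, 0.45)
    flankR <- genedecay:::.random_bases(2000L, 0.45)
    region <- setNames(paste0(flankL, toupper(loc$genomic[[1L]]), flankR),
                       "region")
    del <- plant_mutations(loc$genomic, loc$model,
                           list(list(kind = "gene_deletion")))
    region_del <- setNames(paste0(flankL, toupper(del$genomic[[1L]]),
                                  flankR), "region_del")
    cache <<- list(region = region, region_del = region_del,
                   gene = c(2001L, 2000L + nchar(loc$genomic[[1L]])))
    cache
  }
})

test_that("error-free reads match exactly at their true positions", {
  fx <- presence_fixture()
  rs <- make_reads(fx$region, length = 100L, depth = 3, error_rate = 0,
                   seed = 1L)
  m <- match_reads(rs, fx$region)
  expect_identical(nrow(m), length(rs$reads))
  expect_true(all(m$identity == 1))
  expect_true(all(m$qcov == 1))
  expect_identical(m$start, rs$start[match(m$read, names(rs$reads))])
})

test_that("the identity filter is exactly thresholded", {
  fx <- presence_fixture()
  g <- fx$region[[1L]]
  # 1000-nt probe read: clean first 100 nt (keeps k-mer seeds alive),
  # mismatches spread evenly over the rest, ending on a matching base
  plant <- function(nmis) {
    r <- strsplit(substr(g, 501L, 1500L), "")[[1L]]
    pos <- round(seq(105L, 995L, length.out = nmis))
    r[pos] <- vapply(r[pos], function(b)
      setdiff(c("A", "C", "G", "T"), b)[1L], "")
    setNames(paste0(r, collapse = ""), "probe")
  }
  at <- match_reads(plant(100L), fx$region, k = 16L)  # identity exactly 0.90
  expect_identical(nrow(at), 1L)
  expect_identical(at$identity, 0.90)
  expect_identical(nrow(match_reads(plant(101L), fx$region, k = 16L)), 0L)

  # reads engineered at exactly 85% identity yield zero retained matches
  starts <- seq(101L, 1001L, by = 100L)
  bad <- vapply(starts, function(s) {
    r <- strsplit(substr(g, s, s + 99L), "")[[1L]]
    pos <- round(seq(25L, 97L, length.out = 15L))
    r[pos] <- vapply(r[pos], function(b)
      setdiff(c("A", "C", "G", "T"), b)[1L], "")
    paste0(r, collapse = "")
  }, "")
  names(bad) <- paste0("bad", seq_along(bad))
  expect_identical(nrow(match_reads(bad, fx$region)), 0L)

  # reads from inside the non-homologous replacement segment never match
  repl <- setNames(substr(fx$region_del[[1L]], fx$gene[1L] + 10L,
                          fx$gene[1L] + 800L), "repl")
  rep_reads <- make_reads(repl, length = 100L, depth = 3, error_rate = 0,
                          seed = 4L)
  expect_identical(nrow(match_reads(rep_reads, fx$region)), 0L)

  expect_error(match_reads(setNames("ACGTACGT", "tiny"), fx$region, k = 16L),
               "seed length")
})

test_that("deletion calling is decisive on control and deleted loci", {
  fx <- presence_fixture()
  target <- c(fx$gene[1L] + 100L, fx$gene[2L] - 100L)
  rs <- make_reads(fx$region, length = 100L, depth = 20, error_rate = 0.01,
                   seed = 5L)
  m <- match_reads(rs, fx$region)
  tr <- coverage_track(m, nchar(fx$region[[1L]]))
  expect_identical(call_deletion(tr, target), "present")

  rs2 <- make_reads(fx$region_del, length = 100L, depth = 20,
                    error_rate = 0.01, seed = 6L)
  m2 <- match_reads(rs2, fx$region)
  tr2 <- coverage_track(m2, nchar(fx$region[[1L]]))
  expect_identical(call_deletion(tr2, target), "deleted")

  # permutation invariance in read order
  m2p <- m2[sample.int(nrow(m2)), ]
  tr2p <- coverage_track(m2p, nchar(fx$region[[1L]]))
  expect_identical(call_deletion(tr2p, target), "deleted")

  empty <- coverage_track(match_reads(character(0), fx$region),
                          nchar(fx$region[[1L]]))
  expect_identical(call_deletion(empty, target), "inconclusive")
})

test_that("dot_matrix shows diagonals, breaks, and near-zero background", {
  fx <- presence_fixture()
  a <- setNames(substr(fx$region[[1L]], 1L, 1500L), "a")
  d <- dot_matrix(a, a)
  fwd <- d[d$strand == "+", ]
  expect_true(all(seq_len(1500L - 12L + 1L) %in% fwd$i[fwd$i == fwd$j]))

  # locus vs locus-with-gene-replaced: diagonal broken over the replacement
  dA <- dot_matrix(fx$region, fx$region_del)
  diag_pts <- dA[dA$strand == "+" & dA$i == dA$j, ]
  inside <- diag_pts$i > fx$gene[1L] & diag_pts$i < fx$gene[2L] - 12L
  expect_identical(sum(inside), 0L)
  expect_gt(sum(diag_pts$i < fx$gene[1L] - 12L), 1900L)

  # unrelated random sequences: expected points ~ (L-w+1)^2 / 4^12
  set.seed(10)
  r1 <- setNames(genedecay:::.random_bases(1000L, 0.5), "r1")
  r2 <- setNames(genedecay:::.random_bases(1000L, 0.5), "r2")
  d0 <- dot_matrix(r1, r2)
  expect_lt(nrow(d0[d0$strand == "+", ]), 5L)  # expectation ~ 0.06
})
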