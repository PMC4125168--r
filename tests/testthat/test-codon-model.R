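test_that("F3x4 frequencies match a counting oracle and basic symmetry", {
  # two taxa, three codons, counted by hand via direct tabulation
  aln <- codon_alignment(c(a = "ATGAAATTT", b = "ATGCCCTTT"))
  m <- unclass(aln)
  cods <- attr(aln, "codons")[as.vector(m)]
  nt <- do.call(rbind, strsplit(cods, ""))
  f <- sapply(1:3, function(p) {
    tab <- table(factor(nt[, p], levels = c("A", "C", "G", "T")))
    as.numeric(tab / sum(tab))
  })
  ntc <- do.call(rbind, strsplit(attr(aln, "codons"), ""))
  base <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  expected <- f[base[ntc[, 1L]], 1L] * f[base[ntc[, 2L]], 2L] *
    f[base[ntc[, 3L]], 3L]
  expected <- expected / sum(expected)
  expect_equal(f3x4_frequencies(aln), expected, tolerance = 1e-12)
  expect_equal(sum(f3x4_frequencies(aln)), 1, tolerance = 1e-12)

  # uniform nucleotide usage at every position -> uniform over 61 codons
  # after renormalization is NOT uniform (stop removal skews it); instead
  # check the defining product property on a balanced alignment
  expect_equal(sum(f1x4_frequencies(aln)), 1, tolerance = 1e-12)
  expect_equal(sum(f61_frequencies(aln)), 1, tolerance = 1e-12)

  gap <- codon_alignment(c(a = "---", b = "---"))
  expect_error(f3x4_frequencies(gap), "no observed data")
})

test_that("the GY94 generator has the prescribed structure", {
  pi <- rep(1 / 61, 61)
  Q <- codon_rate_matrix(kappa = 2, omega = 0.5, pi = pi)
  # synonymous transition vs nonsynonymous transversion = kappa / omega
  expect_equal(Q["TTT", "TTC"] / Q["TTT", "TTA"], 4, tolerance = 1e-12)
  # codons differing at >1 position never exchange directly
  expect_identical(Q["TTT", "ACT"], 0)
  expect_identical(Q["AAA", "CCA"], 0)
  # omega = kappa = 1, uniform pi: all permitted off-diagonals equal
  Q1 <- codon_rate_matrix(1, 1, pi)
  off <- Q1[Q1 > 0]
  expect_lt(diff(range(off)), 1e-14)
  # detailed balance (pi_i q_ij == pi_j q_ji) and unit equilibrium flux
  expect_lt(max(abs(pi * Q - t(pi * Q))), 1e-14)
  expect_lt(abs(-sum(pi * diag(Q)) - 1), 1e-12)

  set.seed(1)
  pir <- {x <- rgamma(61, 2); x / sum(x)}
  Qr <- codon_rate_matrix(3, 0.2, pir)
  expect_lt(max(abs(pir * Qr - t(pir * Qr))), 1e-14)
  expect_lt(abs(-sum(pir * diag(Qr)) - 1), 1e-12)
  for (t in c(0, 0.1, 1, 10)) {
    P <- codon_pmat(3, 0.2, pir, t)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_true(all(P >= 0))
  }
})

test_that("pruning equals enumeration, and is invariant to root and order", {
  set.seed(7)
  pi <- {x <- rgamma(61, 1); x / sum(x)}
  lt <- read_newick_labeled(text = "(A:0.2,B:0.5,C:0.1);")
  aln <- simulate_codon_alignment(lt, list(kappa = 3, omega = 0.4, pi = pi),
                                  6L, seed = 7L)
  ll <- codon_log_likelihood(aln, lt, kappa = 3, omega = 0.4, pi = pi)
  oracle <- brute_lnL_star(aln, c(0.2, 0.5, 0.1), 3, rep(0.4, 3), pi)
  expect_equal(as.numeric(ll), oracle, tolerance = 1e-8)

  # single taxon, single codon: lnL = log pi_c
  one <- codon_alignment(c(A = "ATG"))
  lt1 <- labeled_tree(ape::read.tree(text = "(A);"))
  idx <- match("ATG", codon_states()$codons)
  expect_equal(as.numeric(codon_log_likelihood(one, lt1, 2, 0.4, pi = pi)),
               log(pi[idx]), tolerance = 1e-12)

  # re-rooting leaves the likelihood unchanged (reversibility)
  phy <- ape::read.tree(text =
    "((A:0.1,B:0.2):0.05,(C:0.3,D:0.15):0.1,E:0.25);")
  lt5 <- labeled_tree(phy)
  aln5 <- simulate_codon_alignment(lt5, list(kappa = 2, omega = 0.3,
                                             pi = pi), 40L, seed = 8L)
  ll_un <- codon_log_likelihood(aln5, lt5, 2, 0.3, pi = pi)
  re <- ape::root(phy, outgroup = "C", resolve.root = TRUE)
  ll_re <- codon_log_likelihood(aln5, labeled_tree(re), 2, 0.3, pi = pi)
  expect_lt(abs(ll_un - ll_re), 1e-9)

  # taxon order in the alignment is irrelevant
  shuffled <- unclass(aln5)[c(3L, 1L, 5L, 2L, 4L), ]
  aln5s <- structure(shuffled, codons = attr(aln5, "codons"),
                     class = "codon_alignment")
  expect_equal(as.numeric(codon_log_likelihood(aln5s, lt5, 2, 0.3, pi = pi)),
               as.numeric(ll_un), tolerance = 1e-12)

  # missing codons contribute all-ones partials: dropping a taxon's data
  # entirely equals the likelihood of the remaining tree marginal
  m <- unclass(aln)
  m["C", ] <- NA_integer_
  alnNA <- structure(m, codons = attr(aln, "codons"),
                     class = "codon_alignment")
  llNA <- codon_log_likelihood(alnNA, lt, 3, 0.4, pi = pi)
  two <- codon_alignment(setNames(
    vapply(c("A", "B"), function(tx) paste0(
      codon_states()$codons[unclass(aln)[tx, ]], collapse = ""), ""),
    c("A", "B")))
  lt2 <- labeled_tree(ape::read.tree(text = "(A:0.7,B:0);"))
  # A-B path length 0.2 + 0.5; C's branch integrates out
  ll2 <- codon_log_likelihood(two, lt2, 3, 0.4, pi = pi)
  expect_equal(as.numeric(llNA), as.numeric(ll2), tolerance = 1e-8)
})

test_that("fitting honours constraints, counts parameters, and nests", {
  phy <- ape::read.tree(text =
    "((t1:0.1,t2:0.2):0.05,(t3:0.1,t4:0.3):0.05,t5:0.2);")
  lt <- labeled_tree(phy, as.integer(phy$edge[, 2L] %in% 1:2))
  aln <- simulate_codon_alignment(lt, list(kappa = 2, omega = c(0.3, 1)),
                                  200L, seed = 21L)
  nedge <- nrow(phy$edge)

  fit1 <- fit_codon_model(aln, labeled_tree(phy), n_starts = 1L)
  expect_identical(fit1$np, 1L + 1L + nedge)
  fit2 <- fit_codon_model(aln, lt, n_starts = 1L)
  expect_identical(fit2$np, 2L + 1L + nedge)
  fit2f <- fit_codon_model(aln, lt, fixed = c("1" = 1), n_starts = 1L)
  expect_identical(fit2f$np, 1L + 1L + nedge)
  expect_identical(unname(fit2f$omega[2L]), 1)
  fitF <- fit_codon_model(aln, labeled_tree(phy), free_ratio = TRUE,
                          n_starts = 1L)
  expect_identical(fitF$np, nedge + 1L + nedge)
  expect_length(fitF$omega_by_branch, nedge)

  # nesting: every constrained model is dominated by its relaxation
  expect_lte(fit1$lnL, fit2$lnL + 1e-6)
  expect_lte(fit2f$lnL, fit2$lnL + 1e-6)
  expect_lte(fit2$lnL, fitF$lnL + 1e-6)
  expect_true(all(vapply(list(fit1, fit2, fit2f, fitF),
                         function(f) f$converged, TRUE)))

  expect_error(fit_codon_model(aln, lt, fixed = c("5" = 1)), "out of range")
  alnX <- codon_alignment(c(x1 = "ATG", x2 = "ATG"))
  expect_error(fit_codon_model(alnX, lt), "missing from alignment")
})
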