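# Shared fixtures and independent oracles.
#
# The brute-force likelihood enumerates internal-node states with matrix
# exponentials from Matrix::expm -- a code path fully independent of the
# package's eigendecomposition + pruning implementation.

# enumeration oracle for a 3-taxon unrooted star (one internal node)
brute_lnL_star <- function(aln, blen, kappa, omega_by_edge, pi) {
  m <- unclass(aln)
  stopifnot(nrow(m) == 3L)
  P <- lapply(seq_len(3L), function(i) {
    Q <- codon_rate_matrix(kappa, omega_by_edge[i], pi)
    as.matrix(Matrix::expm(Q * blen[i]))
  })
  tot <- 0
  for (s in seq_len(ncol(m))) {
    like_tip <- function(i) {
      st <- m[i, s]
      if (is.na(st)) rowSums(P[[i]]) else P[[i]][, st]  # missing: all states
    }
    tot <- tot + log(sum(pi * like_tip(1L) * like_tip(2L) * like_tip(3L)))
  }
  tot
}

# small five-exon locus used across annotator tests
fixture_locus <- function(seed = 42L) {
  make_locus(locus_spec(n_exons = 5L, exon_lengths = c(120L, 150L, 90L,
                                                       120L, 120L),
                        intron_lengths = 60L, seed = seed))
}

ref_exon_seqs <- function(loc) {
  widths <- loc$model$exons$end - loc$model$exons$start + 1L
  substring(loc$model$cdna, loc$model$cdna_offset + 1L,
            loc$model$cdna_offset + widths)
}

# random legal mutation set for the planted-truth round-trip property;
# placements keep clear of exon edges so events cannot interact
random_mutation_set <- function(n_exons, exon_lengths, rng_seed) {
  set.seed(rng_seed)
  if (runif(1) < 0.05) return(list(list(kind = "gene_deletion")))
  n <- sample(0:3, 1L)
  if (n == 0L) return(list())
  kinds <- sample(c("nonsense", "frameshift_insertion", "frameshift_deletion",
                    "inframe_deletion", "splice_donor", "splice_acceptor",
                    "start_loss", "exon_deletion"), n)
  used_exons <- integer(0)
  out <- list()
  offs <- cumsum(c(0L, exon_lengths))[seq_len(n_exons)]
  for (kind in kinds) {
    legal <- switch(kind,
      start_loss = 1L,
      splice_donor = seq_len(n_exons - 1L),
      splice_acceptor = 2:n_exons,
      exon_deletion = 2:(n_exons - 1L),
      2:(n_exons - 1L))
    legal <- setdiff(legal, used_exons)
    if (!length(legal)) next
    e <- if (length(legal) == 1L) legal else sample(legal, 1L)
    # reserve neighbours so edits can never touch the same intron
    used_exons <- c(used_exons, switch(kind,
      exon_deletion = (e - 1L):(e + 1L),
      splice_donor = c(e, e + 1L),
      splice_acceptor = c(e - 1L, e),
      e))
    elen <- exon_lengths[e]
    m <- list(kind = kind, exon = e)
    if (kind == "nonsense") {
      # interior codon boundary >= 9 nt from either exon edge
      cand <- which((offs[e] + seq_len(elen) - 1L) %% 3L == 0L)
      cand <- cand[cand >= 9L & cand <= elen - 11L]
      if (!length(cand)) next
      m$offset <- sample(cand, 1L)
    } else if (kind %in% c("frameshift_insertion", "frameshift_deletion",
                           "inframe_deletion")) {
      m$length <- switch(kind, frameshift_insertion = sample(c(1L, 2L, 4L), 1L),
                         frameshift_deletion = sample(c(1L, 2L, 4L, 13L), 1L),
                         inframe_deletion = sample(c(3L, 6L), 1L))
      m$offset <- sample(seq(9L, elen - m$length - 8L), 1L)
    } else if (kind == "start_loss") {
      m$offset <- 1L
    }
    out[[length(out) + 1L]] <- m
  }
  out
}

.bind_records_for_test <- function(...) genedecay:::.bind_records(...)

# "2 units in the last printed digit" of a number given as a string,
# e.g. "2.34e-74" -> 2e-76, "0.04815" -> 2e-5
last_digit_tol <- function(s) {
  mant <- sub("[eE].*$", "", s)
  expo <- if (grepl("[eE]", s)) as.integer(sub("^.*[eE]", "", s)) else 0L
  dec <- if (grepl("\\.", mant)) nchar(sub("^[^.]*\\.", "", mant)) else 0L
  2 * 10^(expo - dec)
}

# (kind, exon, exon_end, length) multiset for truth comparison
mutation_key <- function(rec) {
  if (nrow(rec) == 0L) return(character(0))
  sort(paste(rec$kind, rec$exon, rec$exon_end, rec$length, sep = ":"))
}
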