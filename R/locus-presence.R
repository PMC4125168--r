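# Gene presence/absence from shotgun reads.
#
# Reads are placed on the locus by exact k-mer seeding and ungapped
# extension (a banded gapped rescue via pairwise alignment handles the rare
# seed-consistent but indel-containing case).  A read is retained only when
# its identity and query coverage both clear their thresholds -- the
# conventional "90% identity, 90% coverage" match rule.  Presence or
# absence of a target interval is then read off the per-position coverage
# track: a deletion call requires a completely bare target flanked on both
# sides by well-covered sequence.

# maximal-scoring contiguous segment of a match/mismatch vector under
# +1/-1 scoring (vectorized Kadane); returns 1-based [from, to] and the
# match count inside
.best_segment <- function(cmp) {
  x <- ifelse(cmp, 1L, -1L)
  s <- cumsum(x)
  pre <- c(0L, s[-length(s)])
  m <- cummin(pre)
  b <- which.max(s - m)
  a <- which(pre == m[b])[1L]  # first index achieving the min prefix
  list(from = a, to = b, matches = sum(cmp[a:b]), len = b - a + 1L)
}

# positions of every k-mer of s, as an environment keyed by k-mer string
.kmer_index <- function(s, k, mask = NULL) {
  L <- nchar(s)
  pos <- seq_len(L - k + 1L)
  if (!is.null(mask)) {
    # a seed is masked when any of its bases is masked
    bad <- unique(unlist(lapply(pos, function(p)
      if (any(mask[p:(p + k - 1L)])) p else NULL)))
    pos <- setdiff(pos, bad)
  }
  words <- substring(s, pos, pos + k - 1L)
  split(pos, words)
}

#' Match reads against a reference locus
#'
#' @param reads A `read_set` from [make_reads()], or a named character
#'   vector of read sequences.
#' @param locus Locus sequence (named character of length 1).
#' @param min_identity Minimum identity (matching bases / aligned length)
#'   within the best local segment; retained matches satisfy
#'   `identity >= min_identity`.
#' @param min_qcov Minimum query coverage: aligned segment length / read
#'   length.  Reads hanging off the locus or into non-homologous sequence
#'   fail this filter, so a deleted region stays strictly bare.
#' @param k Exact-seed length (error if longer than the reads).
#' @param mask Optional logical vector (locus length): masked positions are
#'   excluded from seeding, emulating repeat masking.
#' @return Data frame of retained matches: `read`, `start`, `end` (locus,
#'   1-based), `identity`, `qcov`.  Best location per read.
#' @export
match_reads <- function(reads, locus, min_identity = 0.90, min_qcov = 0.90,
                        k = 16L, mask = NULL) {
  rd <- if (inherits(reads, "read_set")) reads$reads else reads
  g <- toupper(unname(locus[[1L]]))
  L <- nchar(g)
  if (length(rd) == 0L)
    return(data.frame(read = character(), start = integer(),
                      end = integer(), identity = numeric(),
                      qcov = numeric(), stringsAsFactors = FALSE))
  if (any(k > nchar(rd))) stop("seed length k exceeds a read length")
  idx <- .kmer_index(g, k, mask)
  gchars <- strsplit(g, "")[[1L]]
  out <- vector("list", length(rd))
  for (i in seq_along(rd)) {
    r <- toupper(rd[[i]])
    rl <- nchar(r)
    qpos <- unique(c(seq(1L, rl - k + 1L, by = k), rl - k + 1L))
    words <- substring(r, qpos, qpos + k - 1L)
    hit <- idx[words]
    diags <- unlist(lapply(seq_along(qpos), function(j)
      if (!is.null(hit[[j]])) hit[[j]] - qpos[j] + 1L else NULL))
    if (is.null(diags) || !length(diags)) next
    tab <- sort(table(diags), decreasing = TRUE)
    cand <- as.integer(names(tab))[seq_len(min(3L, length(tab)))]
    best <- NULL
    rchars <- strsplit(r, "")[[1L]]
    for (d in cand) {
      s0 <- max(1L, d); e0 <- min(L, d + rl - 1L)
      qs <- s0 - d + 1L; qe <- e0 - d + 1L
      # maximal-scoring ungapped segment (match +1 / mismatch -1): the HSP
      cmp <- gchars[s0:e0] == rchars[qs:qe]
      hsp <- .best_segment(cmp)
      identity <- hsp$matches / hsp$len
      qcov <- hsp$len / rl
      hs <- s0 + hsp$from - 1L
      he <- s0 + hsp$to - 1L
      if (identity + 1e-9 < min_identity && rl >= 2L * k) {
        # gapped rescue in a small band around the seeded diagonal
        ws <- max(1L, s0 - 10L); we <- min(L, e0 + 10L)
        pa <- pairwiseAlignment(r, substr(g, ws, we), type = "global-local",
                                substitutionMatrix = .gd_submat(),
                                gapOpening = 3, gapExtension = 1)
        identity <- nmatch(pa) / rl
        hs <- ws + start(subject(pa)) - 1L
        he <- ws + end(subject(pa)) - 1L
        qcov <- (end(pattern(pa)) - start(pattern(pa)) + 1L) / rl
      }
      if (is.null(best) || identity > best$identity)
        best <- list(start = hs, end = he, identity = identity, qcov = qcov)
    }
    if (best$identity + 1e-9 >= min_identity &&
        best$qcov + 1e-9 >= min_qcov) {
      out[[i]] <- data.frame(read = names(rd)[i], start = best$start,
                             end = best$end, identity = best$identity,
                             qcov = best$qcov, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res))
    res <- data.frame(read = character(), start = integer(),
                      end = integer(), identity = numeric(),
                      qcov = numeric(), stringsAsFactors = FALSE)
  res
}

#' Per-position coverage track from read matches
#'
#' @param matches Match table from [match_reads()].
#' @param locus_length Length of the locus.
#' @param mask Optional logical vector; masked positions get NA counts.
#' @return Integer vector of match counts per locus position (NA where
#'   masked).
#' @export
coverage_track <- function(matches, locus_length, mask = NULL) {
  cov <- integer(locus_length)
  if (nrow(matches)) {
    # difference-array accumulation
    d <- integer(locus_length + 1L)
    for (i in seq_len(nrow(matches))) {
      d[matches$start[i]] <- d[matches$start[i]] + 1L
      d[matches$end[i] + 1L] <- d[matches$end[i] + 1L] - 1L
    }
    cov <- cumsum(d[seq_len(locus_length)])
  }
  if (!is.null(mask)) cov[mask] <- NA_integer_
  cov
}

#' Call presence/absence of a target interval from coverage
#'
#' @param track Coverage track from [coverage_track()].
#' @param target Integer vector `c(start, end)` of the interval under test
#'   (e.g. the gene span), 1-based inclusive.
#' @param flanks List of two `c(start, end)` intervals flanking the target;
#'   default: everything left and right of the target.
#' @param min_flank_cov Minimum mean flank coverage for a decisive call.
#' @return `"deleted"` (bare target, both flanks covered), `"present"`
#'   (target mean at least `min_flank_cov`), else `"inconclusive"`.
#' @export
call_deletion <- function(track, target, flanks = NULL, min_flank_cov = 5) {
  L <- length(track)
  stopifnot(target[1L] >= 1L, target[2L] <= L, target[1L] <= target[2L])
  if (is.null(flanks)) {
    flanks <- list()
    if (target[1L] > 1L) flanks <- c(flanks, list(c(1L, target[1L] - 1L)))
    if (target[2L] < L) flanks <- c(flanks, list(c(target[2L] + 1L, L)))
  }
  if (!length(flanks)) stop("no flanking sequence to judge against")
  mean_cov <- function(iv) mean(track[iv[1L]:iv[2L]], na.rm = TRUE)
  tmean <- mean_cov(target)
  fmeans <- vapply(flanks, mean_cov, 0)
  if (is.nan(tmean)) return("inconclusive")
  if (tmean == 0 && all(fmeans >= min_flank_cov)) return("deleted")
  if (tmean >= min_flank_cov) return("present")
  "inconclusive"
}

#' Dot-matrix comparison of two sequences
#'
#' Exact shared words of length `word` on the forward strand, plus
#' reverse-complement matches flagged `strand = "-"`.
#'
#' @param seqA,seqB Sequences (character of length 1).
#' @param word Word size (>= 4).
#' @return Data frame of match points `i` (position in `seqA`), `j`
#'   (position in `seqB`, forward coordinates), `strand`.
#' @export
dot_matrix <- function(seqA, seqB, word = 12L) {
  if (word < 4L) stop("word size must be >= 4")
  a <- toupper(unname(seqA[[1L]])); b <- toupper(unname(seqB[[1L]]))
  if (nchar(a) < word || nchar(b) < word)
    return(data.frame(i = integer(), j = integer(), strand = character()))
  idxB <- .kmer_index(b, word)
  posA <- seq_len(nchar(a) - word + 1L)
  wordsA <- substring(a, posA, posA + word - 1L)
  fwd <- idxB[wordsA]
  pts <- do.call(rbind, lapply(seq_along(posA), function(i)
    if (!is.null(fwd[[i]]))
      data.frame(i = posA[i], j = fwd[[i]], strand = "+") else NULL))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(a)))
  wordsR <- substring(rc, posA, posA + word - 1L)
  rev <- idxB[wordsR]
  La <- nchar(a)
  ptsR <- do.call(rbind, lapply(seq_along(posA), function(i)
    if (!is.null(rev[[i]]))
      data.frame(i = La - word + 2L - posA[i], j = rev[[i]], strand = "-")
    else NULL))
  out <- rbind(pts, ptsR)
  if (is.null(out))
    out <- data.frame(i = integer(), j = integer(), strand = character())
  out
}
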