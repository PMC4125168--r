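# Spliced exon mapping: reconstruct a species' exon set from genomic
# sequence, one reference exon at a time.
#
# Each reference exon is located by affine-gap local alignment (match +1,
# mismatch -1, gap open -4, extend -1), the hit is extended to cover the
# whole reference exon, and the boundaries are refined toward canonical
# splice sites: a "gt" immediately after the exon (donor side) and an "ag"
# immediately before it (acceptor side), searched within a window.  The
# unrefined alignment boundary always remains a candidate, so a mutated
# splice site does not drag the exon onto a spurious canonical site --
# candidates are ranked by alignment identity, ties broken by smallest
# coordinate shift.  Exons are searched left to right, each downstream of
# the previous hit, which enforces ordered non-overlapping hits.

.gd_submat <- function() {
  if (is.null(.gd$submat))
    .gd$submat <- nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                               baseOnly = FALSE)
  .gd$submat
}

# identity of ref exon vs a genomic interval: global matches over alignment
# columns, so both over- and under-extension of the interval cost identity
.interval_identity <- function(ref, g, s, e) {
  if (s < 1L || e > nchar(g) || e < s) return(0)
  pa <- pairwiseAlignment(ref, substr(g, s, e), type = "global",
                          substitutionMatrix = .gd_submat(),
                          gapOpening = 3, gapExtension = 1)
  nmatch(pa) / nchar(as.character(alignedPattern(pa)))
}

#' Map reference exons onto a genomic sequence
#'
#' @param genomic Genomic sequence (named or bare character of length 1).
#' @param ref_exons Character vector of reference exon sequences, in gene
#'   order, each at least 6 nt.
#' @param min_identity Minimum alignment identity (matches / reference exon
#'   length) for an exon to count as found; default 0.7 tolerates
#'   cross-species divergence while rejecting paralogous noise.
#' @param boundary_window Half-width (nt) of the splice-site refinement
#'   search around the raw alignment boundary.
#' @return Data frame of exon hits: `exon`, `start`, `end` (1-based
#'   inclusive on the genomic sequence; NA when missing), `identity`,
#'   `status` (`"found"`/`"missing"`).
#' @export
map_exons <- function(genomic, ref_exons, min_identity = 0.7,
                      boundary_window = 50L) {
  if (any(nchar(ref_exons) < 6L)) stop("reference exons must be >= 6 nt")
  g <- toupper(unname(genomic[[1L]]))
  L <- nchar(g)
  n <- length(ref_exons)
  out <- data.frame(exon = seq_len(n), start = NA_integer_,
                    end = NA_integer_, identity = NA_real_,
                    status = "missing", stringsAsFactors = FALSE)
  cursor <- 1L
  for (i in seq_len(n)) {
    ref <- toupper(ref_exons[i])
    if (cursor > L - 5L) break
    sub <- substr(g, cursor, L)
    pa <- pairwiseAlignment(ref, sub, type = "local",
                            substitutionMatrix = .gd_submat(),
                            gapOpening = 3, gapExtension = 1)
    rl <- nchar(ref)
    if (nmatch(pa) / rl < min_identity) next
    s <- cursor + start(subject(pa)) - 1L
    e <- cursor + end(subject(pa)) - 1L
    # re-cover short unaligned reference flanks (local alignment trims
    # terminal mismatches); long unaligned tails signal an indel near the
    # exon edge and are left to splice-site refinement instead, which
    # recovers the boundary from identity over the full interval
    s <- max(1L, s - min(start(pattern(pa)) - 1L, 6L))
    e <- min(L, e + min(rl - end(pattern(pa)), 6L))

    offs <- seq(-boundary_window, boundary_window)
    # acceptor side: "ag" must immediately precede the exon (not for exon 1)
    if (i > 1L) {
      ok <- vapply(s + offs, function(p) {
        p - 2L >= 1L && p <= e && substr(g, p - 2L, p - 1L) == "AG"
      }, TRUE)
      cand <- sort(unique(c(s, (s + offs)[ok])))
      ids <- vapply(cand, function(sc) .interval_identity(ref, g, sc, e), 0)
      s <- cand[order(-ids, abs(cand - s))[1L]]
    }
    # donor side: "gt" must immediately follow the exon (not for last exon)
    if (i < n) {
      ok <- vapply(e + offs, function(p) {
        p >= s && p + 2L <= L && substr(g, p + 1L, p + 2L) == "GT"
      }, TRUE)
      cand <- sort(unique(c(e, (e + offs)[ok])))
      ids <- vapply(cand, function(ec) .interval_identity(ref, g, s, ec), 0)
      e <- cand[order(-ids, abs(cand - e))[1L]]
    }
    out$start[i] <- s
    out$end[i] <- e
    out$identity[i] <- .interval_identity(ref, g, s, e)
    if (out$identity[i] < min_identity) {
      out$start[i] <- NA_integer_; out$end[i] <- NA_integer_
      next
    }
    out$status[i] <- "found"
    cursor <- e + 1L
  }
  out
}

#' Concatenate found exons into a virtual cDNA
#'
#' Missing exons contribute nothing; the gaps they leave are recorded in the
#' hit table, not in the sequence.
#'
#' @param hits Exon hit table from [map_exons()].
#' @param genomic The genomic sequence the hits refer to.
#' @return Named character: the virtual cDNA (uppercase).  Errors when no
#'   exon was found ("gene absent or unmappable").
#' @export
build_virtual_cdna <- function(hits, genomic) {
  g <- toupper(unname(genomic[[1L]]))
  found <- hits[hits$status == "found", , drop = FALSE]
  if (nrow(found) == 0L) stop("gene absent or unmappable: no exon found")
  nm <- if (!is.null(names(genomic))) names(genomic)[1L] else "virtual_cdna"
  setNames(paste0(substring(g, found$start, found$end), collapse = ""),
           paste0(nm, "_vcdna"))
}

#' Translate a coding sequence
#'
#' Standard genetic code; translation continues through internal stop codons
#' rendering them `*` (pseudogene ORFs stay displayable), codons containing
#' gaps or ambiguity become `X`, and a terminal stop is trimmed from the
#' product.  Trailing bases short of a full codon are ignored.
#'
#' @param cdna Coding sequence (character of length 1, length >= 3).
#' @param require_atg Error unless the sequence starts with ATG?
#' @return Named character: the protein sequence.
#' @export
translate_cds <- function(cdna, require_atg = FALSE) {
  s <- toupper(unname(cdna[[1L]]))
  if (nchar(s) < 3L) stop("coding sequence shorter than one codon")
  if (require_atg && substr(s, 1L, 3L) != "ATG")
    stop("coding sequence does not start with ATG")
  starts <- seq(1L, nchar(s) - 2L, by = 3L)
  cods <- substring(s, starts, starts + 2L)
  aa <- GENETIC_CODE[cods]
  aa[is.na(aa)] <- "X"
  if (length(aa) > 1L && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  nm <- if (!is.null(names(cdna))) paste0(names(cdna)[1L], "_protein") else
    "protein"
  setNames(paste0(aa, collapse = ""), nm)
}
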