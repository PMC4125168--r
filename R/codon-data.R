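#' @keywords internal
"_PACKAGE"

# Internal cache for codon bookkeeping tables (built once per session).
.gd <- new.env(parent = emptyenv())

#' Sense-codon state space
#'
#' Returns the bookkeeping tables for the 61 sense codons of the standard
#' genetic code: the codon strings (alphabetical order, stop codons excluded),
#' the encoded amino acid per codon, and the table of single-nucleotide
#' codon pairs annotated with transition/transversion and
#' synonymous/nonsynonymous status.  Everything downstream (rate matrices,
#' pruning, simulation) indexes codons by position in this vector.
#'
#' @return A list with elements `codons` (character, length 61), `aa`
#'   (character, length 61), and `pairs` (integer matrix, one row per
#'   unordered single-nucleotide pair: 0-based indices `i`, `j`, flags
#'   `transition`, `synonymous`).
#' @export
codon_states <- function() {
  if (!is.null(.gd$codon)) return(.gd$codon)
  b <- c("A", "C", "G", "T")
  all64 <- sort(apply(expand.grid(b, b, b, stringsAsFactors = FALSE), 1L,
                      paste0, collapse = ""))
  code <- GENETIC_CODE[all64]
  keep <- code != "*"
  codons <- all64[keep]
  aa <- unname(code[keep])
  n <- length(codons)
  nt <- do.call(rbind, strsplit(codons, ""))
  ts_pair <- function(x, y) {
    (x == "A" & y == "G") | (x == "G" & y == "A") |
      (x == "C" & y == "T") | (x == "T" & y == "C")
  }
  rows <- vector("list", 3L * n)
  m <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      diffs <- which(nt[i, ] != nt[j, ])
      if (length(diffs) != 1L) next
      m <- m + 1L
      rows[[m]] <- c(i - 1L, j - 1L,
                     as.integer(ts_pair(nt[i, diffs], nt[j, diffs])),
                     as.integer(aa[i] == aa[j]))
    }
  }
  pairs <- do.call(rbind, rows[seq_len(m)])
  storage.mode(pairs) <- "integer"
  colnames(pairs) <- c("i", "j", "transition", "synonymous")
  .gd$codon <- list(codons = codons, aa = aa, pairs = pairs)
  .gd$codon
}

# codon string -> 1-based state index; NA for anything outside the 61 states
.codon_index <- function(x) {
  cs <- codon_states()
  match(toupper(x), cs$codons)
}

# standard-code translation of a codon index vector
.aa_of <- function(idx) codon_states()$aa[idx]
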