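# Whole-genome-shotgun read simulator.
#
# The read model is intentionally minimal: uniform start positions, fixed
# read length, i.i.d. per-base substitution errors, no indels and no quality
# model -- the matching rule under test downstream is identity/coverage
# thresholding, not gapped alignment fidelity.

#' Simulate a shotgun read set from a locus
#'
#' @param genomic Locus sequence (named character of length 1).
#' @param length Read length in nt (must not exceed the locus length).
#' @param depth Target mean per-base coverage (> 0).
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param seed Integer seed; the read set is a pure function of it.
#' @return A `read_set`: list with `reads` (named uppercase sequences),
#'   `start` (true 1-based start positions), and the simulation parameters.
#' @export
make_reads <- function(genomic, length = 100L, depth = 20, error_rate = 0,
                       seed = 1L) {
  g <- toupper(unname(genomic[[1L]]))
  L <- nchar(g)
  length <- as.integer(length)
  if (length > L) stop("read length ", length, " exceeds locus length ", L)
  if (depth <= 0) stop("depth must be > 0")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0,1)")
  .with_seed(seed, {
    n <- max(1L, round(depth * L / length))
    starts <- sample.int(L - length + 1L, n, replace = TRUE)
    reads <- substring(g, starts, starts + length - 1L)
    if (error_rate > 0) {
      bases <- c("A", "C", "G", "T")
      nerr <- stats::rbinom(n, length, error_rate)
      for (i in which(nerr > 0L)) {
        pos <- sample.int(length, nerr[i])
        chars <- strsplit(reads[i], "")[[1L]]
        chars[pos] <- vapply(chars[pos], function(b)
          sample(setdiff(bases, b), 1L), "")
        reads[i] <- paste0(chars, collapse = "")
      }
    }
    structure(list(reads = setNames(reads, sprintf("read_%05d", seq_len(n))),
                   start = starts, length = length, depth = depth,
                   error_rate = error_rate, seed = as.integer(seed)),
              class = "read_set")
  })
}
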