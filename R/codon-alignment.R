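# Codon alignment container: an integer matrix of 1-based indices into the
# 61 sense codons (see codon_states()), one row per taxon, one column per
# codon site.  Codons containing a gap, N, or any non-ACGT character -- and
# stop codons, which are outside the model's state space -- are stored as NA
# and treated as missing data (all-ones partials) by the likelihood.

#' Build a codon alignment from nucleotide sequences
#'
#' @param seqs Named character vector of aligned nucleotide sequences, all the
#'   same length, length divisible by 3.
#' @return A `codon_alignment`: integer matrix (taxa x codon sites) of codon
#'   state indices with NA for missing-data codons.  The codon strings are
#'   attached as attribute `codons`.
#' @export
codon_alignment <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    stop("aligned sequences differ in length: taxon '",
         names(seqs)[which(nchar(seqs) != len[1L])[1L]], "'")
  if (len %% 3L != 0L)
    stop("alignment length ", len, " is not a multiple of 3")
  nsites <- len %/% 3L
  starts <- seq(1L, len, by = 3L)
  mat <- t(vapply(seqs, function(s) {
    .codon_index(substring(s, starts, starts + 2L))
  }, integer(nsites)))
  dim(mat) <- c(length(seqs), nsites)  # keep matrix shape for 1-site case
  rownames(mat) <- names(seqs)
  structure(mat, codons = codon_states()$codons, class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon alignment:", nrow(x), "taxa x", ncol(x), "codon sites;",
      sum(is.na(x)), "missing codons\n")
  invisible(x)
}

.is_codon_alignment <- function(x) inherits(x, "codon_alignment")

#' Read a sequential relaxed-PHYLIP codon alignment
#'
#' Parses the "codeml-style" dialect: a header line `ntaxa nchar`, then for
#' each taxon a whitespace-delimited name (any length) followed by sequence
#' characters, possibly wrapped over several lines, until `nchar` characters
#' have been read.
#'
#' @param path Path to the alignment file.
#' @return A `codon_alignment` (codons with `-`/`N` are missing).
#' @export
read_paml_alignment <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(hdr) < 2L || anyNA(suppressWarnings(as.integer(hdr[1:2]))))
    stop("malformed PHYLIP header: '", lines[1L], "'")
  ntax <- as.integer(hdr[1L]); nchar_aln <- as.integer(hdr[2L])
  if (nchar_aln %% 3L != 0L)
    stop("alignment length ", nchar_aln, " is not a multiple of 3")
  toks <- unlist(strsplit(trimws(lines[-1L]), "\\s+"))
  seqs <- character(ntax); ids <- character(ntax)
  k <- 1L
  for (i in seq_len(ntax)) {
    if (k > length(toks)) stop("expected ", ntax, " taxa, found ", i - 1L)
    ids[i] <- toks[k]; k <- k + 1L
    acc <- ""
    while (nchar(acc) < nchar_aln) {
      if (k > length(toks))
        stop("sequence for taxon '", ids[i], "' is shorter than ", nchar_aln)
      acc <- paste0(acc, toks[k]); k <- k + 1L
    }
    if (nchar(acc) != nchar_aln)
      stop("sequence for taxon '", ids[i], "' has ", nchar(acc),
           " characters, expected ", nchar_aln)
    seqs[i] <- acc
  }
  if (anyDuplicated(ids)) stop("duplicate taxon '", ids[duplicated(ids)][1L], "'")
  codon_alignment(setNames(seqs, ids))
}

#' Write a codon alignment as sequential relaxed PHYLIP
#'
#' Missing-data codons are written as `---`.
#'
#' @param aln A `codon_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paml_alignment <- function(aln, path) {
  stopifnot(.is_codon_alignment(aln))
  cods <- attr(aln, "codons")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(aln), ncol(aln) * 3L), con)
  for (i in seq_len(nrow(aln))) {
    s <- ifelse(is.na(aln[i, ]), "---", cods[aln[i, ]])
    writeLines(paste(rownames(aln)[i], paste0(s, collapse = "")), con)
  }
  invisible(path)
}
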