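# FASTA / FASTQ plumbing.
#
# Sequences travel through the package as named character vectors (name = id,
# value = sequence).  Case is preserved verbatim because it carries meaning in
# locus reports: uppercase marks coding sequence, lowercase introns and other
# noncoding sequence.  The readers are deliberately line-oriented so that
# malformed input can be reported with the offending line number, which the
# generic binary-safe readers do not do.

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences, in file order, case preserved.
#'   Fails if a header is empty, a record has no sequence, sequence lines
#'   precede the first header, or two records share an id.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- startsWith(lines, ">")
  if (!any(hdr)) stop("no FASTA header found in '", path, "'")
  first_seq <- which(!hdr & nzchar(trimws(lines)))
  if (length(first_seq) && first_seq[1L] < which(hdr)[1L])
    stop("sequence before first header at line ", first_seq[1L])
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  if (any(!nzchar(ids)))
    stop("empty FASTA header at line ", which(hdr)[!nzchar(ids)][1L])
  grp <- cumsum(hdr)
  body <- vapply(split(lines[!hdr], grp[!hdr]), paste0, "", collapse = "")
  body <- body[names(body) %in% as.character(seq_along(ids))]
  seqs <- setNames(rep("", length(ids)), as.character(seq_along(ids)))
  seqs[names(body)] <- gsub("\\s", "", body)
  if (any(!nzchar(seqs))) {
    bad <- which(!nzchar(seqs))[1L]
    stop("record '", ids[bad], "' (line ", which(hdr)[bad], ") has no sequence")
  }
  if (anyDuplicated(ids))
    stop("duplicate FASTA id '", ids[duplicated(ids)][1L], "'")
  setNames(unname(seqs), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' Qualities are parsed but discarded: the read-matching machinery is purely
#' identity/coverage thresholded and carries no quality model.
#'
#' @param path Path to a FASTQ file.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ: ", length(lines), " lines is not a multiple of 4")
  ids <- lines[seq(1L, length(lines), by = 4L)]
  if (any(!startsWith(ids, "@")))
    stop("malformed FASTQ header at record ",
         which(!startsWith(ids, "@"))[1L])
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  setNames(seqs, sub("\\s.*$", "", sub("^@", "", ids)))
}

#' Write reads to FASTQ with constant quality
#'
#' @param seqs Named character vector of read sequences.
#' @param path Output path.
#' @param quality Single quality character applied to every base (default "I").
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path, quality = "I") {
  stopifnot(is.character(seqs), !is.null(names(seqs)), nchar(quality) == 1L)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0("@", names(seqs)[i]), seqs[[i]], "+",
                 strrep(quality, nchar(seqs[[i]]))), con)
  }
  invisible(path)
}

#' Read exon intervals from a BED file
#'
#' BED is 0-based half-open; the returned intervals are converted to the
#' package's user-facing convention of 1-based inclusive coordinates.
#'
#' @param path Path to a BED3+ file.
#' @return Data frame with columns `chrom`, `start`, `end` (1-based inclusive)
#'   and `name` when a fourth column is present.
#' @export
read_bed_exons <- function(path) {
  bed <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(bed) < 3L) stop("BED file needs at least 3 columns")
  out <- data.frame(chrom = bed[[1L]], start = bed[[2L]] + 1L, end = bed[[3L]],
                    stringsAsFactors = FALSE)
  if (ncol(bed) >= 4L) out$name <- bed[[4L]]
  if (any(out$end < out$start)) stop("BED interval with end < start")
  out
}

#' Write exon intervals to BED
#'
#' @param exons Data frame with `start`, `end` in 1-based inclusive
#'   coordinates and optionally `chrom` and `name`.
#' @param path Output path.
#' @param chrom Chromosome/sequence name used when `exons$chrom` is absent.
#' @return `path`, invisibly.
#' @export
write_bed_exons <- function(exons, path, chrom = "locus") {
  chr <- if (!is.null(exons$chrom)) exons$chrom else rep(chrom, nrow(exons))
  name <- if (!is.null(exons$name)) exons$name else
    paste0("exon_", seq_len(nrow(exons)))
  write.table(data.frame(chr, exons$start - 1L, exons$end, name),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
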