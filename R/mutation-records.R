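# ORF-disrupting mutation records and the report grammar.
#
# A mutation catalogue is a data frame with one row per event.  The `kind`
# vocabulary covers every disruption class the pipeline recognises:
# nonsense, frameshift_insertion, frameshift_deletion, inframe_deletion,
# splice_donor, splice_acceptor, start_loss, exon_deletion, gene_deletion.
# Reports render records in the conventional catalogue grammar, e.g.
# "exon 2: 4-nt deletion; exon 3: splice donor mutation (GT to GA)", with
# consecutive same-exon events sharing the "exon N:" prefix.

.mutation_kinds <- c("nonsense", "frameshift_insertion", "frameshift_deletion",
                     "inframe_deletion", "splice_donor", "splice_acceptor",
                     "start_loss", "exon_deletion", "gene_deletion")

#' Construct mutation records
#'
#' @param species Species name (recycled).
#' @param kind One of the nine-kind vocabulary (see Details).
#' @param exon 1-based exon index the event is attributed to (NA for
#'   `gene_deletion`); splice donors belong to the exon upstream of the
#'   affected intron, splice acceptors to the exon downstream.
#' @param position 1-based nucleotide position within the exon (reference
#'   coordinates), or NA where meaningless.
#' @param length Indel length in nt (NA for substitutions).
#' @param detail Free-text allele detail in report grammar, e.g. `"GT to GA"`
#'   or `"ATG to GTG"`.
#' @param exon_end Last exon of a multi-exon deletion (defaults to `exon`).
#' @param polymorphic Logical flag, supplied by the caller (never inferred).
#' @return Data frame of class `mutation_record`.
#' @export
mutation_record <- function(species, kind, exon = NA_integer_,
                            position = NA_integer_, length = NA_integer_,
                            detail = NA_character_, exon_end = exon,
                            polymorphic = FALSE) {
  if (length(kind) == 0L || length(species) == 0L) {
    out <- data.frame(species = character(), kind = character(),
                      exon = integer(), exon_end = integer(),
                      position = integer(), length = integer(),
                      detail = character(), polymorphic = logical(),
                      stringsAsFactors = FALSE)
    class(out) <- c("mutation_record", "data.frame")
    return(out)
  }
  kind <- match.arg(kind, .mutation_kinds, several.ok = TRUE)
  n <- max(lengths(list(species, kind, exon, position, length, detail)))
  out <- data.frame(species = rep_len(as.character(species), n),
                    kind = rep_len(kind, n),
                    exon = rep_len(as.integer(exon), n),
                    exon_end = rep_len(as.integer(exon_end), n),
                    position = rep_len(as.integer(position), n),
                    length = rep_len(as.integer(length), n),
                    detail = rep_len(as.character(detail), n),
                    polymorphic = rep_len(polymorphic, n),
                    stringsAsFactors = FALSE)
  indel <- out$kind %in% c("frameshift_insertion", "frameshift_deletion",
                           "inframe_deletion")
  bad <- indel & (is.na(out$length) |
                    ((out$length %% 3L != 0L) !=
                       (out$kind != "inframe_deletion")))
  if (any(bad))
    stop("indel length inconsistent with frameshift status for kind '",
         out$kind[bad][1L], "' length ", out$length[bad][1L])
  class(out) <- c("mutation_record", "data.frame")
  out
}

.bind_records <- function(...) {
  pieces <- Filter(function(x) !is.null(x) && nrow(x) > 0L, list(...))
  if (!length(pieces))
    return(mutation_record(character(), character()))
  out <- do.call(rbind, lapply(pieces, as.data.frame))
  class(out) <- c("mutation_record", "data.frame")
  out
}

# one rendered description, without the exon prefix
.describe_mutation <- function(rec) {
  poly <- if (isTRUE(rec$polymorphic)) ", polymorphic" else ""
  d <- switch(rec$kind,
    nonsense = "nonsense codon",
    frameshift_insertion = paste0(rec$length, "-nt insertion"),
    frameshift_deletion = paste0(rec$length, "-nt deletion"),
    inframe_deletion = paste0(rec$length, "-nt deletion"),
    splice_donor = if (is.na(rec$detail) || rec$detail == "deletion")
      "splice donor deletion" else
      paste0("splice donor mutation (", rec$detail, ")"),
    splice_acceptor = if (is.na(rec$detail) || rec$detail == "deletion")
      "splice acceptor deletion" else
      paste0("splice acceptor mutation (", rec$detail, ")"),
    start_loss = paste0("start codon mutation (", rec$detail, ")"),
    exon_deletion = "exon deletion",
    gene_deletion = "gene deletion",
    stop("unknown mutation kind '", rec$kind, "'"))
  paste0(d, poly)
}

#' Render one species' mutation records as a catalogue string
#'
#' Events are ordered by exon then position; consecutive events in the same
#' exon share a single `exon N:` prefix; two nonsense codons in one exon
#' collapse to `"two nonsense codons"`; multi-exon deletions render as
#' `"exons N and M: exon deletion"`.
#'
#' @param records A `mutation_record` data frame for one species.
#' @return A single string ("" when no records).
#' @export
format_mutations <- function(records) {
  if (is.null(records) || nrow(records) == 0L) return("")
  if (any(records$kind == "gene_deletion")) return("gene deletion")
  # within an exon: acceptor (5' edge) first, donor (3' edge) last,
  # everything else by position
  poskey <- ifelse(records$kind == "splice_acceptor", -1,
                   ifelse(records$kind == "splice_donor", Inf,
                          ifelse(is.na(records$position), 0,
                                 records$position)))
  records <- records[order(records$exon, poskey), , drop = FALSE]

  # collapse repeated nonsense codons within one exon into a single phrase
  drop <- logical(nrow(records))
  texts <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    if (rec$kind == "nonsense") {
      grp <- which(records$kind == "nonsense" & records$exon == rec$exon &
                     records$polymorphic == rec$polymorphic)
      if (grp[1L] != i) { drop[i] <- TRUE; next }
      n <- length(grp)
      if (n > 1L) {
        word <- if (n == 2L) "two" else as.character(n)
        texts[i] <- paste0(word, " nonsense codons",
                           if (isTRUE(rec$polymorphic)) ", polymorphic" else "")
        next
      }
    }
    texts[i] <- .describe_mutation(rec)
  }
  keep <- which(!drop)
  prefixes <- vapply(keep, function(i) {
    rec <- records[i, ]
    if (!is.na(rec$exon_end) && !is.na(rec$exon) && rec$exon_end > rec$exon)
      paste0("exons ", rec$exon, " and ", rec$exon_end)
    else if (is.na(rec$exon)) ""
    else paste0("exon ", rec$exon)
  }, "")
  out <- character(length(keep))
  for (j in seq_along(keep)) {
    new_exon <- j == 1L || prefixes[j] != prefixes[j - 1L]
    out[j] <- if (new_exon && nzchar(prefixes[j]))
      paste0(prefixes[j], ": ", texts[keep[j]]) else texts[keep[j]]
  }
  paste(out, collapse = "; ")
}

#' Write a per-species mutation report as TSV
#'
#' One row per species with a `Mutations` column in catalogue grammar.
#' Species with no records get an empty field.
#'
#' @param records A `mutation_record` data frame (any number of species).
#' @param path Output path; `NULL` returns the TSV text.
#' @param species Optional character vector fixing row order and including
#'   species without mutations.
#' @return TSV text (invisibly when written to a file).
#' @export
write_mutation_report <- function(records, path = NULL, species = NULL) {
  if (is.null(species))
    species <- unique(records$species)
  rows <- vapply(species, function(sp) {
    format_mutations(records[records$species == sp, , drop = FALSE])
  }, "")
  txt <- c("Species\tMutations", paste(species, rows, sep = "\t"))
  if (is.null(path)) return(paste(txt, collapse = "\n"))
  writeLines(txt, path)
  invisible(paste(txt, collapse = "\n"))
}
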