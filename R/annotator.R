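# Cataloguing ORF-disrupting mutations against a reference gene model.
#
# Conventions that keep the catalogue faithful to how such tables are
# curated by hand:
#   * indels come from global alignment of each species exon against the
#     reference exon; every maximal gap run is one event, frameshift iff
#     length %% 3 != 0;
#   * premature stops are scanned in the REFERENCE codon frame (per-exon
#     alignments map reference codons onto species bases), so a stop that
#     exists only because of an upstream frameshift is a consequence, not an
#     independent nonsense mutation, and is never double-counted;
#   * splice-site checks test the canonical gt..ag dinucleotides of each
#     intron between mapped exons;
#   * the functional call applies the precedence
#     gene_absent > pseudogene > altered_Cterm > intact, where
#     altered_Cterm covers the special case of a frameshift confined to the
#     last exon that truncates the C-terminus but leaves the upstream open
#     reading frame intact.

.disruptive_kinds <- c("nonsense", "frameshift_insertion",
                       "frameshift_deletion", "splice_donor",
                       "splice_acceptor", "start_loss", "exon_deletion",
                       "gene_deletion")

#' Detect indels between a species exon and the reference exon
#'
#' @param species_exon,ref_exon Nucleotide sequences (character).
#' @param species Species label for the records.
#' @param exon 1-based exon index for the records.
#' @return A `mutation_record` with one row per maximal gap run, positions in
#'   reference-exon coordinates.  Insertions with length divisible by 3 are
#'   not ORF-disrupting and are omitted; in-frame deletions are reported as
#'   `inframe_deletion`.
#' @export
detect_exon_indels <- function(species_exon, ref_exon, species = "query",
                               exon = 1L) {
  stopifnot(nchar(species_exon) > 0L, nchar(ref_exon) > 0L)
  pa <- pairwiseAlignment(toupper(ref_exon), toupper(species_exon),
                          type = "global",
                          substitutionMatrix = .gd_submat(),
                          gapOpening = 3, gapExtension = 1)
  rgap <- as.character(alignedPattern(pa))  # reference with '-' = insertion
  sgap <- as.character(alignedSubject(pa))  # species with '-' = deletion
  recs <- list()
  gap_runs <- function(x) {
    m <- gregexpr("-+", x)[[1L]]
    if (m[1L] == -1L) return(NULL)
    data.frame(at = as.integer(m), len = attr(m, "match.length"))
  }
  # alignment column -> reference coordinate (position of last ref base seen)
  refpos <- cumsum(strsplit(rgap, "")[[1L]] != "-")
  del <- gap_runs(sgap)
  if (!is.null(del)) {
    for (r in seq_len(nrow(del))) {
      kind <- if (del$len[r] %% 3L == 0L) "inframe_deletion" else
        "frameshift_deletion"
      recs[[length(recs) + 1L]] <-
        mutation_record(species, kind, exon, position = refpos[del$at[r]],
                        length = del$len[r])
    }
  }
  ins <- gap_runs(rgap)
  if (!is.null(ins)) {
    for (r in seq_len(nrow(ins))) {
      if (ins$len[r] %% 3L == 0L) next
      pos <- if (ins$at[r] == 1L) 0L else refpos[ins$at[r] - 1L]
      recs[[length(recs) + 1L]] <-
        mutation_record(species, "frameshift_insertion", exon,
                        position = pos, length = ins$len[r])
    }
  }
  do.call(.bind_records, recs)
}

# per-exon map from reference position to species base (NA where deleted)
.ref_to_species_base <- function(species_exon, ref_exon) {
  pa <- pairwiseAlignment(toupper(ref_exon), toupper(species_exon),
                          type = "global",
                          substitutionMatrix = .gd_submat(),
                          gapOpening = 3, gapExtension = 1)
  r <- strsplit(as.character(alignedPattern(pa)), "")[[1L]]
  s <- strsplit(as.character(alignedSubject(pa)), "")[[1L]]
  out <- rep(NA_character_, nchar(ref_exon))
  ri <- 0L
  for (k in seq_along(r)) {
    if (r[k] != "-") {
      ri <- ri + 1L
      if (s[k] != "-") out[ri] <- s[k]
    }
  }
  out
}

#' Detect nonsense and start-codon mutations in the reference frame
#'
#' Reference codons are projected onto the species sequence through per-exon
#' alignments; a species codon that reads TAA/TAG/TGA at a reference codon
#' position before the natural stop is recorded as a nonsense mutation in
#' the exon holding that codon's first base.  Codon 1 not reading ATG is a
#' start-codon loss.  Stops that arise only in the shifted frame downstream
#' of an indel never appear here (see module header).
#'
#' @param species_exons Character vector of species exon sequences (NA or
#'   empty for missing exons), in gene order.
#' @param model Reference `gene_model`.
#' @param species Species label for the records.
#' @return A `mutation_record`.
#' @export
detect_nonsense_and_start <- function(species_exons, model,
                                      species = "query") {
  stopifnot(inherits(model, "gene_model"))
  widths <- model$exons$end - model$exons$start + 1L
  n <- length(widths)
  ref_cdna <- model$cdna
  # species base under each reference cDNA position
  base <- rep(NA_character_, nchar(ref_cdna))
  for (i in seq_len(n)) {
    se <- species_exons[i]
    if (is.na(se) || !nzchar(se)) next
    ref_exon <- substr(ref_cdna, model$cdna_offset[i] + 1L,
                       model$cdna_offset[i] + widths[i])
    base[model$cdna_offset[i] + seq_len(widths[i])] <-
      .ref_to_species_base(se, ref_exon)
  }
  ncod <- nchar(ref_cdna) %/% 3L
  exon_of <- findInterval(seq(0L, by = 3L, length.out = ncod),
                          model$cdna_offset)
  recs <- list()
  stops <- c("TAA", "TAG", "TGA")
  for (ci in seq_len(ncod)) {
    idx <- (ci - 1L) * 3L + 1:3
    sp <- base[idx]
    if (anyNA(sp)) next
    cod <- paste0(sp, collapse = "")
    ref_cod <- substr(ref_cdna, idx[1L], idx[3L])
    if (ci == 1L && cod != "ATG") {
      recs[[length(recs) + 1L]] <-
        mutation_record(species, "start_loss", 1L, position = 1L,
                        detail = paste0("ATG to ", cod))
      next
    }
    if (cod %in% stops && !(ref_cod %in% stops)) {
      ex <- exon_of[ci]
      recs[[length(recs) + 1L]] <-
        mutation_record(species, "nonsense", ex,
                        position = idx[1L] - model$cdna_offset[ex],
                        detail = cod)
    }
  }
  do.call(.bind_records, recs)
}

#' Check canonical splice sites between mapped exons
#'
#' Every intron between two consecutively found exons must start `gt` and
#' end `ag`.  A non-canonical donor is attributed to the exon upstream of
#' the intron, a non-canonical acceptor to the exon downstream.  An intron
#' too short to host both sites is reported as a splice-site deletion.
#'
#' @param genomic Genomic sequence.
#' @param hits Exon hit table from [map_exons()].
#' @param species Species label for the records.
#' @return A `mutation_record`.
#' @export
check_splice_sites <- function(genomic, hits, species = "query") {
  g <- unname(genomic[[1L]])
  found <- which(hits$status == "found")
  if (length(found) < 2L) return(.bind_records())
  recs <- list()
  for (k in seq_len(length(found) - 1L)) {
    # consecutive found exons; when a deleted exon separates them the
    # remaining intronic sequence still carries exon i's donor and exon j's
    # acceptor, so both are checked either way
    i <- found[k]; j <- found[k + 1L]
    is_ <- hits$end[i] + 1L
    ie <- hits$start[j] - 1L
    if (ie - is_ + 1L < 4L) {
      recs[[length(recs) + 1L]] <-
        mutation_record(species, "splice_donor", hits$exon[i],
                        detail = "deletion")
      next
    }
    donor <- toupper(substr(g, is_, is_ + 1L))
    accep <- toupper(substr(g, ie - 1L, ie))
    if (donor != "GT")
      recs[[length(recs) + 1L]] <-
        mutation_record(species, "splice_donor", hits$exon[i],
                        detail = paste0("GT to ", donor))
    if (accep != "AG")
      recs[[length(recs) + 1L]] <-
        mutation_record(species, "splice_acceptor", hits$exon[j],
                        detail = paste0("AG to ", accep))
  }
  do.call(.bind_records, recs)
}

# translate in the species frame up to the first stop; returns aa length and
# the codon index of the first premature stop (NA when none)
.orf_scan <- function(vcdna, ref_ncod) {
  s <- toupper(unname(vcdna[[1L]]))
  ncod <- nchar(s) %/% 3L
  if (ncod == 0L) return(list(len = 0L, stop = NA_integer_))
  starts <- seq(1L, by = 3L, length.out = ncod)
  cods <- substring(s, starts, starts + 2L)
  is_stop <- cods %in% c("TAA", "TAG", "TGA")
  first <- if (any(is_stop)) which(is_stop)[1L] else NA_integer_
  len <- if (is.na(first)) ncod else first - 1L
  premature <- !is.na(first) && first < ref_ncod
  list(len = len, stop = if (premature) first else NA_integer_)
}

#' Classify the functional status of a gene copy
#'
#' @param records A `mutation_record` for one species.
#' @param hits Exon hit table from [map_exons()] (NULL allowed with a
#'   deletion call).
#' @param model Reference `gene_model`.
#' @param deletion_call Optional read-based presence call
#'   (`"present"`/`"deleted"`/`"inconclusive"`) from [call_deletion()].
#' @param virtual_cdna Optional species virtual cDNA for protein length.
#' @return A `functional_call`: `status` (`intact`, `altered_Cterm`,
#'   `pseudogene`, `gene_absent`), `protein_length` (aa, translation to the
#'   first stop in the species frame), `first_premature_stop` (codon index
#'   or NA).
#' @export
classify_gene <- function(records, hits, model, deletion_call = NULL,
                          virtual_cdna = NULL) {
  n_exons <- nrow(model$exons)
  ref_ncod <- nchar(model$cdna) %/% 3L
  absent <- (!is.null(deletion_call) && identical(deletion_call, "deleted")) ||
    is.null(hits) || !any(hits$status == "found") ||
    (nrow(records) > 0L && any(records$kind == "gene_deletion"))
  if (absent) {
    out <- list(status = "gene_absent", protein_length = NA_integer_,
                first_premature_stop = NA_integer_)
    class(out) <- "functional_call"
    return(out)
  }
  dis <- records[records$kind %in% .disruptive_kinds, , drop = FALSE]
  scan <- if (!is.null(virtual_cdna)) .orf_scan(virtual_cdna, ref_ncod) else
    list(len = NA_integer_, stop = NA_integer_)
  status <- if (nrow(dis) == 0L) "intact"
  else if (all(dis$kind %in% c("frameshift_deletion", "frameshift_insertion")
               & dis$exon == n_exons)) "altered_Cterm"
  else "pseudogene"
  out <- list(status = status, protein_length = scan$len,
              first_premature_stop = scan$stop)
  class(out) <- "functional_call"
  out
}

#' @export
print.functional_call <- function(x, ...) {
  cat("functional call:", x$status,
      if (!is.na(x$protein_length)) paste0("(", x$protein_length, " aa)"),
      "\n")
  invisible(x)
}

#' Annotate a species locus against a reference gene model
#'
#' Driver for the whole catalogue: maps exons, checks splice sites, detects
#' indels and reference-frame stop/start mutations, records exon deletions
#' for missing exons, and classifies the gene.
#'
#' @param genomic Species genomic sequence.
#' @param model Reference `gene_model`.
#' @param species Species label.
#' @param min_identity,boundary_window Passed to [map_exons()].
#' @param deletion_call Optional read-based presence call.
#' @return List with `hits`, `records` (a `mutation_record`), `call`
#'   (a `functional_call`), and `virtual_cdna` (NULL when absent).
#' @export
annotate_gene <- function(genomic, model, species = "query",
                          min_identity = 0.7, boundary_window = 50L,
                          deletion_call = NULL) {
  widths <- model$exons$end - model$exons$start + 1L
  ref_exons <- substring(model$cdna, model$cdna_offset + 1L,
                         model$cdna_offset + widths)
  hits <- map_exons(genomic, ref_exons, min_identity = min_identity,
                    boundary_window = boundary_window)
  if (!any(hits$status == "found")) {
    recs <- mutation_record(species, "gene_deletion")
    call <- classify_gene(recs, hits, model, deletion_call = deletion_call)
    return(list(hits = hits, records = recs, call = call,
                virtual_cdna = NULL))
  }
  g <- toupper(unname(genomic[[1L]]))
  species_exons <- rep(NA_character_, length(ref_exons))
  fi <- hits$status == "found"
  species_exons[fi] <- substring(g, hits$start[fi], hits$end[fi])

  indels <- list()
  for (i in which(fi)) {
    indels[[length(indels) + 1L]] <-
      detect_exon_indels(species_exons[i], ref_exons[i], species, i)
  }
  splice <- check_splice_sites(genomic, hits, species)
  nsst <- detect_nonsense_and_start(species_exons, model, species)
  # merge consecutive missing exons into single exon-deletion events
  missing <- which(!fi)
  exdel <- list()
  if (length(missing)) {
    runs <- split(missing, cumsum(c(1L, diff(missing) != 1L)))
    for (r in runs) {
      exdel[[length(exdel) + 1L]] <-
        mutation_record(species, "exon_deletion", r[1L],
                        exon_end = r[length(r)])
    }
  }
  records <- do.call(.bind_records,
                     c(indels, list(splice, nsst), exdel))
  vcdna <- build_virtual_cdna(hits, genomic)
  call <- classify_gene(records, hits, model,
                        deletion_call = deletion_call,
                        virtual_cdna = vcdna)
  list(hits = hits, records = records, call = call, virtual_cdna = vcdna)
}
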