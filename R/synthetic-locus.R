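# Synthetic multi-exon loci with known ground truth.
#
# The generator states a simple world: exon sequences are i.i.d. codons at a
# chosen GC content with an ATG start, a single terminal stop and no internal
# stops; introns are i.i.d. bases flanked by canonical gt..ag dinucleotides.
# Exons are written in uppercase and introns in lowercase, the usual display
# convention for locus reports.  There is no repeat model: a "repeat-rich"
# replacement fragment is emulated by any non-homologous random segment.
# All generators are pure functions of their seed.

# run expr under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.random_bases <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste0(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Specify a synthetic locus
#'
#' Defaults emulate a 13-exon gene with a 1857-nt coding sequence (618
#' translated residues after removing the terminal stop), the shape of the
#' monooxygenase gene family members studied with this machinery.
#'
#' @param n_exons Number of coding exons.
#' @param exon_lengths Exon lengths in nt; total must be divisible by 3 and
#'   at least 6.
#' @param intron_lengths Intron lengths in nt (each >= 20); recycled to
#'   `n_exons - 1`.
#' @param gc GC fraction for generated bases.
#' @param seed Integer seed; the locus is a pure function of the spec.
#' @return A `locus_spec` list.
#' @export
locus_spec <- function(n_exons = 13L,
                       exon_lengths = NULL,
                       intron_lengths = 90L,
                       gc = 0.45, seed = 1L) {
  n_exons <- as.integer(n_exons)
  if (is.null(exon_lengths)) {
    # near-even split of 1857 nt over n_exons, kept divisible by 3 in total
    total <- 1857L
    base <- total %/% n_exons
    exon_lengths <- rep(base, n_exons)
    exon_lengths[n_exons] <- total - base * (n_exons - 1L)
  }
  exon_lengths <- as.integer(exon_lengths)
  if (length(exon_lengths) != n_exons)
    stop("need ", n_exons, " exon lengths")
  total <- sum(exon_lengths)
  if (total < 6L || total %% 3L != 0L)
    stop("total CDS length ", total, " must be >= 6 and divisible by 3")
  intron_lengths <- rep_len(as.integer(intron_lengths), max(n_exons - 1L, 0L))
  if (any(intron_lengths < 20L)) stop("introns must be >= 20 nt")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0,1)")
  structure(list(n_exons = n_exons, exon_lengths = exon_lengths,
                 intron_lengths = intron_lengths, gc = gc,
                 seed = as.integer(seed)), class = "locus_spec")
}

#' Build a gene model
#'
#' @param exons Data frame with 1-based inclusive `start`, `end` columns on
#'   the genomic sequence, in ascending non-overlapping order.
#' @param cdna Reference cDNA sequence (single string); its length must equal
#'   the summed exon lengths.
#' @return A `gene_model` list with exon coordinates, the reference cDNA, and
#'   the cDNA offset of each exon.
#' @export
gene_model <- function(exons, cdna) {
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  if (any(diff(exons$start) <= 0) || any(exons$end < exons$start) ||
      any(utils::head(exons$end, -1L) >= utils::tail(exons$start, -1L)))
    stop("exons must be ascending and non-overlapping")
  widths <- exons$end - exons$start + 1L
  if (sum(widths) != nchar(cdna))
    stop("exon lengths sum to ", sum(widths), " but cDNA has ", nchar(cdna))
  structure(list(exons = exons, cdna = unname(cdna),
                 cdna_offset = cumsum(c(0L, utils::head(widths, -1L)))),
            class = "gene_model")
}

#' Generate a synthetic locus
#'
#' @param spec A `locus_spec`.
#' @return List with `genomic` (named sequence, uppercase exons / lowercase
#'   introns), `model` (the `gene_model` ground truth), and `cdna` (named
#'   coding sequence).  The cDNA starts with ATG, ends with a stop codon, and
#'   has no internal stop; every intron starts `gt` and ends `ag`.
#' @export
make_locus <- function(spec) {
  stopifnot(inherits(spec, "locus_spec"))
  .with_seed(spec$seed, {
    cs <- codon_states()
    sense <- setdiff(cs$codons, "ATG")  # ATG fixed at codon 1 anyway
    gcw <- function(codon) {
      nt <- strsplit(codon, "")[[1L]]
      prod(ifelse(nt %in% c("G", "C"), spec$gc / 2, (1 - spec$gc) / 2))
    }
    w <- vapply(cs$codons, gcw, 0)
    ncod <- sum(spec$exon_lengths) %/% 3L
    body <- sample(cs$codons, ncod - 2L, replace = TRUE, prob = w)
    stopc <- sample(c("TAA", "TAG", "TGA"), 1L)
    cdna <- paste0(c("ATG", body, stopc), collapse = "")
    ends <- cumsum(spec$exon_lengths)
    starts_cdna <- c(1L, utils::head(ends, -1L) + 1L)
    exon_seq <- substring(cdna, starts_cdna, ends)
    introns <- vapply(spec$intron_lengths, function(L) {
      paste0("gt", tolower(.random_bases(L - 4L, spec$gc)), "ag")
    }, "")
    pieces <- character(0)
    gstart <- integer(spec$n_exons); gend <- integer(spec$n_exons)
    pos <- 0L
    for (i in seq_len(spec$n_exons)) {
      gstart[i] <- pos + 1L
      pieces <- c(pieces, exon_seq[i])
      pos <- pos + spec$exon_lengths[i]
      gend[i] <- pos
      if (i < spec$n_exons) {
        pieces <- c(pieces, introns[i])
        pos <- pos + spec$intron_lengths[i]
      }
    }
    genomic <- paste0(pieces, collapse = "")
    model <- gene_model(data.frame(start = gstart, end = gend), cdna)
    list(genomic = setNames(genomic, "synthetic_locus"),
         model = model,
         cdna = setNames(cdna, "synthetic_locus_cdna"))
  })
}

# genomic interval touched by one planted mutation (for overlap checks)
.mutation_span <- function(mut, model) {
  ex <- model$exons
  switch(mut$kind,
    gene_deletion = c(ex$start[1L], ex$end[nrow(ex)]),
    exon_deletion = if (mut$exon_end < nrow(ex))
      c(ex$start[mut$exon], ex$start[mut$exon_end + 1L] - 1L) else
      c(ex$end[mut$exon - 1L] + 1L, ex$end[mut$exon_end]),
    splice_donor = ex$end[mut$exon] + c(1L, 2L),
    splice_acceptor = ex$start[mut$exon] - c(2L, 1L),
    start_loss = c(ex$start[1L], ex$start[1L]),
    nonsense = ex$start[mut$exon] + mut$offset - 1L + c(0L, 2L),
    frameshift_insertion = ex$start[mut$exon] + mut$offset - 1L + c(0L, 0L),
    c(ex$start[mut$exon] + mut$offset - 1L,
      ex$start[mut$exon] + mut$offset - 1L + mut$length - 1L))
}

#' Plant ORF-disrupting mutations in a synthetic locus
#'
#' Each mutation is a list with `kind` (nine-kind vocabulary of
#' [mutation_record()]), `exon`, `offset` (1-based nt within the exon),
#' `length` (indel kinds) and `payload` (inserted bases, substituted stop
#' codon, replacement splice dinucleotide, or replacement start base).
#' `start_loss` is only legal at exon 1 codon 1; splice kinds address the
#' intron after (`splice_donor`) or before (`splice_acceptor`) the named
#' exon; `gene_deletion` replaces the whole gene span with a non-homologous
#' random segment.  Nonsense substitutions must fall on a reference codon
#' boundary and default to TAA.
#'
#' @param genomic Locus sequence (named character of length 1).
#' @param model The `gene_model` truth for `genomic`.
#' @param mutations List of mutation descriptions (see Details).
#' @param species Species label recorded in the returned truth records.
#' @param seed Seed for random payloads (insertion bases, replacement
#'   segment).
#' @return List with mutated `genomic` and `truth` (a `mutation_record`).
#' @export
plant_mutations <- function(genomic, model, mutations,
                            species = "planted", seed = 1L) {
  stopifnot(inherits(model, "gene_model"))
  g <- unname(genomic[[1L]])
  ex <- model$exons
  n_ex <- nrow(ex)
  norm <- lapply(mutations, function(m) {
    m$kind <- match.arg(m$kind, .mutation_kinds)
    if (is.null(m$exon)) m$exon <- if (m$kind == "gene_deletion") 1L else
      stop("mutation of kind '", m$kind, "' needs an exon")
    if (is.null(m$exon_end)) m$exon_end <- m$exon
    if (is.null(m$offset)) m$offset <- 1L
    if (is.null(m$length))
      m$length <- if (!is.null(m$payload)) nchar(m$payload) else NA_integer_
    if (m$kind %in% c("exon_deletion", "splice_donor", "splice_acceptor",
                      "gene_deletion", "start_loss", "nonsense"))
      m$length <- NA_integer_
    m
  })
  # legality checks
  for (m in norm) {
    if (m$exon < 1L || m$exon_end > n_ex) stop("exon index out of range")
    elen <- ex$end[m$exon] - ex$start[m$exon] + 1L
    if (m$kind == "start_loss" && (m$exon != 1L || m$offset != 1L))
      stop("start_loss is only legal at exon 1, codon 1")
    if (m$kind == "splice_donor" && m$exon >= n_ex)
      stop("no intron after the last exon")
    if (m$kind == "splice_acceptor" && m$exon <= 1L)
      stop("no intron before the first exon")
    if (m$kind == "nonsense") {
      cds_pos <- model$cdna_offset[m$exon] + m$offset
      if ((cds_pos - 1L) %% 3L != 0L)
        stop("nonsense offset ", m$offset, " in exon ", m$exon,
             " is not on a codon boundary")
      if (m$offset + 2L > elen) stop("nonsense codon crosses the exon end")
    }
    if (m$kind %in% c("frameshift_deletion", "inframe_deletion")) {
      if (is.na(m$length) || m$offset + m$length - 1L > elen)
        stop("deletion does not fit in exon ", m$exon)
      if ((m$length %% 3L != 0L) != (m$kind == "frameshift_deletion"))
        stop("deletion length ", m$length, " inconsistent with kind ", m$kind)
    }
    if (m$kind == "frameshift_insertion" &&
        !is.na(m$length) && m$length %% 3L == 0L)
      stop("frameshift insertion length must not be a multiple of 3")
  }
  spans <- lapply(norm, .mutation_span, model = model)
  if (length(spans) > 1L) {
    o <- order(vapply(spans, function(x) as.numeric(x[1L]), 0))
    for (i in seq_along(o)[-1L]) {
      if (spans[[o[i]]][1L] <= spans[[o[i - 1L]]][2L])
        stop("overlapping incompatible edits")
    }
  }
  .with_seed(seed, {
    truth <- list()
    # apply right-to-left so earlier coordinates stay valid
    ord <- order(vapply(spans, function(x) as.numeric(x[1L]), 0), decreasing = TRUE)
    for (m in norm[ord]) {
      estart <- ex$start[m$exon]
      rec <- NULL
      if (m$kind == "nonsense") {
        payload <- toupper(if (is.null(m$payload)) "TAA" else m$payload)
        if (!payload %in% c("TAA", "TAG", "TGA"))
          stop("nonsense payload must be a stop codon")
        p <- estart + m$offset - 1L
        g <- paste0(substr(g, 1L, p - 1L), payload,
                    substr(g, p + 3L, nchar(g)))
        rec <- mutation_record(species, "nonsense", m$exon,
                               position = m$offset, detail = payload)
      } else if (m$kind %in% c("frameshift_deletion", "inframe_deletion")) {
        p <- estart + m$offset - 1L
        g <- paste0(substr(g, 1L, p - 1L), substr(g, p + m$length, nchar(g)))
        rec <- mutation_record(species, m$kind, m$exon,
                               position = m$offset, length = m$length)
      } else if (m$kind == "frameshift_insertion") {
        payload <- if (is.null(m$payload))
          .random_bases(if (is.na(m$length)) 1L else m$length, 0.5) else
            toupper(m$payload)
        if (nchar(payload) %% 3L == 0L)
          stop("frameshift insertion length must not be a multiple of 3")
        p <- estart + m$offset - 1L
        g <- paste0(substr(g, 1L, p), payload, substr(g, p + 1L, nchar(g)))
        rec <- mutation_record(species, "frameshift_insertion", m$exon,
                               position = m$offset, length = nchar(payload))
      } else if (m$kind == "splice_donor") {
        payload <- tolower(if (is.null(m$payload)) "ga" else m$payload)
        p <- ex$end[m$exon] + 1L
        g <- paste0(substr(g, 1L, p - 1L), payload,
                    substr(g, p + 2L, nchar(g)))
        rec <- mutation_record(species, "splice_donor", m$exon,
                               detail = paste0("GT to ", toupper(payload)))
      } else if (m$kind == "splice_acceptor") {
        payload <- tolower(if (is.null(m$payload)) "gg" else m$payload)
        p <- ex$start[m$exon] - 2L
        g <- paste0(substr(g, 1L, p - 1L), payload,
                    substr(g, p + 2L, nchar(g)))
        rec <- mutation_record(species, "splice_acceptor", m$exon,
                               detail = paste0("AG to ", toupper(payload)))
      } else if (m$kind == "start_loss") {
        payload <- toupper(if (is.null(m$payload)) "G" else m$payload)
        if (payload == "A") stop("start_loss payload leaves ATG intact")
        p <- ex$start[1L]
        g <- paste0(substr(g, 1L, p - 1L), payload,
                    substr(g, p + 1L, nchar(g)))
        rec <- mutation_record(species, "start_loss", 1L, position = 1L,
                               detail = paste0("ATG to ", payload, "TG"))
      } else if (m$kind == "exon_deletion") {
        # remove the exon run plus the following intron (preceding one when
        # the run reaches the last exon) so the remaining structure is clean
        from <- ex$start[m$exon]; to <- ex$end[m$exon_end]
        if (m$exon_end < n_ex) to <- ex$start[m$exon_end + 1L] - 1L
        else from <- ex$end[m$exon - 1L] + 1L
        g <- paste0(substr(g, 1L, from - 1L), substr(g, to + 1L, nchar(g)))
        rec <- mutation_record(species, "exon_deletion", m$exon,
                               exon_end = m$exon_end)
      } else if (m$kind == "gene_deletion") {
        from <- ex$start[1L]; to <- ex$end[n_ex]
        repl <- .random_bases(max(200L, round((to - from + 1L) * 0.6)), 0.5)
        g <- paste0(substr(g, 1L, from - 1L), tolower(repl),
                    substr(g, to + 1L, nchar(g)))
        rec <- mutation_record(species, "gene_deletion")
      }
      truth[[length(truth) + 1L]] <- rec
    }
    list(genomic = setNames(g, names(genomic)[1L]),
         truth = do.call(.bind_records, rev(truth)))
  })
}
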