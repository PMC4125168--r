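# Dataset preparation, named model batteries, and likelihood-ratio tests for
# relaxed selection.
#
# A battery is a declarative list of branch models over one tree: each entry
# names the branch sets that share an omega class (by tip-set descriptors, so
# the same battery file works on any tree containing those taxa), optionally
# pins classes to fixed values (omega = 1 encodes the neutral/relaxed null),
# or requests the free-ratio model.  Nested fits are compared with 2*dlnL
# against a chi-square with df equal to the parameter-count difference; no
# boundary mixture correction is applied, matching standard practice for
# published branch-model tables.

#' Exclusion rules for dataset preparation
#'
#' @param drop_exons Integer exon indices to remove entirely.
#' @param drop_codon_positions Reference codon indices (1-based, over the
#'   reference CDS) to remove, e.g. codons disrupted in some species.
#' @param reason Optional free-text notes.
#' @return An `exclusion_spec` list.
#' @export
exclusion_spec <- function(drop_exons = integer(0),
                           drop_codon_positions = integer(0),
                           reason = character(0)) {
  structure(list(drop_exons = as.integer(drop_exons),
                 drop_codon_positions = as.integer(drop_codon_positions),
                 reason = reason), class = "exclusion_spec")
}

#' Prepare a codon alignment from per-species virtual cDNAs
#'
#' The inputs are reference-frame virtual cDNAs: one sequence per species,
#' all the same length as the reference CDS, with `-` padding where a species
#' has no sequence.  Excluded exons (resolved through the gene model) and
#' excluded reference codon positions are cut codon-wise; the result is a
#' `codon_alignment` whose nucleotide count is reported as attribute `nt`.
#'
#' @param cdnas Named character vector of reference-frame cDNAs.
#' @param model The reference `gene_model` (needed when dropping exons).
#' @param spec An `exclusion_spec`.
#' @return A `codon_alignment` with attribute `nt` (alignment length in nt).
#' @export
prepare_dataset <- function(cdnas, model = NULL, spec = exclusion_spec()) {
  stopifnot(is.character(cdnas), length(cdnas) >= 1L)
  len <- unique(nchar(cdnas))
  if (length(len) != 1L) stop("virtual cDNAs differ in length")
  if (len %% 3L != 0L) stop("cDNA length not a multiple of 3")
  ncod <- len %/% 3L
  drop <- rep(FALSE, ncod)
  if (length(spec$drop_exons)) {
    if (is.null(model)) stop("dropping exons requires the gene model")
    widths <- model$exons$end - model$exons$start + 1L
    for (e in spec$drop_exons) {
      if (e < 1L || e > length(widths)) stop("exon index ", e, " out of range")
      nt_range <- model$cdna_offset[e] + seq_len(widths[e])
      # a codon is dropped when any of its bases falls in a dropped exon
      drop[unique((nt_range - 1L) %/% 3L + 1L)] <- TRUE
    }
  }
  if (length(spec$drop_codon_positions)) {
    if (any(spec$drop_codon_positions < 1L |
              spec$drop_codon_positions > ncod))
      stop("codon position out of range")
    drop[spec$drop_codon_positions] <- TRUE
  }
  keep <- which(!drop)
  if (!length(keep)) stop("all positions excluded; empty dataset")
  starts <- (keep - 1L) * 3L + 1L
  out <- vapply(cdnas, function(s)
    paste0(substring(s, starts, starts + 2L), collapse = ""), "")
  aln <- codon_alignment(setNames(out, names(cdnas)))
  attr(aln, "nt") <- length(keep) * 3L
  aln
}

# ---- branch-class resolution ------------------------------------------------

.mrca_of <- function(phy, tips) {
  idx <- match(tips, phy$tip.label)
  if (anyNA(idx)) stop("unknown taxa: ",
                       paste(tips[is.na(idx)], collapse = ", "))
  if (length(idx) == 1L) return(idx)
  getMRCA(phy, idx)
}

# edges (rows of phy$edge) selected by one descriptor
.select_edges <- function(phy, sel) {
  type <- match.arg(sel$type, c("terminal", "clade", "stem"))
  tips <- sel$tips
  if (type == "terminal") {
    idx <- match(tips, phy$tip.label)
    if (anyNA(idx)) stop("unknown taxa: ",
                         paste(tips[is.na(idx)], collapse = ", "))
    return(which(phy$edge[, 2L] %in% idx))
  }
  node <- .mrca_of(phy, tips)
  if (type == "stem") return(which(phy$edge[, 2L] == node))
  desc <- node
  repeat {
    more <- phy$edge[phy$edge[, 1L] %in% desc, 2L]
    new <- setdiff(more, desc)
    if (!length(new)) break
    desc <- c(desc, new)
  }
  rows <- which(phy$edge[, 1L] %in% desc)
  if (isTRUE(sel$include_stem) || isTRUE(sel$stem))
    rows <- union(rows, which(phy$edge[, 2L] == node))
  rows
}

#' Resolve declarative branch-set descriptors into a labeled tree
#'
#' @param phy An `ape::phylo` tree.
#' @param classes List indexed by class (class 1, 2, ... in order); each
#'   element is a list of selectors, each a list with `type`
#'   (`"terminal"`, `"clade"`, `"stem"`), `tips`, and for clades
#'   `include_stem`.  Branches not named fall in class 0.
#' @return A `labeled_tree`.
#' @export
resolve_branch_classes <- function(phy, classes) {
  cls <- integer(nrow(phy$edge))
  for (k in seq_along(classes)) {
    for (sel in classes[[k]]) {
      rows <- .select_edges(phy, sel)
      taken <- rows[cls[rows] != 0L & cls[rows] != k]
      if (length(taken))
        stop("branch assigned to two classes (edge ", taken[1L], ")")
      cls[rows] <- k
    }
  }
  labeled_tree(phy, cls)
}

#' Run a named battery of branch models
#'
#' @param aln A `codon_alignment`.
#' @param phy An `ape::phylo` over the alignment's taxa.
#' @param battery List of model descriptions: each a list with `name`,
#'   `classes` (as in [resolve_branch_classes()]; `NULL` or empty for the
#'   one-ratio model), `fixed` (named omega constraints, names are class
#'   indices as strings), and `free_ratio`.
#' @param ... Passed to [fit_codon_model()] (e.g. `n_starts`, `frequencies`).
#' @return List with `fits` (named list of `codon_fit`) and `table`
#'   (data frame: model, lnL, np, omega estimates).
#' @export
model_battery <- function(aln, phy, battery, ...) {
  fits <- list()
  rows <- list()
  for (m in battery) {
    lt <- if (isTRUE(m$free_ratio) || is.null(m$classes) ||
                !length(m$classes))
      labeled_tree(phy) else resolve_branch_classes(phy, m$classes)
    fixed <- if (!is.null(m$fixed)) unlist(m$fixed) else NULL
    fit <- fit_codon_model(aln, lt, fixed = fixed,
                           free_ratio = isTRUE(m$free_ratio), ...)
    fits[[m$name]] <- fit
    om <- if (fit$free_ratio) "variable" else
      paste(paste0(names(fit$omega), "=", signif(fit$omega, 5)),
            collapse = ", ")
    rows[[m$name]] <- data.frame(model = m$name, lnL = fit$lnL, np = fit$np,
                                 omega = om, stringsAsFactors = FALSE)
  }
  list(fits = fits, table = do.call(rbind, rows))
}

#' Read a battery definition from JSON
#'
#' @param path Path to a JSON battery file (see `inst/extdata` for the
#'   catarrhine and whale examples).
#' @return A battery list for [model_battery()].
#' @export
read_battery <- function(path) {
  read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
            simplifyMatrix = FALSE)
}

# ---- likelihood-ratio tests -------------------------------------------------

#' Upper-tail chi-square probability
#'
#' The regularized upper incomplete gamma function `Q(df/2, stat/2)`, stable
#' down to the smallest representable p-values.
#'
#' @param stat Test statistic (>= 0).
#' @param df Degrees of freedom (>= 1).
#' @return Upper-tail probability.
#' @export
chisq_upper_tail <- function(stat, df) {
  if (any(df < 1L) || any(df != round(df))) stop("df must be a positive integer")
  if (any(stat < 0)) stop("stat must be >= 0")
  pchisq(stat, df, lower.tail = FALSE)
}

#' Significance stars
#'
#' @param p P-value(s).
#' @return `"***"` for p < 0.001, `"**"` < 0.01, `"*"` < 0.05, else `"ns"`.
#' @export
significance_stars <- function(p) {
  cut(p, c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", "ns"), right = FALSE) |> as.character()
}

#' Likelihood-ratio test between two nested fits
#'
#' @param null The constrained fit (a `codon_fit`, or any list with `lnL`
#'   and `np`).
#' @param alt The relaxing fit.
#' @param labels Optional `c(null, alt)` model names for the printout.
#' @return An `lrt_result`: `stat` = 2(lnL_alt - lnL_null), `df` =
#'   np_alt - np_null, `p` (upper-tail chi-square), `stars`.
#' @export
lrt <- function(null, alt, labels = c("null", "alt")) {
  if (alt$np <= null$np)
    stop("alternative must have more parameters than the null (",
         alt$np, " vs ", null$np, ")")
  stat <- 2 * (alt$lnL - null$lnL)
  if (stat < -1e-6)
    stop("negative LRT statistic (", signif(stat, 4),
         "): models not nested or a fit failed")
  stat <- max(stat, 0)
  df <- alt$np - null$np
  p <- chisq_upper_tail(stat, df)
  structure(list(stat = stat, df = df, p = p,
                 stars = significance_stars(p),
                 models = paste(labels[1L], "vs", labels[2L])),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("%s: 2dlnL = %.4f, df = %d, P = %.4g %s\n",
              x$models, x$stat, x$df, x$p, x$stars))
  invisible(x)
}

# ---- published model tables -------------------------------------------------

#' Published branch-model summary tables
#'
#' Returns the printed maximum-likelihood summaries (model id, description
#' tag, omega estimates, lnL, np) for the two shipped datasets: the
#' catarrhine primate battery (models A-L) and the whale battery (models
#' A-G).  These numbers are inputs for LRT arithmetic, not outputs of this
#' package.
#'
#' @param dataset `"catarrhine"` or `"whale"`.
#' @return Data frame with columns `model`, `omega0`, `omega1`, `omega2`,
#'   `lnL`, `np`.
#' @export
model_table <- function(dataset = c("catarrhine", "whale")) {
  dataset <- match.arg(dataset)
  path <- system.file("extdata", paste0(dataset, "_model_table.tsv"),
                      package = "genedecay", mustWork = TRUE)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Likelihood-ratio test from a model summary table
#'
#' Convenience wrapper: looks up two models in a summary table (as returned
#' by [model_table()] or built from [model_battery()]) and runs [lrt()].
#'
#' @param tbl Data frame with `model`, `lnL`, `np` columns.
#' @param null,alt Model ids (e.g. `"B"`, `"A"`).
#' @return An `lrt_result`.
#' @export
lrt_from_table <- function(tbl, null, alt) {
  get1 <- function(id) {
    row <- tbl[tbl$model == id, , drop = FALSE]
    if (nrow(row) != 1L) stop("model '", id, "' not found in table")
    list(lnL = row$lnL, np = row$np)
  }
  lrt(get1(null), get1(alt), labels = c(null, alt))
}
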