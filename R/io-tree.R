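# Species trees with branch omega-class labels.
#
# A labeled_tree wraps an ape "phylo" with an integer class per edge.  Class 0
# is the background; classes 1..K-1 mark branch sets that receive their own
# dN/dS ratio in branch models.  On disk the labels use the codeml Newick
# dialect: "#k" appended to the node (tip or internal) under the branch.

#' Construct a labeled tree
#'
#' @param phy An `ape::phylo` tree with unique tip labels.
#' @param class Integer vector of branch classes, one per row of `phy$edge`
#'   (default all 0).  Classes must form a contiguous set `{0..K-1}`.
#' @return A `labeled_tree` object.
#' @export
labeled_tree <- function(phy, class = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (anyDuplicated(phy$tip.label))
    stop("duplicate taxon name '", phy$tip.label[duplicated(phy$tip.label)][1L], "'")
  ne <- nrow(phy$edge)
  if (is.null(class)) class <- integer(ne)
  class <- as.integer(class)
  if (length(class) != ne) stop("need one class per edge (", ne, ")")
  k <- sort(unique(class))
  if (!identical(k, seq(0L, max(class)))) {
    stop("branch classes must be contiguous 0..K-1, got {",
         paste(k, collapse = ","), "}")
  }
  structure(list(phy = phy, class = class), class = "labeled_tree")
}

#' @export
print.labeled_tree <- function(x, ...) {
  cat("labeled tree:", length(x$phy$tip.label), "tips,",
      nrow(x$phy$edge), "edges,", max(x$class) + 1L, "branch class(es)\n")
  invisible(x)
}

# class of the edge above each node (tips first, ape numbering)
.edge_class_by_node <- function(lt) {
  out <- rep(NA_integer_, max(lt$phy$edge))
  out[lt$phy$edge[, 2L]] <- lt$class
  out
}

#' Read a Newick tree with codeml branch labels
#'
#' Branch-class marks are written `#k` (integer k >= 1) after a tip name or
#' internal node; unlabeled branches fall in class 0.
#'
#' @param path Path to a Newick file, or a literal Newick string via `text`.
#' @param text Optional Newick string (overrides `path`).
#' @return A `labeled_tree`.
#' @export
read_newick_labeled <- function(path = NULL, text = NULL) {
  phy <- if (is.null(text)) read.tree(path) else read.tree(text = text)
  if (is.null(phy)) stop("could not parse Newick input")
  take <- function(labels) {
    labels[is.na(labels)] <- ""
    cls <- integer(length(labels))
    has <- grepl("#", labels, fixed = TRUE)
    if (any(has)) {
      tag <- sub("^.*#", "", labels[has])
      k <- suppressWarnings(as.integer(tag))
      bad <- is.na(k) | tag != as.character(k) | k < 1L
      bad[is.na(bad)] <- TRUE
      if (any(bad)) stop("malformed branch label '#", tag[bad][1L], "'")
      cls[has] <- k
    }
    list(label = sub("#.*$", "", labels), class = cls)
  }
  tips <- take(phy$tip.label)
  phy$tip.label <- tips$label
  node_cls <- integer(phy$Nnode)
  if (!is.null(phy$node.label)) {
    nodes <- take(phy$node.label)
    phy$node.label <- nodes$label
    node_cls <- nodes$class
    if (all(!nzchar(phy$node.label))) phy$node.label <- NULL
  }
  ntip <- length(phy$tip.label)
  by_node <- c(tips$class, node_cls)
  labeled_tree(phy, by_node[phy$edge[, 2L]])
}

#' Write a labeled tree as Newick with codeml branch labels
#'
#' Branch lengths, if present, are written to 10 significant digits; class-k
#' branches (k >= 1) get `#k` appended to the node under them.
#'
#' @param lt A `labeled_tree`.
#' @param path Output path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick_labeled <- function(lt, path = NULL) {
  stopifnot(inherits(lt, "labeled_tree"))
  phy <- lt$phy
  by_node <- .edge_class_by_node(lt)
  ntip <- length(phy$tip.label)
  tag <- ifelse(!is.na(by_node) & by_node > 0L, paste0("#", by_node), "")
  phy$tip.label <- paste0(phy$tip.label, tag[seq_len(ntip)])
  nl <- if (is.null(phy$node.label)) rep("", phy$Nnode) else phy$node.label
  phy$node.label <- paste0(nl, tag[ntip + seq_len(phy$Nnode)])
  if (all(!nzchar(phy$node.label))) phy$node.label <- NULL
  txt <- write.tree(phy, digits = 10)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
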