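# Dollo-style placement of shared mutations on a species tree.
#
# A derived disruptive mutation is assumed to arise once and never revert.
# An identical event (same kind, exon, position, length, allele) observed in
# a set of species is assigned to the single branch above their most recent
# common ancestor -- but only when the observed species set is exactly the
# MRCA's tip set among sampled species.  Any other pattern is explained as
# independent events on the terminal branches.

#' Assign mutation events to branches of a species tree
#'
#' @param records A `mutation_record` across species.
#' @param phy An `ape::phylo` whose tip labels cover all record species.
#' @return Data frame with one row per placed event: the identity key
#'   columns (`kind`, `exon`, `position`, `length`, `detail`), `species`
#'   (comma-joined carriers), `node` (ape node number under the assigned
#'   branch), `branch_label` (tip name or `node<N>`), and `shared`.
#' @export
assign_mutations_to_tree <- function(records, phy) {
  stopifnot(inherits(phy, "phylo"))
  unknown <- setdiff(unique(records$species), phy$tip.label)
  if (length(unknown))
    stop("species not in tree: ", paste(unknown, collapse = ", "))
  if (nrow(records) == 0L)
    return(data.frame(kind = character(), exon = integer(),
                      position = integer(), length = integer(),
                      detail = character(), species = character(),
                      node = integer(), branch_label = character(),
                      shared = logical(), stringsAsFactors = FALSE))
  key <- paste(records$kind, records$exon, records$position,
               records$length, records$detail, sep = "|")
  ntip <- length(phy$tip.label)
  clade_tips <- function(node) {
    if (node <= ntip) return(phy$tip.label[node])
    desc <- node
    repeat {
      new <- setdiff(phy$edge[phy$edge[, 1L] %in% desc, 2L], desc)
      if (!length(new)) break
      desc <- c(desc, new)
    }
    phy$tip.label[desc[desc <= ntip]]
  }
  out <- list()
  for (k in unique(key)) {
    rows <- records[key == k, , drop = FALSE]
    sp <- unique(rows$species)
    place <- function(node, carriers, shared) {
      data.frame(kind = rows$kind[1L], exon = rows$exon[1L],
                 position = rows$position[1L], length = rows$length[1L],
                 detail = rows$detail[1L],
                 species = paste(carriers, collapse = ","),
                 node = node,
                 branch_label = if (node <= ntip) phy$tip.label[node] else
                   paste0("node", node),
                 shared = shared, stringsAsFactors = FALSE)
    }
    if (length(sp) == 1L) {
      out[[length(out) + 1L]] <- place(match(sp, phy$tip.label), sp, FALSE)
      next
    }
    node <- getMRCA(phy, match(sp, phy$tip.label))
    if (setequal(clade_tips(node), sp)) {
      out[[length(out) + 1L]] <- place(node, sp, TRUE)
    } else {
      for (s in sp)
        out[[length(out) + 1L]] <- place(match(s, phy$tip.label), s, FALSE)
    }
  }
  do.call(rbind, out)
}
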