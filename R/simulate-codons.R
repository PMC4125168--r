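# Forward simulation under the branch-class codon model -- the inverse of
# fitting, used for parameter-recovery and null-calibration experiments.

#' Simulate a codon alignment on a labeled tree
#'
#' The root codon is drawn from the equilibrium frequencies; each branch then
#' evolves its parent state through the transition matrix `exp(Q t)` built
#' with that branch's omega class.
#'
#' @param tree A `labeled_tree` with branch lengths (substitutions/codon).
#' @param params List with `kappa`, `omega` (one value per branch class) and
#'   `pi` (61 sense-codon frequencies; default uniform).
#' @param n_codons Number of codon sites.
#' @param seed Integer seed.
#' @return A `codon_alignment` with the tree's tips as taxa.
#' @export
simulate_codon_alignment <- function(tree, params, n_codons, seed = 1L) {
  stopifnot(inherits(tree, "labeled_tree"))
  phy <- tree$phy
  if (is.null(phy$edge.length)) stop("tree needs branch lengths")
  cs <- codon_states()
  ns <- length(cs$codons)
  pi <- if (is.null(params$pi)) rep(1 / ns, ns) else params$pi
  if (any(pi < 0) || all(pi == 0)) stop("invalid equilibrium frequencies")
  if (sum(pi > 0) < 2L) stop("degenerate single-state frequencies")
  pi <- pi / sum(pi)
  omegas <- params$omega
  if (length(omegas) < max(tree$class) + 1L)
    stop("need one omega per branch class")
  po <- reorder(phy, "postorder")
  # carry the class labels through the edge reordering
  key <- paste(phy$edge[, 1L], phy$edge[, 2L])
  cls <- tree$class[match(paste(po$edge[, 1L], po$edge[, 2L]), key)]
  .with_seed(seed, {
    nnode <- max(po$edge)
    ntip <- length(po$tip.label)
    states <- matrix(NA_integer_, nnode, n_codons)
    root <- po$edge[nrow(po$edge), 1L]
    states[root, ] <- sample.int(ns, n_codons, replace = TRUE, prob = pi)
    pmats <- list()
    for (e in rev(seq_len(nrow(po$edge)))) {  # preorder: parents first
      parent <- po$edge[e, 1L]; child <- po$edge[e, 2L]
      keyp <- paste(cls[e], signif(po$edge.length[e], 12))
      if (is.null(pmats[[keyp]]))
        pmats[[keyp]] <- codon_pmat(params$kappa, omegas[cls[e] + 1L], pi,
                                    po$edge.length[e])
      P <- pmats[[keyp]]
      ps <- states[parent, ]
      out <- integer(n_codons)
      for (s in unique(ps)) {
        idx <- which(ps == s)
        out[idx] <- sample.int(ns, length(idx), replace = TRUE, prob = P[s, ])
      }
      states[child, ] <- out
    }
    seqs <- vapply(seq_len(ntip), function(i)
      paste0(cs$codons[states[i, ]], collapse = ""), "")
    codon_alignment(setNames(seqs, po$tip.label))
  })
}
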