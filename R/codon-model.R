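# Goldman-Yang codon substitution model with branch-specific dN/dS classes.
#
# The instantaneous rate from codon i to codon j is zero unless the codons
# differ at exactly one position, and otherwise proportional to pi_j with a
# factor kappa for transitions and omega for nonsynonymous changes.  The
# generator is rescaled so branch lengths are expected substitutions per
# codon.  Likelihoods are computed by Felsenstein pruning over the 61 sense
# codons (compiled code); the model is reversible, so root placement is
# irrelevant and trees may be rooted or unrooted.

#' Empirical codon frequencies (F3x4)
#'
#' Position-specific nucleotide frequencies are tabulated from the observed
#' (non-missing) codons; the equilibrium frequency of each sense codon is the
#' product of its three positional nucleotide frequencies, renormalized over
#' the 61 sense codons.
#'
#' @param aln A `codon_alignment`.
#' @return Numeric vector of 61 frequencies summing to 1.
#' @export
f3x4_frequencies <- function(aln) {
  stopifnot(.is_codon_alignment(aln))
  cs <- codon_states()
  nt <- do.call(rbind, strsplit(cs$codons, ""))
  obs <- table(factor(aln[!is.na(aln)], levels = seq_len(61L)))
  f <- matrix(0, 3L, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (p in 1:3) {
    tab <- tapply(as.numeric(obs), nt[, p], sum)
    f[p, names(tab)] <- tab
  }
  if (any(rowSums(f) == 0))
    stop("a codon position has no observed data")
  f <- f / rowSums(f)
  pi <- f[1L, nt[, 1L]] * f[2L, nt[, 2L]] * f[3L, nt[, 3L]]
  unname(pi / sum(pi))
}

#' Empirical codon frequencies (F61)
#'
#' Observed sense-codon proportions with a small floor so that no state has
#' zero equilibrium frequency (required for the reversible eigensolver).
#'
#' @param aln A `codon_alignment`.
#' @param floor Minimum frequency assigned to unobserved codons.
#' @return Numeric vector of 61 frequencies summing to 1.
#' @export
f61_frequencies <- function(aln, floor = 1e-6) {
  stopifnot(.is_codon_alignment(aln))
  obs <- as.numeric(table(factor(aln[!is.na(aln)], levels = seq_len(61L))))
  if (sum(obs) == 0) stop("alignment has no observed codons")
  pi <- pmax(obs / sum(obs), floor)
  pi / sum(pi)
}

#' Empirical codon frequencies (F1x4)
#'
#' A single overall nucleotide composition applied at every codon position.
#'
#' @param aln A `codon_alignment`.
#' @return Numeric vector of 61 frequencies summing to 1.
#' @export
f1x4_frequencies <- function(aln) {
  stopifnot(.is_codon_alignment(aln))
  cs <- codon_states()
  nt <- do.call(rbind, strsplit(cs$codons, ""))
  obs <- table(factor(aln[!is.na(aln)], levels = seq_len(61L)))
  cnt <- setNames(numeric(4L), c("A", "C", "G", "T"))
  for (p in 1:3) {
    tab <- tapply(as.numeric(obs), nt[, p], sum)
    cnt[names(tab)] <- cnt[names(tab)] + tab
  }
  if (sum(cnt) == 0) stop("alignment has no observed data")
  f <- cnt / sum(cnt)
  pi <- f[nt[, 1L]] * f[nt[, 2L]] * f[nt[, 3L]]
  unname(pi / sum(pi))
}

.pi_from_option <- function(aln, frequencies, pi) {
  if (!is.null(pi)) return(pi / sum(pi))
  switch(match.arg(frequencies, c("f3x4", "f61", "f1x4")),
         f3x4 = f3x4_frequencies(aln),
         f61 = f61_frequencies(aln),
         f1x4 = f1x4_frequencies(aln))
}

#' GY94 rate matrix
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega dN/dS ratio (> 0).
#' @param pi Equilibrium frequencies over the 61 sense codons.
#' @return 61 x 61 generator `Q`, rescaled so that the expected substitution
#'   rate at equilibrium is 1 (`-sum(pi * diag(Q)) == 1`).
#' @export
codon_rate_matrix <- function(kappa, omega, pi) {
  stopifnot(kappa > 0, omega > 0, length(pi) == 61L, all(pi >= 0))
  if (abs(sum(pi) - 1) > 1e-8) stop("frequencies must sum to 1")
  cs <- codon_states()
  Q <- codon_Q_cpp(kappa, omega, pi, cs$pairs)
  dimnames(Q) <- list(cs$codons, cs$codons)
  Q
}

#' GY94 transition probability matrix exp(Q t)
#'
#' @inheritParams codon_rate_matrix
#' @param t Branch length in expected substitutions per codon (>= 0).
#' @return 61 x 61 stochastic matrix.
#' @export
codon_pmat <- function(kappa, omega, pi, t) {
  stopifnot(t >= 0)
  cs <- codon_states()
  P <- codon_pmat_cpp(kappa, omega, pi, cs$pairs, t)
  dimnames(P) <- list(cs$codons, cs$codons)
  P
}

# align taxa, build 0-based tip matrix in postorder tip numbering
.prune_inputs <- function(aln, tree) {
  phy <- tree$phy
  miss <- setdiff(phy$tip.label, rownames(aln))
  if (length(miss))
    stop("taxa missing from alignment: ", paste(miss, collapse = ", "))
  po <- reorder(phy, "postorder")
  key <- paste(phy$edge[, 1L], phy$edge[, 2L])
  cls <- tree$class[match(paste(po$edge[, 1L], po$edge[, 2L]), key)]
  tips <- unclass(aln)[po$tip.label, , drop = FALSE]
  tips[is.na(tips)] <- 0L
  list(po = po, class = cls, tips = tips - 1L)
}

#' Log-likelihood of a codon alignment on a labeled tree
#'
#' Felsenstein pruning over the 61 sense codons.  Missing-data codons
#' contribute all-ones partials; the root is weighted by the equilibrium
#' frequencies.
#'
#' @param aln A `codon_alignment`.
#' @param tree A `labeled_tree` with branch lengths.
#' @param kappa Transition/transversion rate ratio.
#' @param omega Numeric vector, one dN/dS per branch class.
#' @param pi Equilibrium frequencies (default F3x4 from the alignment).
#' @param site Return per-site log-likelihoods as attribute `site`?
#' @return The total log-likelihood (numeric scalar).
#' @export
codon_log_likelihood <- function(aln, tree, kappa, omega, pi = NULL,
                                 site = FALSE) {
  stopifnot(.is_codon_alignment(aln), inherits(tree, "labeled_tree"))
  if (is.null(pi)) pi <- f3x4_frequencies(aln)
  cs <- codon_states()
  if (length(tree$phy$tip.label) == 1L) {
    states <- unclass(aln)[tree$phy$tip.label, ]
    lls <- ifelse(is.na(states), 0, log(pi[states]))
    return(structure(sum(lls), site = if (site) lls else NULL))
  }
  if (is.null(tree$phy$edge.length)) stop("tree needs branch lengths")
  pin <- .prune_inputs(aln, tree)
  res <- codon_lnL_cpp(pin$tips, pin$po$edge, pin$po$edge.length,
                       pin$class, kappa, omega, pi, cs$pairs)
  if (!all(is.finite(res$site_lnL))) {
    bad <- which(!is.finite(res$site_lnL))[1L]
    stop("non-finite site likelihood at codon site ", bad)
  }
  structure(res$lnL, site = if (site) res$site_lnL else NULL)
}

#' Fit a branch-class codon model by maximum likelihood
#'
#' Maximizes the pruning log-likelihood over kappa, the free omega classes,
#' and all branch lengths, using log-transformed box-constrained
#' quasi-Newton iterations with multiple jittered starts.  Classes named in
#' `fixed` keep their value (e.g. `fixed = c("1" = 1)` pins class-1 branches
#' to neutrality).  With `free_ratio = TRUE` every branch gets its own omega
#' class.
#'
#' @param aln A `codon_alignment`.
#' @param tree A `labeled_tree`; existing branch lengths seed the optimizer.
#' @param fixed Named numeric of fixed omega values, names = class indices.
#' @param free_ratio Give every branch its own free omega?
#' @param frequencies Frequency model: `"f3x4"` (default), `"f61"`, `"f1x4"`.
#' @param pi Explicit equilibrium frequencies (overrides `frequencies`).
#' @param n_starts Number of optimizer starts (jitter factors 0.5, 1, 2).
#' @param init List overriding the starting values `kappa = 2`,
#'   `omega = 0.4`, `blen = 0.1`.
#' @param control Passed to [stats::nlminb()] control (on top of the
#'   defaults `rel.tol = 1e-10`, `iter.max = 1000`).
#' @return A `codon_fit`: `lnL`, parameter count `np` (free omegas + kappa +
#'   branch lengths), `kappa`, `omega` (all classes, fixed included),
#'   `branch_lengths` (in `tree$phy$edge` order), `tree` (with fitted
#'   lengths), `converged`, and `omega_by_branch` when `free_ratio`.
#' @export
fit_codon_model <- function(aln, tree, fixed = NULL, free_ratio = FALSE,
                            frequencies = "f3x4", pi = NULL, n_starts = 3L,
                            init = list(), control = list()) {
  stopifnot(.is_codon_alignment(aln), inherits(tree, "labeled_tree"))
  if (free_ratio) {
    tree <- labeled_tree(tree$phy, seq_len(nrow(tree$phy$edge)) - 1L)
    if (!is.null(fixed)) stop("fixed omegas are not meaningful in free-ratio mode")
  }
  pi <- .pi_from_option(aln, frequencies, pi)
  cs <- codon_states()
  pin <- .prune_inputs(aln, tree)
  nedge <- nrow(pin$po$edge)
  nclass <- max(tree$class) + 1L
  fixed_idx <- integer(0)
  fixed_val <- numeric(0)
  if (!is.null(fixed)) {
    fixed_idx <- as.integer(names(fixed))
    if (anyNA(fixed_idx) || any(fixed_idx < 0L) || any(fixed_idx >= nclass))
      stop("fixed omega class out of range")
    fixed_val <- as.numeric(fixed)
  }
  free_idx <- setdiff(seq_len(nclass) - 1L, fixed_idx)
  nfree <- length(free_idx)

  ini <- modifyList(list(kappa = 2, omega = 0.4, blen = 0.1), init)
  bl0 <- if (!is.null(pin$po$edge.length) &&
               all(is.finite(pin$po$edge.length)) &&
               all(pin$po$edge.length > 0))
    pin$po$edge.length else rep(ini$blen, nedge)

  omega_full <- rep(NA_real_, nclass)
  omega_full[fixed_idx + 1L] <- fixed_val

  obj <- function(par) {
    kappa <- exp(par[1L])
    om <- omega_full
    if (nfree) om[free_idx + 1L] <- exp(par[1L + seq_len(nfree)])
    bl <- exp(par[1L + nfree + seq_len(nedge)])
    res <- codon_lnL_cpp(pin$tips, pin$po$edge, bl, pin$class,
                         kappa, om, pi, cs$pairs)
    if (!is.finite(res$lnL)) return(1e10)
    -res$lnL
  }

  base_start <- log(c(ini$kappa, rep(ini$omega, nfree), bl0))
  lower <- log(c(1e-4, rep(1e-6, nfree), rep(1e-7, nedge)))
  upper <- log(c(1e3, rep(50, nfree), rep(20, nedge)))
  ctrl <- modifyList(list(rel.tol = 1e-10, iter.max = 1000L,
                          eval.max = 5000L), control)
  jitter <- c(1, 0.5, 2)[seq_len(max(1L, min(3L, n_starts)))]
  best <- NULL
  conv <- FALSE
  for (f in jitter) {
    st <- pmin(pmax(base_start + log(f), lower), upper)
    res <- tryCatch(nlminb(st, obj, lower = lower, upper = upper,
                           control = ctrl),
                    error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$objective < best$objective) best <- res
    if (res$convergence == 0L) conv <- TRUE
  }
  if (is.null(best)) stop("all optimizer starts failed")

  par <- best$par
  kappa <- exp(par[1L])
  omega <- omega_full
  if (nfree) omega[free_idx + 1L] <- exp(par[1L + seq_len(nfree)])
  bl_po <- exp(par[1L + nfree + seq_len(nedge)])
  # map fitted lengths back to the input tree's edge order
  key_po <- paste(pin$po$edge[, 1L], pin$po$edge[, 2L])
  key_in <- paste(tree$phy$edge[, 1L], tree$phy$edge[, 2L])
  bl <- bl_po[match(key_in, key_po)]
  fitted_tree <- tree
  fitted_tree$phy$edge.length <- bl
  out <- list(lnL = -best$objective,
              np = nfree + 1L + nedge,
              kappa = kappa,
              omega = setNames(omega, paste0("omega", seq_len(nclass) - 1L)),
              fixed = fixed,
              branch_lengths = bl,
              pi = pi,
              tree = fitted_tree,
              free_ratio = free_ratio,
              converged = conv)
  if (free_ratio)
    out$omega_by_branch <- setNames(omega[tree$class + 1L],
                                    .branch_labels(tree))
  class(out) <- "codon_fit"
  out
}

# human-readable branch names "parent->child(tipname)"
.branch_labels <- function(tree) {
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  child <- phy$edge[, 2L]
  nm <- ifelse(child <= ntip, phy$tip.label[child], paste0("node", child))
  paste0(phy$edge[, 1L], "..", nm)
}

#' @export
print.codon_fit <- function(x, ...) {
  cat("codon model fit: lnL =", format(x$lnL, digits = 10),
      " np =", x$np, "\n  kappa =", signif(x$kappa, 5), "\n")
  om <- if (x$free_ratio) "free-ratio (one omega per branch)" else
    paste(names(x$omega), "=", signif(x$omega, 5), collapse = ", ")
  cat("  omega:", om, "\n")
  if (!x$converged) cat("  WARNING: optimizer did not report convergence\n")
  invisible(x)
}
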