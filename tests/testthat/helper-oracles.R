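# independent brute-force oracles and small generators used across tests

make_coding <- function(x) {
  # x: named list of integer state sets, or named integer vector
  if (!is.list(x)) x <- lapply(x, function(v) as.integer(v))
  structure(x, class = "character_coding")
}

# random rooted tree with positive branch lengths; occasionally a star
# polytomy to exercise multifurcations
rand_tree <- function(n, star = FALSE) {
  tr <- if (star) ape::stree(n, "star") else ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 2)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

rand_state_sets <- function(n) {
  pool <- list(0L, 1L, 2L, c(0L, 1L), c(1L, 2L), c(0L, 2L), 0:2)
  sets <- pool[sample.int(length(pool), n, replace = TRUE)]
  names(sets) <- paste0("t", seq_len(n))
  make_coding(sets)
}

# all assignments of states to "free" nodes (internal nodes + ambiguous
# tips), as a matrix over all nodes
.assignments <- function(tree, coding) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(ntip)) sets[[i]] <- coding[[tree$tip.label[i]]]
  for (i in (ntip + 1L):nn) sets[[i]] <- 0:2
  as.matrix(expand.grid(sets, KEEP.OUT.ATTRS = FALSE))
}

# exhaustive-enumeration ER log-likelihood
enum_loglik <- function(tree, coding, q, prior = rep(1 / 3, 3)) {
  po <- ape::reorder.phylo(tree, "postorder")
  E <- po$edge
  lens <- po$edge.length
  G <- .assignments(tree, coding)
  root <- E[nrow(E), 1L]
  like <- prior[G[, root] + 1L]
  for (j in seq_len(nrow(E))) {
    e <- exp(-3 * q * lens[j])
    same <- G[, E[j, 1L]] == G[, E[j, 2L]]
    like <- like * ifelse(same, 1 / 3 + 2 / 3 * e, 1 / 3 - 1 / 3 * e)
  }
  log(sum(like))
}

# exhaustive joint-posterior marginals, per node
enum_marginals <- function(tree, coding, q, prior = rep(1 / 3, 3)) {
  po <- ape::reorder.phylo(tree, "postorder")
  E <- po$edge
  lens <- po$edge.length
  G <- .assignments(tree, coding)
  root <- E[nrow(E), 1L]
  like <- prior[G[, root] + 1L]
  for (j in seq_len(nrow(E))) {
    e <- exp(-3 * q * lens[j])
    same <- G[, E[j, 1L]] == G[, E[j, 2L]]
    like <- like * ifelse(same, 1 / 3 + 2 / 3 * e, 1 / 3 - 1 / 3 * e)
  }
  nn <- ncol(G)
  M <- matrix(0, nn, 3)
  for (n in seq_len(nn))
    for (s in 0:2) M[n, s + 1L] <- sum(like[G[, n] == s])
  M / rowSums(M)
}

# exhaustive minimum-change cost and MPR sets (states appearing in at
# least one minimal labeling), unit cost matrix
enum_sankoff <- function(tree, coding) {
  po <- ape::reorder.phylo(tree, "postorder")
  E <- po$edge
  G <- .assignments(tree, coding)
  cost <- rowSums(matrix(G[, E[, 1L]] != G[, E[, 2L]], nrow = nrow(G)))
  best <- min(cost)
  opt <- G[cost == best, , drop = FALSE]
  mpr <- lapply(seq_len(ncol(G)), function(n) sort(unique(opt[, n])))
  list(cost = best, mpr = mpr)
}
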