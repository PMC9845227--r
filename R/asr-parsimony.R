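#' Sankoff parsimony ancestral reconstruction with MPR state sets
#'
#' Minimum-change reconstruction of the 3-state character under a unit
#' (unordered) cost matrix. Branch lengths are ignored. For every node the
#' full set of states occurring in at least one most-parsimonious
#' reconstruction (the MPR set) is returned, computed by the Sankoff
#' down-pass followed by an up-pass that adds, for each node and state, the
#' minimal cost of the rest of the tree conditional on that node bearing
#' that state. Ambiguous tips contribute zero cost for any state in their
#' set and may themselves have multi-state MPR sets.
#'
#' @param tree rooted `phylo`; polytomies allowed.
#' @param coding a `character_coding` covering every tip.
#' @return an `asr_result` with `method = "MP"`, elements `cost` (minimum
#'   number of changes) and `mpr` (list of integer state sets, one per
#'   node, tips first in ape numbering).
#' @export
sankoff_asr <- function(tree, coding) {
  validate_tree(tree)
  tipM <- coding_matrix(coding, tree)
  k <- length(STATES)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  E <- ape::reorder.phylo(tree, "postorder")$edge

  # down-pass: g[n, s] = min changes in the subtree of n given state s at n
  g <- matrix(0, nn, k)
  g[seq_len(ntip), ] <- ifelse(tipM == 1, 0, Inf)
  # per-edge child->parent message under unit costs:
  # m(s) = min(g[child, s], min(g[child, ]) + 1)
  msg <- matrix(0, nrow(E), k)
  for (i in seq_len(nrow(E))) {
    p <- E[i, 1L]; ch <- E[i, 2L]
    m <- pmin(g[ch, ], min(g[ch, ]) + 1)
    msg[i, ] <- m
    g[p, ] <- g[p, ] + m
  }
  root <- E[nrow(E), 1L]
  cost <- min(g[root, ])

  # up-pass: f[n, s] = min changes outside the subtree of n given state s
  # at n; for child v of u: f[v, s] = min_su [f[u, su] + g[u, su] -
  # m_v(su) + 1{su != s}]
  f <- matrix(0, nn, k)
  f[root, ] <- 0
  for (i in rev(seq_len(nrow(E)))) {
    p <- E[i, 1L]; ch <- E[i, 2L]
    rest <- f[p, ] + g[p, ] - msg[i, ]   # cost above+beside, per parent state
    f[ch, ] <- pmin(rest, min(rest) + 1) # absorb the connecting branch
    # (f[ch, s] = min(rest[s], min_{su != s}(rest[su]) + 1); since
    #  rest[s] <= rest[s] + 1 this equals min(rest[s], min(rest) + 1))
  }

  h <- g + f
  mpr <- lapply(seq_len(nn), function(n) STATES[h[n, ] <= cost + 1e-9])
  new_asr_result(method = "MP", tree = tree, cost = cost, mpr = mpr)
}
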