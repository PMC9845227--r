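#' Read a stratigraphic range table
#'
#' Expects delimited text (TSV or CSV, chosen by extension) with columns
#' `taxon`, `fad_ma`, `lad_ma`: first and last appearance data in Ma
#' (millions of years before present, so FAD >= LAD >= 0). Extant taxa are
#' represented with `lad_ma = 0`.
#'
#' @param file path to the table.
#' @return a `data.frame` with columns `taxon`, `fad_ma`, `lad_ma`.
#' @export
read_strat_ranges <- function(file) {
  if (!file.exists(file)) stop("range file not found: ", file)
  sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(file, sep = sep, stringsAsFactors = FALSE)
  validate_strat_ranges(df)
}

#' Validate a stratigraphic range table
#'
#' @param df data.frame with columns `taxon`, `fad_ma`, `lad_ma`.
#' @return the validated data.frame (taxon coerced to character).
#' @export
validate_strat_ranges <- function(df) {
  need <- c("taxon", "fad_ma", "lad_ma")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("range table lacks column(s): ", paste(miss, collapse = ", "))
  df$taxon <- as.character(df$taxon)
  if (anyDuplicated(df$taxon))
    stop("duplicate taxa in range table: ",
         paste(unique(df$taxon[duplicated(df$taxon)]), collapse = ", "))
  if (any(df$lad_ma < 0)) stop("negative LAD in range table")
  bad <- df$taxon[df$fad_ma < df$lad_ma]
  if (length(bad))
    stop("FAD < LAD for taxa: ", paste(bad, collapse = ", "))
  df
}

#' Assign node ages from stratigraphic ranges
#'
#' Tip ages follow `tip_age_policy` (FAD, LAD, or range midpoint). Each
#' internal node is as old as the oldest first appearance among its
#' descendant tips: a node cannot be younger than the first appearance of
#' any lineage it subtends. This is the basic node-dating rule for
#' paleontological trees; zero-length branches that it produces are dealt
#' with by [apply_branch_lengths()].
#'
#' @param tree `phylo`.
#' @param ranges data.frame as from [read_strat_ranges()].
#' @param tip_age_policy one of `"FAD"` (default), `"LAD"`, `"midpoint"`.
#' @return numeric vector of ages in Ma, length `Ntip + Nnode`, indexed by
#'   ape node number.
#' @export
assign_node_ages <- function(tree, ranges, tip_age_policy = c("FAD", "LAD", "midpoint")) {
  validate_tree(tree)
  tip_age_policy <- match.arg(tip_age_policy)
  ranges <- validate_strat_ranges(as.data.frame(ranges))
  ntip <- length(tree$tip.label)
  idx <- match(tree$tip.label, ranges$taxon)
  if (anyNA(idx))
    stop("no stratigraphic range for tip(s): ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  fad <- ranges$fad_ma[idx]
  lad <- ranges$lad_ma[idx]
  tip_age <- switch(tip_age_policy,
                    FAD = fad, LAD = lad, midpoint = (fad + lad) / 2)
  nn <- ntip + tree$Nnode
  ages <- numeric(nn)
  ages[seq_len(ntip)] <- tip_age
  maxfad <- numeric(nn)
  maxfad[seq_len(ntip)] <- fad
  E <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(E))) {
    p <- E[i, 1L]; ch <- E[i, 2L]
    maxfad[p] <- max(maxfad[p], maxfad[ch])
  }
  ages[(ntip + 1L):nn] <- maxfad[(ntip + 1L):nn]
  ages
}

#' Derive branch lengths from node ages with a minimum-branch-length floor
#'
#' Branch length is parent age minus child age (Myr). Any branch shorter
#' than `mbl` is repaired by shifting ancestral nodes rootward (older) by
#' the minimum amount that restores all floors: nodes are visited in
#' postorder and each is aged to at most satisfy its children's
#' constraints, so the total shift is pointwise minimal and the relative
#' order of nodes is preserved. Tip ages are never moved.
#'
#' @param tree `phylo`.
#' @param ages numeric vector from [assign_node_ages()] (or true simulated
#'   ages), length `Ntip + Nnode`.
#' @param mbl minimum branch length in Myr; must be > 0 (zero-length
#'   branches make likelihood methods degenerate).
#' @return the tree with `edge.length` set, plus elements `node.ages`
#'   (corrected ages), `mbl`, and `bl_mode = "timescaled"`.
#' @export
apply_branch_lengths <- function(tree, ages, mbl = 1) {
  validate_tree(tree)
  if (!is.numeric(mbl) || length(mbl) != 1L || mbl <= 0)
    stop("'mbl' must be a single positive number of Myr")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  if (length(ages) != nn) stop("'ages' must have length Ntip + Nnode")
  E0 <- tree$edge
  if (any(ages[E0[, 1L]] < ages[E0[, 2L]]))
    stop("inconsistent ages: a child is older than its parent")
  E <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(E))) {
    p <- E[i, 1L]; ch <- E[i, 2L]
    ages[p] <- max(ages[p], ages[ch] + mbl)
  }
  tree$edge.length <- ages[E0[, 1L]] - ages[E0[, 2L]]
  tree$node.ages <- ages
  tree$mbl <- mbl
  tree$bl_mode <- "timescaled"
  tree
}

#' Timescale a tree from stratigraphic ranges
#'
#' Convenience wrapper: [assign_node_ages()] then [apply_branch_lengths()].
#'
#' @inheritParams assign_node_ages
#' @inheritParams apply_branch_lengths
#' @return a timescaled `phylo` (see [apply_branch_lengths()]).
#' @export
timescale_tree <- function(tree, ranges, mbl = 1,
                           tip_age_policy = c("FAD", "LAD", "midpoint")) {
  tip_age_policy <- match.arg(tip_age_policy)
  ages <- assign_node_ages(tree, ranges, tip_age_policy)
  apply_branch_lengths(tree, ages, mbl = mbl)
}

#' Set every branch length to one
#'
#' The conventional "without branch length estimates" mode for ancestral
#' state reconstruction: all branches get length exactly 1 and node ages
#' are cleared.
#'
#' @param tree `phylo`.
#' @return the tree with unit `edge.length` and `bl_mode = "unit"`.
#' @export
unit_branch_lengths <- function(tree) {
  validate_tree(tree)
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree$node.ages <- NULL
  tree$mbl <- NULL
  tree$bl_mode <- "unit"
  tree
}
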