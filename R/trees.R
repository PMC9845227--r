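#' @importFrom stats optimize optim runif rexp rpois rbinom rnorm dexp acf var setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

STATES <- 0:2

#' Read a rooted tree from a Newick string or file
#'
#' Parses a single Newick statement into an [ape::phylo] object. The
#' outermost node of the statement is taken as the root (rooted convention
#' throughout the package); polytomies, quoted labels and branch lengths are
#' supported. Input is validated before parsing so that malformed
#' parentheses or quotes are reported with a character offset, and duplicate
#' tip labels are rejected by name.
#'
#' @param text Newick string terminated by ";". Exactly one of `text` and
#'   `file` must be given.
#' @param file path to a file whose first Newick statement is read.
#' @return an object of class `phylo`.
#' @seealso [write_newick()], [graft()]
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'")
  if (!is.null(file)) {
    if (!file.exists(file)) stop("tree file not found: ", file)
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  if (!nzchar(text)) stop("empty Newick input")
  .check_newick_syntax(text)
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop("Newick parse failed")
  if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
  validate_tree(phy)
  phy
}

# balanced-parenthesis / quote scan; reports 1-based character offset
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  quote_open <- 0L
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") {
      in_quote <- !in_quote
      if (in_quote) quote_open <- i
      next
    }
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unmatched ')' at character offset ", i)
    }
  }
  if (in_quote)
    stop("malformed Newick: unclosed quote opened at character offset ",
         quote_open)
  if (depth > 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at character offset ",
         nchar(text))
  if (!endsWith(text, ";"))
    stop("malformed Newick: missing terminal ';' at character offset ",
         nchar(text))
}

#' Validate a phylo object against the package's tree contract
#'
#' Checks rootedness conventions used throughout: unique tip labels and
#' non-negative branch lengths when present. Called internally by all tree
#' consumers; exported for completeness.
#'
#' @param tree a `phylo` object.
#' @return the tree, invisibly.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  invisible(tree)
}

#' Serialize a tree to Newick
#'
#' @param tree a `phylo` object.
#' @param file optional path; when given the string is also written there.
#' @return the Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(tree) || !inherits(tree, "phylo") || length(tree$tip.label) == 0L)
    stop("cannot serialize an empty or invalid tree")
  validate_tree(tree)
  txt <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Graft a source tree onto a backbone at a landmark taxon
#'
#' Implements supertree assembly by landmark grafting: the landmark tip of
#' the backbone is replaced, in place, by the smallest subtree of `source`
#' that contains the landmark together with every source taxon not already
#' present in the backbone. The backbone's topology restricted to its own
#' taxa is preserved exactly. If that smallest source clade also contains
#' other taxa shared with the backbone, their placement conflicts with the
#' backbone's; a topology-conflict warning is issued naming them and they
#' are pruned from the grafted subtree (the composite cladogram is informal,
#' so conflicts are logged rather than fatal).
#'
#' Branch lengths are retained only when both trees carry them; otherwise
#' the result is a topology-only cladogram (lengths are assigned later by
#' timescaling).
#'
#' @param backbone `phylo`; the growing composite cladogram.
#' @param source `phylo`; a published tree sharing the landmark.
#' @param landmark taxon name present as a tip in both trees.
#' @return the grafted `phylo`.
#' @export
graft <- function(backbone, source, landmark) {
  validate_tree(backbone)
  validate_tree(source)
  if (length(landmark) != 1L || !is.character(landmark))
    stop("'landmark' must be a single taxon name")
  if (!landmark %in% backbone$tip.label)
    stop("landmark '", landmark, "' is not a tip of the backbone")
  if (!landmark %in% source$tip.label)
    stop("landmark '", landmark, "' is not a tip of the source tree")
  new_taxa <- setdiff(source$tip.label, backbone$tip.label)
  if (length(new_taxa) == 0L) return(backbone)

  keep <- c(landmark, new_taxa)
  if (length(source$tip.label) > length(keep)) {
    node <- ape::getMRCA(source, keep)
    clade_tips <- ape::extract.clade(source, node)$tip.label
    extra_shared <- setdiff(intersect(clade_tips, backbone$tip.label), landmark)
    if (length(extra_shared))
      warning("topology conflict: shared taxa ",
              paste(extra_shared, collapse = ", "),
              " fall inside the grafted clade of the source tree; ",
              "their backbone placement is kept and they are pruned ",
              "from the grafted subtree")
    sub <- ape::keep.tip(source, keep)
  } else if (length(keep) == length(source$tip.label)) {
    sub <- source
  } else {
    sub <- ape::keep.tip(source, keep)
  }

  if (is.null(backbone$edge.length) || is.null(sub$edge.length)) {
    backbone$edge.length <- NULL
    sub$edge.length <- NULL
  }
  out <- suppressWarnings(
    ape::bind.tree(backbone, sub, where = match(landmark, backbone$tip.label))
  )
  validate_tree(out)
  out
}

#' Most recent common ancestor of a taxon set
#'
#' @param tree `phylo`.
#' @param taxa character vector of tip labels. A single taxon returns the
#'   tip node itself.
#' @return integer node number (ape convention: tips `1..Ntip`, internal
#'   nodes `Ntip+1..`).
#' @export
mrca_node <- function(tree, taxa) {
  validate_tree(tree)
  taxa <- unique(as.character(taxa))
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    stop("unknown taxon/taxa: ", paste(unknown, collapse = ", "))
  if (length(taxa) == 1L) return(match(taxa, tree$tip.label))
  ape::getMRCA(tree, taxa)
}

#' Tips descended from a node
#'
#' @param tree `phylo`.
#' @param node integer node number.
#' @return character vector of tip labels below (and including) `node`.
#' @export
tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

# descendant tip indices for every node, as a list (tips map to themselves)
.descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  out <- vector("list", nn)
  for (i in seq_len(ntip)) out[[i]] <- i
  E <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(E))) {
    p <- E[i, 1L]; ch <- E[i, 2L]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  out
}
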