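#' Read / write Newick trees
#'
#' Thin wrappers around ape's Newick parser that add validation: duplicate
#' leaf labels are rejected and read/write round-trips preserve topology,
#' labels and branch lengths.
#'
#' @param path File path (or for `read_tree_text`, a Newick string).
#' @return An `ape::phylo` tree.
#' @export
read_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file")
  validate_tree(tr)
}

#' @rdname read_tree
#' @param text Newick string.
#' @export
read_tree_text <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  if (is.null(tr)) stop("could not parse Newick string")
  validate_tree(tr)
}

#' @rdname read_tree
#' @param tree An `ape::phylo`.
#' @export
write_tree <- function(tree, path = NULL) {
  if (is.null(path)) ape::write.tree(tree) else ape::write.tree(tree, file = path)
}

validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels in tree")
  if (!is.null(tree$edge.length)) {
    if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
      stop("branch lengths must be finite and non-negative")
    }
  }
  tree
}

# postorder indexing of a rooted tree; children list, parent vector,
# edge length by child node
tree_index <- function(tree) {
  # any phylo has a unique top node; a multifurcating top is treated as the
  # root (harmless under reversible models)
  tree <- stats::reorder(tree, "postorder")
  edge <- tree$edge
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  parent <- rep(NA_integer_, nnode)
  parent[edge[, 2]] <- edge[, 1]
  elen <- rep(NA_real_, nnode)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  elen[edge[, 2]] <- tree$edge.length
  children <- vector("list", nnode)
  for (i in seq_len(nrow(edge))) {
    children[[edge[i, 1]]] <- c(children[[edge[i, 1]]], edge[i, 2])
  }
  root <- edge[nrow(edge), 1]
  # postorder over internal nodes: order of first appearance as parent
  int_post <- unique(edge[, 1])
  # preorder: reverse postorder
  list(tree = tree, edge = edge, ntip = ntip, nnode = nnode, root = root,
       parent = parent, elen = elen, children = children,
       int_postorder = int_post, int_preorder = rev(int_post))
}

node_descendant_tips <- function(idx) {
  desc <- vector("list", idx$nnode)
  for (v in seq_len(idx$ntip)) desc[[v]] <- v
  for (v in idx$int_postorder) {
    desc[[v]] <- sort(unlist(desc[idx$children[[v]]]))
  }
  desc
}

#' Branch identifiers
#'
#' Every branch of a rooted tree is identified by its child clade: terminal
#' branches by the leaf label, internal branches by the sorted descendant
#' leaf labels joined with `"|"`. These ids are stable across Newick
#' round-trips and node renumbering.
#'
#' @param tree Rooted `ape::phylo`.
#' @return Character vector indexed by child node number (NA for the root).
#' @export
branch_ids <- function(tree) {
  idx <- tree_index(tree)
  desc <- node_descendant_tips(idx)
  ids <- rep(NA_character_, idx$nnode)
  for (v in seq_len(idx$nnode)) {
    if (v == idx$root) next
    ids[v] <- paste(sort(idx$tree$tip.label[desc[[v]]]), collapse = "|")
  }
  ids
}

#' Resolve a branch specification to its child node
#'
#' A branch can be given as a leaf label (terminal branch), a character
#' vector of leaf labels (the branch subtending exactly that clade), or an
#' id produced by [branch_ids()].
#'
#' @param tree Rooted `ape::phylo`.
#' @param branch Branch specification.
#' @return Child node number of the branch.
#' @export
match_branch <- function(tree, branch) {
  idx <- tree_index(tree)
  labs <- if (length(branch) == 1 && grepl("|", branch, fixed = TRUE)) {
    strsplit(branch, "|", fixed = TRUE)[[1]]
  } else branch
  missing <- setdiff(labs, idx$tree$tip.label)
  if (length(missing)) stop("unknown taxa in branch spec: ", paste(missing, collapse = ", "))
  want <- sort(match(labs, idx$tree$tip.label))
  desc <- node_descendant_tips(idx)
  for (v in seq_len(idx$nnode)) {
    if (v != idx$root && identical(desc[[v]], want)) return(v)
  }
  stop("no branch subtends exactly the clade {", paste(labs, collapse = ", "), "}")
}

#' Root a tree on an outgroup taxon
#'
#' @param tree `ape::phylo`.
#' @param outgroup Leaf label.
#' @export
root_at <- function(tree, outgroup) {
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  validate_tree(ape::root(tree, outgroup = outgroup, resolve.root = TRUE))
}

#' Set all branch lengths
#'
#' @param tree `ape::phylo`.
#' @param length Length assigned to every branch (default 1).
#' @export
set_branch_lengths <- function(tree, length = 1) {
  tree$edge.length <- rep(length, nrow(tree$edge))
  tree
}

#' Unrooted bipartition set of a tree
#'
#' Each internal edge of the unrooted tree is represented canonically by the
#' side of its split that does not contain the first taxon, as a sorted
#' label string. Used for round-trip and monophyly checks.
#'
#' @param tree `ape::phylo`.
#' @return Character vector of canonical splits.
#' @export
bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  idx <- tree_index(root_at_node(tree))
  desc <- node_descendant_tips(idx)
  out <- character(0)
  all_tips <- seq_len(ntip)
  ref <- match(min(idx$tree$tip.label), idx$tree$tip.label)  # canonical side excludes this leaf
  for (v in seq_len(idx$nnode)) {
    if (v <= ntip || v == idx$root) next
    side <- desc[[v]]
    if (ref %in% side) side <- setdiff(all_tips, side)
    if (length(side) < 2 || length(side) > ntip - 2) next
    out <- c(out, paste(sort(idx$tree$tip.label[side]), collapse = "|"))
  }
  sort(unique(out))
}

# root an unrooted tree arbitrarily (at an internal node) without changing
# the underlying unrooted topology
root_at_node <- function(tree) {
  if (ape::is.rooted(tree)) return(tree)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
}
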