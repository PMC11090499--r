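# Rooted phylogenies: thin validation layer over ape's "phylo" class plus
# the traversal index shared by the parsimony and simulation code.

#' Parse a rooted Newick tree
#'
#' Wraps [ape::read.tree()] with strict validation: one statement terminated
#' by `';'`, balanced parentheses, unique leaf labels, unique (non-empty)
#' internal-node labels. Internal labels are clade names resolvable with
#' [clade_node()].
#'
#' @param text Newick text.
#' @param file Optional file path read instead of `text`.
#' @return An [ape::read.tree()] `"phylo"` object.
#' @examples
#' tr <- parse_newick("((A,B)AB,C)root;")
#' clade_node(tr, "AB")
#' @export
parse_newick <- function(text, file = NULL) {
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  text <- trimws(paste(text, collapse = ""))
  if (!nzchar(text)) stop_format("empty Newick input")
  if (!grepl(";", text, fixed = TRUE))
    stop_format("Newick statement must be terminated by ';'")
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0) || depth[length(depth)] != 0)
    stop_format("unbalanced parentheses in Newick input")
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop_format("malformed Newick input")
  if (anyDuplicated(tr$tip.label))
    stop_format("duplicate leaf label(s): %s",
                paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                      collapse = ", "))
  if (!is.null(tr$node.label)) {
    named <- tr$node.label[nzchar(tr$node.label)]
    if (anyDuplicated(named))
      stop_format("duplicate internal-node label(s): %s",
                  paste(unique(named[duplicated(named)]), collapse = ", "))
  }
  tr
}

#' Write a tree as Newick text
#'
#' @param tree A `"phylo"` tree.
#' @return Newick string terminated by `';'`.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Resolve a named clade to its ancestral node
#'
#' @param tree A `"phylo"` tree.
#' @param clade Either an internal-node label, or a character vector of two
#'   or more leaf labels whose most recent common ancestor is taken.
#' @return Internal node number.
#' @export
clade_node <- function(tree, clade) {
  ntip <- length(tree$tip.label)
  if (length(clade) == 1L && !is.null(tree$node.label) &&
      clade %in% tree$node.label) {
    return(ntip + match(clade, tree$node.label))
  }
  missing <- setdiff(clade, tree$tip.label)
  if (length(missing))
    stop_arg("cannot resolve clade: %s",
             paste(missing, collapse = ", "))
  if (length(clade) == 1L) return(match(clade, tree$tip.label))
  ape::getMRCA(tree, clade)
}

# Traversal index reused across characters: children lists, parents,
# postorder over internal nodes, and stable branch identifiers.
tree_index <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  nn <- ntip + nnode
  parent <- integer(nn)
  children <- vector("list", nn)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1L]
    ch <- tree$edge[k, 2L]
    parent[ch] <- p
    children[[p]] <- c(children[[p]], ch)
  }
  root <- ntip + 1L
  # iterative postorder of internal nodes
  post <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    post <- c(post, v)
    kids <- children[[v]]
    stack <- c(stack, kids[kids > ntip])
  }
  post <- rev(post)
  ids <- character(nn)
  ids[seq_len(ntip)] <- tree$tip.label
  if (!is.null(tree$node.label) && length(tree$node.label) == nnode) {
    lab <- tree$node.label
  } else {
    lab <- character(nnode)
  }
  for (j in seq_len(nnode)) {
    ids[ntip + j] <- if (nzchar(lab[j])) lab[j] else paste0("node", ntip + j)
  }
  list(ntip = ntip, nnode = nnode, nn = nn, root = root,
       parent = parent, children = children, postorder = post,
       preorder = rev(post), branch_id = ids)
}

#' Stable identifier of the branch above a node
#'
#' Branches are named by their child node: the leaf label for terminal
#' branches, the internal-node label for labelled internal branches, and
#' `node<N>` (ape node number) otherwise.
#'
#' @param tree A `"phylo"` tree.
#' @param node Node number(s).
#' @return Character vector of branch ids.
#' @export
branch_id <- function(tree, node) {
  tree_index(tree)$branch_id[node]
}
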