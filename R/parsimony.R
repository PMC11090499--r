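# Unordered (Fitch) parsimony on a fixed rooted tree, via the unit-cost
# Sankoff dynamic program. The down-pass gives the tree length, the up-pass
# the MPR sets (states attainable at a node in at least one most-
# parsimonious reconstruction); ACCTRAN/DELTRAN are deterministic
# backtrackings through the same tables. Multifurcations are hard
# polytomies and are handled exactly by the DP.
#
# Leaf input is a state SET per taxon: a singleton for an observed state,
# several states for polymorphism (cheapest-member convention), NA for a
# wildcard ('?' or '-'). The state universe of a character is the set of
# states observed in it; wildcards expand to that universe.

# normalize per-leaf state sets into a cost matrix over the state universe
leaf_cost_matrix <- function(tree, state_sets) {
  tips <- tree$tip.label
  if (is.null(names(state_sets)))
    names(state_sets) <- tips[seq_along(state_sets)]
  extra <- setdiff(names(state_sets), tips)
  if (length(extra))
    stop_arg("state sets given for taxa not in the tree: %s",
             paste(extra, collapse = ", "))
  miss <- setdiff(tips, names(state_sets))
  if (length(miss))
    stop_arg("no state set for leaf taxa: %s", paste(miss, collapse = ", "))
  sets <- lapply(state_sets[tips], function(s) {
    if (is.null(s) || all(is.na(s))) NA_integer_ else as.integer(s)
  })
  universe <- sort(unique(unlist(sets[!is.na(sets)])))
  if (!length(universe))
    return(NULL)  # character with zero observed states
  k <- length(universe)
  cost <- matrix(Inf, k, length(tips))
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    if (all(is.na(s))) cost[, i] <- 0
    else cost[match(s, universe), i] <- 0
  }
  list(cost = cost, universe = universe)
}

# Sankoff down- and up-pass; returns all tables needed downstream
sankoff_tables <- function(idx, leaf) {
  k <- length(leaf$universe)
  nn <- idx$nn
  S <- matrix(0, k, nn)
  S[, seq_len(idx$ntip)] <- leaf$cost
  contrib <- matrix(0, k, nn)
  for (v in idx$postorder) {
    acc <- numeric(k)
    for (ch in idx$children[[v]]) {
      contrib[, ch] <- pmin(S[, ch], min(S[, ch]) + 1)
      acc <- acc + contrib[, ch]
    }
    S[, v] <- acc
  }
  L <- min(S[, idx$root])
  # up-pass: A[s, v] = min changes in the rest of the tree given state s at v
  A <- matrix(0, k, nn)
  for (v in idx$preorder) {
    D <- A[, v] + S[, v]
    for (ch in idx$children[[v]]) {
      E <- D - contrib[, ch]
      A[, ch] <- pmin(E, min(E) + 1)
    }
  }
  list(S = S, A = A, L = L, k = k, universe = leaf$universe)
}

#' Fitch (unordered-parsimony) length of a character on a tree
#'
#' Minimum number of state changes over all ancestral-state assignments,
#' for an unordered multistate character on a rooted, possibly
#' multifurcating tree.
#'
#' @param tree A `"phylo"` tree.
#' @param states Per-leaf state sets: a list named by tip label whose
#'   elements are integer vectors (singleton = observed state, several =
#'   polymorphism) or `NA` for a wildcard (`'?'`/`'-'`).
#' @return Non-negative integer length, or `NA` (with a warning) for a
#'   character with no observed state.
#' @examples
#' tr <- parse_newick("((A,B),C);")
#' fitch_length(tr, list(A = 0, B = 1, C = 0))
#' @export
fitch_length <- function(tree, states) {
  leaf <- leaf_cost_matrix(tree, states)
  if (is.null(leaf)) {
    warning("character has no observed state; skipped")
    return(NA_integer_)
  }
  idx <- tree_index(tree)
  k <- length(leaf$universe)
  S <- matrix(0, k, idx$nn)
  S[, seq_len(idx$ntip)] <- leaf$cost
  for (v in idx$postorder) {
    acc <- numeric(k)
    for (ch in idx$children[[v]]) acc <- acc + pmin(S[, ch], min(S[, ch]) + 1)
    S[, v] <- acc
  }
  as.integer(min(S[, idx$root]))
}

#' Most-parsimonious-reconstruction (MPR) state sets
#'
#' For every node, the set of states it takes in at least one
#' most-parsimonious full assignment.
#'
#' @inheritParams fitch_length
#' @return Named list (one element per node, leaves first, names from
#'   [branch_id()]) of integer state vectors, with attributes `length`
#'   (the Fitch length) and `universe`.
#' @export
mpr_sets <- function(tree, states) {
  leaf <- leaf_cost_matrix(tree, states)
  if (is.null(leaf)) {
    warning("character has no observed state; skipped")
    return(NULL)
  }
  idx <- tree_index(tree)
  tb <- sankoff_tables(idx, leaf)
  sets <- lapply(seq_len(idx$nn), function(v) {
    tb$universe[tb$S[, v] + tb$A[, v] == tb$L]
  })
  names(sets) <- idx$branch_id
  attr(sets, "length") <- as.integer(tb$L)
  attr(sets, "universe") <- tb$universe
  sets
}

# backtrack one full assignment through the DP tables
backtrack_assignment <- function(idx, tb, mode) {
  k <- tb$k
  assign <- integer(idx$nn)       # indices into universe
  root_cand <- which(tb$S[, idx$root] == tb$L)
  assign[idx$root] <- min(root_cand)
  for (v in idx$preorder) {
    p <- assign[v]
    for (ch in idx$children[[v]]) {
      f <- tb$S[, ch] + as.numeric(seq_len(k) != p)
      cand <- which(f == min(f))
      if (mode == "acctran") {
        off <- setdiff(cand, p)
        assign[ch] <- if (length(off)) min(off) else p
      } else {
        assign[ch] <- if (p %in% cand) p else min(cand)
      }
    }
  }
  tb$universe[assign]
}

#' Resolve a character's ancestral states (ACCTRAN or DELTRAN)
#'
#' Produces one full most-parsimonious assignment. ACCTRAN accelerates
#' transformations (changes placed as close to the root as possible),
#' DELTRAN delays them toward the tips. Remaining ties are broken
#' deterministically in favour of the smallest state symbol, so output is
#' reproducible; scientific ambiguity is carried by the MPR sets, not by
#' the tie-break.
#'
#' @inheritParams fitch_length
#' @param mode `"acctran"` or `"deltran"`.
#' @return An object of class `reconstruction`: list with `mode`,
#'   `length`, `assignment` (named integer vector over all nodes),
#'   `mpr` (the MPR sets), and `changes`, a data frame with one row per
#'   branch carrying a state change (`branch`, `node`, `from`, `to`,
#'   `ambiguous`). A change is flagged unambiguous only when parent and
#'   child MPR sets are both singletons, i.e. when every
#'   most-parsimonious assignment places that change on that branch.
#' @export
resolve <- function(tree, states, mode = c("acctran", "deltran")) {
  mode <- match.arg(mode)
  leaf <- leaf_cost_matrix(tree, states)
  if (is.null(leaf)) {
    warning("character has no observed state; skipped")
    return(NULL)
  }
  idx <- tree_index(tree)
  tb <- sankoff_tables(idx, leaf)
  assign <- backtrack_assignment(idx, tb, mode)
  names(assign) <- idx$branch_id
  mpr <- lapply(seq_len(idx$nn), function(v) {
    tb$universe[tb$S[, v] + tb$A[, v] == tb$L]
  })
  names(mpr) <- idx$branch_id
  ch_nodes <- setdiff(seq_len(idx$nn), idx$root)
  ch_nodes <- ch_nodes[assign[ch_nodes] != assign[idx$parent[ch_nodes]]]
  changes <- data.frame(
    branch = idx$branch_id[ch_nodes],
    node = ch_nodes,
    from = unname(assign[idx$parent[ch_nodes]]),
    to = unname(assign[ch_nodes]),
    ambiguous = vapply(ch_nodes, function(v) {
      !(length(mpr[[idx$parent[v]]]) == 1L && length(mpr[[v]]) == 1L)
    }, logical(1)),
    stringsAsFactors = FALSE)
  structure(list(mode = mode, length = as.integer(tb$L),
                 assignment = assign, mpr = mpr, changes = changes),
            class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf("Parsimony reconstruction (%s): length %d, %d change(s)\n",
              x$mode, x$length, nrow(x$changes)))
  if (nrow(x$changes)) print(x$changes)
  invisible(x)
}

# Optimal (parent, child) state pairs on the branch above node v: the
# combinations realized on that branch by at least one most-parsimonious
# assignment. cost(a, b) = [rest of tree | parent = a] + [a != b] +
# [subtree of v | v = b]. Exactly one optimal pair <=> parent and child
# MPR sets are both singletons.
optimal_branch_pairs <- function(idx, tb, v) {
  p <- idx$parent[v]
  contrib_v <- pmin(tb$S[, v], min(tb$S[, v]) + 1)
  rest <- tb$A[, p] + tb$S[, p] - contrib_v
  k <- tb$k
  cost <- outer(rest, tb$S[, v], "+") + (1 - diag(k))
  hit <- which(cost == tb$L, arr.ind = TRUE)
  data.frame(from = tb$universe[hit[, 1L]], to = tb$universe[hit[, 2L]])
}

# state sets of one character column of a character_matrix, keyed by taxon
matrix_column_states <- function(cm, j) {
  sets <- lapply(cm$taxa, function(tx) {
    s <- cell_states(cm, tx, j)
    if (all(is.na(s))) NA_integer_ else s
  })
  names(sets) <- cm$taxa
  sets
}

#' Reconstruct every character of a matrix on a tree
#'
#' @param tree A `"phylo"` tree whose tips are a subset of the matrix taxa.
#' @param cm A [character_matrix()].
#' @return List of class `reconstruction_set`: per character, the
#'   `"reconstruction"` objects for both modes plus MPR sets; characters
#'   with no observed state are skipped with a warning and carried as
#'   `NULL`.
#' @export
reconstruct_matrix <- function(tree, cm) {
  missing <- setdiff(tree$tip.label, cm$taxa)
  if (length(missing))
    stop_arg("tree taxa absent from matrix: %s", paste(missing, collapse = ", "))
  out <- lapply(seq_len(ncol(cm$cells)), function(j) {
    states <- matrix_column_states(cm, j)[tree$tip.label]
    if (is.null(leaf_cost_matrix(tree, states))) {
      warning(sprintf("character %d has no observed state; skipped", j))
      return(NULL)
    }
    list(character = j,
         acctran = resolve(tree, states, "acctran"),
         deltran = resolve(tree, states, "deltran"))
  })
  structure(out, class = "reconstruction_set")
}

#' Identify clade synapomorphies
#'
#' A synapomorphy is operationalized as a state change on the stem branch
#' of a named clade: the branch from the clade ancestor's parent down to
#' the clade ancestor. A record is emitted whenever at least one
#' most-parsimonious reconstruction places a change there. It is
#' `"unambiguous"` when every such reconstruction assigns the same
#' parent and child states (equivalently, both MPR sets are singletons);
#' otherwise the record carries the smallest optimal transition and
#' `ambiguity = "ambiguous"`. Reversals within the clade do not remove
#' the record; they appear in the per-character change tables of
#' [reconstruct_matrix()].
#'
#' @param tree A `"phylo"` tree.
#' @param cm A [character_matrix()].
#' @param clades Named list; each element is an internal-node label or a
#'   character vector of leaf labels (the clade is their MRCA).
#' @return Data frame with columns `clade`, `character`, `from`, `to`,
#'   `ambiguity` (`"unambiguous"`/`"ambiguous"`).
#' @export
identify_synapomorphies <- function(tree, cm, clades) {
  if (is.null(names(clades)) || any(!nzchar(names(clades))))
    stop_arg("clades must be a named list")
  missing <- setdiff(tree$tip.label, cm$taxa)
  if (length(missing))
    stop_arg("tree taxa absent from matrix: %s", paste(missing, collapse = ", "))
  idx <- tree_index(tree)
  nodes <- vapply(clades, function(cl) clade_node(tree, cl), 0L)
  rows <- list()
  for (j in seq_len(ncol(cm$cells))) {
    states <- matrix_column_states(cm, j)[tree$tip.label]
    leaf <- leaf_cost_matrix(tree, states)
    if (is.null(leaf)) {
      warning(sprintf("character %d has no observed state; skipped", j))
      next
    }
    tb <- sankoff_tables(idx, leaf)
    for (ci in seq_along(nodes)) {
      v <- nodes[ci]
      if (v == idx$root) next   # root has no stem branch
      bp <- optimal_branch_pairs(idx, tb, v)
      chg <- bp[bp$from != bp$to, , drop = FALSE]
      if (!nrow(chg)) next
      unamb <- nrow(bp) == 1L
      chg <- chg[order(chg$from, chg$to), , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        clade = names(clades)[ci], character = j,
        from = chg$from[1L], to = chg$to[1L],
        ambiguity = if (unamb) "unambiguous" else "ambiguous",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(clade = character(0), character = integer(0),
                      from = integer(0), to = integer(0),
                      ambiguity = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[!duplicated(out[c("clade", "character", "from", "to")]), , drop = FALSE]
}

#' Count synapomorphy records
#'
#' @param records Data frame from [identify_synapomorphies()].
#' @param scope `"unambiguous"` (default) counts only records present on
#'   their branch in every most-parsimonious assignment; `"all"` includes
#'   ambiguous placements.
#' @return Integer count, deduplicated by (clade, character, transition).
#' @export
count_synapomorphies <- function(records, scope = c("unambiguous", "all")) {
  scope <- match.arg(scope)
  if (!nrow(records)) return(0L)
  rec <- records[!duplicated(records[c("clade", "character", "from", "to")]), ,
                 drop = FALSE]
  if (scope == "unambiguous") rec <- rec[rec$ambiguity == "unambiguous", ,
                                         drop = FALSE]
  nrow(rec)
}
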