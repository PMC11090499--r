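# Synthetic data with full per-branch ground truth: Yule trees, equal-rates
# Mk characters, and ossification timelines evolving by adjacent
# transpositions — so that encoding, ordination, shift mapping and
# parsimony can all be validated against known answers.

# run code under a given seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

#' Simulation specification
#'
#' Parameters for the synthetic-data generator. Defaults mirror the scale
#' of the study system: 10 taxa, the 7-event hyoid registry, 39 ternary
#' characters.
#'
#' @param n_taxa Number of leaves (>= 2).
#' @param birth_rate Yule speciation rate per lineage per unit time.
#' @param n_characters Number of discrete characters.
#' @param k_states States per character (2..10), equal-rates Mk.
#' @param substitution_rate Expected state changes per unit branch length.
#' @param missing_fraction,inapplicable_fraction Per-cell probabilities of
#'   masking a simulated state as `'?'` / `'-'`; their sum must be < 1.
#' @param base_order Root event order: a permutation of the registry codes.
#' @param swap_rate Expected adjacent transpositions of the event order
#'   per unit branch length.
#' @param truncation Optional `list(clade =, n_never =)`: for leaves of
#'   that clade the last `n_never` events of their order are scored
#'   `"never"` (emulating lineages where most elements never ossify).
#' @param forced_swaps Optional data frame (`branch`, `position`) of
#'   deterministic transpositions applied on named branches in addition to
#'   the Poisson process.
#' @param registry An [event_registry()].
#' @param seed Integer seed; every generator call is reproducible
#'   bit-for-bit under a fixed spec.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_taxa = 10L, birth_rate = 1, n_characters = 39L,
                            k_states = 3L, substitution_rate = 0.1,
                            missing_fraction = 0.1,
                            inapplicable_fraction = 0.05,
                            base_order = NULL, swap_rate = 0.05,
                            truncation = NULL, forced_swaps = NULL,
                            registry = default_registry(), seed = 1L) {
  if (n_taxa < 2L) stop_arg("n_taxa must be >= 2")
  if (birth_rate <= 0) stop_arg("birth_rate must be > 0")
  if (k_states < 2L || k_states > 10L) stop_arg("k_states must be in 2..10")
  if (substitution_rate < 0 || swap_rate < 0)
    stop_arg("rates must be non-negative")
  if (missing_fraction < 0 || inapplicable_fraction < 0 ||
      missing_fraction + inapplicable_fraction >= 1)
    stop_arg("masking fractions must be >= 0 and sum to < 1")
  if (is.null(base_order)) base_order <- registry$codes
  if (!setequal(base_order, registry$codes) ||
      length(base_order) != length(registry$codes))
    stop_arg("base_order must be a permutation of the registry codes")
  structure(list(n_taxa = as.integer(n_taxa), birth_rate = birth_rate,
                 n_characters = as.integer(n_characters),
                 k_states = as.integer(k_states),
                 substitution_rate = substitution_rate,
                 missing_fraction = missing_fraction,
                 inapplicable_fraction = inapplicable_fraction,
                 base_order = as.character(base_order),
                 swap_rate = swap_rate, truncation = truncation,
                 forced_swaps = forced_swaps, registry = registry,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a Yule (pure-birth) tree
#'
#' Forward simulation: the root splits into two lineages; while `k`
#' lineages are alive the waiting time to the next split is exponential
#' with rate `birth_rate * k` and a uniformly chosen lineage splits. After
#' the `n_taxa`-th lineage appears, tips are extended by one final waiting
#' time. Tips are labelled `t1..tn`, internal nodes `nd<i>`.
#'
#' @param spec A [simulation_spec()].
#' @return A rooted binary `"phylo"` tree with branch lengths.
#' @export
simulate_tree <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    n <- spec$n_taxa
    lambda <- spec$birth_rate
    parent <- c(0L, 1L, 1L)
    elen <- c(0, 0, 0)
    active <- c(2L, 3L)
    while (length(active) < n) {
      k <- length(active)
      dt <- rexp(1L, lambda * k)
      elen[active] <- elen[active] + dt
      i <- active[sample.int(k, 1L)]
      id1 <- length(parent) + 1L
      id2 <- length(parent) + 2L
      parent <- c(parent, i, i)
      elen <- c(elen, 0, 0)
      active <- c(setdiff(active, i), id1, id2)
    }
    dt <- rexp(1L, lambda * n)
    elen[active] <- elen[active] + dt
    # assemble Newick from the parent table
    children <- split(seq_along(parent)[-1L], parent[-1L])
    tipname <- integer(0)
    tip_counter <- 0L
    deparse_node <- function(id) {
      kids <- children[[as.character(id)]]
      if (is.null(kids)) {
        tip_counter <<- tip_counter + 1L
        sprintf("t%d:%.10g", tip_counter, elen[id])
      } else {
        inner <- paste(vapply(kids, deparse_node, ""), collapse = ",")
        if (id == 1L) sprintf("(%s)nd1;", inner)
        else sprintf("(%s)nd%d:%.10g", inner, id, elen[id])
      }
    }
    parse_newick(deparse_node(1L))
  })
}

# traverse edges in preorder applying `fn(parent_state, branch_node)`;
# used by both character and timeline simulators
edge_preorder <- function(idx) {
  ord <- integer(0)
  for (v in idx$preorder) ord <- c(ord, idx$children[[v]])
  ord
}

#' Simulate an Mk character matrix on a tree
#'
#' Each character starts from a uniform root state; along every branch,
#' changes arise as a Poisson process with rate `substitution_rate` per
#' unit branch length, each change jumping uniformly to one of the other
#' `k_states - 1` states. Missing/inapplicable masks are applied
#' independently per cell. Ground truth records every change with its
#' branch.
#'
#' @param tree A `"phylo"` tree with branch lengths (e.g. from
#'   [simulate_tree()]).
#' @param spec A [simulation_spec()].
#' @return List with `matrix` (a [character_matrix()]), `truth` (list with
#'   `changes` data frame — `character`, `branch`, `node`, `from`, `to` —
#'   and `n_changes` per character), and `true_states` (unmasked leaf
#'   state matrix).
#' @export
simulate_characters <- function(tree, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  idx <- tree_index(tree)
  eord <- edge_preorder(idx)
  elen <- numeric(idx$nn)
  elen[tree$edge[, 2L]] <- tree$edge.length
  with_seed(spec$seed + 1L, {
    k <- spec$k_states
    nch <- spec$n_characters
    states <- matrix(0L, idx$nn, nch)
    rows <- list()
    for (j in seq_len(nch)) {
      states[idx$root, j] <- sample.int(k, 1L) - 1L
      for (v in eord) {
        s <- states[idx$parent[v], j]
        nev <- rpois(1L, spec$substitution_rate * elen[v])
        if (nev > 0) {
          for (e in seq_len(nev)) {
            new <- sample_one(setdiff(0:(k - 1L), s))
            rows[[length(rows) + 1L]] <- data.frame(
              character = j, branch = idx$branch_id[v], node = v,
              from = s, to = new, stringsAsFactors = FALSE)
            s <- new
          }
        }
        states[v, j] <- s
      }
    }
    leaf <- states[seq_len(idx$ntip), , drop = FALSE]
    cells <- matrix(as.character(leaf), nrow = idx$ntip)
    u <- matrix(runif(length(cells)), nrow = nrow(cells))
    cells[u < spec$missing_fraction] <- "?"
    cells[u >= spec$missing_fraction &
            u < spec$missing_fraction + spec$inapplicable_fraction] <- "-"
    cm <- character_matrix(tree$tip.label, cells)
    changes <- if (length(rows)) do.call(rbind, rows) else
      data.frame(character = integer(0), branch = character(0),
                 node = integer(0), from = integer(0), to = integer(0),
                 stringsAsFactors = FALSE)
    n_changes <- vapply(seq_len(nch), function(j)
      sum(changes$character == j), 0L)
    rownames(leaf) <- tree$tip.label
    list(matrix = cm,
         truth = list(changes = changes, n_changes = n_changes),
         true_states = leaf)
  })
}

# sample.int-safe uniform draw from a vector
sample_one <- function(x) x[sample.int(length(x), 1L)]

#' Simulate ossification timelines with heterochronic transpositions
#'
#' The event order evolves along the tree: on each branch, adjacent
#' transpositions arise as a Poisson process with rate `swap_rate` per
#' unit branch length (plus any `forced_swaps`), each swapping a uniformly
#' chosen adjacent position of the current order. Leaf timelines report
#' onsets equal to the order's ranks. With `truncation`, leaves of the
#' chosen clade score the last `n_never` events of their order as
#' `"never"`. Ground truth records every transposition with its branch and
#' the affected event pair.
#'
#' @inheritParams simulate_characters
#' @return List with `timelines` (list of [timeline()]) and `truth`
#'   (data frame `branch`, `node`, `event_a`, `event_b`, `pair` — the
#'   canonical pair id).
#' @export
simulate_timelines <- function(tree, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  idx <- tree_index(tree)
  eord <- edge_preorder(idx)
  elen <- numeric(idx$nn)
  elen[tree$edge[, 2L]] <- tree$edge.length
  reg <- spec$registry
  nev <- length(reg$codes)
  canonical_id <- function(a, b) {
    ia <- match(a, reg$codes); ib <- match(b, reg$codes)
    if (ia < ib) paste(a, b, sep = ":") else paste(b, a, sep = ":")
  }
  with_seed(spec$seed + 2L, {
    orders <- vector("list", idx$nn)
    orders[[idx$root]] <- spec$base_order
    rows <- list()
    for (v in eord) {
      ord <- orders[[idx$parent[v]]]
      nsw <- rpois(1L, spec$swap_rate * elen[v])
      if (!is.null(spec$forced_swaps)) {
        fs <- spec$forced_swaps
        forced <- fs$position[fs$branch == idx$branch_id[v]]
      } else forced <- integer(0)
      pos <- c(if (nsw > 0) sample.int(nev - 1L, nsw, replace = TRUE),
               forced)
      for (p in pos) {
        a <- ord[p]; b <- ord[p + 1L]
        ord[c(p, p + 1L)] <- c(b, a)
        rows[[length(rows) + 1L]] <- data.frame(
          branch = idx$branch_id[v], node = v, event_a = a, event_b = b,
          pair = canonical_id(a, b), stringsAsFactors = FALSE)
      }
      orders[[v]] <- ord
    }
    trunc_leaves <- character(0)
    if (!is.null(spec$truncation)) {
      cn <- clade_node(tree, spec$truncation$clade)
      desc <- if (cn <= idx$ntip) cn else {
        keep <- integer(0); stack <- cn
        while (length(stack)) {
          v <- stack[length(stack)]; stack <- stack[-length(stack)]
          if (v <= idx$ntip) keep <- c(keep, v)
          else stack <- c(stack, idx$children[[v]])
        }
        keep
      }
      trunc_leaves <- tree$tip.label[desc]
    }
    timelines <- lapply(seq_len(idx$ntip), function(i) {
      ord <- orders[[i]]
      onsets <- as.list(setNames(seq_len(nev), ord))
      if (tree$tip.label[i] %in% trunc_leaves) {
        kcut <- spec$truncation$n_never
        for (e in ord[seq.int(nev - kcut + 1L, nev)]) onsets[[e]] <- "never"
      }
      timeline(tree$tip.label[i], onsets, reg)
    })
    truth <- if (length(rows)) do.call(rbind, rows) else
      data.frame(branch = character(0), node = integer(0),
                 event_a = character(0), event_b = character(0),
                 pair = character(0), stringsAsFactors = FALSE)
    list(timelines = timelines, truth = truth)
  })
}
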