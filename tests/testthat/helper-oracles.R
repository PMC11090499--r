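# Independent oracles and random-instance generators for property tests.
# The parsimony oracle enumerates ancestral assignments exhaustively and
# shares no code with the package's dynamic program; the PCA oracle is a
# direct covariance eigendecomposition.

# --- exhaustive parsimony oracle ---------------------------------------
# states: list named by tip label; integer vectors or NA for wildcards.
# Returns minimum length and per-node MPR sets over the universe of
# observed states (the package's state-universe convention).
oracle_parsimony <- function(tree, states) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  universe <- sort(unique(unlist(states[!vapply(states, function(s)
    all(is.na(s)), TRUE)])))
  k <- length(universe)
  internal <- seq.int(ntip + 1L, ntip + nnode)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nnode)))
  cost <- numeric(nrow(grid))
  leaf_parent <- integer(ntip)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]
    ch <- tree$edge[e, 2L]
    pcol <- match(p, internal)
    if (ch > ntip) {
      cost <- cost + (grid[, pcol] != grid[, match(ch, internal)])
    } else {
      leaf_parent[ch] <- pcol
      s <- states[[tree$tip.label[ch]]]
      if (all(is.na(s))) next              # wildcard leaf: free
      sidx <- match(s, universe)
      cost <- cost + !(grid[, pcol] %in% sidx)
    }
  }
  L <- min(cost)
  opt <- grid[cost == L, , drop = FALSE]
  mpr <- vector("list", ntip + nnode)
  for (j in seq_len(nnode))
    mpr[[internal[j]]] <- sort(universe[unique(opt[, j])])
  for (l in seq_len(ntip)) {
    s <- states[[tree$tip.label[l]]]
    sidx <- if (all(is.na(s))) seq_len(k) else match(s, universe)
    got <- integer(0)
    for (p in unique(opt[, leaf_parent[l]])) {
      got <- union(got, if (p %in% sidx) p else sidx)
    }
    mpr[[l]] <- sort(universe[got])
  }
  list(length = L, mpr = mpr, universe = universe,
       assignments = opt, internal = internal)
}

# --- random instances --------------------------------------------------
# random rooted topology over given labels, with multifurcations
random_topology <- function(labels) {
  build <- function(lab) {
    n <- length(lab)
    if (n == 1L) return(lab)
    ng <- sample(2:min(4L, n), 1L)
    grp <- sample(rep_len(seq_len(ng), n))
    parts <- split(sample(lab), grp)
    paste0("(", paste(vapply(parts, build, ""), collapse = ","), ")")
  }
  parse_newick(paste0(build(labels), ";"))
}

# random leaf state sets: wildcards, polymorphisms, singletons
random_states <- function(labels, k_states) {
  sets <- lapply(labels, function(l) {
    u <- runif(1)
    if (u < 0.15) NA_integer_
    else if (u < 0.30 && k_states >= 2L)
      sort(sample(0:(k_states - 1L), 2L))
    else sample(0:(k_states - 1L), 1L)
  })
  names(sets) <- labels
  # guarantee at least one observed state
  if (all(vapply(sets, function(s) all(is.na(s)), TRUE)))
    sets[[1L]] <- sample(0:(k_states - 1L), 1L)
  sets
}

# random strict-order timeline over the registry
random_timeline <- function(name, registry, p_never = 0, p_unknown = 0) {
  n <- length(registry$codes)
  onsets <- as.list(setNames(sample(n), registry$codes))
  for (e in registry$codes) {
    u <- runif(1)
    if (u < p_never) onsets[[e]] <- "never"
    else if (u < p_never + p_unknown) onsets[[e]] <- "unknown"
  }
  timeline(name, onsets, registry)
}

# state-set list for one column of a character matrix, keyed by taxon
matrix_states_for_test <- function(cm, j, taxa) {
  sets <- lapply(taxa, function(tx) {
    s <- cell_states(cm, tx, j)
    if (all(is.na(s))) NA_integer_ else s
  })
  names(sets) <- taxa
  sets
}

# --- PCA oracle --------------------------------------------------------
oracle_pca <- function(x) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  eg <- eigen(stats::cov(x), symmetric = TRUE)
  list(values = eg$values, scores = xc %*% eg$vectors, vectors = eg$vectors)
}

# the Pelodiscus sinensis incubation-day chronology used across tests
psin_timeline <- function(registry = default_registry()) {
  timeline("Pelodiscus_sinensis",
           c(CBI = 29, CBII = 37, CHp = 41, CHa = 44, CHi = 44.5,
             EPI = "never", PL = "never"), registry)
}
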