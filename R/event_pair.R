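# Event-pair encoding of developmental sequences and heterochronic-shift
# detection. Each ordered pair of registry events becomes one discrete
# character: 0 = first event before second, 1 = simultaneous, 2 = after.

#' Canonical event-pair list
#'
#' All unordered pairs of registry events, ordered lexicographically by
#' registry position; this fixes the column order of every event-pair
#' matrix.
#'
#' @param registry An [event_registry()] with at least two events.
#' @return Data frame with columns `first`, `second` (event codes) and
#'   `id` (`"first:second"`); `n(n-1)/2` rows.
#' @examples
#' canonical_pairs(event_registry(c("a", "b", "c")))
#' @export
canonical_pairs <- function(registry) {
  stopifnot(inherits(registry, "event_registry"))
  n <- length(registry$codes)
  if (n < 2L) stop_arg("need at least two events to form pairs")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  first <- registry$codes[idx[, "row"]]
  second <- registry$codes[idx[, "col"]]
  data.frame(first = first, second = second,
             id = paste(first, second, sep = ":"),
             stringsAsFactors = FALSE)
}

# effective comparison value per event: observed onset, never -> +Inf
# (policy "last") or NA (policy "missing"), unknown -> NA
effective_onsets <- function(t, registry, never_policy, digits = NULL) {
  v <- t$onset[registry$codes]
  st <- t$status[registry$codes]
  if (!is.null(digits)) v <- round(v, digits)
  v[st == "never"] <- if (never_policy == "last") Inf else NA_real_
  v[st == "unknown"] <- NA_real_
  v
}

#' Encode one timeline as an event-pair state vector
#'
#' @param t An [timeline()] object.
#' @param registry An [event_registry()].
#' @param never_policy `"last"`: never-ossifying events rank after every
#'   observed onset and two of them are simultaneous; `"missing"`: pairs
#'   involving them are scored missing.
#' @param digits Optional rounding precision applied to onsets before
#'   comparison (simultaneity is exact equality after rounding).
#' @return Named integer vector over [canonical_pairs()] ids with values
#'   0 (first before second), 1 (simultaneous), 2 (first after second) or
#'   `NA` (missing).
#' @examples
#' reg <- default_registry()
#' t <- timeline("Psin", c(CBI = 29, CBII = 37, CHp = 41, CHa = 44,
#'                         CHi = 44.5, EPI = "never", PL = "never"), reg)
#' encode_timeline(t, reg)
#' @export
encode_timeline <- function(t, registry, never_policy = c("last", "missing"),
                            digits = NULL) {
  never_policy <- match.arg(never_policy)
  stopifnot(inherits(t, "ossification_timeline"))
  pairs <- canonical_pairs(registry)
  v <- effective_onsets(t, registry, never_policy, digits)
  vi <- v[pairs$first]
  vj <- v[pairs$second]
  state <- ifelse(is.na(vi) | is.na(vj), NA_integer_,
                  ifelse(vi < vj, 0L, ifelse(vi == vj, 1L, 2L)))
  setNames(as.integer(state), pairs$id)
}

#' Build an event-pair matrix from timelines
#'
#' @param timelines List of [timeline()] objects with unique taxa.
#' @inheritParams encode_timeline
#' @return Object of class `event_pair_matrix`: list with `taxa`, `pairs`
#'   (the [canonical_pairs()] table), `states` (taxa x pairs integer matrix
#'   with `NA` for missing) and `never_policy`.
#' @export
build_event_pair_matrix <- function(timelines, registry,
                                    never_policy = c("last", "missing"),
                                    digits = NULL) {
  never_policy <- match.arg(never_policy)
  taxa <- vapply(timelines, function(t) t$taxon, "")
  if (anyDuplicated(taxa))
    stop_arg("duplicate taxa: %s",
             paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  pairs <- canonical_pairs(registry)
  states <- t(vapply(timelines, encode_timeline, integer(nrow(pairs)),
                     registry = registry, never_policy = never_policy,
                     digits = digits))
  dimnames(states) <- list(taxa, pairs$id)
  structure(list(taxa = taxa, pairs = pairs, states = states,
                 never_policy = never_policy),
            class = "event_pair_matrix")
}

#' @export
print.event_pair_matrix <- function(x, ...) {
  cat(sprintf("Event-pair matrix: %d taxa x %d pairs (never_policy = %s)\n",
              length(x$taxa), nrow(x$pairs), x$never_policy))
  print(x$states)
  invisible(x)
}

#' Write an event-pair matrix as CSV text
#'
#' Taxon rows, pair-id columns; missing cells empty.
#'
#' @param epm An [build_event_pair_matrix()] result.
#' @return CSV text.
#' @export
write_epm_csv <- function(epm) {
  df <- data.frame(taxon = epm$taxa, epm$states, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- textConnection("out", "w", local = TRUE)
  write.csv(df, con, row.names = FALSE, na = "")
  close(con)
  paste(c(out, ""), collapse = "\n")
}

#' Convert an event-pair matrix to a character matrix
#'
#' States 0/1/2 become character states and missing cells `'?'`, so the
#' pair characters can be exported (e.g. as NEXUS) for external parsimony
#' programs or fed to [reconstruct_matrix()].
#'
#' @param epm An event-pair matrix.
#' @return A [character_matrix()] with one character per event pair.
#' @export
epm_as_character_matrix <- function(epm) {
  cells <- matrix(as.character(epm$states), nrow = length(epm$taxa))
  cells[is.na(cells)] <- "?"
  character_matrix(epm$taxa, cells, descriptions = epm$pairs$id,
                   symbols = c("0", "1", "2"))
}

#' Heterochronic shifts between two event-pair vectors
#'
#' @param a,b Equal-length state vectors with identical pair ordering
#'   (as returned by [encode_timeline()]).
#' @return Data frame of shift records (`pair`, `from`, `to`), one row per
#'   pair scored in both vectors with unequal states; missing-vs-anything
#'   is not a shift.
#' @export
diff_event_pairs <- function(a, b) {
  if (length(a) != length(b))
    stop_arg("state vectors differ in length (%d vs %d)", length(a), length(b))
  if (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b)))
    stop_arg("state vectors have different pair orderings")
  hit <- which(!is.na(a) & !is.na(b) & a != b)
  ids <- if (!is.null(names(a))) names(a)[hit] else as.character(hit)
  data.frame(pair = ids, from = as.integer(a[hit]), to = as.integer(b[hit]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Map heterochronic shifts onto tree branches
#'
#' Each event-pair column is optimized on the tree as an unordered
#' character (missing cells as wildcards). A branch shift is reported as
#' unambiguous when the state change lies on that branch in every
#' most-parsimonious reconstruction (equivalently, parent and child MPR
#' sets are both singletons and differ). Branches where only some
#' most-parsimonious reconstructions place a change are listed separately
#' as ambiguous, with the smallest optimal transition reported.
#'
#' @param tree A `"phylo"` tree whose tips are a subset of the matrix taxa.
#' @param epm An [build_event_pair_matrix()] result.
#' @return Object of class `branch_shifts`: list with data frames `shifts`
#'   and `ambiguous`, each with columns `branch`, `node`, `pair`, `from`,
#'   `to`.
#' @export
branch_shifts <- function(tree, epm) {
  missing <- setdiff(tree$tip.label, epm$taxa)
  if (length(missing))
    stop_arg("tree taxa absent from event-pair matrix: %s",
             paste(missing, collapse = ", "))
  idx <- tree_index(tree)
  states <- epm$states[tree$tip.label, , drop = FALSE]
  ntip <- idx$ntip
  shift_rows <- list()
  amb_rows <- list()
  nonroot <- setdiff(seq_len(idx$nn), idx$root)
  for (col in seq_len(ncol(states))) {
    st <- states[, col]
    universe <- sort(unique(st[!is.na(st)]))
    if (length(universe) < 2L) next  # constant or unscored: no changes
    k <- length(universe)
    cost <- matrix(Inf, k, ntip)
    cost[, is.na(st)] <- 0
    obs <- which(!is.na(st))
    cost[cbind(match(st[obs], universe), obs)] <- 0
    tb <- sankoff_tables(idx, list(cost = cost, universe = universe))
    pid <- epm$pairs$id[col]
    for (v in nonroot) {
      bp <- optimal_branch_pairs(idx, tb, v)
      chg <- bp[bp$from != bp$to, , drop = FALSE]
      if (!nrow(chg)) next
      chg <- chg[order(chg$from, chg$to), , drop = FALSE]
      row <- data.frame(branch = idx$branch_id[v], node = v, pair = pid,
                        from = chg$from[1L], to = chg$to[1L],
                        stringsAsFactors = FALSE)
      if (nrow(bp) == 1L) shift_rows[[length(shift_rows) + 1L]] <- row
      else amb_rows[[length(amb_rows) + 1L]] <- row
    }
  }
  empty <- data.frame(branch = character(0), node = integer(0),
                      pair = character(0), from = integer(0), to = integer(0),
                      stringsAsFactors = FALSE)
  structure(list(
    shifts = if (length(shift_rows)) do.call(rbind, shift_rows) else empty,
    ambiguous = if (length(amb_rows)) do.call(rbind, amb_rows) else empty),
    class = "branch_shifts")
}

#' @export
print.branch_shifts <- function(x, ...) {
  cat(sprintf("Branch shifts: %d unambiguous, %d ambiguous placement(s)\n",
              nrow(x$shifts), nrow(x$ambiguous)))
  if (nrow(x$shifts)) print(x$shifts)
  invisible(x)
}
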