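# Event-pair encoding and heterochronic-shift detection.

reg <- default_registry()

test_that("canonical pairs follow registry order", {
  p <- canonical_pairs(reg)
  expect_equal(nrow(p), 21L)           # 7*6/2
  expect_equal(p$first[1L], "CBI")
  expect_equal(p$second[1L], "CBII")

  p2 <- canonical_pairs(event_registry(c("x", "y")))
  expect_equal(nrow(p2), 1L)

  p3 <- canonical_pairs(event_registry(c("a", "b", "c")))
  expect_equal(p3$id, c("a:b", "a:c", "b:c"))

  expect_error(canonical_pairs(event_registry("solo")),
               class = "hetseq_argument_error")
})

test_that("the P. sinensis chronology encodes to the documented states", {
  v <- encode_timeline(psin_timeline(), reg, "last")
  expect_equal(unname(v["CBI:CBII"]), 0L)   # CBI day 29 before CBII day 37
  expect_equal(unname(v["CHp:CHi"]), 0L)
  expect_equal(unname(v["CHi:CHa"]), 2L)    # anterior center precedes medial
  expect_equal(unname(v["EPI:PL"]), 1L)     # two never events simultaneous
  expect_equal(unname(v["CBI:EPI"]), 0L)
  expect_false(anyNA(v))

  # under never_policy = "missing" the never pairs drop out
  vm <- encode_timeline(psin_timeline(), reg, "missing")
  expect_true(is.na(vm["EPI:PL"]))
  expect_equal(unname(vm["CBI:CBII"]), 0L)
})

test_that("simultaneous onsets give state 1 everywhere", {
  t <- timeline("tie", setNames(as.list(rep(5, 7)), reg$codes), reg)
  expect_true(all(encode_timeline(t, reg) == 1L))
})

test_that("onset reversal maps states by the 0<->2 involution", {
  set.seed(101)
  for (r in 1:25) {
    t <- random_timeline(paste0("t", r), reg)
    rev_t <- timeline(t$taxon, setNames(as.list(-t$onset), reg$codes), reg)
    a <- encode_timeline(t, reg)
    b <- encode_timeline(rev_t, reg)
    expect_identical(unname(b), unname(c(2L, 1L, 0L)[a + 1L]))
  }
})

test_that("a mostly never timeline stays analyzable under policy last", {
  chel <- timeline("Chelonoidis",
                   c(CBI = 1, CBII = "never", CHp = "never", CHi = "never",
                     CHa = "never", EPI = "never", PL = "never"), reg)
  epm <- build_event_pair_matrix(list(chel), reg, "last")
  v <- epm$states[1L, ]
  p <- canonical_pairs(reg)
  cbi_pairs <- p$first == "CBI"
  expect_true(all(v[p$id[cbi_pairs]] == 0L))         # CBI before everything
  expect_true(all(v[p$id[!cbi_pairs]] == 1L))        # never-never ties
})

test_that("the matrix rows equal per-taxon encodings and taxa are unique", {
  set.seed(202)
  tls <- lapply(1:10, function(i) random_timeline(paste0("tax", i), reg,
                                                  p_never = 0.1,
                                                  p_unknown = 0.1))
  epm <- build_event_pair_matrix(tls, reg, "last")
  for (i in seq_along(tls))
    expect_identical(epm$states[i, ],
                     encode_timeline(tls[[i]], reg, "last"))
  expect_error(build_event_pair_matrix(c(tls, tls[1L]), reg),
               class = "hetseq_argument_error")
})

test_that("pairwise shift detection ignores missing and is symmetric", {
  a <- encode_timeline(psin_timeline(), reg)
  expect_equal(nrow(diff_event_pairs(a, a)), 0L)

  # a taxon where the corpus hyoideus starts before cornu branchiale II
  raf <- timeline("Rafetus",
                  c(CBI = 1, CHp = 2, CBII = 3, CHa = 4, CHi = 5,
                    EPI = "never", PL = "never"), reg)
  b <- encode_timeline(raf, reg)
  d <- diff_event_pairs(a, b)
  expect_true("CBII:CHp" %in% d$pair)
  hit <- d[d$pair == "CBII:CHp", ]
  expect_equal(hit$from, 0L)
  expect_equal(hit$to, 2L)

  # symmetry: same pairs with from/to swapped
  d2 <- diff_event_pairs(b, a)
  expect_setequal(d$pair, d2$pair)
  m <- merge(d, d2, by = "pair")
  expect_equal(m$from.x, m$to.y)
  expect_equal(m$to.x, m$from.y)

  # missing-vs-anything is not a shift
  am <- a; am["CBI:CBII"] <- NA
  expect_false("CBI:CBII" %in% diff_event_pairs(am, b)$pair)

  expect_error(diff_event_pairs(a[-1L], b),
               class = "hetseq_argument_error")
})

test_that("one adjacent transposition yields exactly one shift", {
  reg5 <- event_registry(letters[1:5])
  base <- timeline("base", setNames(as.list(1:5), reg5$codes), reg5)
  vb <- encode_timeline(base, reg5)
  for (p in 1:4) {
    ons <- setNames(1:5, reg5$codes)
    ons[c(p, p + 1L)] <- ons[c(p + 1L, p)]
    tw <- timeline("tw", as.list(ons), reg5)
    d <- diff_event_pairs(vb, encode_timeline(tw, reg5))
    expect_equal(nrow(d), 1L)
    expect_equal(d$pair,
                 paste(reg5$codes[p], reg5$codes[p + 1L], sep = ":"))
  }
})

test_that("fully scored encodings induce an acyclic precedence relation", {
  set.seed(303)
  p <- canonical_pairs(reg)
  n <- length(reg$codes)
  for (r in 1:25) {
    v <- encode_timeline(random_timeline(paste0("t", r), reg), reg)
    # digraph: edge first->second for state 0, second->first for state 2
    adj <- matrix(FALSE, n, n, dimnames = list(reg$codes, reg$codes))
    adj[cbind(p$first[v == 0L], p$second[v == 0L])] <- TRUE
    adj[cbind(p$second[v == 2L], p$first[v == 2L])] <- TRUE
    # Kahn topological sort must consume every node
    remaining <- reg$codes
    repeat {
      indeg <- colSums(adj[remaining, remaining, drop = FALSE])
      src <- remaining[indeg == 0L]
      if (!length(src)) break
      remaining <- setdiff(remaining, src)
      if (!length(remaining)) break
    }
    expect_length(remaining, 0L)
  }
})

test_that("branch shifts: identical rows give none; root-adjacent changes are ambiguous", {
  tls <- lapply(paste0("s", 1:4), function(nm)
    timeline(nm, setNames(as.list(1:7), reg$codes), reg))
  epm <- build_event_pair_matrix(tls, reg)
  tr <- parse_newick("((s1,s2),(s3,s4));")
  bs <- branch_shifts(tr, epm)
  expect_equal(nrow(bs$shifts), 0L)
  expect_equal(nrow(bs$ambiguous), 0L)

  # A=B=state0 vs C=D=state2 on one pair: placement depends on the root
  # state, so it must be flagged ambiguous and excluded (brute-force MPR:
  # both stems are optimal under opposite root states)
  ons <- setNames(1:7, reg$codes)
  swapped <- ons; swapped[c("CBI", "CBII")] <- c(2, 1)
  tls2 <- list(timeline("s1", as.list(ons), reg),
               timeline("s2", as.list(ons), reg),
               timeline("s3", as.list(swapped), reg),
               timeline("s4", as.list(swapped), reg))
  epm2 <- build_event_pair_matrix(tls2, reg)
  bs2 <- branch_shifts(tr, epm2)
  expect_false("CBI:CBII" %in% bs2$shifts$pair)
  expect_true("CBI:CBII" %in% bs2$ambiguous$pair)

  expect_error(branch_shifts(parse_newick("((s1,s9),s3);"), epm2),
               class = "hetseq_argument_error")
})

test_that("an injected transposition maps back to its branch", {
  spec0 <- simulation_spec(n_taxa = 12, swap_rate = 0, seed = 99L)
  tr <- simulate_tree(spec0)
  # pick an internal branch away from the root: changes on the root's own
  # child branches are inherently ambiguous (the root state can absorb them)
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  cand <- tr$edge[tr$edge[, 1] != root & tr$edge[, 2] > ntip, 2]
  target <- tr$node.label[cand[1L] - ntip]
  spec <- simulation_spec(n_taxa = 12, swap_rate = 0,
                          forced_swaps = data.frame(branch = target,
                                                    position = 2L),
                          seed = 99L)
  sim <- simulate_timelines(tr, spec)
  expect_equal(nrow(sim$truth), 1L)
  epm <- build_event_pair_matrix(sim$timelines, reg)
  bs <- branch_shifts(tr, epm)
  expect_equal(nrow(bs$shifts), 1L)
  expect_equal(bs$shifts$branch, sim$truth$branch)
  expect_equal(bs$shifts$pair, sim$truth$pair)
})

test_that("unambiguous shifts per pair never exceed the Fitch length", {
  set.seed(404)
  for (r in 1:15) {
    labels <- paste0("x", 1:8)
    tr <- random_topology(labels)
    tls <- lapply(labels, function(nm)
      random_timeline(nm, reg, p_never = 0.1, p_unknown = 0.1))
    epm <- build_event_pair_matrix(tls, reg)
    bs <- branch_shifts(tr, epm)
    cmx <- epm_as_character_matrix(epm)
    for (pid in unique(bs$shifts$pair)) {
      j <- match(pid, epm$pairs$id)
      L <- fitch_length(tr, matrix_states_for_test(cmx, j, tr$tip.label))
      expect_lte(sum(bs$shifts$pair == pid), L)
    }
  }
})
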