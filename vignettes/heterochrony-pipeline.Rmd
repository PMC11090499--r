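---
title: "Analyzing ossification-sequence heterochrony with hetseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing ossification-sequence heterochrony with hetseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetseq)
```

## The problem

Skeletal elements ossify in a characteristic order during development, and
that order itself evolves. Comparing ossification sequences across species
raises two coupled questions: *which* relative timings have shifted between
lineages (heterochronic shifts), and *where* on the phylogeny those shifts
and other discrete character changes occurred. hetseq implements a complete
comparative pipeline for this kind of data, developed around the turtle
hyoid apparatus — seven elements (cornua branchialia I/II, three
ossification centers of the corpus hyoideus, epibranchial I, processus
lingualis) scored across cryptodire and pleurodire species — but generic
over any event registry and character matrix.

The pipeline has four analysis stages plus a simulator:

1. **Event-pair encoding.** A timeline of event onsets (days of incubation,
   or ordinal stages) becomes a vector of discrete characters, one per
   unordered pair of registry events, with states 0 (first event earlier),
   1 (simultaneous), 2 (first event later). For $n$ events there are
   $\binom{n}{2}$ pairs (21 for the 7-element hyoid registry). Encoding is
   a pure function of onset comparisons, so sequences of different absolute
   duration are directly comparable.
2. **Rank ordination.** Onsets are rank-transformed per taxon (average
   ranks for ties) and the taxa × events rank matrix is ordinated by PCA,
   giving per-element loadings alongside taxon scores.
3. **Shift detection.** Event-pair vectors are compared pairwise
   (`diff_event_pairs`) or optimized on a fixed tree as unordered
   characters (`branch_shifts`), mapping state changes to branches.
4. **Ancestral-state reconstruction.** Any multistate character matrix is
   optimized on the tree under unordered (Fitch) parsimony, with full MPR
   sets, ACCTRAN/DELTRAN resolutions, and clade-synapomorphy extraction.

## The parsimony model

Characters are unordered and nonadditive: any state may change into any
other at unit cost, the standard treatment for morphological multistate
characters in parsimony programs. The engine is the unit-cost Sankoff
dynamic program on the rooted tree:

* the **down-pass** computes, for each node $v$ and state $s$, the minimum
  number of changes in the subtree of $v$ given $v = s$; the tree length
  is the minimum over root states;
* the **up-pass** computes the complementary quantity for the rest of the
  tree, so a state belongs to a node's **MPR set** exactly when some
  most-parsimonious full assignment uses it there;
* **ACCTRAN/DELTRAN** are deterministic backtrackings: at each branch, the
  child state is chosen among the cost-minimal options, preferring a
  change on the current branch (ACCTRAN, accelerating transformations
  toward the root) or retention of the parent state (DELTRAN, delaying
  them toward the tips).

Multifurcations are hard polytomies; the dynamic program is exact for
them. Polymorphic cells are treated as "any member of the set" (the
cheapest-member convention), and both `'?'` (missing) and `'-'`
(inapplicable) leaves become full wildcards during optimization, though
the two markers are kept distinct in storage and I/O. The state universe
of a character is the set of states observed in it: under unit costs an
unobserved state can never reduce the number of changes, so the
restriction loses nothing.

**Ambiguity.** A change on a branch is *unambiguous* when every
most-parsimonious reconstruction places that same transition there. This
is decided by enumerating the cost-optimal (parent, child) state pairs on
the branch from the down/up-pass tables; there is exactly one optimal
pair precisely when the parent and child MPR sets are both singletons.
When several optimal pairs exist but all of them could involve a change,
the record is reported with the smallest optimal transition and flagged
ambiguous. ACCTRAN/DELTRAN tie-breaks (smallest state symbol) are purely
for reproducibility; scientific ambiguity is always carried by the MPR
sets, never by a tie-break. This matters in practice: changes on the two
branches incident to the root are often inherently ambiguous (the root
state can absorb them), and the unambiguous/ambiguous split keeps such
cases from being over-interpreted.

**Synapomorphies** are operationalized as state changes on the stem branch
of a named clade. Reversals deeper inside the clade do not remove the
record (losses can re-emerge in subclades); they remain visible in the
per-character change tables.

## Policies and parameters

* `never_policy` (default `"last"`): elements that never ossify in a taxon
  rank after every observed onset, and two such elements are simultaneous.
  This keeps taxa with a single ossified element (the tortoise and
  podocnemidid pattern) analyzable and places them meaningfully in the
  ordination; `"missing"` reproduces the older convention of scoring only
  occurring events and drops such pairs instead.
* Ties (state 1) are data, not missing: day-resolution scoring makes
  simultaneity genuinely observable. Onsets are real-valued so that
  sub-day evidence (e.g. relative staining intensity at the same
  incubation day) can be expressed as fractional onsets; simultaneity is
  exact equality after an optional rounding precision (`digits`,
  default: none).
* `tie_policy = "average_rank"`: within-taxon ranks average over ties, so
  a fully scored taxon's ranks always sum to $n(n+1)/2$.
* Imputation (`column_mean`, default for ordination): missing rank cells
  take their event-column mean and are flagged `imputed`; with `none` the
  PCA refuses incomplete matrices rather than silently dropping taxa.
* PCA operates on the 7 per-element ranks, not the 21 event-pair columns,
  so loadings are interpretable per element; covariance (center-only)
  PCA is the default because ranks share a scale, with correlation PCA as
  an option. Eigenvector signs follow a fixed convention (largest-magnitude
  loading entry positive), making outputs platform-reproducible. Scores
  and eigenvalues agree with a direct covariance eigendecomposition to
  1e-8 (tested), and taxa with identical timelines coincide exactly in
  score space.

## The synthetic-data generator

Because the empirical specimen data cannot ship with the package, every
stage is validated against simulated data with known ground truth:

* **Trees**: pure-birth (Yule) simulation, exponential waiting times at
  rate `birth_rate` × lineages, stopped at `n_taxa` tips and extended by
  one final waiting time; trees are ultrametric by construction.
* **Characters**: equal-rates Mk — uniform root state, Poisson changes at
  `substitution_rate` per unit branch length, uniform jumps among the
  other $k-1$ states, independent per-cell `'?'`/`'-'` masking. Every
  change is recorded with its branch.
* **Timelines**: the event order evolves by adjacent transpositions
  arising as a Poisson process at `swap_rate` per unit branch length —
  the minimal heterochrony process, chosen because shifts are reported as
  single event-pair changes. An optional per-clade truncation marks a
  suffix of the order as never-ossifying, emulating the single-element
  lineages. Leaf onsets are the order's ranks.

Defaults (10 taxa, 39 ternary characters, 7 events) mirror the scale of
the motivating dataset. The generator emulates the *structure* of real
data, not its biology: no rate heterogeneity across characters or
branches, no correlated characters, no directional bias in transpositions.
Passing the recovery tests therefore demonstrates that the detection
machinery is correct and well-calibrated under the stated model, not that
real shifts are always recoverable — in empirical data, shifts near the
root or multiple swaps of the same pair remain ambiguous or canceled, and
the pipeline reports them as such rather than guessing.

At the validation scale used by the test suite (500 replicates of
50-taxon trees with `swap_rate = 0.05`, about 2–3 transpositions per
tree), branch-level recovery of injected transpositions exceeds 90%
sensitivity with a false-branch rate well under 5%; the residual misses
are dominated by the inherent root-adjacent ambiguity discussed above.
The parsimony engine itself is checked against exhaustive enumeration of
all ancestral assignments on 200 random instances (up to 8 leaves, 4
states, wildcards, polymorphisms, multifurcations).

## Numerical and degenerate-input choices

* All orderings are deterministic: registry order fixes pair order; taxa
  keep input order; reports sort keys; every stochastic operation draws
  from an explicit seed, leaving the caller's RNG state untouched.
* A character with no observed state is skipped with a warning rather
  than an error, so bulk matrices with empty columns still optimize.
* Timelines that are entirely unknown encode to all-missing vectors
  rather than failing; zero-variance rank matrices are refused by the
  PCA with a degenerate-input error.
* Readers reject malformed input with located errors (line numbers) and
  never coerce `'-'` to `'?'` silently.

## Known limitations

* Ordered/additive characters, step matrices and implied weighting are
  out of scope; the topology is fixed (no tree search).
* Branch-level shift mapping assumes the event-pair columns evolve
  independently; compensating swaps within one branch cancel and are
  invisible to any sequence-based method.
* The NEXUS reader covers non-interleaved `CHARACTERS`/`DATA` blocks with
  standard symbols, the dialect the pipeline itself writes; it is not a
  general-purpose NEXUS implementation. NEXUS/TNT symbol conventions are
  never auto-detected — the dialect is always explicit.
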