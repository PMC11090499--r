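# hetseq

Comparative analysis of developmental sequence heterochrony on a fixed
phylogeny, built around ossification sequences of the turtle hyoid
apparatus but generic over any set of developmental events and any
discrete morphological character matrix.

The package is aimed at comparative morphologists and evo-devo workers
who have, per species, the order (or absolute timing) in which skeletal
elements begin to ossify, plus a multistate character matrix and a
reference tree — and who want to know which relative timings shifted,
where on the tree they shifted, and which character-state changes
diagnose which clades.

## What it computes

* **Event-pair encoding.** A timeline of event onsets becomes
  $\binom{n}{2}$ discrete characters, one per pair $(i, j)$ of registry
  events, scored $0$ ($i$ before $j$), $1$ (simultaneous), $2$ ($i$
  after $j$), or missing. Elements that never ossify can rank last
  (default) or be scored missing.
* **Heterochronic shifts.** Pairwise comparison of encodings
  (`diff_event_pairs`) or branch mapping (`branch_shifts`), in which each
  pair column is optimized on the tree as an unordered character and a
  shift is assigned to a branch only when every most-parsimonious
  reconstruction places that state change there; ambiguous placements are
  listed separately.
* **Rank ordination.** Per-taxon average ranks of onsets, then covariance
  PCA of the taxa × events rank matrix, with per-element loadings,
  deterministic eigenvector signs, and optional column-mean imputation.
* **Unordered parsimony.** Fitch tree length, MPR state sets, ACCTRAN and
  DELTRAN resolutions, per-branch change tables, and clade-synapomorphy
  extraction (`identify_synapomorphies`, `count_synapomorphies`) for
  multistate matrices with missing (`?`), inapplicable (`-`) and
  polymorphic (`[01]`) cells, on rooted, possibly multifurcating trees.
* **Synthetic data.** Yule trees, equal-rates Mk character matrices and
  timelines evolving by adjacent transpositions, all with per-branch
  ground truth, so every stage can be validated end to end.

I/O: delimited event tables, NEXUS `CHARACTERS`/`DATA` and TNT `xread`
matrices (read and write, cells preserved exactly), Newick trees with
named clades, JSON/CSV reports. A thin CLI with subcommands `encode`,
`ordinate`, `shifts`, `reconstruct`, `simulate` is installed at
`exec/hetseq`.

## Worked example

The *Pelodiscus sinensis* chronology (cornu branchiale I ossifying by
incubation day 29, cornu branchiale II on day 37, the posterior corpus
hyoideus center on day 41, the anterior center just before the
intermediate one around day 44, epibranchial I and processus lingualis
never):

```r
library(hetseq)
reg <- default_registry()   # CBI, CBII, CHp, CHi, CHa, EPI, PL
psin <- timeline("Pelodiscus_sinensis",
                 c(CBI = 29, CBII = 37, CHp = 41, CHa = 44, CHi = 44.5,
                   EPI = "never", PL = "never"), reg)
head(encode_timeline(psin, reg), 8)
#> CBI:CBII  CBI:CHp  CBI:CHi  CBI:CHa  CBI:EPI   CBI:PL CBII:CHp CBII:CHi
#>        0        0        0        0        0        0        0        0
```

Every pair involving CBI is 0 — it precedes everything; `CHi:CHa` is 2
(the anterior center precedes the intermediate one) and `EPI:PL` is 1
(both never ossify, hence simultaneous under the default policy). The
rank transform used for ordination:

```r
rank_events(psin, reg)
#>  CBI CBII  CHp  CHi  CHa  EPI   PL
#>  1.0  2.0  3.0  5.0  4.0  6.5  6.5
```

A taxon in which the corpus hyoideus starts ossifying before cornu
branchiale II shows exactly one heterochronic shift against this
sequence:

```r
raf <- timeline("Rafetus_euphraticus",
                c(CBI = 1, CHp = 2, CBII = 3, CHa = 4, CHi = 5,
                  EPI = "never", PL = "never"), reg)
diff_event_pairs(encode_timeline(psin, reg), encode_timeline(raf, reg))
#>       pair from to
#> 1 CBII:CHp    0  2
```

Synapomorphy extraction on a toy five-taxon matrix for one character
(epibranchial II: 0 absent, 1 cartilage, 2 bone), where absence is
derived for the (Ge, Te) clade:

```r
tr <- parse_newick("((Tr1,Tr2),(Out,(Ge,Te)));")
cm <- character_matrix(c("Tr1", "Tr2", "Out", "Ge", "Te"),
                       matrix(c("2", "2", "1", "0", "0"), ncol = 1))
identify_synapomorphies(tr, cm, list(Testuguria = c("Ge", "Te")))
#>        clade character from to ambiguity
#> 1 Testuguria         1    1  0 ambiguous
```

The `1 -> 0` loss is recovered on the clade's stem; with only five taxa
the reconstruction cannot pin the ancestral state (the root state can
absorb the change), so the record is honestly flagged `ambiguous` —
with a full outgroup sample it becomes unambiguous.

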