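---
title: "Implied-weighting parsimony for morphological matrices: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Implied-weighting parsimony: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladiw)
```

# The problem and the model

`cladiw` analyses discrete morphological character matrices under maximum
parsimony. Its packaged data set is a 68-taxon x 99-character matrix for
the woodlouse flies (Diptera: Rhinophoridae) — a family whose adults carry
no unique derived trait but whose first-instar larvae, specialised woodlouse
parasitoids, do — plus 11 oestroid outgroups, with *Musca* spp. as the
conventional rooting taxon.

Characters are **unordered** multistate (states coded contiguously from 0,
at most five per character): a change between any two states costs one
step. For a character on a binary tree, the minimum number of changes
(steps, $s$) is found by Fitch set optimization. The data-dependent floor
$m = \max(0, u - 1)$, with $u$ the number of distinct states observed in at
least one single-state cell, is the fewest steps the character can need on
*any* tree, so the homoplasy on a tree is the extra steps $es = s - m$.
Implied weighting scores a tree by the concave fit

$$F \;=\; \sum_i \frac{k}{k + es_i},$$

maximized over topologies. The concavity constant $k$ (default 4, the
value under which the packaged analysis presents its tree; the surrounding
study explored 3–10, 15, 20) controls how strongly homoplastic characters
are discounted: as $k \to \infty$ the ranking converges to equal-weights
tree length, which the package also offers as an objective.

## Cell semantics

* **Polymorphic cells** (`0/1`, `[01]`, `{01}`) are stored as state sets
  and enter Fitch passes as ambiguity sets (standard set-Fitch). No
  distinction between polymorphism and uncertainty is kept, since the
  downstream optimization treats both identically.
* **Unknown (`?`) and inapplicable (`-`)** cells are distinguished in the
  data model (`cellKind`) but both score as full ambiguity over the
  character's defined states — the default behaviour of the field's
  standard programs. The distinction is preserved for reporting and for
  the simulator.
* $m$ counts only unambiguous observations; a character observed solely
  through polymorphic or missing cells has $m = 0$. This guarantees
  $es \ge 0$ on every tree that carries all taxa. When a tree covers only
  a subset of taxa, `iwFit()` measures homoplasy against the induced
  sub-matrix.

## Fit-reporting conventions

Different programs print different totals for the same optimization, so
`ScoreReport` exposes all three: the all-character fit $F$; the minimized
complement $\mathrm{nchar} - F = \sum es_i/(es_i + k)$; and the fit summed
over **parsimony-informative** characters only. A character is informative
here when at least two of its states are each observed unambiguously in two
or more taxa; otherwise its extra steps are zero on every tree and its fit
contribution is constant at 1. The packaged matrix has 9 such uninformative
characters, and the published headline value for its fittest tree (62.33 at
$k = 4$) is the informative-characters total — equal to the all-character
optimum 71.33 minus 9. The acceptance script reports that quantity as its
primary value, with the other two conventions alongside.

# Tree search

The search reproduces the "traditional search" strategy: independent
replicates of **random addition sequences** (taxa inserted in a seeded
random order, each at the locally optimal edge) followed by **TBR branch
swapping** (every edge is bisected; the two fragments, with their cut-point
vertices suppressed, are rejoined across every pair of their edges). Each
candidate reconnection is scored exactly in one pass using per-edge Fitch
root sets of the two fragments: the joined length per character is
`len(F1) + len(F2) + [root sets disjoint]`.

Choices a user should know about:

* **Acceptance policy** is accept-first in a deterministic edge-enumeration
  order; after an accepted move the sweep restarts. Equal-score,
  topologically distinct neighbours of the final tree are collected into a
  buffer (default `treesPerReplicate = 10`, overflow logged, not an
  error) but are not themselves used as swap starts.
* **Determinism.** Every stochastic step derives from the master seed of
  `searchConfig()`; identical seeds give bit-identical results. Fit
  comparisons use an absolute tolerance of $10^{-9}$; equal-weights lengths
  are exact integers.
* **Replicates** default to 20 (the published setting of 1000 is reachable
  through the configuration; on the packaged matrix 20–80 replicates
  reliably find the optimum in seconds, as the acceptance script's
  escalation loop demonstrates).
* The kernel (Fitch counting, stepwise addition, TBR rescoring) is C++
  via Rcpp, the usual choice for parsimony engines in R; everything above
  it is plain R on `ape` `phylo` objects.
* `strictConsensus()` (via `ape::consensus`) and `rfDistance()` (bipartition
  symmetric difference, via `ape::dist.topo`) summarise multi-tree results.
  Best trees are reported fully binary; `collapseZeroLength()` optionally
  removes branches carrying no unambiguous change.

# Apomorphy mapping

Character changes are mapped on the tree rooted on the outgroup's pendant
edge (`rootOnOutgroup`). For each character and branch, the package
enumerates, by dynamic programming over most-parsimonious reconstructions
(MPRs), the set of (parent state, child state) pairs realized by at least
one MPR. A change is **unambiguous** when *every* MPR assigns different
states to the branch ends — the criterion behind "unambiguous
transformation" mapping. If the endpoints differ in every MPR but the state
pair varies across MPRs, the branch cannot be rendered as one
`index:state` item; it is excluded and logged in the
`"ambiguousEndpoint"` attribute.

A change into state $x$ is a **global apomorphy** when no MPR gains $x$ on
any other branch (no convergence) and none loses it inside the clade it
subtends (no reversal); otherwise it is **local**. Two conventions apply,
mirrored exactly by the exhaustive-MPR oracle in the test suite:

* the two root-incident branches represent a single unrooted edge: the
  root edge carries no reportable changes, and for convergence/reversal
  scanning only the ingroup-side root branch is examined;
* pendant branches to leaves without a single unambiguous observation are
  transparent to the scan (only reconstructed internal states and
  unambiguous leaf states count).

`cladeSupport()` reports, for a taxon set, whether it forms an exact clade
and the classified changes on its subtending branch in the field's
`index:state` notation.

# The simulator

`simulateMatrix()` generates matrices for end-to-end verification: a
uniform random unrooted binary topology; per character a
Poisson(`changeRate`) number of change events placed uniformly on branches
(a jump process, not a rate-matrix model — parsimony is the inference
target and the generating events themselves are needed to test apomorphy
mapping); then independent per-cell masking to unknown or inapplicable at
configured rates. It emulates the statistical shape of compact
morphological matrices — few states, heavy missing/inapplicable load in
some partitions — but deliberately **not** correlated characters,
hierarchically inapplicable characters, or branch-length heterogeneity.
Passing recovery tests therefore show the pipeline is correct and
well-behaved under clean assumptions, not that real morphological data meet
those assumptions.

Test problem sizes were fixed in advance as desk-scale choices: oracle
equivalence on hundreds of instances of up to 7 taxa (where exhaustive
enumeration over all 945 topologies, all internal-state assignments, and
all MPRs is feasible); topology recovery at 12 taxa and 500 clean
characters over 20 seeds; law-of-large-numbers checks at $10^4$ characters.

# Known limitations and open points

* On the packaged (printed) matrix, the $k=4$ search attains total fit
  71.33 (62.33 over informative characters) and reproduces the published
  supports for the family clade (eight unambiguous changes, with the larval
  terminal-sucker change 86:1 global and the seta-reduction change 25:1
  local) and for all four newly erected genera, change for change. The
  fittest trees do **not**, however, recover the two larva-defined basal
  subclades (the *Phyto* group and the *Stevenia* group) as monophyletic:
  under this matrix their diagnostic larval characters are outweighed at
  the base by adult characters of the many larva-unknown terminals. The
  matrix as printed is the package's source of truth (the externally
  deposited copy may differ in a few cells); results are reported against
  the package's own best trees, and the acceptance suite states this
  discrepancy rather than relaxing it.
* Printed-table spelling variants are resolved to the valid names
  (`Bixinia_winkleri`, `Marshallicona_quitu`), with the variant kept in
  `source_note`; the male+female composite terminal is a single OTU, noted
  the same way. One named clade (G) is shipped only through its members'
  memberships in larger clades because its full composition is not stated.
* No ordered/additive characters, step matrices, continuous characters,
  ratchet/sectorial/driven searches, or resampling supports: the scope is
  the equal-weights and implied-weighting analysis of unordered matrices.
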