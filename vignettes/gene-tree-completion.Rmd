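---
title: "Optimal completion of incomplete gene trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal completion of incomplete gene trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octal)
```

## The problem

Multi-locus phylogenomic pipelines routinely produce *incomplete* gene
trees: for many loci, sequence data are unavailable for some species, so
the estimated gene tree is missing those taxa. Because several downstream
methods (notably coalescent-based species-tree summary methods) behave
best with complete gene trees, one wants a principled way to place the
missing taxa back into each gene tree.

This package solves that placement problem exactly under the
Robinson–Foulds (RF) distance. Given

* a binary unrooted *reference tree* $T$ on the full taxon set $S$
  (typically an estimated species tree), and
* a binary unrooted *gene tree* $t$ on a subset $R \subseteq S$,

it returns a binary tree $T'$ on $S$ that (i) is a *completion* of $t$,
meaning $T'|_R = t$ where $|_R$ denotes restriction to $R$ with degree-2
nodes suppressed, and (ii) minimizes $\mathrm{RF}(T, T')$ over **all**
completions of $t$. The RF distance counts the nontrivial bipartitions
(splits) present in exactly one of the two trees.

## The algorithm and its certificate

Missing taxa are inserted one at a time. To add taxon $x$, the reference
is restricted to $R \cup \{x\}$, rooted at $x$, and $x$ and its pendant
edge are removed, giving a rooted view of where the reference places $x$
relative to the current gene tree. Walking from the root towards the
leaves, the first edge whose clade also forms a split of the gene tree (a
*shared* edge) identifies a corresponding edge of the gene tree; that edge
is subdivided and $x$ attached to the new node. Leaf-incident edges are
always shared, so the walk terminates on every path.

Optimality is certified through the *superleaf decomposition*. The
*backbone* of $T$ relative to $t$ is the set of edges of $T$ on paths
between taxa of $R$. Removing the backbone splits the missing taxa
$S \setminus R$ into pendant rooted groups, the *superleaves*, each
attached to one backbone edge. A superleaf is **Type I** when its
attachment edge is shared between $T|_R$ and $t$, and **Type II** when it
is unique. Writing $r = \mathrm{RF}(T|_R, t)$ and $m$ for the number of
Type II superleaves:

* no completion can score better than $r + 2m$ — adding leaves never
  removes disagreement, and each Type II superleaf necessarily creates at
  least one new unique split in each tree, costing 2;
* inserting on shared edges never disturbs other shared edges, so the
  greedy insertion achieves exactly $r + 2m$.

Every completion therefore ships with a machine-checkable certificate:
`achieved_rf == r + 2m`, exposed in the `completion_report`. The optimal
*score* is unique although the optimal *tree* generally is not; the report
logs which edge was subdivided for each taxon so the choices made are
auditable.

Shared/unique status is decided by hashing canonical bipartition keys (the
split side not containing the lexicographically smallest taxon, in sorted
label order). This gives the same $O(n)$ per-edge, $O(n^2)$ per-tree
budget as the classical LCA/clade-count bookkeeping while being far
simpler to audit, and the classification tables are simply recomputed
after each insertion. At the problem sizes this package targets (tens to
a few hundred taxa) the whole pipeline — 200 genes on 26 taxa, say —
completes in seconds, so we deliberately traded the incremental-update
micro-optimization for transparency.

## Parameters that matter

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `order` | `octal()` | `"lex"` | Insertion order over missing taxa. The achieved RF is provably order-independent; `"lex"` makes the returned tree deterministic, `"random"` (with `seed`) explores alternative optima. |
| `cap` | `enumerate_completions()` | `1e6` | Refusal threshold on the number of attachment sequences; the oracle never truncates silently. |
| `target_ad` | `perturb_to_ad()`, `run_simulate()` | 0.10 | Target normalized RF between a gene tree and the species tree ("AD"), the standard proxy for discordance level; 0.10 emulates moderate incomplete lineage sorting, 0.36 high, 0.75 very high. |
| `fraction_incomplete` | `deletion_protocol()` | 0.75 | Fraction of genes subjected to taxon deletion (150 of 200 in the emulated study design). |
| `min_leaves` | `deletion_protocol()` | 3 | Deletion draws leaving fewer taxa are redrawn, since completion requires at least 3 common taxa. |
| `max_moves` | `perturb_to_ad()` | 200 | Cap on NNI moves when chasing `target_ad`. |

## What the generator emulates — and what it does not

The synthetic module stands in for coalescent-simulation datasets:

* **Species trees** are uniform random binary topologies, generated by
  sequential equiprobable leaf attachment (the classical star-resolution
  scheme, under which all labelled topologies are equally likely).
* **Gene tree discordance** is produced by random NNI walks stopped the
  first time the normalized RF to the species tree reaches the target AD.
  This gives direct, distribution-free control of the one statistic the
  completion algorithm is sensitive to — topological distance between
  gene tree and reference. It does *not* reproduce the multispecies
  coalescent: real ILS concentrates discordance on short internal
  branches, while NNI walks spread it uniformly, and no branch lengths or
  sequence-level estimation error are modelled. A user-supplied gene-tree
  sampler can be substituted wherever a list of trees is accepted.
  Because the walk stops at the first crossing, realized AD overshoots
  the target by at most one NNI step (about $2/(2(n-3))$ normalized RF
  units); over many genes the mean tracks the target within a few
  percent.
* **Missing data** follow a clade-size protocol: the species tree is
  rooted at a declared outgroup, the sizes of all non-root clades form a
  multiset, and each gene selected to be incomplete loses a uniformly
  drawn multiset size's worth of uniformly drawn taxa. This mimics
  studies where whole clades are unsampled for a locus, without forcing
  the deleted taxa to be clade-mates.
* **Reference trees** can be built with `greedy_consensus()` (extended
  majority consensus): bipartitions ranked by frequency, accepted
  greedily under pairwise compatibility. Frequency ties are broken by the
  lexicographically smallest canonical bipartition, so the output is
  deterministic. The consensus may contain polytomies; since completion
  requires a binary reference, the study pipeline resolves any remaining
  polytomies deterministically (`ape::multi2di(random = FALSE)`) before
  use.

Consequently, passing tests on these instances demonstrates the
*algorithmic guarantees* — optimality, the $r + 2m$ certificate, order
invariance — on arbitrary topological configurations. They do not certify
accuracy on any particular empirical dataset, where the quality of a
completion is bounded by how close the chosen reference tree is to the
true gene tree.

## Numerical and degenerate-input choices

* All tree equality, hashing and serialization is topological. Branch
  lengths are carried as metadata through parsing, restriction (summed
  across suppressed nodes) and output, but no algorithm reads them, and
  edges created by completion carry none.
* Serialization is canonical: a trifurcation at the internal node
  adjacent to the smallest leaf, children ordered by smallest descendant
  label, labels compared in the C locale. Two trees are topologically
  equal exactly when their canonical strings match.
* Trivial (leaf) splits are excluded from every RF count and from the
  matching distance; they are identical on a common leaf set.
* Algorithms require binary input trees and at least 3 common taxa;
  non-binary trees and smaller overlaps are rejected with explicit
  errors rather than refined or guessed at. The parser itself accepts
  2-leaf trees and polytomies (needed for consensus output).
* Gene trees containing taxa absent from the reference are rejected, not
  silently pruned.
* The quartet distance reads each quartet's induced topology off the
  four-point condition on unit-branch-length path distances; in a binary
  tree the minimizing pairing is unique, so no tie-break is needed. The
  test suite cross-checks against an independent implementation that
  restricts both trees to every 4-subset.
* The matching distance solves its assignment problem exactly with an
  $O(k^3)$ Hungarian implementation (validated against brute-force
  permutation search); pair weights use the orientation-minimizing
  symmetric difference $\min(|A \mathbin{\triangle} C|,
  |A \mathbin{\triangle} D|)$. Only the raw weight is reported — no
  normalization is defined for this distance.

## Validation strategy and problem sizes

The shipped test suite validates, at sizes chosen to keep the whole suite
inside a coffee break on one core:

* exact agreement with a brute-force enumeration oracle on 200 random
  instances of up to 8 taxa with 1–3 missing (every completion sequence
  visited, $\prod_i (2(\ell+i)-3)$ of them);
* the $r + 2m$ certificate and restriction identity on 500 random
  instances of up to 50 taxa;
* shared-edge preservation after every single insertion, and superleaf
  topology preservation, on 100 stepwise-audited instances;
* the Type II increment law (minimum increase exactly 2, never less) by
  exhaustive placement on 100 single-missing-leaf instances, the same
  computation `scripts/acceptance.R` reports;
* insertion-order invariance of the optimum over 20 random orders on 50
  instances;
* a scaled-down end-to-end study — 26 taxa, 200 genes at target AD 0.10,
  75% of genes incomplete, greedy-consensus reference — checking that
  optimal completion lands closer to the true gene trees than uniformly
  random attachment.

## Known limitations

* Exactly one optimal completion is returned; the optimum set is not
  enumerated or summarized, although the insertion log and the
  `"random"` order policy allow sampling alternatives.
* Gene trees with unresolved (multifurcating) nodes are not accepted;
  collapsing unreliable branches and completing the refined set is out of
  scope.
* The optimality guarantee is specific to the RF objective; quartet and
  matching distances are provided for *evaluation* only.
* When the reference tree is topologically far from the true gene tree
  (e.g. under very high discordance), an optimal completion against that
  reference can still be a poor estimate of the true gene tree — the
  method is only as good as its reference.
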