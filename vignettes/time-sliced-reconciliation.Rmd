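---
title: "Time-sliced reconciliation and clade-family supertrees: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-sliced reconciliation and clade-family supertrees: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `sliceRec`, the
choices that were genuinely open when building the package, and what
the accompanying tests do and do not establish.

## The reconciliation model

### Time slices and the auxiliary outgroup

Unconstrained reconciliation with horizontal transfers is NP-hard
because a transfer may connect arbitrary branches.  The model here
restores tractability by *dating* the species tree coarsely: each tube
(species-tree edge) is cut into integer segments so that the tree
becomes a stack of horizontal *time slices*, and a transfer is allowed
only between tubes of the same slice.  `build_slices()` constructs the
sliced tree `S0` in two modes:

* **auto** — every leaf is pushed to the common maximal depth `h`
  (leaf tubes are subdivided as needed, internal tubes keep one
  segment per unit depth), giving `h + 1` slices including the slice
  occupied by the root tube `d0` alone;
* **explicit** — the Newick "branch lengths" of the input are read as
  integer segment counts and must give every root-to-leaf path the
  same number of slices.

An auxiliary outgroup leaf `d*` is attached as a sibling of the
original root, under a new root carrying the root tube `d0`.  The
outgroup tube is stretched so that each slice below `d0`'s contains
exactly one outgroup segment.  The outgroup is not a biological taxon:
its segments are the formal location of a gene before it is gained,
after it goes dormant, and before the whole family originates.  `d0`
occupies its own topmost slice; no transfer partner is ever needed
there, and the root-specific event rows treat it separately.

### Events and the dynamic program

Reconciliation of a binary rooted gene tree `G` (with super-root edge
`e0`) against `S0` fills a table over pairs `<e, d>`:

    c_min(e, d) = min_i c(e, d, i)

with `i` ranging over 35 event rows.  They group as follows:

* **endings** (rows 0–2): a leaf edge finishes in a terminal tube —
  for free when gene and species cohere, at the price of a final
  transfer without retention into the right species otherwise, or as a
  terminal gain if the edge sits in the outgroup;
* **passes and forks** (3–7): the edge follows a tube into the next
  slice, speciates into both children, or speciates with a loss on one
  side;
* **root rows** (8–13): at `d0` the gene may be present in the root
  and continue into the in-group (`nout`), be absent and continue in
  the outgroup (`out`), duplicate, or duplicate for free provided one
  copy exits through the outgroup (`dup0`).  The `dupl` row at `d0`
  requires that *neither* copy exits; the implementation therefore
  keeps, for every cell at `d0`, the minimum over non-exit rows and
  over exit rows separately, and rows 12/13 combine those restricted
  minima.  Backtracking and the scenario DAG key their vertices by
  `<e, d, restriction>` so that the constraint survives into the
  reported scenarios;
* **duplications** (12, 14): charged in any in-group tube, free in the
  outgroup;
* **transfers and gains** (15–18, 21–34): every transfer row that
  moves the gene out of an in-group tube has a gain-row mirror that
  moves it out of the outgroup; both minimize over a same-slice donor
  `d'` (or an ordered pair `<d', d">` for the double-transfer rows).
  Transfers with retention keep a copy in the donor; transfers without
  retention implicitly lose it (the `loss-` tag below);
* **dormancy and family origin** (19, 20): a gene may sleep into the
  outgroup segment of its slice, and the root edge `e0` may enter the
  in-group anywhere via the `gain_big` row.

Two printed conditions in the source event table are treated as typos:
the gain mirrors of the transfer-speciation rows are implemented with
`d = d*` like every other gain row, and the double-transfer constraint
is read as `d" ≠ d'` and `d" ≠ d*`.

Edges are processed children-first and tubes from the deepest slice
upwards.  Within a slice the outgroup segment is visited first for
`e ≠ e0` (the sleep row reads it) and last for `e0` (the `gain_big`
row reads the in-group cells of its own slice).  These are the only
same-slice dependencies, so the program is well-founded; everything
else reads strictly deeper cells.  The table is `O(|G| × |S0|)` cells
with slice-width factors on the donor minimizations; the inner loops
are implemented in C++ (`src/reconcile_dp.cpp`).

Ties are broken deterministically everywhere: equal-cost rows resolve
to the lowest row index, equal-cost donors to the tube closest to `d`
(path length between the tubes' parent vertices) and then to the
lowest tube id in creation order.

### Default event costs

The source model does not fix numeric costs, so the defaults are the
package's own and should be overridden when an application dictates
otherwise:

| parameter     | default | reading                                      |
|---------------|---------|----------------------------------------------|
| `loss`        | 1       | cheapest event; losses are common            |
| `dupl`        | 2       | duplications rarer than losses               |
| `gain`        | 3       | gains comparable to transfers                |
| `tr_with`     | 3       | transfer keeping a donor copy                |
| `tr_without`  | 3       | transfer losing the donor copy               |
| `sleep`       | 1       | dormancy is cheap but must be paid back by a gain |
| `gain_big`    | 0       | a family may originate below the root for free |

`gain_big = 0` means the entry point of a gene family is chosen
freely; this matches the counting convention of the supertree
recursion (see below).  All costs are dimensionless and nonnegative.

### First scenario and mapping beta

Backtracking from `<e0, d0>` projects, at each vertex, the unary or
binary edge recorded by the forward run, tagged with its event row;
the result is the *event tree*, whose cost equals `c(G, S)` by
construction (asserted in the tests as an identity, and re-derived in
the tests by summing the elementary charges of its tagged edges).  For
each gene-tree edge `e`, `beta_mapping()` collects the tubes of the
event-tree vertices `<e, d>` in root-ward order; the resulting path is
connected in `S0` — consecutive tubes are parent/child, transfer
donor/acceptor within a slice, or the acceptor's child — and ends with
the final event that consumes the edge (a fork, a duplication, a
terminal event, or a composite transfer row).

## The second scenario: a k-best DAG

The event tree keeps only the minimal event per cell, but near-ties
are biologically meaningful when the true costs are uncertain.
`build_dag()` keeps the `k` cheapest applicable alternatives per
vertex (default `k = 10`).  The source model requires only that the
probability of an alternative decrease with its cost and that `k = 1`
be deterministic; the exact rule is the package's choice:

    p_i  ∝  exp(−(c_i − c_min) / τ)

normalized over the kept alternatives, with temperature `τ` defaulting
to the mean of the configured elementary costs.  The soft-minimum
satisfies both constraints and gives a single interpretable knob: a
small `τ` concentrates on the optimum, a large `τ` approaches a
uniform choice among the `k` best.

Unconditional masses propagate from the root (mass 1) in topological
order; a binary edge delivers its full mass to both termini, so masses
are *expected inclusion counts* and may exceed one after duplications
— the package keeps the historical name "probability" in reports with
this caveat.

Every projected edge carries tag triplets (tag, gene edge, tube):
`gain`, `gain_big`, `dupl`, `loss`, `sleep`, the four transfer tags
(`tr±o` out of a tube, `tr±i` into a tube, with/without retention) and
`loss-` (the donor copy lost by a transfer without retention).  The
expectations

    f(I, u)   g(I, T)   cf(I, u)   cg(I, T)

sum edge masses whose triplets match a tag set `I` and a tube `u` or a
marked gene-edge set `T`; composite references (`d'&d"`, `e1&e2`) of
the double-transfer rows contribute half per member.  Cost expectations
weight each tag by its elementary cost; `loss-` is charged zero because
a transfer without retention is charged once, on its `tr-o` side —
with this convention the second-scenario cost at `k = 1` under the
default tag set (gains, family origin, duplications, losses, transfers
out of a tube, donor losses) reproduces the first-scenario cost
whenever no sleep event occurs.  At `k = 1` all five expectation
operations collapse to the event-tree counts and costs; this collapse,
probability conservation (`Σ p_i = 1` within `1e-12`), and the
smoothness of expectations between consecutive `k` are tested
properties.

## Supertree amalgamation

Phase I processes the clade family `P` — all clades of the input
forest plus the full species set `V0`, optionally extended by
transfer-difference sets — in ascending cardinality, computing for
every basic set its best partition, cost, tree and weight from the
good-vertex counts (formulas in the README).  Implementation choices:

* partitions are enumerated as `V1 ∈ P`, `V1 ⊂ V`, `|V1| ≤ |V|/2`,
  `V∖V1 ∈ P`, both basic, with symmetric duplicates removed; ties
  resolve to the lexicographically smallest `V1`;
* `w(V) = 1` when no runner-up partition exists or its cost is zero;
* if `V0` is not basic the pipeline warns (the exactness condition
  fails) but Phase II still runs on the eligible basic trees;
* basic trees with fewer than three leaves are excluded from Phase II
  scoring.

Phase II seeds with the cheapest rooted triplet over all 3-subsets of
`V0` and all three topologies, then repeatedly evaluates every
(unplaced species × insertion position) pair — one new vertex on each
edge plus a new root — and keeps the extension with the minimal
weighted basic-tree cost; the species and the position are chosen
jointly, not in a fixed species order, which is the natural reading of
"choose the minimal-cost extension".  Scoring prunes each basic tree
to the candidate's species set, treats it as a one-gene-per-species
gene tree, and reconciles it with the full event model (the `β` cost);
a separate classical mapping cost is not implemented.

### Exactness and its boundary

With only duplications and losses active and condition (*) — `V0`
basic — Phase I provably attains the global minimum of the total cost
over species trees whose clades lie in `P`.  Two clarifications that
the package's tests make precise:

* the matching reconciliation cost charges nothing above a family's
  entry point, i.e. the dup/loss cost must be taken with a free
  `gain_big` route or, equivalently, with the good-vertex counting's
  convention that lineages "enter" at their maximal fitting clades;
* duplications strictly inside a single species are invisible to the
  recursion (they sit below the singleton level where `c(V) = 0`), so
  exactness holds for forests whose monospecific subtrees are single
  leaves.  This matches the occurrence notion used by the pruning
  step, where an inextensible monospecific subtree counts as one
  occurrence of its species.

The acceptance suite verifies the equality on 100 random forests of up
to 6 species (paralogs allowed, monospecific subtrees excluded)
against exhaustive enumeration of all rooted topologies.

## Rooting and binarization

Both procedures around the core algorithms are the package's own
designs, since only their existence is specified by the source model:

* `root_unrooted()` evaluates every edge of an unrooted tree as a root
  position and keeps the rooting with the smallest reconciliation cost
  against a sliced reference, ties by edge enumeration order;
* `binarize()` resolves each polytomy by greedy agglomeration: the
  pair of child subtrees whose standalone reconciliation cost against
  the reference is smallest is joined first (without a reference, the
  symmetric difference of their species clades is the score).  For a
  3-polytomy the greedy choice coincides with exhaustive scoring of
  the three resolutions.

## The simulator

`generate_gene_trees()` evolves each gene as a branching process down
the sliced tree: per tube and lineage it duplicates with `p_dup`
(both copies restart the tube), dies with `p_loss`, or jumps to a
uniform same-slice non-outgroup tube with `p_tr`; otherwise it follows
speciation.  Genes extinct everywhere or surviving as a single leaf
are redrawn.  Defaults (`p_dup = 0.02`, `p_loss = 0.02`,
`p_tr = 0.01`, `n = 50` trees) are the low-rate regime a prokaryotic
gene-family study would consider mild, and they are the regime of the
recovery experiments.

What the simulator emulates: tube-granular events, within-slice
transfers, paralog birth, species-level loss.  What it does not:
branch-length-dependent rates, rate heterogeneity across families,
sequence evolution and reconstruction error, replacement transfers.
Consequently, passing recovery tests show that the amalgamation
algorithm inverts *this* generative process at low rates; they do not
certify performance on trees estimated from sequences.

## Problem sizes and numerical choices

The test and acceptance runs use: 500 random instances of ≤ 4 species
and ≤ 4 leaves with randomized positive costs for the oracle
equivalence check (the oracle is an independent memoized top-down
enumeration of every applicable event and donor); 100 random forests
of ≤ 6 species for the Phase I exactness check; 20 seeded replicates
of 8 species × 50 gene trees for supertree recovery with a ≥ 90%
pass bound; `k ∈ {1, 2, 5, 10}` for probability conservation.
Conservation and collapse identities are asserted at `1e-12`; all cost
comparisons are exact up to floating-point addition.  Degenerate
inputs are defined: an empty forest has total cost 0, a basic tree
pruned below two leaves scores 0, a species universe of fewer than
three species makes Phase II trivial.

## Known limitations

* Phase II is greedy and inherits no optimality guarantee; with the
  full event model even Phase I is a heuristic.
* The soft-minimum probability rule is one of many monotone choices;
  second-scenario expectations depend on `τ` and `k` quantitatively,
  though the tested collapse and smoothness properties bound the
  dependence qualitatively.
* The sliced model forbids transfers across slices by construction;
  conclusions about transfer counts are conditional on the slicing.
* Single-process only; the dynamic program parallelizes naturally over
  gene trees if needed.
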