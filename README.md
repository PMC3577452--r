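# sliceRec

Gene-tree/species-tree reconciliation in a time-sliced species tree
under an extended duplication–transfer–loss event model, and supertree
amalgamation by dynamic programming over a family of candidate clades.

`sliceRec` is aimed at molecular evolution studies that start from a
forest of rooted gene trees `{G_j}` with leaves labeled
`species-gene` (paralogs allowed) and ask two questions:

1. **Reconciliation.** Given a rooted binary species tree `S`, what is
   the minimal-cost evolutionary scenario — duplications, losses,
   gains, horizontal transfers with and without retention in the
   donor, and dormancy — that explains a gene tree `G` along `S`?
2. **Amalgamation.** Which species tree `S*` minimizes the total
   reconciliation cost `c({G_j}, S) = Σ_j k_j · c(G_j, S)` over trees
   whose clades come from a fixed family `P` (by default, the clades
   observed in the input trees)?

## The model in brief

Horizontal transfers are restricted to *time slices*: the species tree
is converted into a sliced tree `S0` in which every root-to-leaf path
crosses every slice exactly once and transfers are only allowed between
tubes (species-tree edges) of the same slice.  An auxiliary outgroup
leaf `d*` is attached beside the root; its per-slice segments model
gene gains, dormancy, and the origin of a family below the root.  The
root tube `d0` and the gene tree's root edge `e0` make the super-root
explicit.

Reconciliation fills a table over pairs `<e, d>` (gene-tree edge ×
tube):

```
c_min(e, d) = min_i c(e, d, i),          c(G, S) = c_min(e0, d0)
```

where `i` ranges over 35 event types, each with an applicability
condition and a cost rule (several minimize over a same-slice donor
tube `d'` or a pair `<d', d">`).  Backtracking the table yields the
*first scenario* — an explicit event tree — and the mapping `β` that
assigns each gene-tree edge its connected path of tubes.  Keeping the
`k` best alternatives per cell instead of one yields the *second
scenario*, a probability-weighted DAG over which the package computes
expectations `f(I, u)` (number of events with tags `I` in tube `u`),
`g(I, T)` (events on a marked edge set `T`), their cost analogues
`cf`/`cg`, and the second-scenario cost.

The supertree algorithm runs in two phases.  Phase I processes the
clade family `P` in order of ascending cardinality; a set `V` is
*basic* if it is a singleton or splits into two basic members of `P`,
and its tree and cost follow the recursion

```
c(V) = min { c(V1) + c(V2) + C_d + C_l  |  V = V1 + V2 }
C_d  = c_d · (|R(V1)| + |R(V2)| − |R(V)| − |r(V1,V2)|)
C_l  = c_l · (|R(V1)| + |R(V2)| − 2 |r(V1,V2)|)
```

with `R(V)` the *good vertices* (gene-tree vertices whose clade fits
inside `V` while the parent's does not) and `r(V1,V2)` the vertices
speciating across the partition.  Each basic tree gets a weight
`w(V) = 1 + (c/(a·m)) · (c(V') − c(V))/c(V')` from the runner-up
partition `V'`.  Phase II seeds with the best rooted species triplet
and greedily inserts one species at a time, scoring every candidate by
the weighted sum of reconciliation costs of the basic trees.

## Worked example

```r
library(sliceRec)

## reconciliation -----------------------------------------------------
s0 <- slice_species_tree("((A,B),C);")
s0
#> Sliced species tree: 10 tubes in 4 slices over 3 species

g  <- parse_gene_tree("((A-1,B-1),(A-2,B-2));")
reconcile_cost(g, slice_species_tree("(A,B);"))
#> [1] 2                      # one duplication at the default c(dupl) = 2

cm <- compute_cost_matrix(g, slice_species_tree("(A,B);"))
build_event_tree(cm)
#> Event tree: 8 vertices, 4 tagged edges; cost = 2
#>   events: dupl=1

## supertree ----------------------------------------------------------
f <- gene_forest(c("((A-1,B-1),C-1);", "((A-1,C-1),B-1);",
                   "(A-2,(B-2,C-2));"))
res <- supertree(f)
res$newick
#> [1] "((B,C),A);"
res$total_cost
#> [1] 6                      # the two discordant trees cost 3 each

## second scenario ----------------------------------------------------
s1   <- slice_species_tree(res$newick)
dags <- lapply(f, function(g)
  build_dag(compute_cost_matrix(binarize(g, s1), s1), k = 10))
scenario_cost(dags)
#> [1] 24.38934
```

The reconciliation cost 2 is the single duplication needed for the
two-paralog family; the supertree `((B,C),A)` is one of the three tied
topologies for a maximally discordant forest (ties resolve
deterministically by enumeration order); and the second-scenario cost
exceeds the first-scenario cost because it averages over suboptimal
scenarios as well.

A command-line interface exposes the same operations
(`inst/exec/sliceRec slice|root|binarize|reconcile|scenario|supertree|simulate`).

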