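## ---------------------------------------------------------------------------
## Supertree amalgamation: Phase I (basic trees over the clade family P)
## and Phase II (greedy assembly scored by reconciliation)
## ---------------------------------------------------------------------------

set_key <- function(s) paste(sort(s), collapse = "\x1f")

#' Build the clade family P of a forest
#'
#' The standard family contains every clade of every gene tree plus the
#' full species set `V0`.  With `with_transfer_sets = TRUE`, for every
#' pair of noncomparable vertices `v1, v2` of a tree whose clades
#' overlap, the differences `cl(v_i) - cl(v1) %intersect% cl(v2)` are
#' added, and for every vertex `v` ancestral to exactly one of the pair,
#' the difference `cl(v) - cl(v_i)`; this admits clades broken by
#' horizontal transfers.
#'
#' @param forest a `gene_forest`.
#' @param with_transfer_sets add the transfer-difference sets.
#' @return an object of class `clade_set`: sets ordered by ascending
#'   cardinality with provenance flags.
#' @export
build_clade_set <- function(forest, with_transfer_sets = FALSE) {
  stopifnot(length(forest) > 0)
  V0 <- forest_species(forest)
  sets <- list(); prov <- character(0); keys <- character(0)
  add_set <- function(s, origin) {
    s <- sort(unique(s))
    if (length(s) == 0) return()
    k <- set_key(s)
    if (k %in% keys) return()
    sets[[length(sets) + 1L]] <<- s
    prov[[length(prov) + 1L]] <<- origin
    keys[[length(keys) + 1L]] <<- k
  }
  for (tree in forest) {
    cl <- tree_clades(tree)
    for (s in cl) add_set(s, "clade")
    if (with_transfer_sets) {
      anc <- ancestor_matrix(tree)
      n <- n_vertices(tree)
      for (v1 in seq_len(n)) {
        for (v2 in seq_len(n)) {
          if (v1 >= v2) next
          if (anc[v1, v2] || anc[v2, v1]) next
          I <- intersect(cl[[v1]], cl[[v2]])
          if (length(I) == 0) next
          add_set(setdiff(cl[[v1]], I), "transfer")
          add_set(setdiff(cl[[v2]], I), "transfer")
          for (v in seq_len(n)) {
            for (vi in c(v1, v2)) {
              other <- if (vi == v1) v2 else v1
              if (anc[v, vi] && !anc[v, other]) {
                add_set(setdiff(cl[[v]], cl[[vi]]), "transfer")
              }
            }
          }
        }
      }
    }
  }
  add_set(V0, "V0")
  ord <- order(lengths(sets), vapply(sets, set_key, character(1)))
  structure(list(sets = sets[ord], provenance = prov[ord],
                 keys = vapply(sets[ord], set_key, character(1)),
                 species = V0),
            class = "clade_set")
}

ancestor_matrix <- function(tree) {
  n <- n_vertices(tree)
  anc <- matrix(FALSE, n, n)      # anc[a, b]: a is a proper ancestor of b
  for (v in seq_len(n)) {
    p <- tree$parent[v]
    while (p != 0L) { anc[p, v] <- TRUE; p <- tree$parent[p] }
  }
  anc
}

#' @export
print.clade_set <- function(x, ...) {
  cat("Clade family P:", length(x$sets), "sets over",
      length(x$species), "species\n")
  invisible(x)
}

## Precompute per-tree structures for good-vertex counting: clades as
## index vectors into the sorted species universe.
prep_forest <- function(forest, universe) {
  lapply(forest, function(tree) {
    cl <- tree_clades(tree)
    idx <- lapply(cl, function(s) match(s, universe))
    list(children = tree$children, parent = tree$parent,
         root = tree$root, clade = idx,
         binary = all(lengths(tree$children) %in% c(0L, 2L)))
  })
}

mask_of <- function(s, universe) {
  m <- logical(length(universe))
  m[match(s, universe)] <- TRUE
  m
}

count_good_tree <- function(pre, mask) {
  inV <- vapply(pre$clade, function(ix) all(mask[ix]), logical(1))
  if (pre$binary) {
    good <- 0L
    for (v in seq_along(pre$parent)) {
      if (v == pre$root) {
        if (inV[v]) good <- good + 1L
      } else if (inV[v] && !inV[pre$parent[v]]) {
        good <- good + 1L
      }
    }
    good
  } else {
    ## polytomous rule over vertices plus the super-root
    good <- if (inV[pre$root]) 1L else 0L    # super-root
    for (v in seq_along(pre$parent)) {
      ch <- pre$children[[v]]
      if (length(ch) == 0L) next
      if (!inV[v] && any(inV[ch])) good <- good + 1L
    }
    good
  }
}

count_pairs_tree <- function(pre, mask1, mask2) {
  in1 <- vapply(pre$clade, function(ix) all(mask1[ix]), logical(1))
  in2 <- vapply(pre$clade, function(ix) all(mask2[ix]), logical(1))
  cnt <- 0L
  for (v in seq_along(pre$parent)) {
    ch <- pre$children[[v]]
    if (length(ch) == 0L) next
    has1 <- !in1[v] && any(in1[ch])
    has2 <- !in2[v] && any(in2[ch])
    if (has1 && has2) cnt <- cnt + 1L
  }
  cnt
}

#' Good vertices of a gene tree with respect to a species set
#'
#' A non-root vertex is good when its clade fits inside `V` while its
#' parent's clade does not; the root is good when its clade fits.  For
#' polytomous trees a vertex (including the super-root) is good when at
#' least one child satisfies the same condition.  Only the cardinality
#' of the good set enters the supertree recursion.
#'
#' @param tree a `gene_tree`.
#' @param V character vector of species.
#' @return integer count of good vertices in this tree.
#' @export
good_vertices <- function(tree, V) {
  stopifnot(length(V) > 0)
  universe <- sort(unique(c(V, tree$species[is_leaf(tree)])))
  pre <- prep_forest(structure(list(tree), class = "gene_forest"),
                     universe)[[1]]
  count_good_tree(pre, mask_of(V, universe))
}

#' Vertices speciating across a partition
#'
#' Counts the vertices with one child good for `V1` and another good
#' for `V2` (condition (4) on the children); used in the duplication
#' and loss counts of the supertree recursion.
#'
#' @param tree a `gene_tree`.
#' @param V1,V2 disjoint nonempty species sets.
#' @return integer count.
#' @export
pair_vertices <- function(tree, V1, V2) {
  if (length(intersect(V1, V2)) > 0) stop("V1 and V2 must be disjoint")
  stopifnot(length(V1) > 0, length(V2) > 0)
  universe <- sort(unique(c(V1, V2, tree$species[is_leaf(tree)])))
  pre <- prep_forest(structure(list(tree), class = "gene_forest"),
                     universe)[[1]]
  count_pairs_tree(pre, mask_of(V1, universe), mask_of(V2, universe))
}

#' Phase I: basic sets, basic trees and their costs
#'
#' Processes the clade family `P` in order of ascending cardinality.  A
#' set is basic when it is a singleton or splits into two disjoint basic
#' members of `P`.  For every partition the duplication and loss totals
#' are counted from the good-vertex cardinalities
#' (`C_d = c_d (|R(V1)|+|R(V2)|-|R(V)|-|r(V1,V2)|)`,
#' `C_l = c_l (|R(V1)|+|R(V2)|-2 |r(V1,V2)|)`) and the minimal
#' partition defines the basic tree `S(V)`, its cost `c(V)` and its
#' weight `w(V) = 1 + (c/(a m)) (c(V')-c(V))/c(V')` from the runner-up
#' partition `V'`.
#'
#' @param forest a `gene_forest`.
#' @param P a `clade_set` (built from the forest if missing).
#' @param costs an [event_costs()] object; its `dupl` and `loss`
#'   components are the `c_d`, `c_l` parameters of the recursion.
#' @param weight_c weight steepness parameter `c` (default 10).
#' @return an object of class `phase1_result`: a named list of records
#'   (one per basic set) plus `condition_star` (is the full species set
#'   basic?), the clade family and the species universe.
#' @export
phase1 <- function(forest, P = NULL, costs = event_costs(),
                   weight_c = 10) {
  if (is.null(P)) P <- build_clade_set(forest)
  V0 <- P$species
  m <- length(V0)
  pre <- prep_forest(forest, V0)
  masks <- lapply(P$sets, mask_of, universe = V0)
  nR <- vapply(masks, function(mk) {
    sum(vapply(pre, count_good_tree, integer(1), mask = mk))
  }, integer(1))
  names(nR) <- P$keys
  c_d <- costs[["dupl"]]; c_l <- costs[["loss"]]
  records <- list()
  for (i in seq_along(P$sets)) {
    V <- P$sets[[i]]
    key <- P$keys[i]
    if (length(V) == 1L) {
      records[[key]] <- list(V = V, basic = TRUE, cost = 0,
                             partition = NULL, tree = list(species = V),
                             weight = 1, second_cost = NA_real_,
                             leaves = 1L)
      next
    }
    ## candidate partitions: V1 in P, V1 subset of V, |V1| <= |V|/2,
    ## V \ V1 in P, both halves basic
    cand <- list()
    for (j in seq_len(i - 1L)) {
      V1 <- P$sets[[j]]
      if (length(V1) > length(V) / 2) next
      if (!all(V1 %in% V)) next
      V2 <- setdiff(V, V1)
      k2 <- set_key(V2)
      r1 <- records[[P$keys[j]]]; r2 <- records[[k2]]
      if (is.null(r1) || is.null(r2)) next
      if (!r1$basic || !r2$basic) next
      if (length(V1) == length(V2) && P$keys[j] > k2) next  # dedupe
      m1 <- masks[[j]]; m2 <- mask_of(V2, V0)
      nr <- sum(vapply(pre, count_pairs_tree, integer(1),
                       mask1 = m1, mask2 = m2))
      Cd <- unname(c_d * (nR[[P$keys[j]]] + nR[[k2]] - nR[[key]] - nr))
      Cl <- unname(c_l * (nR[[P$keys[j]]] + nR[[k2]] - 2 * nr))
      cand[[length(cand) + 1L]] <- list(
        V1 = V1, V2 = V2, k1 = P$keys[j],
        cost = r1$cost + r2$cost + Cd + Cl)
    }
    if (length(cand) == 0L) {
      records[[key]] <- list(V = V, basic = FALSE)
      next
    }
    cc <- vapply(cand, `[[`, numeric(1), "cost")
    kk <- vapply(cand, `[[`, character(1), "k1")
    ord <- order(cc, kk)
    best <- cand[[ord[1]]]
    second <- if (length(ord) >= 2) cc[ord[2]] else NA_real_
    r1 <- records[[set_key(best$V1)]]
    r2 <- records[[set_key(best$V2)]]
    tree <- list(children = list(r1$tree, r2$tree))
    a <- length(V)
    w <- if (is.na(second) || second == 0) 1 else {
      1 + (weight_c / (a * m)) * (second - best$cost) / second
    }
    records[[key]] <- list(V = V, basic = TRUE, cost = best$cost,
                           partition = list(V1 = best$V1, V2 = best$V2),
                           tree = tree, weight = w,
                           second_cost = second, leaves = a)
  }
  star <- !is.null(records[[set_key(V0)]]) &&
    isTRUE(records[[set_key(V0)]]$basic)
  if (!star) {
    warning("the full species set V0 is not basic: the exactness ",
            "condition of the supertree recursion fails")
  }
  structure(list(records = records, P = P, V0 = V0,
                 condition_star = star, weight_c = weight_c,
                 costs = costs),
            class = "phase1_result")
}

#' @export
print.phase1_result <- function(x, ...) {
  nb <- sum(vapply(x$records, function(r) isTRUE(r$basic), logical(1)))
  cat("Phase I:", nb, "basic sets of", length(x$P$sets),
      "candidates; V0 basic:", x$condition_star, "\n")
  invisible(x)
}

## Basic trees eligible for Phase II scoring: basic, at least 3 leaves.
eligible_records <- function(ph1) {
  Filter(function(r) isTRUE(r$basic) && r$leaves >= 3L, ph1$records)
}

## Convert a nested species tree (basic tree or candidate supertree)
## to a gene tree with one gene per species.
nested_to_pseudo_gene <- function(nested) {
  decorate <- function(node) {
    if (is.null(node$children)) {
      return(list(species = node$species, gene = "1"))
    }
    list(children = lapply(node$children, decorate))
  }
  nested_to_gene_tree(decorate(nested))
}

## Prune a nested tree to a species subset; NULL if empty, collapses
## unary vertices.
prune_nested <- function(node, keep) {
  if (is.null(node$children)) {
    if (node$species %in% keep) return(node)
    return(NULL)
  }
  kids <- Filter(Negate(is.null), lapply(node$children, prune_nested,
                                         keep = keep))
  if (length(kids) == 0) return(NULL)
  if (length(kids) == 1) return(kids[[1]])
  list(children = kids)
}

nested_leaf_count <- function(node) {
  if (is.null(node$children)) return(1L)
  sum(vapply(node$children, nested_leaf_count, integer(1)))
}

#' Cost of a basic tree against a species tree
#'
#' The basic tree is pruned to the species present in `S`, treated as a
#' gene tree with one gene per species, and reconciled into the sliced
#' `S`; a pruned tree with fewer than two leaves contributes 0.
#'
#' @param SV a basic tree: nested list as stored in Phase I records, or
#'   a `species_tree`.
#' @param S a `species_tree` (or Newick string) to score against.
#' @param costs an [event_costs()] object.
#' @return nonnegative numeric cost.
#' @export
basic_tree_cost <- function(SV, S, costs = event_costs()) {
  if (inherits(SV, "species_tree")) SV <- species_tree_nested(SV)
  if (is.character(S)) S <- read_species_tree(S)
  W <- S$label[!is.na(S$label)]
  pr <- prune_nested(SV, W)
  if (is.null(pr) || nested_leaf_count(pr) < 2L) return(0)
  s0 <- build_slices(S)
  reconcile_cost(nested_to_pseudo_gene(pr), s0, costs)
}

## Score one candidate species tree (nested) against the eligible basic
## trees, all pre-pruned to the candidate's leaf set.
score_candidate <- function(nested, pruned_genes, weights, costs) {
  if (length(pruned_genes) == 0) return(0)
  st <- species_tree_from_nested(nested)
  s0 <- build_slices(st)
  genes <- lapply(pruned_genes, gene_to_cpp, s0 = s0)
  v <- cpp_total_costs(genes, s0, unclass(costs))
  sum(weights * v)
}

## All rooted triplet topologies on three species, in enumeration order.
triplet_topologies <- function(sp) {
  leaf <- function(s) list(species = s)
  join <- function(a, b) list(children = list(a, b))
  list(join(join(leaf(sp[1]), leaf(sp[2])), leaf(sp[3])),
       join(join(leaf(sp[1]), leaf(sp[3])), leaf(sp[2])),
       join(join(leaf(sp[2]), leaf(sp[3])), leaf(sp[1])))
}

## All single-species extensions of a nested tree: a new vertex on each
## edge (preorder enumeration) plus a new root, each connecting leaf s.
tree_extensions <- function(nested, s) {
  out <- list()
  insert_at <- function(node, path) {
    ## returns the tree with a new vertex above the subtree at `path`
    splice <- function(cur, depth) {
      if (depth > length(path)) {
        return(list(children = list(cur, list(species = s))))
      }
      kids <- cur$children
      kids[[path[depth]]] <- splice(kids[[path[depth]]], depth + 1L)
      list(children = kids)
    }
    splice(nested, 1L)
  }
  walk <- function(node, path) {
    if (length(path) > 0) {
      out[[length(out) + 1L]] <<- insert_at(nested, path)
    }
    if (!is.null(node$children)) {
      for (i in seq_along(node$children)) {
        walk(node$children[[i]], c(path, i))
      }
    }
  }
  walk(nested, integer(0))
  out[[length(out) + 1L]] <- list(children = list(nested,
                                                  list(species = s)))
  out
}

#' Phase II: greedy assembly of the supertree
#'
#' Seeds with the minimal-cost rooted triplet over all 3-subsets of the
#' species universe, then repeatedly inserts the species/position pair
#' whose extended tree minimizes the weighted sum of basic-tree
#' reconciliation costs, until every species is placed.  Ties are broken
#' by enumeration order.
#'
#' @param ph1 a `phase1_result`.
#' @param costs an [event_costs()] object used for scoring.
#' @param use_weights multiply each basic-tree cost by its Phase I
#'   weight `w(V)` (default `TRUE`).
#' @return an object of class `supertree_result`: the supertree (as a
#'   `species_tree` and Newick), the per-step log, and the final
#'   weighted basic-tree cost.
#' @export
phase2 <- function(ph1, costs = ph1$costs, use_weights = TRUE) {
  V0 <- sort(ph1$V0)
  recs <- eligible_records(ph1)
  weights_all <- vapply(recs, function(r) {
    if (use_weights) r$weight else 1
  }, numeric(1))
  steps <- list()
  score_all <- function(cands, W) {
    pruned <- list(); wts <- numeric(0)
    for (i in seq_along(recs)) {
      pr <- prune_nested(recs[[i]]$tree, W)
      if (is.null(pr) || nested_leaf_count(pr) < 2L) next
      pruned[[length(pruned) + 1L]] <- nested_to_pseudo_gene(pr)
      wts <- c(wts, weights_all[i])
    }
    vapply(cands, score_candidate, numeric(1),
           pruned_genes = pruned, weights = wts, costs = costs)
  }
  if (length(V0) <= 2L) {
    nested <- if (length(V0) == 1L) list(species = V0) else
      list(children = list(list(species = V0[1]),
                           list(species = V0[2])))
    cost <- 0
  } else {
    combos <- utils::combn(V0, 3L)
    cands <- list()
    for (ci in seq_len(ncol(combos))) {
      cands <- c(cands, triplet_topologies(combos[, ci]))
    }
    Ws <- lapply(seq_len(ncol(combos)), function(ci) combos[, ci])
    sc <- numeric(length(cands))
    for (ci in seq_len(ncol(combos))) {
      idx <- (ci - 1L) * 3L + 1:3
      sc[idx] <- score_all(cands[idx], Ws[[ci]])
    }
    bi <- which.min(sc)
    nested <- cands[[bi]]
    cost <- sc[bi]
    steps[[1]] <- data.frame(step = 0L, action = "seed",
                             species = NA_character_, cost = cost)
  }
  W <- nested_species(nested)
  step <- 0L
  while (length(setdiff(V0, W)) > 0) {
    step <- step + 1L
    remaining <- setdiff(V0, W)
    cands <- list(); cand_s <- character(0)
    for (s in remaining) {
      ext <- tree_extensions(nested, s)
      cands <- c(cands, ext)
      cand_s <- c(cand_s, rep(s, length(ext)))
    }
    ## candidates are scored per species group, each with its own
    ## extended leaf set
    sc <- numeric(length(cands))
    pos <- 1L
    for (s in remaining) {
      n_s <- sum(cand_s == s)
      idx <- seq(pos, pos + n_s - 1L)
      sc[idx] <- score_all(cands[idx], c(W, s))
      pos <- pos + n_s
    }
    bi <- which.min(sc)
    nested <- cands[[bi]]
    W <- nested_species(nested)
    cost <- sc[bi]
    steps[[length(steps) + 1L]] <-
      data.frame(step = step, action = "insert", species = cand_s[bi],
                 cost = cost)
  }
  st <- species_tree_from_nested(nested)
  structure(list(tree = st, newick = species_tree_newick(st),
                 steps = do.call(rbind, steps), cost = cost,
                 use_weights = use_weights),
            class = "supertree_result")
}

#' @export
print.supertree_result <- function(x, ...) {
  cat("Supertree:", x$newick, "\n  weighted basic-tree cost:",
      x$cost, "\n")
  invisible(x)
}

#' Total amalgamation cost of a species tree
#'
#' Slices `S` and sums the (weighted) reconciliation costs of every
#' gene tree of the forest against it.
#'
#' @param forest a `gene_forest` (binarized automatically if needed).
#' @param S a `species_tree` or Newick string.
#' @param costs an [event_costs()] object.
#' @return numeric total cost.
#' @export
amalgamation_cost <- function(forest, S, costs = event_costs()) {
  if (is.character(S)) S <- read_species_tree(S)
  s0 <- build_slices(S)
  forest <- structure(lapply(forest, binarize, reference = s0,
                             costs = costs),
                      class = "gene_forest")
  total_cost(forest, s0, costs)
}

#' Amalgamate a forest into a supertree
#'
#' End-to-end wrapper: optional rare-species pruning, clade family
#' construction, Phase I and Phase II, plus the total reconciliation
#' cost of the result.
#'
#' @param forest a `gene_forest`.
#' @param costs an [event_costs()] object.
#' @param p_min rare-species pruning threshold (0 = keep everything).
#' @param transfer_sets add transfer-difference sets to `P`.
#' @param use_weights weight basic-tree costs by `w(V)`.
#' @param weight_c weight steepness parameter.
#' @return a `supertree_result` with the Phase I result attached and
#'   `total_cost`, the forest's amalgamation cost against the supertree.
#' @export
supertree <- function(forest, costs = event_costs(), p_min = 0,
                      transfer_sets = FALSE, use_weights = TRUE,
                      weight_c = 10) {
  forest <- prune_rare_species(forest, p_min)
  if (length(forest) == 0) stop("no trees left after pruning")
  P <- build_clade_set(forest, with_transfer_sets = transfer_sets)
  ph1 <- phase1(forest, P, costs, weight_c)
  res <- phase2(ph1, costs, use_weights)
  res$phase1 <- ph1
  res$total_cost <- amalgamation_cost(forest, res$tree, costs)
  res
}
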