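# Shared tree helpers for the tests.

# Species tree (package-internal representation) from an ape phylo.
st_from_phylo <- function(phy) {
  v <- sliceRec:::phylo_to_vertices(phy)
  lab <- rep(NA_character_, length(v$parent))
  lab[seq_len(v$ntip)] <- v$tip.label
  sliceRec:::new_species_tree(v$parent, v$children, lab,
                              rep(1L, length(v$parent)))
}

st_clades <- function(st) {
  cl <- vector("list", length(st$parent))
  for (v in sliceRec:::postorder_species(st)) {
    cl[[v]] <- if (length(st$children[[v]]) == 0L) st$label[v] else
      sort(unique(unlist(cl[st$children[[v]]])))
  }
  cl
}

clade_keys <- function(st) {
  sort(vapply(st_clades(st), function(s) paste(sort(s), collapse = "|"),
              character(1)))
}

# Rooted topology equality via clade-set identity.
same_rooted_topology <- function(a, b) {
  if (is.character(a)) a <- read_species_tree(a)
  if (is.character(b)) b <- read_species_tree(b)
  identical(clade_keys(a), clade_keys(b))
}

gt_clade_keys <- function(tree) {
  cl <- sliceRec:::tree_clades(tree)
  sort(vapply(cl, function(s) paste(sort(s), collapse = "|"),
              character(1)))
}

# Multiset of leaf labels of a gene tree.
leaf_labels <- function(tree) {
  lv <- which(sliceRec:::is_leaf(tree))
  sort(paste0(tree$species[lv], tree$separator, tree$gene[lv]))
}

# Gene tree without paralogs over a species vector.
random_gene_tree_nopar <- function(species, nleaves) {
  sp <- sample(species, nleaves, replace = FALSE)
  pool <- lapply(seq_len(nleaves), function(i) {
    list(species = sp[i], gene = "1")
  })
  while (length(pool) > 1) {
    ij <- sample.int(length(pool), 2)
    pool <- c(pool[-ij], list(list(children = pool[ij])))
  }
  sliceRec:::nested_to_gene_tree(pool[[1]])
}

has_monospecific_subtree <- function(tree) {
  cl <- sliceRec:::tree_clades(tree)
  any(lengths(cl) == 1 & lengths(tree$children) > 0)
}

# Classical duplication/loss-only event costs with every other route
# prohibitively expensive (families enter at the species-tree root).
duploss_costs <- function(cd = 2, cl = 1) {
  event_costs(loss = cl, dupl = cd, gain = 1e6, tr_with = 1e6,
              tr_without = 1e6, sleep = 1e6, gain_big = 1e6)
}

set_key <- function(s) paste(sort(s), collapse = "\x1f")

# Exhaustive minimum of the total reconciliation cost over all rooted
# binary species trees whose clades all belong to P.
exhaustive_min_cost <- function(forest, P, costs) {
  V0 <- P$species
  cands <- phangorn::allTrees(length(V0), rooted = TRUE, tip.label = V0)
  best <- Inf
  for (i in seq_along(cands)) {
    st <- st_from_phylo(cands[[i]])
    keys <- vapply(st_clades(st), set_key, character(1))
    if (!all(keys %in% P$keys)) next
    best <- min(best, total_cost(forest, build_slices(st), costs))
  }
  best
}
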