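#' @useDynLib sliceRec, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif setNames
#' @importFrom utils head
NULL

## ---------------------------------------------------------------------------
## Internal rooted-tree representation
##
## A tree is a list of parallel vectors indexed by vertex id:
##   parent[v]    id of the parent vertex (0 for the root)
##   children[[v]] integer vector of child ids, in stored (input) order
##   species[v]   species name for leaves, NA otherwise
##   gene[v]      gene identifier for leaves, NA otherwise
## Edges are identified with their lower vertex, so the root id also names
## the root edge e0 that connects the root to the implicit super-root.
## ---------------------------------------------------------------------------

new_gene_tree <- function(parent, children, species, gene,
                          separator = "-", weight = 1) {
  structure(
    list(parent = as.integer(parent), children = children,
         species = as.character(species), gene = as.character(gene),
         root = which(parent == 0L)[1], separator = separator,
         weight = weight),
    class = "gene_tree")
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("Gene tree:", sum(is_leaf(x)), "leaves,",
      length(x$parent) - sum(is_leaf(x)), "internal vertices\n")
  cat(" ", gene_tree_newick(x), "\n")
  invisible(x)
}

is_leaf <- function(tree) lengths(tree$children) == 0L

n_vertices <- function(tree) length(tree$parent)

## Post-order vertex ids (children before parents).
postorder <- function(tree) {
  out <- integer(0)
  walk <- function(v) {
    for (ch in tree$children[[v]]) walk(ch)
    out[[length(out) + 1L]] <<- v
  }
  walk(tree$root)
  unlist(out)
}

## Clade of every vertex: sorted species sets at descendant leaves.
tree_clades <- function(tree) {
  n <- n_vertices(tree)
  cl <- vector("list", n)
  for (v in postorder(tree)) {
    cl[[v]] <- if (length(tree$children[[v]]) == 0L) {
      tree$species[v]
    } else {
      sort(unique(unlist(cl[tree$children[[v]]])))
    }
  }
  cl
}

split_leaf_label <- function(label, separator = "-") {
  pos <- regexpr(separator, label, fixed = TRUE)
  bad <- pos < 0L
  if (any(bad)) {
    stop("leaf label(s) without species", separator,
         "gene separator: ", paste(label[bad], collapse = ", "),
         " (label position ", paste(which(bad), collapse = ", "), ")")
  }
  data.frame(species = substr(label, 1L, pos - 1L),
             gene = substr(label, pos + nchar(separator), nchar(label)),
             stringsAsFactors = FALSE)
}

## Convert an ape "phylo" object into the internal representation.
phylo_to_vertices <- function(phy) {
  ntip <- length(phy$tip.label)
  n <- ntip + phy$Nnode
  parent <- integer(n)
  children <- rep(list(integer(0)), n)
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1]; b <- phy$edge[i, 2]
    parent[b] <- a
    children[[a]] <- c(children[[a]], b)
  }
  list(parent = parent, children = children, ntip = ntip,
       tip.label = phy$tip.label)
}

check_newick_text <- function(text) {
  if (!nzchar(trimws(text))) stop("empty Newick string")
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced parenthesis at position ", i)
    }
  }
  if (depth != 0L) {
    stop("unbalanced parentheses: ", depth,
         " unclosed at end of string (position ", nchar(text), ")")
  }
  invisible(TRUE)
}

#' Parse a rooted gene tree from Newick text
#'
#' Leaf labels must be of the form `species<separator>gene`
#' (e.g. `"Eco-0042"`); the species part is everything before the first
#' occurrence of the separator.  The returned tree keeps polytomies and
#' the stored order of children, and carries an implicit super-root so
#' that the edge above the root (`e0`) participates in reconciliation.
#'
#' @param text a single Newick statement, e.g. `"(A-1,(B-1,C-2));"`.
#' @param separator string separating species from gene id (default `"-"`).
#' @param weight optional tree weight `k_j` used in total costs.
#' @return an object of class `gene_tree`.
#' @examples
#' g <- parse_gene_tree("(A-1,(B-1,C-2));")
#' gene_tree_newick(g)
#' @export
parse_gene_tree <- function(text, separator = "-", weight = 1) {
  check_newick_text(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("cannot parse Newick string: ", text)
  v <- phylo_to_vertices(phy)
  lab <- split_leaf_label(v$tip.label, separator)
  species <- rep(NA_character_, length(v$parent))
  gene <- rep(NA_character_, length(v$parent))
  species[seq_len(v$ntip)] <- lab$species
  gene[seq_len(v$ntip)] <- lab$gene
  new_gene_tree(v$parent, v$children, species, gene, separator, weight)
}

## Build an ape phylo from the internal representation (children order kept).
vertices_to_phylo <- function(parent, children, tip_label) {
  leaves <- which(lengths(children) == 0L)
  internal <- which(lengths(children) > 0L)
  root <- which(parent == 0L)[1]
  ntip <- length(leaves)
  id <- integer(length(parent))
  id[leaves] <- seq_len(ntip)
  id[root] <- ntip + 1L
  id[setdiff(internal, root)] <- ntip + 1L + seq_len(length(internal) - 1L)
  edge <- matrix(0L, nrow = length(parent) - 1L, ncol = 2)
  k <- 0L
  for (v in seq_along(parent)) {
    for (ch in children[[v]]) {
      k <- k + 1L
      edge[k, ] <- c(id[v], id[ch])
    }
  }
  structure(list(edge = edge, tip.label = tip_label[leaves],
                 Nnode = length(internal)),
            class = "phylo", order = "cladewise")
}

#' Serialize a gene tree back to Newick
#'
#' Children are written in stored order, so parsing and serializing are
#' inverse up to whitespace.
#'
#' @param tree a `gene_tree`.
#' @return a Newick string.
#' @export
gene_tree_newick <- function(tree) {
  lab <- ifelse(is.na(tree$species), "",
                paste0(tree$species, tree$separator, tree$gene))
  phy <- vertices_to_phylo(tree$parent, tree$children, lab)
  ape::write.tree(phy)
}

#' Create a forest of gene trees
#'
#' @param trees list of `gene_tree` objects (or Newick strings).
#' @param separator leaf-label separator used when parsing strings.
#' @param weights optional numeric vector of per-tree weights `k_j`.
#' @return an object of class `gene_forest` (a list of gene trees).
#' @export
gene_forest <- function(trees, separator = "-", weights = NULL) {
  if (is.character(trees)) trees <- as.list(trees)
  trees <- lapply(trees, function(t) {
    if (is.character(t)) parse_gene_tree(t, separator) else t
  })
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(trees))
    for (j in seq_along(trees)) trees[[j]]$weight <- weights[j]
  }
  structure(trees, class = "gene_forest")
}

#' @export
print.gene_forest <- function(x, ...) {
  cat("Gene forest:", length(x), "trees over",
      length(forest_species(x)), "species\n")
  invisible(x)
}

#' Read a forest from a Newick file (one tree per line)
#'
#' @param path file with one rooted Newick tree per line.
#' @inheritParams gene_forest
#' @export
read_gene_forest <- function(path, separator = "-") {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  gene_forest(lines, separator = separator)
}

#' Species universe of a forest
#'
#' @param forest a `gene_forest`.
#' @return sorted character vector of all species occurring at leaves.
#' @export
forest_species <- function(forest) {
  sort(unique(unlist(lapply(forest, function(t) t$species[is_leaf(t)]))))
}

## ---------------------------------------------------------------------------
## Rare-species pruning
## ---------------------------------------------------------------------------

## Occurrences of each species in one tree: the number of inextensible
## (maximal) monospecific subtrees.  A vertex v roots such a subtree when
## all leaves below v belong to one species while v's parent subtree does
## not (or v is the root).
tree_occurrences <- function(tree) {
  cl <- tree_clades(tree)
  mono <- vapply(cl, function(s) length(s) == 1L, logical(1))
  counts <- character(0)
  for (v in seq_along(cl)) {
    if (!mono[v]) next
    p <- tree$parent[v]
    if (p == 0L || !mono[p]) counts <- c(counts, cl[[v]])
  }
  table(factor(counts, levels = sort(unique(counts))))
}

#' Count species occurrences across a forest
#'
#' An occurrence of species `s` in a tree is an inextensible subtree all
#' of whose leaves belong to `s`; a cherry of two paralogs from the same
#' species is a single occurrence.
#'
#' @param forest a `gene_forest`.
#' @return named integer vector of occurrence counts per species.
#' @export
species_occurrences <- function(forest) {
  all <- forest_species(forest)
  counts <- setNames(integer(length(all)), all)
  for (tree in forest) {
    occ <- tree_occurrences(tree)
    counts[names(occ)] <- counts[names(occ)] + as.integer(occ)
  }
  counts
}

## Rebuild a tree keeping only the given leaves; unary vertices created by
## the removal are suppressed together with their (pendant) edges.
keep_leaves <- function(tree, keep) {
  build <- function(v) {
    if (length(tree$children[[v]]) == 0L) {
      if (keep[v]) return(list(species = tree$species[v],
                               gene = tree$gene[v]))
      return(NULL)
    }
    kids <- Filter(Negate(is.null), lapply(tree$children[[v]], build))
    if (length(kids) == 0L) return(NULL)
    if (length(kids) == 1L) return(kids[[1]])
    list(children = kids)
  }
  top <- build(tree$root)
  if (is.null(top)) return(NULL)
  nested_to_gene_tree(top, tree$separator, tree$weight)
}

## Convert a nested list (leaf: species/gene, internal: children) to a tree.
nested_to_gene_tree <- function(nested, separator = "-", weight = 1) {
  parent <- integer(0); children <- list()
  species <- character(0); gene <- character(0)
  add <- function(node, par) {
    id <- length(parent) + 1L
    parent[id] <<- par
    children[[id]] <<- integer(0)
    if (is.null(node$children)) {
      species[id] <<- node$species; gene[id] <<- node$gene
    } else {
      species[id] <<- NA_character_; gene[id] <<- NA_character_
      for (ch in node$children) {
        cid <- add(ch, id)
        children[[id]] <<- c(children[[id]], cid)
      }
    }
    id
  }
  add(nested, 0L)
  new_gene_tree(parent, children, species, gene, separator, weight)
}

#' Remove rarely occurring species from a forest
#'
#' Species with fewer than `p_min` occurrences over the whole forest are
#' removed from every tree; pendant edges are removed with their origin
#' vertices, and trees that become empty or monospecific are dropped.
#'
#' @param forest a `gene_forest`.
#' @param p_min minimum number of occurrences to retain a species
#'   (`p_min = 0` leaves the forest unchanged).
#' @return a pruned `gene_forest`.
#' @export
prune_rare_species <- function(forest, p_min) {
  stopifnot(p_min >= 0)
  if (p_min == 0 || length(forest) == 0) return(forest)
  occ <- species_occurrences(forest)
  keep_species <- names(occ)[occ >= p_min]
  out <- list()
  for (tree in forest) {
    keep <- !is.na(tree$species) & tree$species %in% keep_species
    keep <- keep | is.na(tree$species)
    keep[!is_leaf(tree)] <- FALSE
    pruned <- keep_leaves(tree, keep & is_leaf(tree))
    if (is.null(pruned)) next
    sp <- unique(pruned$species[is_leaf(pruned)])
    if (length(sp) < 2L) next
    out[[length(out) + 1L]] <- pruned
  }
  structure(out, class = "gene_forest")
}

## ---------------------------------------------------------------------------
## Rooting of unrooted trees
## ---------------------------------------------------------------------------

## Orient an unrooted ape phylo from a new root placed on edge k
## (row index into phy$edge); returns a nested-list rooted tree.
orient_from_edge <- function(phy, k, lab) {
  nb <- vector("list", max(phy$edge))
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1]; b <- phy$edge[i, 2]
    nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
  }
  ntip <- length(phy$tip.label)
  grow <- function(v, from) {
    kids <- setdiff(nb[[v]], from)
    if (v <= ntip && length(kids) == 0L) {
      return(list(species = lab$species[v], gene = lab$gene[v]))
    }
    list(children = lapply(kids, grow, from = v))
  }
  a <- phy$edge[k, 1]; b <- phy$edge[k, 2]
  list(children = list(grow(a, b), grow(b, a)))
}

#' Root an unrooted gene tree against a reference species tree
#'
#' Every edge of the unrooted tree is tried as the root position; the
#' rooting with the smallest reconciliation cost against the (sliced)
#' reference is returned, ties broken by edge enumeration order.  An
#' input that is already rooted (binary root) is passed through.
#'
#' @param text Newick string of the (possibly unrooted) tree.
#' @param reference a `sliced_tree` (see [build_slices()]).
#' @param costs an [event_costs()] object.
#' @param separator leaf-label separator.
#' @return a rooted `gene_tree`.
#' @export
root_unrooted <- function(text, reference, costs = event_costs(),
                          separator = "-") {
  check_newick_text(text)
  phy <- ape::read.tree(text = text)
  root_deg <- sum(phy$edge[, 1] == length(phy$tip.label) + 1L)
  if (root_deg == 2L) return(parse_gene_tree(text, separator))
  lab <- split_leaf_label(phy$tip.label, separator)
  missing <- setdiff(unique(lab$species), reference$species_names)
  if (length(missing) > 0) {
    stop("species absent from the reference tree: ",
         paste(missing, collapse = ", "))
  }
  best <- NULL; best_cost <- Inf
  for (k in seq_len(nrow(phy$edge))) {
    cand <- nested_to_gene_tree(orient_from_edge(phy, k, lab), separator)
    cand_b <- binarize(cand, reference, costs)
    cost <- reconcile_cost(cand_b, reference, costs)
    if (cost < best_cost) { best_cost <- cost; best <- cand }
  }
  best
}

## ---------------------------------------------------------------------------
## Binarization of polytomies
## ---------------------------------------------------------------------------

subtree_nested <- function(tree, v) {
  if (length(tree$children[[v]]) == 0L) {
    return(list(species = tree$species[v], gene = tree$gene[v]))
  }
  list(children = lapply(tree$children[[v]], subtree_nested, tree = tree))
}

nested_species <- function(node) {
  if (is.null(node$children)) return(node$species)
  sort(unique(unlist(lapply(node$children, nested_species))))
}

## Score of joining two subtrees during binarization: reconciliation cost
## of the standalone pair against the reference, or (without a reference)
## the symmetric difference of their species clades.
pair_score <- function(a, b, reference, costs, separator) {
  if (is.null(reference)) {
    ca <- nested_species(a); cb <- nested_species(b)
    return(length(setdiff(ca, cb)) + length(setdiff(cb, ca)))
  }
  pair <- nested_to_gene_tree(list(children = list(a, b)), separator)
  reconcile_cost(pair, reference, costs)
}

#' Resolve polytomies by greedy cost-driven agglomeration
#'
#' Each polytomous vertex is resolved by repeatedly joining the pair of
#' child subtrees whose standalone reconciliation cost against the
#' reference is smallest (ties broken by enumeration order).  Without a
#' reference the symmetric difference of species clades is used.  Binary
#' input is returned unchanged.
#'
#' @param tree a `gene_tree`.
#' @param reference optional `sliced_tree` guiding the resolution.
#' @param costs an [event_costs()] object (used with a reference).
#' @return a binary `gene_tree` with the same multiset of leaf labels.
#' @export
binarize <- function(tree, reference = NULL, costs = event_costs()) {
  if (all(lengths(tree$children) %in% c(0L, 2L))) return(tree)
  sep <- tree$separator
  resolve <- function(v) {
    if (length(tree$children[[v]]) == 0L) return(subtree_nested(tree, v))
    kids <- lapply(tree$children[[v]], resolve)
    while (length(kids) > 2L) {
      best <- c(1L, 2L); best_s <- Inf
      for (i in seq_len(length(kids) - 1L)) {
        for (j in seq(i + 1L, length(kids))) {
          s <- pair_score(kids[[i]], kids[[j]], reference, costs, sep)
          if (s < best_s) { best_s <- s; best <- c(i, j) }
        }
      }
      joined <- list(children = kids[best])
      kids[[best[1]]] <- joined
      kids <- kids[-best[2]]
    }
    if (length(kids) == 1L) return(kids[[1]])
    list(children = kids)
  }
  nested_to_gene_tree(resolve(tree$root), sep, tree$weight)
}
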