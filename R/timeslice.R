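## ---------------------------------------------------------------------------
## Species trees, the auxiliary outgroup and time slices
##
## A species tree is stored like a gene tree (parent / children / label)
## plus an integer segment count per vertex: the number of time-slice
## segments of the tube entering that vertex from above.  The sliced tree
## S0 is a table of tubes; tube ids double as the id of the vertex at the
## bottom of the tube, and the root tube d0 has no parent.
## ---------------------------------------------------------------------------

OUTGROUP_LABEL <- "d*"

new_species_tree <- function(parent, children, label, seglen,
                             outgroup = NA_integer_) {
  structure(
    list(parent = as.integer(parent), children = children,
         label = as.character(label), seglen = as.integer(seglen),
         root = which(parent == 0L)[1], outgroup = outgroup),
    class = "species_tree")
}

#' @export
print.species_tree <- function(x, ...) {
  leaves <- lengths(x$children) == 0L
  cat("Species tree:", sum(leaves), "leaves",
      if (!is.na(x$outgroup)) "(outgroup attached)" else "", "\n")
  invisible(x)
}

#' Read a species tree in the integer-length Newick dialect
#'
#' The branch "length" of each vertex, when present, is interpreted as
#' the integer number of time-slice segments of its incoming tube
#' (default 1, meaning no additional vertex is inserted).
#'
#' @param text a Newick string, or `file` a path to read it from.
#' @param file optional path to a file containing the tree.
#' @return an object of class `species_tree` (binary, rooted, without
#'   the auxiliary outgroup).
#' @export
read_species_tree <- function(text = NULL, file = NULL) {
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE),
                                   collapse = "")
  check_newick_text(text)
  phy <- ape::read.tree(text = text)
  v <- phylo_to_vertices(phy)
  label <- rep(NA_character_, length(v$parent))
  label[seq_len(v$ntip)] <- v$tip.label
  seglen <- rep(1L, length(v$parent))
  if (!is.null(phy$edge.length)) {
    for (i in seq_len(nrow(phy$edge))) {
      len <- phy$edge.length[i]
      if (!is.na(len)) seglen[phy$edge[i, 2]] <- as.integer(round(len))
    }
  }
  if (any(seglen < 1L)) stop("tube segment counts must be positive integers")
  st <- new_species_tree(v$parent, v$children, label, seglen)
  deg <- lengths(st$children)
  if (any(!deg %in% c(0L, 2L))) stop("species tree must be binary")
  st
}

## Build a species tree from a nested list (internal plumbing used by the
## supertree assembly): leaves are list(species = "x"), internal vertices
## list(children = list(...)).
species_tree_from_nested <- function(nested) {
  parent <- integer(0); children <- list(); label <- character(0)
  add <- function(node, par) {
    id <- length(parent) + 1L
    parent[id] <<- par; children[[id]] <<- integer(0)
    if (is.null(node$children)) {
      label[id] <<- node$species
    } else {
      label[id] <<- NA_character_
      for (ch in node$children) {
        cid <- add(ch, id)
        children[[id]] <<- c(children[[id]], cid)
      }
    }
    id
  }
  add(nested, 0L)
  new_species_tree(parent, children, label, rep(1L, length(parent)))
}

species_tree_nested <- function(st, v = st$root) {
  if (length(st$children[[v]]) == 0L) return(list(species = st$label[v]))
  list(children = lapply(st$children[[v]], species_tree_nested, st = st))
}

#' Serialize a species tree to Newick (with segment counts)
#'
#' @param st a `species_tree`.
#' @param lengths write segment counts as branch lengths.
#' @export
species_tree_newick <- function(st, lengths = FALSE) {
  phy <- vertices_to_phylo(st$parent, st$children, st$label)
  if (lengths) {
    el <- numeric(nrow(phy$edge))
    leaves <- which(lengths(st$children) == 0L)
    internal <- setdiff(seq_along(st$parent), leaves)
    id <- integer(length(st$parent))
    id[leaves] <- seq_along(leaves)
    ## mirror the numbering used in vertices_to_phylo
    id[st$root] <- length(leaves) + 1L
    id[setdiff(internal, st$root)] <-
      length(leaves) + 1L + seq_len(length(internal) - 1L)
    for (i in seq_len(nrow(phy$edge))) {
      v <- which(id == phy$edge[i, 2])
      el[i] <- st$seglen[v]
    }
    phy$edge.length <- el
  }
  ape::write.tree(phy)
}

#' Attach the auxiliary outgroup leaf and the root tube
#'
#' A new root is created above the old root; its children are the old
#' root and the outgroup leaf `d*`.  The root tube `d0` enters the new
#' root from above and always occupies its own topmost time slice.
#'
#' @param st a `species_tree` without outgroup.
#' @return a `species_tree` with the outgroup recorded.
#' @export
attach_outgroup <- function(st) {
  if (any(!is.na(st$label) & st$label == OUTGROUP_LABEL)) {
    stop("tree already contains the reserved outgroup leaf '",
         OUTGROUP_LABEL, "'")
  }
  n <- length(st$parent)
  parent <- c(st$parent, n + 2L, 0L)          # outgroup leaf, new root
  parent[st$root] <- n + 2L
  children <- c(st$children, list(integer(0)), list(c(st$root, n + 1L)))
  label <- c(st$label, OUTGROUP_LABEL, NA_character_)
  seglen <- c(st$seglen, 1L, 1L)
  new_species_tree(parent, children, label, seglen, outgroup = n + 1L)
}

#' Build the time-sliced species tree S0
#'
#' In `auto` mode the tree is sliced so that every leaf, including the
#' outgroup, lies at the common maximal depth `h`: leaf tubes are
#' subdivided into as many segments as needed, internal tubes keep one
#' segment per unit depth, and the root tube `d0` forms its own topmost
#' slice, giving `h + 1` slices in total.  In `explicit` mode the stored
#' per-tube segment counts are honored and must give every root-to-leaf
#' path the same number of slices.
#'
#' @param st a `species_tree`; the outgroup is attached automatically if
#'   absent.
#' @param mode `"auto"` (default) or `"explicit"`.
#' @return an object of class `sliced_tree`.
#' @examples
#' s0 <- build_slices(read_species_tree("((1,2),3);"))
#' s0$n_slices  # four slices
#' @export
build_slices <- function(st, mode = c("auto", "explicit")) {
  mode <- match.arg(mode)
  if (is.na(st$outgroup)) st <- attach_outgroup(st)
  R <- st$root
  leaves <- which(lengths(st$children) == 0L)
  ## vertex depth in tube units below R, using stored segment counts in
  ## explicit mode and unit counts in auto mode
  depth <- integer(length(st$parent))
  order_down <- rev(postorder_species(st))
  for (v in order_down) {
    if (v == R) { depth[v] <- 0L; next }
    step <- if (mode == "explicit") st$seglen[v] else 1L
    depth[v] <- depth[st$parent[v]] + step
  }
  ingroup_leaves <- setdiff(leaves, st$outgroup)
  h <- max(depth[ingroup_leaves])
  seg <- st$seglen
  if (mode == "auto") {
    seg[] <- 1L
    for (v in leaves) seg[v] <- h - depth[st$parent[v]]
    if (any(seg[leaves] < 1L)) stop("inconsistent leaf depths")
  } else {
    if (any(depth[ingroup_leaves] != h)) {
      stop("explicit segment counts give root-to-leaf paths of unequal ",
           "slice counts")
    }
    ## the auto-attached outgroup tube is stretched to match
    seg[st$outgroup] <- h
  }
  ## create tubes: d0 first (slice 1), then chains of segments per vertex
  tp <- integer(0); tch <- list(); tslice <- integer(0)
  togr <- logical(0); tterm <- logical(0); tsp <- character(0)
  told <- integer(0)
  new_tube <- function(parent, slice, ogr, term, sp, old) {
    id <- length(tp) + 1L
    tp[id] <<- parent; tch[[id]] <<- integer(0)
    tslice[id] <<- slice; togr[id] <<- ogr; tterm[id] <<- term
    tsp[id] <<- sp; told[id] <<- old
    if (parent > 0L) tch[[parent]] <<- c(tch[[parent]], id)
    id
  }
  d0 <- new_tube(0L, 1L, FALSE, FALSE, NA_character_, R)
  walk <- function(v, parent_tube) {
    ## chain of seg[v] tubes for the tube entering vertex v
    is_ogr <- !is.na(st$outgroup) && v == st$outgroup
    is_leaf <- length(st$children[[v]]) == 0L
    cur <- parent_tube
    for (s in seq_len(seg[v])) {
      last <- s == seg[v]
      cur <- new_tube(cur, tslice[cur] + 1L, is_ogr,
                      is_leaf && last,
                      if (is_leaf && last) st$label[v] else NA_character_,
                      v)
    }
    for (ch in st$children[[v]]) walk(ch, cur)
  }
  ## keep the in-group before the outgroup in d0's children order
  for (ch in c(setdiff(st$children[[R]], st$outgroup), st$outgroup)) {
    walk(ch, d0)
  }
  n_slices <- max(tslice)
  slices <- split(seq_along(tp), tslice)
  ogr_in_slice <- rep(NA_integer_, n_slices)
  for (s in seq_len(n_slices)) {
    og <- intersect(slices[[s]], which(togr))
    if (length(og) == 1L) ogr_in_slice[s] <- og
  }
  sliced <- structure(
    list(n = length(tp), parent = tp, children = tch, slice = tslice,
         is_outgroup = togr, terminal = tterm, species = tsp,
         old_tube = told, root_tube = d0, n_slices = n_slices,
         slices = slices, outgroup_in_slice = ogr_in_slice,
         species_names = sort(st$label[setdiff(which(!is.na(st$label)),
                                               st$outgroup)]),
         outgroup_label = OUTGROUP_LABEL,
         species_tree = st),
    class = "sliced_tree")
  sliced$dist <- tube_distances(sliced)
  sliced
}

postorder_species <- function(st) {
  out <- integer(0)
  walk <- function(v) {
    for (ch in st$children[[v]]) walk(ch)
    out[[length(out) + 1L]] <<- v
  }
  walk(st$root)
  unlist(out)
}

#' @export
print.sliced_tree <- function(x, ...) {
  cat("Sliced species tree:", x$n, "tubes in", x$n_slices, "slices over",
      length(x$species_names), "species\n")
  invisible(x)
}

#' One-call slicing of a plain species tree
#'
#' Convenience wrapper: parse (if needed), attach the outgroup and build
#' slices in auto mode.
#'
#' @param tree a Newick string or a `species_tree`.
#' @return a `sliced_tree`.
#' @export
slice_species_tree <- function(tree) {
  if (is.character(tree)) tree <- read_species_tree(tree)
  build_slices(tree, mode = "auto")
}

## Pairwise distances between tubes: the number of tubes on the path
## between the tubes' parent vertices (the parent vertex of a tube is the
## bottom vertex of its parent tube; 0 above d0).  Used for the "closest
## to d" tie-break of transfer donors.
tube_distances <- function(s0) {
  ## vertices are tube ids (= bottom vertex of the tube) plus 0; the
  ## parent vertex of tube d is s0$parent[d]
  n <- s0$n
  vdepth <- integer(n + 1L)       # depth of vertex id (index shifted by 1)
  for (d in seq_len(n)) vdepth[d + 1L] <- s0$slice[d]
  vparent <- c(NA_integer_, s0$parent)  # vertex d's parent vertex
  vdist <- function(a, b) {
    steps <- 0L
    while (a != b) {
      if (vdepth[a + 1L] >= vdepth[b + 1L]) {
        a <- vparent[a + 1L]
      } else {
        b <- vparent[b + 1L]
      }
      steps <- steps + 1L
    }
    steps
  }
  m <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        m[i, j] <- vdist(s0$parent[i], s0$parent[j])
        m[j, i] <- m[i, j]
      }
    }
  }
  m
}

#' Tubes sharing a time slice
#'
#' Lists the tubes in the same slice as `d`, excluding `d` itself and,
#' when `transfer_target = TRUE`, excluding the outgroup segment (no
#' transfer ever targets the outgroup).
#'
#' @param s0 a `sliced_tree`.
#' @param d a tube id.
#' @param transfer_target drop outgroup segments from the result.
#' @return integer vector of tube ids.
#' @export
same_slice_tubes <- function(s0, d, transfer_target = TRUE) {
  out <- setdiff(s0$slices[[s0$slice[d]]], d)
  if (transfer_target) out <- out[!s0$is_outgroup[out]]
  out
}

#' Aggregate per-tube statistics to the original tubes
#'
#' Time slicing subdivides each tube of the input species tree into
#' segments; this sums a per-segment statistic back over each original
#' tube.
#'
#' @param s0 a `sliced_tree`.
#' @param values numeric vector with one entry per tube of `s0` (in tube
#'   id order), or named by tube id.
#' @return named numeric vector, one entry per original tube; names are
#'   the original tube labels (species name for terminal tubes,
#'   `"tube<vertex>"` otherwise).
#' @export
aggregate_by_old_tube <- function(s0, values) {
  if (!is.null(names(values))) {
    idx <- as.integer(names(values))
    if (anyNA(idx) || !all(idx %in% seq_len(s0$n))) {
      stop("names of 'values' must be tube ids of the sliced tree")
    }
    full <- numeric(s0$n)
    full[idx] <- values
    values <- full
  }
  if (length(values) != s0$n) {
    stop("'values' must provide one entry per tube (", s0$n, ")")
  }
  st <- s0$species_tree
  olds <- sort(unique(s0$old_tube))
  out <- vapply(olds, function(o) sum(values[s0$old_tube == o]),
                numeric(1))
  lab <- ifelse(is.na(st$label[olds]), paste0("tube", olds),
                st$label[olds])
  lab[olds == st$root] <- "d0"
  setNames(out, lab)
}
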