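## ---------------------------------------------------------------------------
## Reconciliation of a gene tree into the sliced species tree
## ---------------------------------------------------------------------------

#' Elementary event costs
#'
#' Nonnegative costs of the elementary evolutionary events.  The
#' defaults make losses cheapest and transfers and gains costlier;
#' `gain_big` (origin of the common ancestor of the whole family) is
#' free by default so that a family may enter the species tree below the
#' root without penalty.  All costs are dimensionless.
#'
#' @param loss cost of a gene loss.
#' @param dupl cost of a gene duplication.
#' @param gain cost of a gene gain (emergence from the outgroup).
#' @param tr_with cost of a horizontal transfer with retention in the
#'   donor.
#' @param tr_without cost of a horizontal transfer without retention.
#' @param sleep cost of the gene going dormant (into the outgroup).
#' @param gain_big cost of the origin of the family's common ancestor.
#' @return an object of class `event_costs` (named numeric vector).
#' @export
event_costs <- function(loss = 1, dupl = 2, gain = 3, tr_with = 3,
                        tr_without = 3, sleep = 1, gain_big = 0) {
  v <- c(loss = loss, dupl = dupl, gain = gain, tr_with = tr_with,
         tr_without = tr_without, sleep = sleep, gain_big = gain_big)
  if (any(v < 0)) stop("event costs must be nonnegative")
  structure(v, class = "event_costs")
}

EVENT_NAMES <- c(
  "fin", "tr_fin", "ga_fin", "pass", "fork_lr", "fork_rl", "pass_l",
  "pass_r", "nout_l", "nout_r", "out_l", "out_r", "dupl", "dup0", "outd",
  "tr1", "tr2", "ga1", "ga2", "sl", "ga_big", "tr_pass", "ga_pass",
  "tr_lr", "tr_rl", "ga_lr", "ga_rl", "tr_l", "tr_r", "ga_l", "ga_r",
  "tr_dupl", "ga_dupl", "tr_double", "ga_double")

## Map each gene-tree leaf to the terminal tube of its species.
leaf_tubes <- function(tree, s0) {
  term <- which(s0$terminal & !s0$is_outgroup)
  map <- setNames(term, s0$species[term])
  lt <- rep(NA_integer_, n_vertices(tree))
  leaves <- which(is_leaf(tree))
  missing <- setdiff(unique(tree$species[leaves]), names(map))
  if (length(missing) > 0) {
    stop("gene-tree species missing from the species tree: ",
         paste(missing, collapse = ", "))
  }
  lt[leaves] <- map[tree$species[leaves]]
  lt
}

gene_to_cpp <- function(tree, s0) {
  if (!all(lengths(tree$children) %in% c(0L, 2L))) {
    stop("gene tree must be binary; call binarize() first")
  }
  list(children = tree$children, order = postorder(tree),
       root = tree$root, leaf_tube = leaf_tubes(tree, s0))
}

#' Reconciliation cost of one gene tree
#'
#' The minimal total cost `c(G, S)` of embedding the gene tree into the
#' sliced species tree, i.e. the root cell `c_min(e0, d0)` of the
#' dynamic program over the 35 event types.
#'
#' @param tree a binary `gene_tree`.
#' @param s0 a `sliced_tree`.
#' @param costs an [event_costs()] object.
#' @return nonnegative numeric cost.
#' @examples
#' s0 <- slice_species_tree("(A,B);")
#' reconcile_cost(parse_gene_tree("(A-1,B-2);"), s0)  # 0
#' @export
reconcile_cost <- function(tree, s0, costs = event_costs()) {
  res <- cpp_reconcile(gene_to_cpp(tree, s0), s0, unclass(costs),
                       full = FALSE)
  if (!is.finite(res$cost)) stop("unsolvable reconciliation instance")
  res$cost
}

#' Total reconciliation cost of a forest
#'
#' Sum of per-tree costs, optionally weighted by the tree weights `k_j`
#' stored in the forest.
#'
#' @param forest a `gene_forest` of binary trees.
#' @param s0 a `sliced_tree`.
#' @param costs an [event_costs()] object.
#' @param per_tree return the vector of per-tree costs instead of the
#'   weighted sum.
#' @export
total_cost <- function(forest, s0, costs = event_costs(),
                       per_tree = FALSE) {
  if (length(forest) == 0) return(0)
  genes <- lapply(forest, gene_to_cpp, s0 = s0)
  v <- cpp_total_costs(genes, s0, unclass(costs))
  if (per_tree) return(v)
  w <- vapply(forest, function(t) t$weight, numeric(1))
  sum(w * v)
}

#' Event types applicable at a gene-edge / tube pair
#'
#' Pure transcription of the applicability conditions of the 35 event
#' rows; independent of costs.  Row indices follow the published
#' numbering 0-34 (see `EVENT_NAMES` for names).
#'
#' @param e a gene-tree edge (vertex id below the edge; the root id
#'   denotes the root edge e0).
#' @param d a tube id of `s0`.
#' @param tree a `gene_tree`.
#' @param s0 a `sliced_tree`.
#' @return sorted integer vector of applicable row indices (0-based).
#' @export
applicable_events <- function(e, d, tree, s0) {
  lt <- leaf_tubes(tree, s0)
  leafE <- length(tree$children[[e]]) == 0L
  bifE <- length(tree$children[[e]]) == 2L
  isE0 <- e == tree$root
  isD0 <- d == s0$root_tube
  ogr <- s0$is_outgroup[d]
  term <- s0$terminal[d]
  ch <- s0$children[[d]]
  nchD <- length(ch)
  rows <- integer(0)
  add <- function(i) rows <<- c(rows, i)
  if (leafE && term) {
    if (!is.na(lt[e]) && d == lt[e]) add(0L)
    else if (!ogr) add(1L) else add(2L)
  }
  if (nchD == 1L) add(3L)
  if (bifE && nchD == 2L) { add(4L); add(5L) }
  if (!isD0 && nchD == 2L) { add(6L); add(7L) }
  if (isD0 && nchD == 2L) {
    og1 <- s0$is_outgroup[ch[1]]; og2 <- s0$is_outgroup[ch[2]]
    if (!og1 && og2) { add(8L); add(11L) }
    if (og1 && !og2) { add(9L); add(10L) }
  }
  if (bifE && !ogr) add(12L)
  if (bifE && isD0) add(13L)
  if (bifE && ogr) add(14L)
  ss <- same_slice_tubes(s0, d, transfer_target = TRUE)
  has_ss <- length(ss) > 0L
  ss1 <- ss[vapply(ss, function(t) length(s0$children[[t]]) == 1L,
                   logical(1))]
  ss2 <- ss[vapply(ss, function(t) length(s0$children[[t]]) == 2L,
                   logical(1))]
  if (bifE && !ogr && !isD0 && has_ss) { add(15L); add(16L) }
  if (bifE && ogr && has_ss) { add(17L); add(18L) }
  if (!isE0 && !ogr && !isD0 && !term &&
      !is.na(s0$outgroup_in_slice[s0$slice[d]])) add(19L)
  if (isE0 && ogr && has_ss) add(20L)
  trR <- !ogr && !isD0
  gaR <- ogr && !isE0
  if (trR && length(ss1) > 0L) add(21L)
  if (gaR && length(ss1) > 0L) add(22L)
  if (trR && bifE && length(ss2) > 0L) { add(23L); add(24L) }
  if (gaR && bifE && length(ss2) > 0L) { add(25L); add(26L) }
  if (trR && length(ss2) > 0L) { add(27L); add(28L) }
  if (gaR && length(ss2) > 0L) { add(29L); add(30L) }
  if (trR && bifE && has_ss) add(31L)
  if (gaR && bifE && has_ss) add(32L)
  if (trR && bifE && length(ss) > 1L) add(33L)
  if (gaR && bifE && length(ss) > 1L) add(34L)
  sort(rows)
}

#' Full dynamic-programming table with backpointers
#'
#' Computes every cell `c_min(e, d)` together with the per-row costs and
#' minimal parameters needed to reconstruct scenarios.
#'
#' @inheritParams reconcile_cost
#' @return an object of class `cost_matrix` with elements `cost` (the
#'   root cell `c(G, S)`), `cmin` (edges x tubes matrix), `rowcost`,
#'   `par1`, `par2` (35 x tubes x edges arrays) and the inputs.
#' @export
compute_cost_matrix <- function(tree, s0, costs = event_costs()) {
  res <- cpp_reconcile(gene_to_cpp(tree, s0), s0, unclass(costs),
                       full = TRUE)
  if (!is.finite(res$cost)) {
    bad <- which(!is.finite(res$cmin), arr.ind = TRUE)
    stop("unsolvable cell(s) at edge/tube pair(s): ",
         paste(apply(head(bad, 3), 1, paste, collapse = "/"),
               collapse = ", "))
  }
  structure(list(cost = res$cost, cmin = res$cmin,
                 rowcost = res$rowcost, par1 = res$par1, par2 = res$par2,
                 tree = tree, s0 = s0, costs = costs),
            class = "cost_matrix")
}

#' @export
print.cost_matrix <- function(x, ...) {
  cat("Reconciliation cost matrix:", nrow(x$cmin), "edges x",
      ncol(x$cmin), "tubes; c(G,S) =", x$cost, "\n")
  invisible(x)
}

## Row chosen at a cell under a mode restriction (free / noout / out);
## ties resolved by the lowest row index (rows are enumerated 0..34).
cell_choice <- function(cm, e, d, mode = "free") {
  rc <- cm$rowcost[, d, e]
  keep <- switch(mode,
    free = rep(TRUE, 35),
    noout = !(seq_len(35) %in% c(11L, 12L)),   # rows 10,11 are 0-based
    out = seq_len(35) %in% c(11L, 12L))
  rc[!keep] <- Inf
  i <- which.min(rc)          # first minimum = lowest row index
  list(row = i - 1L, cost = rc[i], par1 = cm$par1[i, d, e],
       par2 = cm$par2[i, d, e])
}

## Termini of the edge projected by event `row` from vertex <e, d>.
## Returns a list of (e, d, mode) children; empty for row 0.
event_termini <- function(row, e, d, par1, par2, tree, s0, lt) {
  ch <- tree$children[[e]]
  dd <- s0$children[[d]]
  isD0 <- d == s0$root_tube
  kid <- function(e, d, mode = "free") list(e = e, d = d, mode = mode)
  switch(as.character(row),
    "0" = list(),
    "1" = list(kid(e, lt[e])),
    "2" = list(kid(e, lt[e])),
    "3" = list(kid(e, dd[1])),
    "4" = list(kid(ch[1], dd[1]), kid(ch[2], dd[2])),
    "5" = list(kid(ch[2], dd[1]), kid(ch[1], dd[2])),
    "6" = list(kid(e, dd[1])),
    "7" = list(kid(e, dd[2])),
    "8" = list(kid(e, dd[1])),
    "9" = list(kid(e, dd[2])),
    "10" = list(kid(e, dd[1])),
    "11" = list(kid(e, dd[2])),
    "12" = list(kid(ch[1], d, if (isD0) "noout" else "free"),
                kid(ch[2], d, if (isD0) "noout" else "free")),
    "13" = list(kid(ch[1], d, if (par1 == 1) "out" else "free"),
                kid(ch[2], d, if (par1 == 2) "out" else "free")),
    "14" = list(kid(ch[1], d), kid(ch[2], d)),
    "15" = list(kid(ch[1], par1), kid(ch[2], d)),
    "16" = list(kid(ch[2], par1), kid(ch[1], d)),
    "17" = list(kid(ch[1], par1), kid(ch[2], d)),
    "18" = list(kid(ch[2], par1), kid(ch[1], d)),
    "19" = list(kid(e, par1)),
    "20" = list(kid(e, par1)),
    "21" = list(kid(e, s0$children[[par1]][1])),
    "22" = list(kid(e, s0$children[[par1]][1])),
    "23" = list(kid(ch[1], s0$children[[par1]][1]),
                kid(ch[2], s0$children[[par1]][2])),
    "24" = list(kid(ch[1], s0$children[[par1]][2]),
                kid(ch[2], s0$children[[par1]][1])),
    "25" = list(kid(ch[1], s0$children[[par1]][1]),
                kid(ch[2], s0$children[[par1]][2])),
    "26" = list(kid(ch[1], s0$children[[par1]][2]),
                kid(ch[2], s0$children[[par1]][1])),
    "27" = list(kid(e, s0$children[[par1]][1])),
    "28" = list(kid(e, s0$children[[par1]][2])),
    "29" = list(kid(e, s0$children[[par1]][1])),
    "30" = list(kid(e, s0$children[[par1]][2])),
    "31" = list(kid(ch[1], par1), kid(ch[2], par1)),
    "32" = list(kid(ch[1], par1), kid(ch[2], par1)),
    "33" = list(kid(ch[1], par1), kid(ch[2], par2)),
    "34" = list(kid(ch[1], par1), kid(ch[2], par2)),
    stop("unknown event row ", row))
}

#' Build the first-scenario event tree by backtracking
#'
#' The backward run starts from the root pair `<e0, d0>` and projects,
#' at each vertex, the unary or binary edge recorded by the dynamic
#' program, tagged with its event row.  The cost of the event tree
#' equals `c(G, S)`.
#'
#' @param cm a `cost_matrix` from [compute_cost_matrix()].
#' @return an object of class `event_tree`: a list with `vertices`
#'   (data frame `e`, `d`), `edges` (data frame `from`, `event`,
#'   `name`, `par1`, `par2`, `to1`, `to2`) and `cost`.
#' @export
build_event_tree <- function(cm) {
  tree <- cm$tree; s0 <- cm$s0
  lt <- leaf_tubes(tree, s0)
  vert_e <- integer(0); vert_d <- integer(0)
  edges <- list()
  new_vertex <- function(e, d) {
    vert_e[[length(vert_e) + 1L]] <<- e
    vert_d[[length(vert_d) + 1L]] <<- d
    length(vert_e)
  }
  expand <- function(e, d, mode) {
    v <- new_vertex(e, d)
    leafE <- length(tree$children[[e]]) == 0L
    cohered <- leafE && s0$terminal[d] && !is.na(lt[e]) && d == lt[e]
    if (cohered) return(v)     # sink: row 0 projects nothing
    pick <- cell_choice(cm, e, d, mode)
    kids <- event_termini(pick$row, e, d, pick$par1, pick$par2,
                          tree, s0, lt)
    to <- vapply(kids, function(k) expand(k$e, k$d, k$mode), integer(1))
    edges[[length(edges) + 1L]] <<- list(
      from = v, event = pick$row, name = EVENT_NAMES[pick$row + 1L],
      par1 = pick$par1, par2 = pick$par2,
      to1 = if (length(to) >= 1) to[1] else NA_integer_,
      to2 = if (length(to) >= 2) to[2] else NA_integer_)
    v
  }
  expand(tree$root, s0$root_tube, "free")
  gi <- function(f) vapply(edges, function(x) as.integer(x[[f]]),
                           integer(1))
  ed <- if (length(edges) > 0) {
    data.frame(from = gi("from"), event = gi("event"),
               name = vapply(edges, `[[`, character(1), "name"),
               par1 = gi("par1"), par2 = gi("par2"),
               to1 = gi("to1"), to2 = gi("to2"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(from = integer(0), event = integer(0),
               name = character(0), par1 = integer(0), par2 = integer(0),
               to1 = integer(0), to2 = integer(0))
  }
  structure(list(vertices = data.frame(e = unlist(vert_e),
                                       d = unlist(vert_d)),
                 edges = ed, cost = cm$cost, tree = tree, s0 = s0,
                 costs = cm$costs),
            class = "event_tree")
}

#' @export
print.event_tree <- function(x, ...) {
  cat("Event tree:", nrow(x$vertices), "vertices,", nrow(x$edges),
      "tagged edges; cost =", x$cost, "\n")
  tab <- table(x$edges$name)
  tab <- tab[!names(tab) %in% c("fin", "pass", "fork_lr", "fork_rl",
                                "nout_l", "nout_r")]
  if (length(tab) > 0) {
    cat("  events:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

## Rows that terminate the gene-tree edge (children are e1/e2 or the
## induction ends); all other rows continue the same edge.
TERMINAL_ROWS <- c(0:2, 4:5, 12:18, 23:26, 31:34)

#' Tube paths of gene-tree edges (mapping beta)
#'
#' For each gene-tree edge `e`, the ordered list of tubes that vertices
#' `<e, d>` of the event tree occupy, from root-ward to leaf-ward,
#' together with the final event that terminates the edge.
#'
#' @param et an `event_tree`.
#' @return a list keyed by gene-tree edge id; each element has `tubes`
#'   (integer vector) and `final` (event row index).
#' @export
beta_mapping <- function(et) {
  verts <- et$vertices
  edges <- et$edges
  out <- list()
  ## successor vertex of a T-vertex along the same gene edge, or NA
  nxt <- rep(NA_integer_, nrow(verts))
  fin <- rep(NA_integer_, nrow(verts))
  for (i in seq_len(nrow(edges))) {
    v <- edges$from[i]
    if (edges$event[i] %in% TERMINAL_ROWS &&
        !edges$event[i] %in% c(1L, 2L)) {
      fin[v] <- edges$event[i]
    } else if (edges$event[i] %in% c(1L, 2L)) {
      ## rows 1-2 continue into the cohered pair, then end with fin
      nxt[v] <- edges$to1[i]
      fin[v] <- NA_integer_
    } else {
      nxt[v] <- edges$to1[i]
    }
  }
  starts <- rep(TRUE, nrow(verts))
  starts[nxt[!is.na(nxt)]] <- FALSE
  ## vertices that begin a new edge chain: the root and every terminus of
  ## a terminal (edge-consuming) event
  for (v in which(starts)) {
    chain <- integer(0)
    cur <- v
    final <- 0L
    repeat {
      chain <- c(chain, verts$d[cur])
      i <- which(edges$from == cur)
      if (length(i) == 1 && edges$event[i] %in% c(1L, 2L)) {
        final <- edges$event[i]
      } else if (length(i) == 1 && edges$event[i] %in% TERMINAL_ROWS) {
        final <- edges$event[i]
      }
      if (is.na(nxt[cur])) break
      cur <- nxt[cur]
    }
    key <- as.character(verts$e[v])
    out[[key]] <- list(tubes = chain, final = final,
                       final_name = EVENT_NAMES[final + 1L])
  }
  out
}

#' Per-tube event counts of the first scenario
#'
#' Counts charged events (per the second-scenario tag definitions, with
#' unit mass on every event-tree edge) in each tube, optionally
#' aggregated to the original tubes.
#'
#' @param et an `event_tree`.
#' @param tags character vector of tags to count (default: all).
#' @param aggregate sum segment counts back to the original tubes.
#' @return numeric vector of counts per tube.
#' @export
event_counts <- function(et, tags = SCENARIO_TAGS, aggregate = FALSE) {
  counts <- numeric(et$s0$n)
  tt <- flatten_triplets(et$edges, et$vertices, et$s0, et$tree,
                         rep(1, nrow(et$edges)))$tubes
  sel <- tt$tag %in% tags & !is.na(tt$tube)
  if (any(sel)) {
    agg <- tapply(tt$mass[sel], tt$tube[sel], sum)
    counts[as.integer(names(agg))] <- agg
  }
  if (aggregate) aggregate_by_old_tube(et$s0, counts) else counts
}
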