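## ---------------------------------------------------------------------------
## Second scenario: a k-best DAG with probabilities and expectations
## ---------------------------------------------------------------------------

#' Event tags of the second scenario design
#'
#' Tags classify what each projected DAG edge does to the gene and where:
#' `gain` (gene gain), `gain_big` (origin of the family's common
#' ancestor), `dupl`, `loss`, `sleep` (dormancy), `tr+o` / `tr-o`
#' (transfer out of a tube with / without retention), `tr+i` / `tr-i`
#' (transfer into a tube with / without retention) and `loss-` (loss of
#' the transferred copy in the donor).
#'
#' @format character vector of the ten known tags.
#' @export
SCENARIO_TAGS <- c("gain", "gain_big", "dupl", "loss", "sleep",
                   "tr+o", "tr-o", "tr+i", "tr-i", "loss-")

## Per-tag elementary costs used by cost expectations.  A transfer
## without retention is charged once, on its "out of the donor" side;
## the bundled loss of the donor copy (loss-) therefore carries no
## separate cost.
tag_cost <- function(tag, costs) {
  switch(tag,
    "gain" = costs[["gain"]], "gain_big" = costs[["gain_big"]],
    "dupl" = costs[["dupl"]], "loss" = costs[["loss"]],
    "sleep" = costs[["sleep"]],
    "tr+o" = costs[["tr_with"]], "tr+i" = costs[["tr_with"]],
    "tr-o" = costs[["tr_without"]], "tr-i" = costs[["tr_without"]],
    "loss-" = 0,
    stop("unknown tag ", tag))
}

## Symbolic tag-triplet table: per event row, a list of
## (tag, edge reference, tube reference).  Edge references: e, e1, e2 or
## the composite e12 (half weight each); tube references: d, x (cohered
## terminal tube), d1/d2 (children of d), dp (the donor d'), dp1/dp2
## (children of d'), dpp (d"), dp12 (composite d'&d", half weight each).
TAG_TABLE <- list(
  "1" = list(c("tr-o", "e", "d"), c("tr-i", "e", "x"),
             c("loss-", "e", "d")),
  "2" = list(c("gain", "e", "x")),
  "6" = list(c("loss", "e", "d2")),
  "7" = list(c("loss", "e", "d1")),
  "12" = list(c("dupl", "e", "d")),
  "15" = list(c("tr+o", "e1", "d"), c("tr+i", "e1", "dp")),
  "16" = list(c("tr+o", "e2", "d"), c("tr+i", "e2", "dp")),
  "17" = list(c("gain", "e1", "dp")),
  "18" = list(c("gain", "e2", "dp")),
  "19" = list(c("sleep", "e", "d")),
  "20" = list(c("gain_big", "e", "dp")),
  "21" = list(c("tr-o", "e", "d"), c("tr-i", "e", "dp"),
              c("loss-", "e", "d")),
  "22" = list(c("gain", "e", "dp")),
  "23" = list(c("tr-o", "e", "d"), c("tr-i", "e", "dp"),
              c("loss-", "e", "d")),
  "24" = list(c("tr-o", "e", "d"), c("tr-i", "e", "dp"),
              c("loss-", "e", "d")),
  "25" = list(c("gain", "e", "dp")),
  "26" = list(c("gain", "e", "dp")),
  "27" = list(c("tr-o", "e", "d"), c("tr-i", "e", "dp"),
              c("loss-", "e", "d"), c("loss", "e", "dp2")),
  "28" = list(c("tr-o", "e", "d"), c("tr-i", "e", "dp"),
              c("loss-", "e", "d"), c("loss", "e", "dp1")),
  "29" = list(c("gain", "e", "dp"), c("loss", "e", "dp2")),
  "30" = list(c("gain", "e", "dp"), c("loss", "e", "dp1")),
  "31" = list(c("tr-o", "e", "d"), c("tr-i", "e", "dp"),
              c("loss-", "e", "d"), c("dupl", "e", "dp")),
  "32" = list(c("gain", "e", "dp"), c("dupl", "e", "dp")),
  "33" = list(c("tr-o", "e", "d"), c("loss-", "e", "d"),
              c("tr-i", "e", "dp12"), c("tr+o", "e12", "dp12"),
              c("tr+i", "e12", "dp12")),
  "34" = list(c("gain", "e", "dp12"), c("tr+o", "e12", "dp12"),
              c("tr+i", "e12", "dp12")))

## Resolve the symbolic triplets of one scenario edge into concrete gene
## edges and tubes with their halving weights.  `edge` is one row of an
## edges data frame with columns from/event/par1/par2, `vertices` maps
## vertex ids to (e, d).  `tree` supplies gene-edge children and `lt`
## the cohered tubes.
edge_tag_triplets <- function(edge, vertices, s0, tree = NULL,
                              lt = NULL) {
  trs <- TAG_TABLE[[as.character(edge$event)]]
  if (is.null(trs)) return(list())
  e <- vertices$e[edge$from]
  d <- vertices$d[edge$from]
  ch <- if (!is.null(tree)) tree$children[[e]] else NULL
  dd <- s0$children[[d]]
  dp <- edge$par1
  dpc <- if (!is.na(dp) && dp <= s0$n) s0$children[[dp]] else NULL
  out <- vector("list", length(trs))
  for (i in seq_along(trs)) {
    t3 <- trs[[i]]
    eref <- switch(t3[2],
      "e" = list(ids = e, frac = 1),
      "e1" = list(ids = ch[1], frac = 1),
      "e2" = list(ids = ch[2], frac = 1),
      "e12" = list(ids = ch, frac = 0.5))
    dref <- switch(t3[3],
      "d" = list(ids = d, frac = 1),
      "x" = list(ids = if (!is.null(lt)) lt[e] else NA_integer_,
                 frac = 1),
      "d1" = list(ids = dd[1], frac = 1),
      "d2" = list(ids = dd[2], frac = 1),
      "dp" = list(ids = dp, frac = 1),
      "dpp" = list(ids = edge$par2, frac = 1),
      "dp1" = list(ids = dpc[1], frac = 1),
      "dp2" = list(ids = dpc[2], frac = 1),
      "dp12" = list(ids = c(dp, edge$par2), frac = 0.5))
    out[[i]] <- list(tag = t3[1], edges = eref$ids,
                     edge_frac = eref$frac, tubes = dref$ids,
                     tube_frac = dref$frac)
  }
  out
}

#' Build the second-scenario DAG of k-best events
#'
#' At every non-sink pair `<e, d>` the `k` cheapest applicable events
#' are kept as alternative unary or binary edges.  The conditional
#' probability of alternative `i` is a Boltzmann soft-minimum
#' `p_i = exp(-(c_i - c_min)/tau)` normalized over the kept
#' alternatives, so cheaper events are more probable and `k = 1`
#' degenerates to the deterministic event tree.
#'
#' @param cm a `cost_matrix` from [compute_cost_matrix()].
#' @param k ramification degree: number of alternatives kept per vertex
#'   (default 10).
#' @param tau softmin temperature; default is the mean of the
#'   configured elementary costs.
#' @return an object of class `scenario_dag` with `vertices` (`e`, `d`,
#'   `mode`, `mass`) and `edges` (`from`, `event`, `par1`, `par2`,
#'   `p`, `mass`, `to1`, `to2`), with unconditional masses propagated
#'   from the root.
#' @export
build_dag <- function(cm, k = 10, tau = NULL) {
  if (k < 1) stop("k must be >= 1")
  if (is.null(tau)) tau <- mean(unclass(cm$costs))
  if (tau <= 0) stop("tau must be positive")
  tree <- cm$tree; s0 <- cm$s0
  lt <- leaf_tubes(tree, s0)
  key_of <- function(e, d, mode) paste(e, d, mode, sep = ".")
  seen <- new.env(parent = emptyenv())
  vert <- list(); edges <- list()
  get_vertex <- function(e, d, mode) {
    key <- key_of(e, d, mode)
    id <- seen[[key]]
    if (!is.null(id)) return(id)
    id <- length(vert) + 1L
    vert[[id]] <<- list(e = e, d = d, mode = mode)
    seen[[key]] <- id
    leafE <- length(tree$children[[e]]) == 0L
    cohered <- leafE && s0$terminal[d] && !is.na(lt[e]) && d == lt[e]
    if (cohered) return(id)    # DAG sink
    rc <- cm$rowcost[, d, e]
    keep <- switch(mode,
      free = rep(TRUE, 35),
      noout = !(seq_len(35) %in% c(11L, 12L)),
      out = seq_len(35) %in% c(11L, 12L))
    rc[!keep] <- Inf
    appl <- which(is.finite(rc))
    if (length(appl) == 0) stop("stuck DAG vertex <", e, ",", d, ">")
    ord <- appl[order(rc[appl], appl)]
    kept <- ord[seq_len(min(k, length(ord)))]
    w <- exp(-(rc[kept] - rc[kept[1]]) / tau)
    p <- w / sum(w)
    for (j in seq_along(kept)) {
      i <- kept[j] - 1L          # 0-based event row
      par1 <- cm$par1[kept[j], d, e]
      par2 <- cm$par2[kept[j], d, e]
      kids <- event_termini(i, e, d, par1, par2, tree, s0, lt)
      to <- vapply(kids, function(kd) get_vertex(kd$e, kd$d, kd$mode),
                   integer(1))
      edges[[length(edges) + 1L]] <<- list(
        from = id, event = i, par1 = par1, par2 = par2,
        p = p[j], cost = rc[kept[j]],
        to1 = if (length(to) >= 1) to[1] else NA_integer_,
        to2 = if (length(to) >= 2) to[2] else NA_integer_)
    }
    id
  }
  root <- get_vertex(tree$root, s0$root_tube, "free")
  vdf <- data.frame(e = vapply(vert, `[[`, integer(1), "e"),
                    d = vapply(vert, `[[`, integer(1), "d"),
                    mode = vapply(vert, `[[`, character(1), "mode"),
                    stringsAsFactors = FALSE)
  gi <- function(f) vapply(edges, function(x) as.integer(x[[f]]),
                           integer(1))
  gn <- function(f) vapply(edges, function(x) as.numeric(x[[f]]),
                           numeric(1))
  edf <- if (length(edges) > 0) {
    data.frame(from = gi("from"), event = gi("event"),
               par1 = gi("par1"), par2 = gi("par2"), p = gn("p"),
               cost = gn("cost"), to1 = gi("to1"), to2 = gi("to2"))
  } else {
    data.frame(from = integer(0), event = integer(0), par1 = integer(0),
               par2 = integer(0), p = numeric(0), cost = numeric(0),
               to1 = integer(0), to2 = integer(0))
  }
  dag <- structure(list(vertices = vdf, edges = edf, root = root,
                        k = k, tau = tau, tree = tree, s0 = s0,
                        costs = cm$costs),
                   class = "scenario_dag")
  dag <- propagate_mass(dag)
  dag$triplets <- flatten_triplets(dag$edges, dag$vertices, s0, tree,
                                   dag$edges$mass)
  dag
}

#' Propagate unconditional masses through a scenario DAG
#'
#' The root carries mass 1; each vertex's mass is the sum of the masses
#' of its incoming edges; an edge's unconditional mass
#' `p(e, d, i)` is the vertex mass times the conditional probability
#' `p_i`, and a binary edge delivers its full mass to both termini (the
#' branching process duplicates the lineage).  After duplications a
#' mass may exceed 1: it is an expected inclusion count.
#'
#' @param dag a `scenario_dag`.
#' @return the DAG with `vertices$mass` and `edges$mass` filled.
#' @export
propagate_mass <- function(dag) {
  nv <- nrow(dag$vertices)
  ne <- nrow(dag$edges)
  mass <- numeric(nv)
  mass[dag$root] <- 1
  if (ne > 0) {
    ## topological order by Kahn's algorithm on the edge list
    indeg <- integer(nv)
    tos <- c(dag$edges$to1, dag$edges$to2)
    tos <- tos[!is.na(tos)]
    for (t in tos) indeg[t] <- indeg[t] + 1L
    queue <- which(indeg == 0L)
    out_of <- split(seq_len(ne), dag$edges$from)
    emass <- numeric(ne)
    topo <- integer(0)
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      topo <- c(topo, v)
      for (i in out_of[[as.character(v)]]) {
        emass[i] <- mass[v] * dag$edges$p[i]
        for (t in c(dag$edges$to1[i], dag$edges$to2[i])) {
          if (is.na(t)) next
          mass[t] <- mass[t] + emass[i]
          indeg[t] <- indeg[t] - 1L
          if (indeg[t] == 0L) queue <- c(queue, t)
        }
      }
    }
    dag$edges$mass <- emass
  }
  dag$vertices$mass <- mass
  dag$triplets <- NULL     # masses changed: cached tables are stale
  dag
}

#' @export
print.scenario_dag <- function(x, ...) {
  cat("Scenario DAG (k =", x$k, "):", nrow(x$vertices), "vertices,",
      nrow(x$edges), "weighted edges\n")
  invisible(x)
}

as_dag_list <- function(dags) {
  if (inherits(dags, "scenario_dag")) list(dags) else dags
}

check_tags <- function(I) {
  bad <- setdiff(I, SCENARIO_TAGS)
  if (length(bad) > 0) stop("unknown tag(s): ", paste(bad, collapse = ", "))
  I
}

## Flatten the tag triplets of a scenario (DAG or event tree, the
## latter with unit masses) into two long tables:
##   tubes: (tag, tube, mass)      with composite halving applied
##   gedges: (tag, gedge, mass)    likewise on the gene-edge side
## All expectation queries reduce to subsetting these tables.
flatten_triplets <- function(edges, vertices, s0, tree, masses) {
  lt <- leaf_tubes(tree, s0)
  acc_t <- list(); acc_e <- list()
  ev <- edges$event; frm <- edges$from
  p1 <- edges$par1; p2 <- edges$par2
  for (i in seq_along(ev)) {
    trs <- TAG_TABLE[[as.character(ev[i])]]
    if (is.null(trs)) next
    e <- vertices$e[frm[i]]; d <- vertices$d[frm[i]]
    ch <- tree$children[[e]]
    dd <- s0$children[[d]]
    dp <- p1[i]
    dpc <- if (!is.na(dp) && dp <= s0$n) s0$children[[dp]] else NULL
    m <- masses[i]
    for (t3 in trs) {
      er <- switch(t3[2], "e" = list(e, 1), "e1" = list(ch[1], 1),
                   "e2" = list(ch[2], 1), "e12" = list(ch, 0.5))
      dr <- switch(t3[3], "d" = list(d, 1), "x" = list(lt[e], 1),
                   "d1" = list(dd[1], 1), "d2" = list(dd[2], 1),
                   "dp" = list(dp, 1), "dpp" = list(p2[i], 1),
                   "dp1" = list(dpc[1], 1), "dp2" = list(dpc[2], 1),
                   "dp12" = list(c(dp, p2[i]), 0.5))
      acc_t[[length(acc_t) + 1L]] <-
        list(t3[1], dr[[1]], m * dr[[2]])
      acc_e[[length(acc_e) + 1L]] <-
        list(t3[1], er[[1]], m * er[[2]])
    }
  }
  expand <- function(acc, col) {
    n <- vapply(acc, function(a) length(a[[2]]), integer(1))
    out <- data.frame(
      tag = rep(vapply(acc, `[[`, character(1), 1), n),
      id = unlist(lapply(acc, `[[`, 2)),
      mass = rep(vapply(acc, `[[`, numeric(1), 3), n),
      stringsAsFactors = FALSE)
    names(out)[2] <- col
    out
  }
  if (length(acc_t) == 0) {
    return(list(tubes = data.frame(tag = character(0),
                                   tube = integer(0),
                                   mass = numeric(0)),
                gedges = data.frame(tag = character(0),
                                    gedge = integer(0),
                                    mass = numeric(0))))
  }
  list(tubes = expand(acc_t, "tube"), gedges = expand(acc_e, "gedge"))
}

dag_triplets <- function(dag) {
  if (!is.null(dag$triplets)) return(dag$triplets)
  flatten_triplets(dag$edges, dag$vertices, dag$s0, dag$tree,
                   dag$edges$mass)
}

#' Expected number of tagged events in a tube
#'
#' `f(I, u)`: the sum of unconditional masses of DAG edges whose tag
#' triplets match a tag in `I` with tube `u`; for the composite
#' `d'&d"` references of the double-transfer rows the matching summand
#' is halved.
#'
#' @param dags a `scenario_dag` or list of them (one per gene tree).
#' @param I character vector of tags (see [SCENARIO_TAGS]).
#' @param u a tube id of the shared sliced species tree.
#' @param weighted multiply each tag's contribution by its elementary
#'   cost (giving `cf(I, u)`).
#' @return numeric expectation.
#' @export
expect_in_tube <- function(dags, I, u, weighted = FALSE) {
  check_tags(I)
  total <- 0
  for (dag in as_dag_list(dags)) {
    tt <- dag_triplets(dag)$tubes
    sel <- tt$tag %in% I & !is.na(tt$tube) & tt$tube == u
    if (!any(sel)) next
    w <- if (weighted) {
      vapply(tt$tag[sel], tag_cost, numeric(1), costs = dag$costs)
    } else 1
    total <- total + sum(tt$mass[sel] * w)
  }
  total
}

#' Marked edge set of a gene tree
#'
#' The set `T` of gene-tree edges all of whose descendant leaves are
#' marked; used by [expect_on_edges()].
#'
#' @param tree a `gene_tree`.
#' @param marked_leaves character vector of leaf labels
#'   (`species-gene`) or leaf vertex ids considered marked.
#' @return integer vector of gene-tree edge ids (edge = lower vertex).
#' @export
marked_edge_set <- function(tree, marked_leaves) {
  leaves <- which(is_leaf(tree))
  if (is.character(marked_leaves)) {
    lab <- paste0(tree$species[leaves], tree$separator,
                  tree$gene[leaves])
    mk <- leaves[lab %in% marked_leaves]
  } else {
    mk <- intersect(as.integer(marked_leaves), leaves)
  }
  ok <- logical(n_vertices(tree))
  for (v in postorder(tree)) {
    ok[v] <- if (length(tree$children[[v]]) == 0L) v %in% mk
             else all(ok[tree$children[[v]]])
  }
  which(ok)
}

#' Expected number of tagged events on marked gene-tree edges
#'
#' `g(I, T)`: like [expect_in_tube()] but matching the gene-edge member
#' of each triplet against the marked set `T`; for the composite
#' `e1&e2` references each matching summand is halved.
#'
#' @param dags a `scenario_dag` or list of them.
#' @param I character vector of tags.
#' @param T integer vector of marked gene-tree edge ids (see
#'   [marked_edge_set()]), or a list with one element per DAG.
#' @param weighted multiply by elementary costs (giving `cg(I, T)`).
#' @return numeric expectation.
#' @export
expect_on_edges <- function(dags, I, T, weighted = FALSE) {
  check_tags(I)
  dl <- as_dag_list(dags)
  Tl <- if (is.list(T)) T else rep(list(T), length(dl))
  total <- 0
  for (j in seq_along(dl)) {
    dag <- dl[[j]]
    te <- dag_triplets(dag)$gedges
    sel <- te$tag %in% I & te$gedge %in% Tl[[j]]
    if (!any(sel)) next
    w <- if (weighted) {
      vapply(te$tag[sel], tag_cost, numeric(1), costs = dag$costs)
    } else 1
    total <- total + sum(te$mass[sel] * w)
  }
  total
}

#' Expected total cost of tagged events
#'
#' `cf(I, u)` / `cg(I, T)`: the cost-weighted analogues of
#' [expect_in_tube()] and [expect_on_edges()].
#'
#' @param dags a `scenario_dag` or list of them.
#' @param I character vector of tags.
#' @param u a tube id, or `T` a marked edge set; exactly one of the two
#'   must be given.
#' @param T marked edge set (see [expect_on_edges()]).
#' @return numeric cost expectation.
#' @export
expect_costs <- function(dags, I, u = NULL, T = NULL) {
  if (is.null(u) == is.null(T)) {
    stop("give exactly one of 'u' (a tube) or 'T' (marked edges)")
  }
  if (!is.null(u)) expect_in_tube(dags, I, u, weighted = TRUE)
  else expect_on_edges(dags, I, T, weighted = TRUE)
}

#' Default tag set of the second-scenario cost
#'
#' Gains, origin of the family, duplications, losses, transfers out of
#' a tube and donor-copy losses.
#' @export
DEFAULT_SCENARIO_TAGS <- c("gain", "gain_big", "dupl", "loss",
                           "tr-o", "tr+o", "loss-")

#' Cost of the second scenario
#'
#' The sum of cost expectations `cf(I, u)` over all tubes `u`, for the
#' tag set `I` (by default [DEFAULT_SCENARIO_TAGS]).
#'
#' @param dags a `scenario_dag` or list of them.
#' @param I character vector of tags.
#' @return numeric scenario cost.
#' @export
scenario_cost <- function(dags, I = DEFAULT_SCENARIO_TAGS) {
  check_tags(I)
  total <- 0
  for (dag in as_dag_list(dags)) {
    ## summing over all tubes: the halved composite entries add back up
    tt <- dag_triplets(dag)$tubes
    sel <- tt$tag %in% I
    if (!any(sel)) next
    w <- vapply(tt$tag[sel], tag_cost, numeric(1), costs = dag$costs)
    total <- total + sum(tt$mass[sel] * w)
  }
  total
}
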