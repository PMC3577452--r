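test_that("conditional probabilities are conserved at every vertex", {
  set.seed(17)
  for (i in 1:6) {
    inst <- random_instance()
    cm <- compute_cost_matrix(inst$tree, inst$s0, inst$costs)
    for (k in c(1, 2, 5, 10)) {
      dag <- build_dag(cm, k = k)
      sums <- tapply(dag$edges$p, dag$edges$from, sum)
      expect_true(all(abs(sums - 1) < 1e-12))
      # sinks are exactly the cohered leaf pairs
      sinks <- setdiff(seq_len(nrow(dag$vertices)),
                       unique(dag$edges$from))
      for (v in sinks) {
        e <- dag$vertices$e[v]; d <- dag$vertices$d[v]
        expect_true(length(inst$tree$children[[e]]) == 0L)
        expect_true(inst$s0$terminal[d])
      }
    }
  }
})

test_that("k = 1 collapses the DAG onto the event tree", {
  set.seed(19)
  for (i in 1:10) {
    inst <- random_instance()
    cm <- compute_cost_matrix(inst$tree, inst$s0, inst$costs)
    et <- build_event_tree(cm)
    dag <- build_dag(cm, k = 1)
    expect_equal(nrow(dag$edges), nrow(et$edges))
    expect_true(all(dag$edges$p == 1))
    expect_true(all(dag$edges$mass == 1))
    # expectations equal deterministic per-tube counts
    counts <- event_counts(et)
    for (u in seq_len(inst$s0$n)) {
      expect_equal(expect_in_tube(dag, SCENARIO_TAGS, u), counts[u],
                   tolerance = 1e-12)
    }
    # cost expectation over all edges equals the cg on the full edge set
    allT <- seq_len(sliceRec:::n_vertices(inst$tree))
    g_all <- expect_on_edges(dag, SCENARIO_TAGS, allT)
    expect_equal(g_all, sum(counts), tolerance = 1e-9)
  }
})

test_that("worked one-duplication instance has unit expectation", {
  costs <- event_costs()
  s0 <- slice_species_tree("(A,B);")
  g <- parse_gene_tree("((A-1,B-1),(A-2,B-2));")
  cm <- compute_cost_matrix(g, s0, costs)
  dag <- build_dag(cm, k = 1)
  # the duplication sits in the in-group root tube
  tubeAB <- setdiff(s0$children[[s0$root_tube]], which(s0$is_outgroup))
  expect_equal(expect_in_tube(dag, "dupl", tubeAB), 1)
  expect_equal(expect_costs(dag, "dupl", u = tubeAB), costs[["dupl"]])
  # all other tubes carry no duplication mass
  others <- setdiff(seq_len(s0$n), tubeAB)
  for (u in others) expect_equal(expect_in_tube(dag, "dupl", u), 0)
  # scenario cost with the default tags equals the duplication charge
  expect_equal(scenario_cost(dag), costs[["dupl"]])
  # on marked edges: the whole tree counts the single duplication
  allT <- seq_len(sliceRec:::n_vertices(g))
  expect_equal(expect_on_edges(dag, "dupl", allT), 1)
  expect_equal(expect_on_edges(dag, "dupl", allT, weighted = TRUE),
               costs[["dupl"]])
})

test_that("congruent forests have zero scenario cost at k = 1", {
  costs <- event_costs()
  s0 <- slice_species_tree("((A,B),C);")
  dags <- lapply(c("((A-1,B-1),C-1);", "((A-2,B-2),C-2);"), function(tx) {
    g <- binarize(parse_gene_tree(tx), s0, costs)
    build_dag(compute_cost_matrix(g, s0, costs), k = 1)
  })
  expect_equal(scenario_cost(dags), 0)
  expect_equal(expect_in_tube(dags, character(0), 1), 0)  # empty I
  expect_equal(expect_on_edges(dags, SCENARIO_TAGS, integer(0)), 0)
})

test_that("tag triplets implement the composite halving rules", {
  s0 <- slice_species_tree("((A,B),C);")
  g <- parse_gene_tree("((A-1,B-1),C-1);")
  lt <- sliceRec:::leaf_tubes(g, s0)
  slice3 <- s0$slices[[3]]
  ingroup3 <- slice3[!s0$is_outgroup[slice3]]
  fake <- data.frame(from = 1L, event = 33L,
                     par1 = ingroup3[1], par2 = ingroup3[2],
                     to1 = NA_integer_, to2 = NA_integer_)
  verts <- data.frame(e = g$root, d = ingroup3[1])
  trs <- sliceRec:::edge_tag_triplets(fake[1, ], verts, s0, g, lt)
  tags <- vapply(trs, `[[`, character(1), "tag")
  expect_setequal(tags, c("tr-o", "loss-", "tr-i", "tr+o", "tr+i"))
  tri <- trs[[which(tags == "tr-i")]]
  expect_equal(tri$tube_frac, 0.5)
  expect_length(tri$tubes, 2L)
  tpo <- trs[[which(tags == "tr+o")]]
  expect_equal(tpo$edge_frac, 0.5)
  expect_length(tpo$edges, 2L)
  # a marked set containing only e1 collects half the tr+o mass
  expect_equal(sum(tpo$edges %in% g$children[[g$root]][1]) *
                 tpo$edge_frac, 0.5)
})

test_that("unit tag costs make cost expectations equal counts", {
  unit <- event_costs(loss = 1, dupl = 1, gain = 1, tr_with = 1,
                      tr_without = 1, sleep = 1, gain_big = 1)
  s0 <- slice_species_tree("((A,C),B);")
  g <- parse_gene_tree("(A-1,B-1);")
  dag <- build_dag(compute_cost_matrix(g, s0, unit), k = 3)
  I <- c("dupl", "loss", "gain")
  for (u in seq_len(s0$n)) {
    expect_equal(expect_costs(dag, I, u = u),
                 expect_in_tube(dag, I, u), tolerance = 1e-12)
  }
})

test_that("expectations change smoothly between k and k+1", {
  set.seed(23)
  for (i in 1:8) {
    inst <- random_instance()
    cm <- compute_cost_matrix(inst$tree, inst$s0, inst$costs)
    for (k in c(1, 2)) {
      d1 <- build_dag(cm, k = k)
      d2 <- build_dag(cm, k = k + 1)
      f1 <- sum(vapply(seq_len(inst$s0$n), function(u) {
        expect_in_tube(d1, SCENARIO_TAGS, u)
      }, numeric(1)))
      f2 <- sum(vapply(seq_len(inst$s0$n), function(u) {
        expect_in_tube(d2, SCENARIO_TAGS, u)
      }, numeric(1)))
      # mass on the newly admitted rank-(k+1) alternatives
      extra <- sum(unlist(lapply(
        split(seq_len(nrow(d2$edges)), d2$edges$from), function(ix) {
          drop <- ix[order(d2$edges$cost[ix])][-seq_len(min(k, length(ix)))]
          d2$edges$mass[drop]
        })))
      # each alternative carries at most five tag triplets and shifts at
      # most proportional downstream mass
      expect_lte(abs(f1 - f2), 6 * extra + 1e-9)
    }
  }
})

test_that("parameter validation rejects bad k, tau and tags", {
  s0 <- slice_species_tree("(A,B);")
  cm <- compute_cost_matrix(parse_gene_tree("(A-1,B-1);"), s0)
  expect_error(build_dag(cm, k = 0), "k")
  expect_error(build_dag(cm, k = 2, tau = 0), "tau")
  dag <- build_dag(cm, k = 2)
  expect_error(expect_in_tube(dag, "nonsense", 1), "unknown tag")
  expect_error(expect_costs(dag, "dupl"), "exactly one")
})
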