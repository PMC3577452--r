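test_that("event applicability transcribes the condition column", {
  s0 <- slice_species_tree("((A,B),C);")
  g <- parse_gene_tree("((A-1,B-1),C-1);")
  tubeA <- which(s0$terminal & !is.na(s0$species) & s0$species == "A")
  leafA <- which(sliceRec:::is_leaf(g) & g$species == "A")
  # cohered leaf edge at its own terminal tube
  expect_true(0L %in% applicable_events(leafA, tubeA, g, s0))
  # non-cohered leaf edge at another in-group terminal tube
  tubeB <- which(s0$terminal & !is.na(s0$species) & s0$species == "B")
  evB <- applicable_events(leafA, tubeB, g, s0)
  expect_true(1L %in% evB)
  expect_false(0L %in% evB)
  # outgroup terminal tube: gain ending
  tubeO <- which(s0$terminal & s0$is_outgroup)
  expect_true(2L %in% applicable_events(leafA, tubeO, g, s0))
  # root edge at the root tube: nout/out rows present, pass_l/r absent
  ev0 <- applicable_events(g$root, s0$root_tube, g, s0)
  expect_length(intersect(ev0, 8:11), 2L)
  expect_false(any(c(6L, 7L) %in% ev0))
  # duplication applies to any bifurcating edge off the outgroup
  inner <- setdiff(which(!sliceRec:::is_leaf(g)), g$root)
  expect_true(12L %in% applicable_events(inner, tubeA, g, s0))
})

test_that("worked reconciliation instances give the textbook costs", {
  costs <- event_costs()
  s_ab <- slice_species_tree("(A,B);")
  expect_equal(reconcile_cost(parse_gene_tree("(A-1,B-2);"), s_ab,
                              costs), 0)
  s_acb <- slice_species_tree("((A,C),B);")
  expect_equal(reconcile_cost(parse_gene_tree("(A-1,B-1);"), s_acb,
                              costs),
               costs[["loss"]])
  expect_equal(reconcile_cost(
    parse_gene_tree("((A-1,B-1),(A-2,B-2));"), s_ab, costs),
    costs[["dupl"]])
  # the same three instances agree with the brute-force oracle
  expect_equal(oracle_cost(parse_gene_tree("(A-1,B-2);"), s_ab, costs), 0)
  expect_equal(oracle_cost(parse_gene_tree("(A-1,B-1);"), s_acb, costs),
               costs[["loss"]])
  expect_equal(oracle_cost(parse_gene_tree("((A-1,B-1),(A-2,B-2));"),
                           s_ab, costs),
               costs[["dupl"]])
})

test_that("the dynamic program matches the brute-force oracle", {
  set.seed(7)
  for (i in 1:60) {
    inst <- random_instance()
    dp <- reconcile_cost(inst$tree, inst$s0, inst$costs)
    expect_gte(dp, 0)
    expect_equal(dp, oracle_cost(inst$tree, inst$s0, inst$costs),
                 tolerance = 1e-12)
  }
})

test_that("total cost sums per-tree costs with weights", {
  s0 <- slice_species_tree("(A,B);")
  expect_equal(total_cost(structure(list(), class = "gene_forest"), s0),
               0)
  f <- gene_forest(c("(A-1,B-1);", "(A-2,B-2);"))
  expect_equal(total_cost(f, s0), 0)
  costs <- event_costs()
  f2 <- gene_forest(c("(A-1,B-1);", "((A-1,B-1),(A-2,B-2));"),
                    weights = c(1, 2))
  expect_equal(total_cost(f2, s0, costs), 2 * costs[["dupl"]])
})

test_that("cost is monotone in each elementary cost", {
  set.seed(31)
  comps <- c("loss", "dupl", "gain", "tr_with", "tr_without", "sleep",
             "gain_big")
  for (i in 1:10) {
    inst <- random_instance()
    base <- reconcile_cost(inst$tree, inst$s0, inst$costs)
    for (w in comps) {
      up <- unclass(inst$costs)
      up[w] <- up[w] + runif(1, 0.1, 1)
      expect_gte(reconcile_cost(inst$tree, inst$s0,
                                do.call(event_costs, as.list(up))),
                 base - 1e-12)
    }
  }
})

test_that("the event tree realizes the minimal cost", {
  costs <- event_costs()
  s_ab <- slice_species_tree("(A,B);")
  cm <- compute_cost_matrix(parse_gene_tree("(A-1,B-2);"), s_ab, costs)
  et <- build_event_tree(cm)
  expect_equal(et$cost, 0)
  expect_true(all(et$edges$event %in% c(3L, 4L, 5L, 8L, 9L, 0L)))

  cm2 <- compute_cost_matrix(
    parse_gene_tree("((A-1,B-1),(A-2,B-2));"), s_ab, costs)
  et2 <- build_event_tree(cm2)
  expect_equal(sum(et2$edges$name == "dupl"), 1L)
  expect_equal(et2$cost, costs[["dupl"]])
})

test_that("event trees decompose into elementary charges", {
  set.seed(13)
  charge <- function(ev, costs) {
    switch(as.character(ev),
      "1" = costs[["tr_without"]], "2" = costs[["gain"]],
      "6" = , "7" = costs[["loss"]], "12" = costs[["dupl"]],
      "15" = , "16" = costs[["tr_with"]],
      "17" = , "18" = costs[["gain"]], "19" = costs[["sleep"]],
      "20" = costs[["gain_big"]], "21" = costs[["tr_without"]],
      "22" = costs[["gain"]],
      "23" = , "24" = costs[["tr_without"]],
      "25" = , "26" = costs[["gain"]],
      "27" = , "28" = costs[["tr_without"]] + costs[["loss"]],
      "29" = , "30" = costs[["gain"]] + costs[["loss"]],
      "31" = costs[["tr_without"]] + costs[["dupl"]],
      "32" = costs[["gain"]] + costs[["dupl"]],
      "33" = costs[["tr_without"]] + costs[["tr_with"]],
      "34" = costs[["gain"]] + costs[["tr_with"]],
      0)
  }
  for (i in 1:25) {
    inst <- random_instance()
    cm <- compute_cost_matrix(inst$tree, inst$s0, inst$costs)
    et <- build_event_tree(cm)
    expect_equal(et$cost, cm$cost)
    total <- sum(vapply(et$edges$event, charge, numeric(1),
                        costs = inst$costs))
    expect_equal(total, cm$cost, tolerance = 1e-9)
  }
})

test_that("beta paths are connected chains in the sliced tree", {
  costs <- event_costs()
  s0 <- slice_species_tree("((A,B),C);")
  g <- parse_gene_tree("((A-1,B-1),C-1);")
  cm <- compute_cost_matrix(g, s0, costs)
  beta <- beta_mapping(build_event_tree(cm))
  # every gene edge has a path; leaf edges end with fin
  leafA <- which(sliceRec:::is_leaf(g) & g$species == "A")
  expect_equal(beta[[as.character(leafA)]]$final, 0L)
  tubeA <- which(s0$terminal & !is.na(s0$species) & s0$species == "A")
  pathA <- beta[[as.character(leafA)]]$tubes
  expect_equal(pathA[length(pathA)], tubeA)
  # connectivity: consecutive tubes are parent/child or same-slice
  check_path <- function(tubes) {
    if (length(tubes) < 2) return(invisible())
    for (i in seq_len(length(tubes) - 1L)) {
      a <- tubes[i]; b <- tubes[i + 1L]
      ok <- s0$parent[b] == a ||
        s0$slice[a] == s0$slice[b] ||
        (s0$parent[b] > 0 && s0$slice[s0$parent[b]] == s0$slice[a])
      expect_true(ok)
    }
  }
  for (bp in beta) check_path(bp$tubes)

  # the C leaf edge passes through both segments of its subdivided tube
  leafC <- which(sliceRec:::is_leaf(g) & g$species == "C")
  expect_equal(length(beta[[as.character(leafC)]]$tubes), 2L)

  # a beta path may terminate with a duplication
  cm2 <- compute_cost_matrix(
    parse_gene_tree("((A-1,B-1),(A-2,B-2));"),
    slice_species_tree("(A,B);"), costs)
  beta2 <- beta_mapping(build_event_tree(cm2))
  finals <- vapply(beta2, `[[`, integer(1), "final")
  expect_true(12L %in% finals)
})

test_that("unsolvable or invalid inputs are rejected", {
  s0 <- slice_species_tree("(A,B);")
  expect_error(reconcile_cost(parse_gene_tree("(A-1,Z-1);"), s0),
               "missing")
  expect_error(reconcile_cost(parse_gene_tree("(A-1,B-1,B-2);"), s0),
               "binar")
  expect_error(event_costs(loss = -1), "nonnegative")
})
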