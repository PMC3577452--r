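key_of <- function(...) paste(sort(c(...)), collapse = "\x1f")

test_that("the standard clade family collects clades plus V0", {
  P <- build_clade_set(gene_forest("(A-1,(B-1,C-1));"))
  expect_length(P$sets, 5L)
  expect_true(key_of("B", "C") %in% P$keys)
  expect_true(key_of("A", "B", "C") %in% P$keys)
  expect_equal(lengths(P$sets), sort(lengths(P$sets)))

  # |P| is bounded by the vertex count plus one
  f <- gene_forest(c("((A-1,B-1),C-1);", "(A-2,(C-2,D-1));"))
  P2 <- build_clade_set(f)
  nv <- sum(vapply(f, sliceRec:::n_vertices, integer(1)))
  expect_lte(length(P2$sets), nv + 1L)
})

test_that("transfer-difference sets extend the family", {
  f <- gene_forest("((A-1,B-1),((B-2,C-1),D-1));")
  P0 <- build_clade_set(f)
  P1 <- build_clade_set(f, with_transfer_sets = TRUE)
  expect_true(all(P0$keys %in% P1$keys))
  # clades {A,B} and {B,C,D} overlap in {B}: the difference {C,D} is
  # not a clade but enters the extended family
  expect_false(key_of("C", "D") %in% P0$keys)
  expect_true(key_of("C", "D") %in% P1$keys)
})

test_that("good vertices follow the fit-inside/stick-out rule", {
  g1 <- parse_gene_tree("((A-1,B-1),C-1);")
  expect_equal(good_vertices(g1, c("A", "B")), 1L)   # the (A,B) vertex
  g2 <- parse_gene_tree("((A-1,C-1),B-1);")
  expect_equal(good_vertices(g2, c("A", "B")), 2L)   # leaves A and B
  # V containing the whole clade set: only the root qualifies
  expect_equal(good_vertices(g1, c("A", "B", "C", "Z")), 1L)
})

test_that("binary and polytomous good-vertex counts agree", {
  set.seed(37)
  for (i in 1:15) {
    m <- sample(3:5, 1)
    g <- random_gene_tree(paste0("s", 1:m), sample(3:6, 1))
    V <- sample(paste0("s", 1:m), sample(1:m, 1))
    universe <- sort(unique(c(V, g$species[sliceRec:::is_leaf(g)])))
    pre <- sliceRec:::prep_forest(
      structure(list(g), class = "gene_forest"), universe)[[1]]
    mk <- sliceRec:::mask_of(V, universe)
    as_binary <- pre; as_binary$binary <- TRUE
    as_poly <- pre; as_poly$binary <- FALSE
    expect_equal(sliceRec:::count_good_tree(as_binary, mk),
                 sliceRec:::count_good_tree(as_poly, mk))
  }
})

test_that("pair vertices count speciations across the partition", {
  g1 <- parse_gene_tree("((A-1,B-1),C-1);")
  expect_equal(pair_vertices(g1, c("A", "B"), "C"), 1L)   # the root
  g2 <- parse_gene_tree("((A-1,C-1),B-1);")
  expect_equal(pair_vertices(g2, c("A", "B"), "C"), 1L)   # (A,C) vertex
  expect_error(pair_vertices(g1, c("A", "B"), c("B", "C")), "disjoint")
})

test_that("Phase I reproduces the concordant worked example", {
  f <- gene_forest(c("(A-1,(B-1,C-1));", "(A-2,(B-2,C-2));"))
  p1 <- phase1(f)
  expect_true(p1$condition_star)
  r <- p1$records
  expect_equal(r[[key_of("B", "C")]]$cost, 0)
  expect_equal(r[[key_of("A", "B", "C")]]$cost, 0)
  part <- r[[key_of("A", "B", "C")]]$partition
  expect_setequal(part$V2, c("B", "C"))
  # a single admissible partition pins the weight at one
  expect_equal(r[[key_of("B", "C")]]$weight, 1)
})

test_that("Phase I reproduces the discordant tie", {
  costs <- event_costs()   # c_d = 2, c_l = 1
  f <- gene_forest(c("((A-1,B-1),C-1);", "((A-1,C-1),B-1);"))
  p1 <- phase1(f, costs = costs)
  rec <- p1$records[[key_of("A", "B", "C")]]
  expect_equal(rec$cost, costs[["dupl"]] + 3 * costs[["loss"]])
  # the runner-up partition ties exactly
  expect_equal(rec$second_cost, rec$cost)
  # tied costs make the tie-break weight collapse to w = 1
  expect_equal(rec$weight, 1)
})

test_that("basic tree costs prune and reconcile", {
  SV <- list(children = list(
    list(children = list(list(species = "A"), list(species = "B"))),
    list(species = "C")))
  expect_equal(basic_tree_cost(SV, "((A,B),C);"), 0)
  expect_equal(basic_tree_cost(SV, "((A,B),D);"), 0)  # pruned to (A,B)
  expect_equal(basic_tree_cost(list(species = "A"), "((A,B),C);"), 0)
  costs <- event_costs()
  mis <- basic_tree_cost(SV, "((A,C),B);", costs)
  expect_gt(mis, 0)
})

test_that("Phase II assembles the supertree greedily", {
  # a single basic topology is returned as the supertree
  f <- gene_forest(c("(A-1,(B-1,C-1));", "(A-2,(B-2,C-2));"))
  res <- supertree(f)
  expect_true(same_rooted_topology(res$newick, "(A,(B,C));"))
  expect_equal(res$total_cost, 0)

  # concordant forest of identical 4-leaf trees
  f4 <- gene_forest(rep("((A-1,B-1),(C-1,D-1));", 2))
  res4 <- supertree(f4)
  expect_true(same_rooted_topology(res4$newick, "((A,B),(C,D));"))
  expect_equal(res4$total_cost, 0)
})

test_that("Phase I equals the exhaustive minimum for dup/loss forests", {
  set.seed(43)
  costs <- duploss_costs()
  done <- 0
  while (done < 10) {
    m <- sample(3:5, 1)
    sp <- paste0("s", 1:m)
    forest <- gene_forest(lapply(seq_len(sample(2:4, 1)), function(j) {
      random_gene_tree_nopar(sp, sample(2:m, 1))
    }))
    if (length(forest_species(forest)) < 3) next
    P <- build_clade_set(forest)
    p1 <- suppressWarnings(phase1(forest, P, costs))
    if (!p1$condition_star) next
    c0 <- p1$records[[paste(sort(p1$V0), collapse = "\x1f")]]$cost
    expect_equal(c0, exhaustive_min_cost(forest, P, costs),
                 tolerance = 1e-9)
    done <- done + 1
  }
})

test_that("amalgamation cost is additive over the forest", {
  costs <- event_costs()
  S <- "((A,B),C);"
  f1 <- gene_forest("((A-1,B-1),C-1);")
  f2 <- gene_forest("((A-1,C-1),B-1);")
  both <- gene_forest(c("((A-1,B-1),C-1);", "((A-1,C-1),B-1);"))
  expect_equal(amalgamation_cost(f1, S, costs), 0)
  expect_equal(amalgamation_cost(both, S, costs),
               amalgamation_cost(f1, S, costs) +
                 amalgamation_cost(f2, S, costs))
  # weighted variant scales per-tree contributions
  wboth <- gene_forest(c("((A-1,B-1),C-1);", "((A-1,C-1),B-1);"),
                       weights = c(1, 2))
  expect_equal(amalgamation_cost(wboth, S, costs),
               2 * amalgamation_cost(f2, S, costs))
})
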