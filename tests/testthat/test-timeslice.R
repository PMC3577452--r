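test_that("outgroup attachment creates the root tube structure", {
  st <- read_species_tree("(A,B);")
  st2 <- attach_outgroup(st)
  R <- st2$root
  expect_length(st2$children[[R]], 2L)
  expect_true(st2$outgroup %in% st2$children[[R]])
  expect_equal(st2$label[st2$outgroup], sliceRec:::OUTGROUP_LABEL)
  # the old root is the outgroup's sibling
  sib <- setdiff(st2$children[[R]], st2$outgroup)
  expect_setequal(st_clades(st2)[[sib]], c("A", "B"))
  # applying twice trips the reserved-label guard
  expect_error(attach_outgroup(st2), "reserved")
})

test_that("a single-leaf in-group slices into two slices", {
  st <- attach_outgroup(sliceRec:::species_tree_from_nested(
    list(species = "A")))
  s0 <- build_slices(st)
  expect_equal(s0$n_slices, 2L)
  expect_equal(s0$n, 3L)   # d0, A tube, outgroup segment
})

test_that("auto slicing equalizes leaf depths and layers the tree", {
  s0 <- slice_species_tree("((1,2),3);")
  expect_equal(s0$n_slices, 4L)
  # per-slice tube sets partition the tubes
  expect_setequal(unlist(s0$slices), seq_len(s0$n))
  # consecutive tubes always change slice by one
  for (d in seq_len(s0$n)) {
    if (s0$parent[d] > 0) {
      expect_equal(s0$slice[d], s0$slice[s0$parent[d]] + 1L)
    }
  }
  # every root-to-leaf tube path visits every slice exactly once
  for (d in which(s0$terminal)) {
    path <- integer(0); cur <- d
    while (cur > 0) { path <- c(path, s0$slice[cur]); cur <- s0$parent[cur] }
    expect_equal(sort(path), seq_len(s0$n_slices))
  }
  # one outgroup segment per slice below the root tube's
  for (s in 2:s0$n_slices) {
    expect_equal(sum(s0$is_outgroup[s0$slices[[s]]]), 1L)
  }
})

test_that("slice counts are h+1 on random trees", {
  set.seed(4)
  for (m in c(2, 4, 7)) {
    st <- generate_species_tree(m)
    st2 <- attach_outgroup(st)
    depth <- integer(length(st2$parent))
    for (v in rev(sliceRec:::postorder_species(st2))) {
      depth[v] <- if (st2$parent[v] == 0) 0L else depth[st2$parent[v]] + 1L
    }
    leaves <- setdiff(which(lengths(st2$children) == 0L), st2$outgroup)
    h <- max(depth[leaves])
    expect_equal(build_slices(st2)$n_slices, h + 1L)
  }
})

test_that("explicit segment counts are honored or rejected", {
  s0 <- build_slices(read_species_tree("((A:2,B:2):1,C:3);"),
                     mode = "explicit")
  # every path crosses 4 tubes below the outgroup-attachment root, plus
  # the root tube's own slice
  expect_equal(s0$n_slices, 5L)
  expect_error(
    build_slices(read_species_tree("((A:1,B:2):1,C:1);"),
                 mode = "explicit"),
    "unequal")
})

test_that("same-slice accessor excludes self and outgroup targets", {
  s0 <- slice_species_tree("((A,B),C);")
  for (d in seq_len(s0$n)) {
    ss <- same_slice_tubes(s0, d)
    expect_false(d %in% ss)
    expect_false(any(s0$is_outgroup[ss]))
    expect_true(all(s0$slice[ss] == s0$slice[d]))
    full <- same_slice_tubes(s0, d, transfer_target = FALSE)
    expect_true(all(ss %in% full))
  }
})

test_that("old-tube aggregation sums segment values", {
  s0 <- slice_species_tree("((A,B),C);")   # C's tube splits in two
  ones <- rep(1, s0$n)
  agg <- aggregate_by_old_tube(s0, ones)
  cseg <- sum(s0$old_tube == s0$old_tube[which(s0$species == "C")])
  expect_equal(cseg, 2)
  expect_equal(unname(agg["C"]), 2)
  expect_equal(unname(agg["A"]), 1)
  expect_equal(sum(agg), s0$n)
  # named subset with fractional values
  vals <- setNames(c(0.5, 1.25), which(s0$old_tube ==
    s0$old_tube[which(s0$species == "C")]))
  expect_equal(unname(aggregate_by_old_tube(s0, vals)["C"]), 1.75)
  expect_error(aggregate_by_old_tube(s0, rep(1, s0$n - 1)), "per tube")

  # undivided in-group tubes aggregate to themselves; only the
  # stretched outgroup tube collects its per-slice segments
  s1 <- slice_species_tree("(A,B);")
  agg1 <- aggregate_by_old_tube(s1, rep(1, s1$n))
  expect_true(all(agg1[setdiff(names(agg1), sliceRec:::OUTGROUP_LABEL)]
                  == 1))
  expect_equal(unname(agg1[sliceRec:::OUTGROUP_LABEL]), 2)
})
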