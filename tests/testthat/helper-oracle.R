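# Independent brute-force reconciliation oracle: top-down memoized
# recursion over states <edge, tube, mode>, enumerating every applicable
# event row and every admissible donor tube (not only the minimal
# parameters).  Transcribed directly from the event table, sharing no
# code with the package's bottom-up dynamic program.

oracle_cost <- function(tree, s0, costs) {
  lt <- sliceRec:::leaf_tubes(tree, s0)
  cl <- costs[["loss"]]; cd <- costs[["dupl"]]; cg <- costs[["gain"]]
  ctw <- costs[["tr_with"]]; cto <- costs[["tr_without"]]
  cs <- costs[["sleep"]]; cgb <- costs[["gain_big"]]
  memo <- new.env(parent = emptyenv())
  d0 <- s0$root_tube

  rec <- function(e, d, mode) {
    key <- paste(e, d, mode)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    ch <- tree$children[[e]]
    leafE <- length(ch) == 0
    bifE <- length(ch) == 2
    e1 <- if (bifE) ch[1] else NA
    e2 <- if (bifE) ch[2] else NA
    isE0 <- e == tree$root
    isD0 <- d == d0
    ogr <- s0$is_outgroup[d]
    term <- s0$terminal[d]
    dd <- s0$children[[d]]
    ss <- setdiff(s0$slices[[s0$slice[d]]], d)
    ss <- ss[!s0$is_outgroup[ss]]
    vals <- numeric(0)
    put <- function(i, v) {
      ok <- switch(mode,
                   free = TRUE,
                   noout = !(i %in% c(10, 11)),
                   out = i %in% c(10, 11))
      if (ok) vals <<- c(vals, v)
    }
    if (leafE && term) {
      if (d == lt[e]) put(0, 0)
      else if (!ogr) put(1, cto)
      else put(2, cg)
    }
    if (length(dd) == 1) put(3, rec(e, dd[1], "free"))
    if (bifE && length(dd) == 2) {
      put(4, rec(e1, dd[1], "free") + rec(e2, dd[2], "free"))
      put(5, rec(e2, dd[1], "free") + rec(e1, dd[2], "free"))
    }
    if (!isD0 && length(dd) == 2) {
      put(6, rec(e, dd[1], "free") + cl)
      put(7, rec(e, dd[2], "free") + cl)
    }
    if (isD0 && length(dd) == 2) {
      og1 <- s0$is_outgroup[dd[1]]; og2 <- s0$is_outgroup[dd[2]]
      if (!og1 && og2) {
        put(8, rec(e, dd[1], "free"))
        put(11, rec(e, dd[2], "free"))
      }
      if (og1 && !og2) {
        put(9, rec(e, dd[2], "free"))
        put(10, rec(e, dd[1], "free"))
      }
    }
    if (bifE && !ogr) {
      if (isD0) {
        put(12, rec(e1, d, "noout") + rec(e2, d, "noout") + cd)
      } else {
        put(12, rec(e1, d, "free") + rec(e2, d, "free") + cd)
      }
    }
    if (bifE && isD0) {
      put(13, min(rec(e1, d, "out") + rec(e2, d, "free"),
                  rec(e1, d, "free") + rec(e2, d, "out")))
    }
    if (bifE && ogr) put(14, rec(e1, d, "free") + rec(e2, d, "free"))
    for (dp in ss) {
      dpc <- s0$children[[dp]]
      if (bifE && !ogr && !isD0) {
        put(15, rec(e1, dp, "free") + rec(e2, d, "free") + ctw)
        put(16, rec(e2, dp, "free") + rec(e1, d, "free") + ctw)
      }
      if (bifE && ogr) {
        put(17, rec(e1, dp, "free") + rec(e2, d, "free") + cg)
        put(18, rec(e2, dp, "free") + rec(e1, d, "free") + cg)
      }
      if (isE0 && ogr) put(20, rec(e, dp, "free") + cgb)
      if (!ogr && !isD0 && length(dpc) == 1) {
        put(21, rec(e, dpc[1], "free") + cto)
      }
      if (!isE0 && ogr && length(dpc) == 1) {
        put(22, rec(e, dpc[1], "free") + cg)
      }
      if (bifE && !ogr && !isD0 && length(dpc) == 2) {
        put(23, rec(e1, dpc[1], "free") + rec(e2, dpc[2], "free") + cto)
        put(24, rec(e1, dpc[2], "free") + rec(e2, dpc[1], "free") + cto)
      }
      if (!isE0 && bifE && ogr && length(dpc) == 2) {
        put(25, rec(e1, dpc[1], "free") + rec(e2, dpc[2], "free") + cg)
        put(26, rec(e1, dpc[2], "free") + rec(e2, dpc[1], "free") + cg)
      }
      if (!ogr && !isD0 && length(dpc) == 2) {
        put(27, rec(e, dpc[1], "free") + cto + cl)
        put(28, rec(e, dpc[2], "free") + cto + cl)
      }
      if (!isE0 && ogr && length(dpc) == 2) {
        put(29, rec(e, dpc[1], "free") + cg + cl)
        put(30, rec(e, dpc[2], "free") + cg + cl)
      }
      if (bifE && !ogr && !isD0) {
        put(31, rec(e1, dp, "free") + rec(e2, dp, "free") + cto + cd)
      }
      if (!isE0 && bifE && ogr) {
        put(32, rec(e1, dp, "free") + rec(e2, dp, "free") + cg + cd)
      }
      for (dq in ss) {
        if (dq == dp) next
        if (bifE && !ogr && !isD0) {
          put(33, rec(e1, dp, "free") + rec(e2, dq, "free") + cto + ctw)
        }
        if (!isE0 && bifE && ogr) {
          put(34, rec(e1, dp, "free") + rec(e2, dq, "free") + cg + ctw)
        }
      }
    }
    if (!isE0 && !ogr && !isD0 && !term) {
      og <- s0$outgroup_in_slice[s0$slice[d]]
      if (!is.na(og)) put(19, rec(e, og, "free") + cs)
    }
    best <- if (length(vals) == 0) Inf else min(vals)
    memo[[key]] <- best
    best
  }
  rec(tree$root, d0, "free")
}

# Random rooted binary gene tree over a species vector (paralogs
# allowed: species are drawn with replacement).
random_gene_tree <- function(species, nleaves) {
  sp <- sample(species, nleaves, replace = TRUE)
  pool <- lapply(seq_len(nleaves), function(i) {
    list(species = sp[i], gene = as.character(i))
  })
  while (length(pool) > 1) {
    ij <- sample.int(length(pool), 2)
    pool <- c(pool[-ij], list(list(children = pool[ij])))
  }
  sliceRec:::nested_to_gene_tree(pool[[1]])
}

random_costs <- function() {
  event_costs(loss = runif(1, 0.1, 3), dupl = runif(1, 0.1, 3),
              gain = runif(1, 0.1, 3), tr_with = runif(1, 0.1, 3),
              tr_without = runif(1, 0.1, 3), sleep = runif(1, 0.1, 3),
              gain_big = runif(1, 0, 2))
}

# Random reconciliation instance on a small species set.
random_instance <- function(max_species = 4, max_leaves = 4) {
  m <- sample(2:max_species, 1)
  st <- generate_species_tree(m)
  s0 <- build_slices(st)
  nl <- sample(2:max_leaves, 1)
  g <- random_gene_tree(paste0("s", seq_len(m)), nl)
  list(s0 = s0, tree = g, costs = random_costs())
}
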