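## ---------------------------------------------------------------------------
## Forest simulation: gene trees evolved along a known species tree
## ---------------------------------------------------------------------------

#' Simulation parameters
#'
#' Per-tube, per-lineage event probabilities of the gene-evolution
#' process.  The defaults are the low-rate regime used throughout the
#' package's recovery experiments.
#'
#' @param p_dup duplication probability per lineage per tube.
#' @param p_loss loss (extinction) probability.
#' @param p_tr within-slice transfer probability.
#' @param n number of gene trees to generate.
#' @param seed optional random seed.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(p_dup = 0.02, p_loss = 0.02, p_tr = 0.01,
                       n = 50, seed = NULL) {
  stopifnot(p_dup >= 0, p_loss >= 0, p_tr >= 0,
            p_dup + p_loss + p_tr < 1, n >= 1)
  structure(list(p_dup = p_dup, p_loss = p_loss, p_tr = p_tr,
                 n = as.integer(n), seed = seed),
            class = "sim_params")
}

#' Generate a random rooted binary species tree
#'
#' Uniform sequential joins over `m` named species (`s1`, ..., `sm`).
#'
#' @param m number of species (at least 2).
#' @param seed optional random seed.
#' @return a `species_tree` without outgroup.
#' @export
generate_species_tree <- function(m, seed = NULL) {
  if (m < 2) stop("m must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  pool <- lapply(seq_len(m), function(i) list(species = paste0("s", i)))
  while (length(pool) > 1) {
    ij <- sample.int(length(pool), 2)
    joined <- list(children = pool[ij])
    pool <- c(pool[-ij], list(joined))
  }
  species_tree_from_nested(pool[[1]])
}

#' Evolve a forest of gene trees along a sliced species tree
#'
#' Each gene starts as a single lineage at the top of the in-group root
#' tube.  In every tube a lineage may duplicate (both copies restart
#' the tube), die, or jump to a uniformly chosen same-slice non-outgroup
#' tube; otherwise it follows the tube to its bottom vertex, speciating
#' into both children or ending at a leaf.  Genes extinct everywhere
#' (or surviving as a single leaf) are discarded and redrawn.
#'
#' @param s0 a `sliced_tree`.
#' @param params a [sim_params()] object.
#' @return a `gene_forest` of rooted (possibly non-binary after
#'   duplications, but in fact binary) gene trees labeled
#'   `species-g<index>`.
#' @export
generate_gene_trees <- function(s0, params = sim_params()) {
  if (!is.null(params$seed)) set.seed(params$seed)
  root_ingroup <- setdiff(s0$children[[s0$root_tube]],
                          which(s0$is_outgroup))
  stopifnot(length(root_ingroup) == 1)
  trees <- vector("list", params$n)
  for (j in seq_len(params$n)) {
    repeat {
      counter <- 0L
      evolve <- function(d) {
        u <- runif(1)
        if (u < params$p_dup) {
          a <- evolve(d); b <- evolve(d)
          if (is.null(a)) return(b)
          if (is.null(b)) return(a)
          return(list(children = list(a, b)))
        }
        if (u < params$p_dup + params$p_loss) return(NULL)
        if (u < params$p_dup + params$p_loss + params$p_tr) {
          targets <- same_slice_tubes(s0, d, transfer_target = TRUE)
          if (length(targets) > 0) {
            d <- targets[sample.int(length(targets), 1)]
          }
        }
        if (s0$terminal[d]) {
          counter <<- counter + 1L
          return(list(species = s0$species[d],
                      gene = paste0("g", counter)))
        }
        kids <- Filter(Negate(is.null),
                       lapply(s0$children[[d]], evolve))
        if (length(kids) == 0) return(NULL)
        if (length(kids) == 1) return(kids[[1]])
        list(children = kids)
      }
      nested <- evolve(root_ingroup)
      if (!is.null(nested) && !is.null(nested$children)) break
    }
    trees[[j]] <- nested_to_gene_tree(nested)
  }
  structure(trees, class = "gene_forest")
}

#' Simulate a full study instance
#'
#' Generates a species tree, slices it, and evolves a forest along it.
#'
#' @param m number of species.
#' @param params a [sim_params()] object.
#' @param seed random seed for both the species tree and the forest.
#' @return list with `species_tree`, `s0` and `forest`.
#' @export
simulate_instance <- function(m, params = sim_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  st <- generate_species_tree(m)
  s0 <- build_slices(st)
  params$seed <- NULL         # keep the single RNG stream
  forest <- generate_gene_trees(s0, params)
  list(species_tree = st, s0 = s0, forest = forest)
}
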