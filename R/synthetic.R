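# Seeded generators for all pipeline inputs: a block-structured association
# matrix, a layered disease ontology DAG, and block-correlated expression
# profiles. Together they define the planted study conditions every
# downstream stage is validated against.

#' Configuration for the synthetic data generators
#'
#' The defaults describe the standard study conditions used throughout the
#' package's tests: 80 circRNAs and 30 diseases partitioned into 4
#' co-association blocks, associations appearing with probability 0.3 inside
#' a block and 0.02 between blocks, 32-dimensional expression profiles with
#' Gaussian noise (sd 0.5) around a shared block profile, and a 4-layer
#' random ontology DAG.
#'
#' @param m number of circRNAs.
#' @param n number of diseases.
#' @param blocks number of planted co-association blocks.
#' @param density_in within-block association probability.
#' @param density_out between-block association probability.
#' @param p expression profile dimension.
#' @param noise_sd standard deviation of per-circRNA expression noise.
#' @param dag_depth number of layers in the random DAG.
#' @param dag_branching maximum number of parents per non-root node.
#' @param seed integer seed; all generators are pure functions of
#'   (config, seed).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(m = 80, n = 30, blocks = 4,
                             density_in = 0.3, density_out = 0.02,
                             p = 32, noise_sd = 0.5,
                             dag_depth = 4, dag_branching = 2, seed = 1) {
  assert_that(m >= 1 && n >= 1 && blocks >= 1 && p >= 1 && dag_depth >= 1,
              "all counts must be positive")
  assert_that(blocks <= m && blocks <= n,
              "more blocks than circRNAs or diseases")
  assert_that(density_out >= 0 && density_in <= 1 && density_out < density_in,
              "need 0 <= density_out < density_in <= 1")
  assert_that(noise_sd >= 0, "noise_sd must be nonnegative")
  structure(list(m = m, n = n, blocks = blocks, density_in = density_in,
                 density_out = density_out, p = p, noise_sd = noise_sd,
                 dag_depth = dag_depth, dag_branching = dag_branching,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

block_partition <- function(count, blocks) {
  sort(rep_len(seq_len(blocks), count))
}

#' Simulate a block-structured association matrix
#'
#' circRNAs and diseases are each partitioned into `cfg$blocks` contiguous
#' groups; cell (i, j) is Bernoulli(`density_in`) when i and j share a block
#' index and Bernoulli(`density_out`) otherwise.
#'
#' @param cfg a [synthetic_config()].
#' @return binary association matrix with `circ_block` / `disease_block`
#'   attributes recording the planted assignment.
#' @export
simulate_associations <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$density_in == 0 && cfg$density_out == 0) {
    stop("expected positive association count is 0; raise density_in/density_out",
         call. = FALSE)
  }
  cb <- block_partition(cfg$m, cfg$blocks)
  db <- block_partition(cfg$n, cfg$blocks)
  prob <- ifelse(outer(cb, db, "=="), cfg$density_in, cfg$density_out)
  am <- withr::with_seed(cfg$seed, {
    matrix(as.integer(stats::runif(cfg$m * cfg$n) < prob), cfg$m, cfg$n)
  })
  dimnames(am) <- list(sprintf("circ_%03d", seq_len(cfg$m)),
                       sprintf("disease_%03d", seq_len(cfg$n)))
  attr(am, "circ_block") <- stats::setNames(cb, rownames(am))
  attr(am, "disease_block") <- stats::setNames(db, colnames(am))
  am
}

#' Simulate a layered block-structured disease DAG
#'
#' Mimics how an ontology such as MeSH clusters related diseases: each
#' planted block forms its own subtree. Under a single synthetic root
#' (`disease_root`), each block with more than one member gets a branch
#' node (`disease_branch_<b>`); the block's diseases are assigned
#' round-robin to `dag_depth` layers inside that subtree, and every
#' non-root node draws 1 to `dag_branching` parents from the layer above
#' within its own block, so the graph is acyclic by construction and
#' same-block diseases share ancestors. With one block and `dag_depth = 1`
#' the DAG is a star from the root.
#'
#' @param cfg a [synthetic_config()].
#' @return a `disease_dag` over the `n` disease identifiers plus the
#'   synthetic root/branch nodes.
#' @export
simulate_dag <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  ids <- sprintf("disease_%03d", seq_len(cfg$n))
  root <- "disease_root"
  db <- block_partition(cfg$n, cfg$blocks)
  edges <- withr::with_seed(cfg$seed + 1L, {
    out <- list()
    for (b in seq_len(cfg$blocks)) {
      members <- ids[db == b]
      anchor <- if (cfg$blocks == 1) root else sprintf("disease_branch_%02d", b)
      if (cfg$blocks > 1) out[[length(out) + 1L]] <- cbind(anchor, root)
      layer <- rep_len(seq_len(cfg$dag_depth), length(members))
      for (i in seq_along(members)) {
        above <- if (layer[i] == 1) anchor else members[layer == layer[i] - 1]
        k <- min(length(above), sample.int(cfg$dag_branching, 1))
        parents <- if (length(above) == 1) above else sample(above, k)
        out[[length(out) + 1L]] <- cbind(members[i], parents)
      }
    }
    do.call(rbind, out)
  })
  disease_dag(edges)
}

#' Simulate block-correlated expression profiles
#'
#' Each planted block has a latent `p`-dimensional profile drawn from
#' N(0, 1); each circRNA's profile is its block's latent profile plus
#' independent N(0, `noise_sd`) noise, so within-block rank correlation
#' exceeds between-block correlation in expectation.
#'
#' @param cfg a [synthetic_config()].
#' @param blocks optional integer block assignment per circRNA (defaults to
#'   the partition used by [simulate_associations()]).
#' @return numeric `m x p` matrix with circRNA row names.
#' @export
simulate_expression <- function(cfg, blocks = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (is.null(blocks)) blocks <- block_partition(cfg$m, cfg$blocks)
  assert_that(length(blocks) == cfg$m, "one block index per circRNA required")
  expr <- withr::with_seed(cfg$seed + 2L, {
    latent <- matrix(stats::rnorm(cfg$blocks * cfg$p), cfg$blocks, cfg$p)
    latent[blocks, , drop = FALSE] +
      matrix(stats::rnorm(cfg$m * cfg$p, sd = cfg$noise_sd), cfg$m, cfg$p)
  })
  dimnames(expr) <- list(sprintf("circ_%03d", seq_len(cfg$m)),
                         sprintf("sample_%02d", seq_len(cfg$p)))
  expr
}

#' Sample negative pairs from the unknown cells of an association matrix
#'
#' Returns all positive cells (label 1) plus `n_neg` cells drawn uniformly
#' without replacement from the zero cells (label 0). With `n_neg` equal to
#' the positive count this reproduces the balanced labelled-pair design.
#'
#' @param am binary association matrix.
#' @param n_neg number of negatives to draw (default: one per positive).
#' @param seed integer seed.
#' @return data frame with integer columns `circ`, `disease` (indices into
#'   `am`) and `label`.
#' @export
sample_negatives <- function(am, n_neg = NULL, seed = 1) {
  validate_assoc_matrix(am)
  pos <- which(am == 1)
  zero <- which(am == 0)
  if (is.null(n_neg)) n_neg <- length(pos)
  if (n_neg > length(zero)) {
    stop("n_neg = ", n_neg, " exceeds the ", length(zero),
         " unknown (zero) cells", call. = FALSE)
  }
  neg <- withr::with_seed(as.integer(seed), {
    zero[sample.int(length(zero), n_neg)]
  })
  cells <- c(pos, neg)
  data.frame(circ = ((cells - 1L) %% nrow(am)) + 1L,
             disease = ((cells - 1L) %/% nrow(am)) + 1L,
             label = rep(c(1L, 0L), c(length(pos), length(neg))))
}

#' Write all synthetic inputs to a directory
#'
#' Emits the association TSV, DAG edge-list TSV, expression TSV and the
#' ground-truth block assignment for a config, mirroring the external input
#' formats of [read_associations()], [read_dag()] and [read_expression()].
#'
#' @param cfg a [synthetic_config()].
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths.
#' @export
write_synthetic_inputs <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  am <- simulate_associations(cfg)
  dag <- simulate_dag(cfg)
  expr <- simulate_expression(cfg)
  paths <- c(associations = file.path(dir, "associations.tsv"),
             dag = file.path(dir, "dag.tsv"),
             expression = file.path(dir, "expression.tsv"),
             blocks = file.path(dir, "blocks.tsv"))
  write_associations(am, paths[["associations"]])
  write_dag(dag, paths[["dag"]])
  write_expression(expr, paths[["expression"]])
  utils::write.table(
    data.frame(id = c(rownames(am), colnames(am)),
               axis = rep(c("circRNA", "disease"), c(nrow(am), ncol(am))),
               block = c(attr(am, "circ_block"), attr(am, "disease_block"))),
    paths[["blocks"]], sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}
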