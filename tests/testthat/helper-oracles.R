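# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force (edge-following, path recursion, pairwise
# enumeration) rather than calling the implementation under test.

# transitive closure of child -> parent edges by repeated edge-following
oracle_closure <- function(edges, node) {
  out <- node
  repeat {
    parents <- edges[edges[, 1] %in% out, 2]
    new <- setdiff(parents, out)
    if (!length(new)) return(sort(out))
    out <- c(out, new)
  }
}

# memoized recursion for the ancestor contribution D_d(e)
oracle_contribution <- function(edges, d, mu) {
  closure <- oracle_closure(edges, d)
  memo <- new.env(parent = emptyenv())
  rec <- function(e) {
    if (e == d) return(1)
    if (!is.null(memo[[e]])) return(memo[[e]])
    children <- intersect(edges[edges[, 2] == e, 1], closure)
    val <- max(vapply(children, rec, numeric(1))) * mu
    memo[[e]] <- val
    val
  }
  stats::setNames(vapply(closure, rec, numeric(1)), closure)
}

oracle_dss1 <- function(edges, di, dj, mu) {
  ci <- oracle_contribution(edges, di, mu)
  cj <- oracle_contribution(edges, dj, mu)
  shared <- intersect(names(ci), names(cj))
  if (!length(shared)) return(0)
  sum(ci[shared] + cj[shared]) / (sum(ci) + sum(cj))
}

# Kahn's algorithm, independent of igraph
oracle_is_dag <- function(edges, nodes) {
  edges <- matrix(as.character(edges), ncol = 2)
  repeat {
    if (nrow(edges) == 0) return(TRUE)
    has_in <- unique(edges[, 2])
    sources <- setdiff(unique(edges[, 1]), has_in)
    if (!length(sources)) return(FALSE)
    edges <- edges[!edges[, 1] %in% sources, , drop = FALSE]
  }
}

oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))

# AUC as concordance: P(score_pos > score_neg) + 1/2 P(tie)
oracle_auc <- function(labels, scores) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  cmp <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
  mean(cmp)
}

oracle_mcc <- function(tp, fn, tn, fp) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

# random small DAG as a child -> parent edge list over n nodes
random_dag_edges <- function(n, p_edge = 0.5) {
  ids <- sprintf("n%02d", seq_len(n))
  edges <- NULL
  for (i in seq_len(n - 1)) {
    parents <- which(stats::runif(n - i) < p_edge) + i
    if (!length(parents)) parents <- i + 1L
    edges <- rbind(edges, cbind(ids[i], ids[parents]))
  }
  edges
}

tmp_tsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# a small, fully wired synthetic dataset for pipeline-level tests
small_dataset <- function(seed = 1, m = 40, n = 16, blocks = 2) {
  cfg <- synthetic_config(m = m, n = n, blocks = blocks, seed = seed)
  am <- simulate_associations(cfg)
  list(cfg = cfg, am = am, dag = simulate_dag(cfg),
       expr = simulate_expression(cfg),
       pairs = sample_negatives(am, seed = seed + 1))
}

fast_config <- function(seed = 1, k = 3, ...) {
  pipeline_config(k = k, ablation = "neither", seed = seed, ...)
}
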