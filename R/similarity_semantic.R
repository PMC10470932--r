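# Disease semantic similarity over an ontology DAG.
#
# Each disease d is described by DAG_d = (N_d, E_d), the sub-DAG induced by
# d and its ancestors. Ancestors contribute to d with a weight that decays
# by a factor mu per edge on the best (max-weight) path:
#   D_d(d) = 1;  D_d(e) = max{ mu * D_d(e') : e' child of e within DAG_d }.
# DV(d) = sum of contributions over N_d, and DSS1 compares two diseases by
# the contribution mass of their shared ancestors. DSS2 replaces the decay
# weight with an information-content weight -log(num(e) / num(diseases)).

#' Ancestor contribution weights for one disease
#'
#' Computes `D_d(e)` for every node `e` in `N_d` (the disease itself plus
#' its ancestors) by a single pass in reverse topological order: the disease
#' contributes 1 to itself, and each ancestor receives `mu` times the
#' largest contribution among its children inside `DAG_d`.
#'
#' @param dag a [disease_dag()].
#' @param d disease identifier (must be a DAG node).
#' @param mu semantic contribution decay factor in (0, 1]; default 0.5.
#' @return named numeric vector of contributions over `N_d`.
#' @export
disease_contribution <- function(dag, d, mu = 0.5) {
  assert_that(inherits(dag, "disease_dag"), "first argument must be a disease_dag")
  assert_that(mu > 0 && mu <= 1, "mu must be in (0, 1]")
  if (!d %in% dag$nodes) stop("disease '", d, "' not in DAG", call. = FALSE)
  nd <- dag$ancestors[[d]]
  sub <- igraph::induced_subgraph(dag$graph, nd)
  ord <- names(igraph::topo_sort(sub, mode = "out"))
  contrib <- stats::setNames(numeric(length(nd)), nd)
  contrib[d] <- 1
  for (e in ord) {
    if (e == d) next
    children <- names(igraph::neighbors(sub, e, mode = "in"))
    contrib[e] <- max(mu * contrib[children])
  }
  contrib
}

#' Semantic value of a disease
#'
#' `DV(d)`: the sum of ancestor contributions `D_d(e)` over `N_d`. Always at
#' least 1 since the disease contributes 1 to itself.
#'
#' @inheritParams disease_contribution
#' @return scalar semantic value.
#' @export
semantic_value <- function(dag, d, mu = 0.5) {
  sum(disease_contribution(dag, d, mu))
}

semantic_tables <- function(dag, diseases, mu) {
  present <- diseases %in% dag$nodes
  contribs <- vector("list", length(diseases))
  names(contribs) <- diseases
  for (d in diseases[present]) contribs[[d]] <- disease_contribution(dag, d, mu)
  list(present = present, contribs = contribs,
       dv = vapply(contribs, function(x) if (is.null(x)) NA_real_ else sum(x),
                   numeric(1)))
}

#' Decay-weighted disease semantic similarity (DSS1)
#'
#' `DSS1(i, j)` is the contribution mass of the shared ancestors of `i` and
#' `j`, normalized by the two semantic values:
#' `sum over shared e of (D_i(e) + D_j(e)) / (DV(i) + DV(j))`. The diagonal
#' is 1; diseases with disjoint DAGs score 0. Diseases absent from the DAG
#' get NA rows/columns; the logical `semantic_mask` attribute flags the
#' present ones (the fusion step falls back to the GIP kernel elsewhere).
#'
#' @param dag a [disease_dag()].
#' @param diseases character vector of disease identifiers (matrix order).
#' @param mu semantic decay factor in (0, 1].
#' @return symmetric n x n matrix with a `semantic_mask` attribute.
#' @export
dss1 <- function(dag, diseases, mu = 0.5) {
  tabs <- semantic_tables(dag, diseases, mu)
  n <- length(diseases)
  out <- matrix(NA_real_, n, n, dimnames = list(diseases, diseases))
  idx <- which(tabs$present)
  for (a in idx) {
    for (b in idx[idx >= a]) {
      ca <- tabs$contribs[[a]]
      cb <- tabs$contribs[[b]]
      shared <- intersect(names(ca), names(cb))
      val <- if (length(shared)) {
        sum(ca[shared] + cb[shared]) / (tabs$dv[a] + tabs$dv[b])
      } else 0
      out[a, b] <- out[b, a] <- val
    }
  }
  attr(out, "semantic_mask") <- stats::setNames(tabs$present, diseases)
  out
}

#' Information-content disease semantic similarity (DSS2)
#'
#' Shared ancestors are weighted by how specific they are across the
#' disease set: `D'(e) = -log(num(e) / num(diseases))` where, in
#' `information_content` mode, `num(e)` counts the diseases whose DAG
#' contains `e` (natural log). In `literal` mode the weight is the constant
#' `-log(|N_d| / num(diseases))` per disease. Pair scores share DSS1's
#' denominator `DV(i) + DV(j)`, are clipped at 0 and rescaled to [0, 1] by
#' dividing by the matrix maximum (the raw -log weights are unbounded).
#'
#' @inheritParams dss1
#' @param mode `"information_content"` (default) or `"literal"`.
#' @return symmetric n x n matrix in [0, 1] with a `semantic_mask` attribute.
#' @export
dss2 <- function(dag, diseases, mu = 0.5,
                 mode = c("information_content", "literal")) {
  mode <- match.arg(mode)
  tabs <- semantic_tables(dag, diseases, mu)
  n <- length(diseases)
  idx <- which(tabs$present)
  n_dis <- length(idx)
  out <- matrix(NA_real_, n, n, dimnames = list(diseases, diseases))
  if (n_dis > 0) {
    # num(e): number of disease DAGs containing node e
    all_anc <- unlist(lapply(tabs$contribs[idx], names), use.names = FALSE)
    num_e <- table(all_anc)
    for (a in idx) {
      for (b in idx[idx >= a]) {
        ca <- names(tabs$contribs[[a]])
        cb <- names(tabs$contribs[[b]])
        shared <- intersect(ca, cb)
        val <- if (length(shared)) {
          wts <- if (mode == "information_content") {
            2 * sum(-log(as.numeric(num_e[shared]) / n_dis))
          } else {
            wa <- -log(length(ca) / n_dis)
            wb <- -log(length(cb) / n_dis)
            length(shared) * (wa + wb)
          }
          wts / (tabs$dv[a] + tabs$dv[b])
        } else 0
        out[a, b] <- out[b, a] <- val
      }
    }
    sub <- out[idx, idx, drop = FALSE]
    sub[sub < 0] <- 0
    mx <- max(sub)
    if (mx > 0) sub <- sub / mx
    out[idx, idx] <- sub
  }
  attr(out, "semantic_mask") <- stats::setNames(tabs$present, diseases)
  out
}
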