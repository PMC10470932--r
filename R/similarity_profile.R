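# Profile-based similarities: Gaussian interaction profile (GIP) kernels
# over rows/columns of the association matrix, Spearman expression-profile
# similarity, and Jaccard similarity of association sets.

#' GIP bandwidth statistic
#'
#' Mean squared Euclidean norm of the interaction profiles (one profile per
#' row). The kernel in [gip_kernel()] uses the *inverse* of this value as
#' its width by default.
#'
#' @param profiles numeric matrix, one interaction profile per row.
#' @return scalar mean squared profile norm.
#' @export
gip_bandwidth <- function(profiles) {
  assert_that(is.matrix(profiles) && nrow(profiles) >= 1,
              "profiles must be a non-empty matrix")
  mean(rowSums(profiles^2))
}

#' Gaussian interaction profile kernel similarity
#'
#' `K(i, j) = exp(-gamma * ||V_i - V_j||^2)` over interaction profiles taken
#' from the association matrix: disease profiles are its columns, circRNA
#' profiles its rows. The width is `gamma = 1 / mu_bar` with `mu_bar` the
#' mean squared profile norm ([gip_bandwidth()]); `literal = TRUE` instead
#' uses `gamma = mu_bar` directly (the printed-formula reading, which
#' collapses the kernel toward 0 as networks densify).
#'
#' @param am binary association matrix (circRNAs x diseases).
#' @param axis `"disease"` (columns of `am`) or `"circrna"` (rows).
#' @param literal use `mu_bar` itself as the kernel width.
#' @return symmetric similarity matrix with unit diagonal, entries in (0, 1].
#' @export
gip_kernel <- function(am, axis = c("disease", "circrna"), literal = FALSE) {
  axis <- match.arg(axis)
  validate_assoc_matrix(am)
  profiles <- if (axis == "disease") t(am) else am
  storage.mode(profiles) <- "double"
  mu_bar <- gip_bandwidth(profiles)
  if (mu_bar == 0) {
    stop("GIP undefined on empty association matrix", call. = FALSE)
  }
  gamma <- if (literal) mu_bar else 1 / mu_bar
  sq <- rowSums(profiles^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0
  k <- exp(-gamma * d2)
  k <- (k + t(k)) / 2
  diag(k) <- 1
  k
}

#' Expression-profile similarity (Spearman)
#'
#' Pairwise similarity of circRNA expression profiles. `"standard"` mode is
#' tie-aware Spearman rank correlation of the two p-dimensional profiles
#' (Pearson correlation of ranks); constant profiles have zero rank variance
#' and their off-diagonal similarities are defined as 0 with a warning.
#' `"literal"` mode evaluates the printed textbook formula
#' `1 - 6 * sum(d^2) / (k * (k - 1))` on descending-sorted profiles with `k`
#' the number of circRNAs; it is unbounded and kept only for comparison.
#'
#' @param expr numeric matrix of profiles (circRNAs x samples), >= 2 columns.
#' @param mode `"standard"` (default) or `"literal"`.
#' @return symmetric k x k matrix; standard-mode entries lie in [-1, 1] with
#'   unit diagonal.
#' @export
expression_similarity <- function(expr, mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  assert_that(is.matrix(expr) && ncol(expr) >= 2,
              "need at least 2 expression dimensions")
  k <- nrow(expr)
  if (mode == "standard") {
    constant <- apply(expr, 1, function(x) length(unique(x)) == 1)
    s <- suppressWarnings(stats::cor(t(expr), method = "spearman"))
    if (any(constant)) {
      warning("constant expression profile(s): ",
              paste(utils::head(rownames(expr)[constant], 3), collapse = ", "),
              "; their similarities are set to 0")
    }
    s[!is.finite(s)] <- 0
    s <- (s + t(s)) / 2
    s[s > 1] <- 1
    s[s < -1] <- -1
    diag(s) <- 1
  } else {
    assert_that(k >= 2, "literal mode needs at least 2 circRNAs")
    sorted <- t(apply(expr, 1, sort, decreasing = TRUE))
    sq <- rowSums(sorted^2)
    d2 <- outer(sq, sq, "+") - 2 * tcrossprod(sorted)
    d2[d2 < 0] <- 0
    s <- 1 - 6 * d2 / (k * (k - 1))
    s <- (s + t(s)) / 2
  }
  dimnames(s) <- list(rownames(expr), rownames(expr))
  s
}

#' Jaccard similarity of association sets
#'
#' For diseases, `ca(d)` is the set of circRNAs with a 1 in `d`'s column;
#' `JD(i, j) = |ca(i) n ca(j)| / |ca(i) u ca(j)|` (and symmetrically over
#' rows for circRNAs). Pairs where both sets are empty score 0, including
#' the diagonal.
#'
#' @inheritParams gip_kernel
#' @return symmetric similarity matrix with entries in [0, 1].
#' @export
jaccard <- function(am, axis = c("disease", "circrna")) {
  axis <- match.arg(axis)
  validate_assoc_matrix(am)
  profiles <- if (axis == "disease") t(am) else am
  storage.mode(profiles) <- "double"
  inter <- tcrossprod(profiles)
  sizes <- rowSums(profiles)
  un <- outer(sizes, sizes, "+") - inter
  j <- ifelse(un > 0, inter / un, 0)
  (j + t(j)) / 2
}

#' Compute the full similarity bundle
#'
#' Convenience wrapper producing all seven similarity matrices the fusion
#' step consumes: DSS1/DSS2 (semantic, diseases), GD/GC (GIP kernels),
#' SE (expression Spearman, circRNAs), JD/JC (Jaccard). Masks record which
#' diseases are present in the DAG and which circRNAs have expression
#' profiles; SE rows for unprofiled circRNAs are NA.
#'
#' @param am binary association matrix (circRNAs x diseases).
#' @param dag a [disease_dag()].
#' @param expr expression matrix with circRNA row names (any subset of
#'   `rownames(am)`).
#' @param mu semantic decay factor.
#' @param dss2_mode passed to [dss2()].
#' @param gip_literal passed to [gip_kernel()].
#' @param se_mode passed to [expression_similarity()].
#' @return list of class `similarity_bundle`.
#' @export
compute_similarities <- function(am, dag, expr, mu = 0.5,
                                 dss2_mode = "information_content",
                                 gip_literal = FALSE, se_mode = "standard") {
  validate_assoc_matrix(am)
  diseases <- colnames(am)
  circ <- rownames(am)
  d1 <- dss1(dag, diseases, mu)
  d2 <- dss2(dag, diseases, mu, mode = dss2_mode)
  expr_mask <- stats::setNames(circ %in% rownames(expr), circ)
  se <- matrix(NA_real_, length(circ), length(circ),
               dimnames = list(circ, circ))
  if (any(expr_mask)) {
    sub <- expression_similarity(expr[circ[expr_mask], , drop = FALSE],
                                 mode = se_mode)
    se[expr_mask, expr_mask] <- sub
  }
  structure(list(
    DSS1 = d1, DSS2 = d2,
    GD = gip_kernel(am, "disease", literal = gip_literal),
    GC = gip_kernel(am, "circrna", literal = gip_literal),
    SE = se,
    JD = jaccard(am, "disease"),
    JC = jaccard(am, "circrna"),
    semantic_mask = attr(d1, "semantic_mask"),
    expression_mask = expr_mask
  ), class = "similarity_bundle")
}
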