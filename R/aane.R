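# Accelerated attributed network embedding (AANE).
#
# Factorizes an attribute cosine-similarity matrix S ~ Q Q' while pulling
# strongly connected nodes together:
#   L(Q) = ||S - Q Q'||_F^2 + lambda * sum_{i<j} w_ij ||q_i - q_j||_2 .
# The elastic-net-like second term is handled by ADMM: a copy Z of Q, a
# scaled dual U, and closed-form row updates
#   q_i <- [2 s_i Z + lambda * sum_j (w_ij / ||q_i - z_j||) z_j + rho (z_i - u_i)] P^-1
#   P    = 2 Z'Z + (lambda * sum_j w_ij / ||q_i - z_j|| + rho) I
# (and symmetrically for z_i with Q and +u_i), followed by U <- U + Q - Z.
# Rows are updated in ascending index order using the latest values
# (Gauss-Seidel); a small epsilon guards the distance denominators.

#' Cosine similarity between attribute rows
#'
#' @param attributes numeric node x feature matrix.
#' @return symmetric matrix with unit diagonal; all-zero attribute rows get
#'   0 off-diagonal similarity with a warning.
#' @export
attribute_similarity <- function(attributes) {
  assert_that(is.matrix(attributes), "attributes must be a matrix")
  norms <- sqrt(rowSums(attributes^2))
  zero <- norms == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero attribute row(s); their similarity is 0")
    norms[zero] <- 1
  }
  a <- attributes / norms
  s <- tcrossprod(a)
  s[s > 1] <- 1
  s[s < -1] <- -1
  s <- (s + t(s)) / 2
  diag(s) <- 1
  dimnames(s) <- list(rownames(attributes), rownames(attributes))
  s
}

aane_objective <- function(S, W, Q, lambda) {
  r <- S - tcrossprod(Q)
  obj <- sum(r^2)
  if (lambda > 0) {
    d <- as.matrix(stats::dist(Q))
    obj <- obj + lambda * sum(W * d) / 2
  }
  obj
}

#' Fit an attributed network embedding by ADMM
#'
#' @param S symmetric attribute similarity matrix (unit diagonal).
#' @param W symmetric nonnegative edge-weight matrix, zero diagonal.
#' @param d embedding dimension (<= N).
#' @param lambda balance between factorization fit and network smoothness.
#' @param rho ADMM penalty parameter (> 0).
#' @param max_iter maximum number of ADMM sweeps.
#' @param tol relative objective-change stopping threshold.
#' @param seed seed for the Gaussian(0, 0.01) initialization.
#' @param Q0 optional explicit N x d initialization (overrides `seed` and
#'   `init`).
#' @param init `"random"` (Gaussian(0, 0.01), the default) or `"spectral"`:
#'   top-d eigenpairs of S, i.e. the exact factorization the objective's
#'   first term targets, making the fit deterministic and independent of
#'   `seed`.
#' @param eps guard added inside distance denominators.
#' @return object of class `aane_fit`: `Q`, `Z`, `U`, `embedding`
#'   (`(Q + Z) / 2`), `objective_trace`, `iterations`, `converged`.
#' @export
aane_fit <- function(S, W, d, lambda = 0.05, rho = 5, max_iter = 50,
                     tol = 1e-4, seed = 1, Q0 = NULL,
                     init = c("random", "spectral"), eps = 1e-10) {
  init <- match.arg(init)
  N <- nrow(S)
  assert_that(is.matrix(S) && ncol(S) == N, "S must be square")
  assert_that(max(abs(S - t(S))) < 1e-8, "S must be symmetric")
  assert_that(all(dim(W) == N), "W must match S")
  assert_that(all(W >= 0), "W must be nonnegative")
  assert_that(all(diag(W) == 0), "W must have zero diagonal")
  assert_that(d >= 1 && d <= N, "need 1 <= d <= N")
  assert_that(lambda >= 0 && rho > 0, "need lambda >= 0 and rho > 0")

  Q <- if (!is.null(Q0)) {
    assert_that(all(dim(Q0) == c(N, d)), "Q0 must be N x d")
    Q0
  } else if (init == "spectral") {
    es <- eigen(S, symmetric = TRUE)
    es$vectors[, seq_len(d), drop = FALSE] %*%
      diag(sqrt(pmax(es$values[seq_len(d)], 0)), d)
  } else {
    withr::with_seed(as.integer(seed), matrix(stats::rnorm(N * d, 0, 0.01), N, d))
  }
  Z <- Q
  U <- matrix(0, N, d)
  Id <- diag(d)
  trace <- aane_objective(S, W, Q, lambda)
  converged <- FALSE
  iters <- 0L

  for (it in seq_len(max_iter)) {
    # Q sweep (Z, U fixed; q_i rows in ascending order)
    ZtZ2 <- 2 * crossprod(Z)
    if (lambda == 0) {
      rhs <- 2 * S %*% Z + rho * (Z - U)
      Q <- t(solve(ZtZ2 + rho * Id, t(rhs)))
    } else {
      for (i in seq_len(N)) {
        diff <- Z - matrix(Q[i, ], N, d, byrow = TRUE)
        dist_i <- sqrt(rowSums(diff^2)) + eps
        wo <- lambda * W[i, ] / dist_i
        rhs <- 2 * (S[i, ] %*% Z) + wo %*% Z + rho * (Z[i, ] - U[i, ])
        Q[i, ] <- solve(ZtZ2 + (sum(wo) + rho) * Id, as.vector(rhs))
      }
    }
    # Z sweep (uses the updated Q)
    QtQ2 <- 2 * crossprod(Q)
    if (lambda == 0) {
      rhs <- 2 * S %*% Q + rho * (Q + U)
      Z <- t(solve(QtQ2 + rho * Id, t(rhs)))
    } else {
      for (i in seq_len(N)) {
        diff <- Q - matrix(Z[i, ], N, d, byrow = TRUE)
        dist_i <- sqrt(rowSums(diff^2)) + eps
        wo <- lambda * W[i, ] / dist_i
        rhs <- 2 * (S[i, ] %*% Q) + wo %*% Q + rho * (Q[i, ] + U[i, ])
        Z[i, ] <- solve(QtQ2 + (sum(wo) + rho) * Id, as.vector(rhs))
      }
    }
    U <- U + Q - Z
    obj <- aane_objective(S, W, Q, lambda)
    if (!is.finite(obj)) {
      stop("AANE objective diverged; reduce rho or lambda", call. = FALSE)
    }
    prev <- trace[length(trace)]
    trace <- c(trace, obj)
    iters <- it
    if (abs(prev - obj) / max(abs(prev), eps) < tol) {
      converged <- TRUE
      break
    }
  }
  emb <- (Q + Z) / 2
  rownames(emb) <- rownames(S)
  structure(list(Q = Q, Z = Z, U = U, embedding = emb,
                 objective_trace = trace, iterations = iters,
                 converged = converged),
            class = "aane_fit")
}

#' @export
print.aane_fit <- function(x, ...) {
  cat("aane_fit:", nrow(x$Q), "nodes x", ncol(x$Q), "dims;",
      x$iterations, "sweeps; objective",
      format(x$objective_trace[length(x$objective_trace)], digits = 6), "\n")
  invisible(x)
}

#' Embed one side of the association network
#'
#' Builds the attribute similarity `S` from a side's fused, reduced
#' attribute rows (`CM` or `DM`), takes the side's fused similarity matrix
#' (`CS` or `DS`) as edge weights `W` (diagonal zeroed, negative entries
#' clamped to 0), and runs [aane_fit()] with spectral initialization (the
#' eigen-factorization of S that motivates the model), which makes the
#' embedding deterministic.
#'
#' @param attributes reduced attribute matrix for the side (nodes x r).
#' @param fused_sim the side's fused similarity matrix (nodes x nodes).
#' @param d embedding dimension; capped at the node count.
#' @param init initialization mode, see [aane_fit()].
#' @param ... further arguments to [aane_fit()].
#' @return node x d embedding matrix.
#' @export
embed_nodes <- function(attributes, fused_sim, d = 16, init = "spectral", ...) {
  assert_that(nrow(attributes) == nrow(fused_sim),
              "attribute and similarity row counts differ")
  s <- attribute_similarity(attributes)
  w <- fused_sim
  w[w < 0] <- 0
  w <- (w + t(w)) / 2
  diag(w) <- 0
  fit <- aane_fit(s, w, d = min(d, nrow(s)), init = init, ...)
  fit$embedding
}
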