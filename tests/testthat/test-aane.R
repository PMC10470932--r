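test_that("attribute cosine similarity matches a dot/norm oracle", {
  one_hot <- diag(4)
  s <- attribute_similarity(one_hot)
  expect_equal(unname(s), diag(4))

  same <- rbind(a = c(1, 2, 3), b = c(2, 4, 6))
  expect_equal(attribute_similarity(same)["a", "b"], 1)

  set.seed(20)
  a <- matrix(rnorm(50), 10, 5)
  s <- attribute_similarity(a)
  for (i in 1:10) for (j in 1:10) {
    oracle <- sum(a[i, ] * a[j, ]) /
      (sqrt(sum(a[i, ]^2)) * sqrt(sum(a[j, ]^2)))
    expect_equal(s[i, j], if (i == j) 1 else oracle, tolerance = 1e-12)
  }

  withzero <- rbind(c(1, 0), c(0, 0))
  expect_warning(sz <- attribute_similarity(withzero), "all-zero")
  expect_equal(sz[1, 2], 0)
  expect_equal(diag(sz), c(1, 1))
})

test_that("ADMM factorization recovers a planted low-rank similarity", {
  set.seed(22)
  N <- 30; d <- 4
  qstar <- matrix(rnorm(N * d), N, d)
  s <- tcrossprod(qstar)
  w <- matrix(0, N, N)
  fit <- aane_fit(s, w, d = d, lambda = 0, rho = 5, max_iter = 50, seed = 1)
  rel <- norm(s - tcrossprod(fit$embedding), "F") / norm(s, "F")
  expect_lte(rel, 0.05)
  expect_lte(fit$objective_trace[length(fit$objective_trace)],
             fit$objective_trace[1])
})

test_that("AANE fits are bitwise deterministic under a fixed seed", {
  set.seed(23)
  s <- attribute_similarity(matrix(rnorm(60), 12, 5))
  w <- matrix(runif(144), 12); w <- (w + t(w)) / 2; diag(w) <- 0
  f1 <- aane_fit(s, w, d = 3, lambda = 0.05, rho = 5, seed = 9)
  f2 <- aane_fit(s, w, d = 3, lambda = 0.05, rho = 5, seed = 9)
  expect_identical(f1$Q, f2$Q)
  expect_identical(f1$objective_trace, f2$objective_trace)
})

test_that("network smoothing pulls planted cliques together", {
  set.seed(24)
  N <- 20
  blk <- rep(1:2, each = 10)
  attrs <- matrix(rnorm(N * 6, sd = 0.2), N, 6) +
    outer(blk == 1, c(1, 1, 1, 0, 0, 0)) + outer(blk == 2, c(0, 0, 0, 1, 1, 1))
  s <- attribute_similarity(attrs)
  w <- outer(blk, blk, "==") * 1; diag(w) <- 0
  fit <- aane_fit(s, w, d = 4, lambda = 0.5, rho = 5, max_iter = 50, seed = 2)
  emb <- fit$embedding / sqrt(rowSums(fit$embedding^2))
  cosm <- tcrossprod(emb)
  same <- outer(blk, blk, "==") & upper.tri(cosm)
  diff <- !outer(blk, blk, "==") & upper.tri(cosm)
  expect_gt(mean(cosm[same]), mean(cosm[diff]))
})

test_that("AANE is equivariant to node permutation given matching init", {
  set.seed(25)
  N <- 15
  s <- attribute_similarity(matrix(rnorm(N * 4), N, 4))
  w <- matrix(runif(N * N), N); w <- (w + t(w)) / 2; diag(w) <- 0
  q0 <- matrix(rnorm(N * 3, 0, 0.01), N, 3)
  perm <- sample(N)
  f <- aane_fit(s, w, d = 3, lambda = 0.1, rho = 5, max_iter = 20, Q0 = q0)
  fp <- aane_fit(s[perm, perm], w[perm, perm], d = 3, lambda = 0.1, rho = 5,
                 max_iter = 20, Q0 = q0[perm, , drop = FALSE])
  expect_equal(unname(fp$embedding), unname(f$embedding[perm, ]),
               tolerance = 1e-8)
})

test_that("aane_fit validates its problem", {
  s <- diag(3); w <- matrix(0, 3, 3)
  expect_error(aane_fit(s, w, d = 5), "d <= N")
  expect_error(aane_fit(s, matrix(-1, 3, 3), d = 2), "nonnegative")
  expect_error(aane_fit(s, w, d = 2, rho = 0), "rho > 0")
})

test_that("embed_nodes returns deterministic spectral embeddings", {
  d <- small_dataset(seed = 26)
  sims <- compute_similarities(d$am, d$dag, d$expr)
  fused <- fuse_features(sims)
  e1 <- embed_nodes(fused$DM, fused$DS, d = 6, lambda = 1, max_iter = 20)
  e2 <- embed_nodes(fused$DM, fused$DS, d = 6, lambda = 1, max_iter = 20)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(ncol(d$am), 6))
  # zero lambda equals a pure factorization run of aane_fit
  s <- attribute_similarity(fused$DM)
  w <- pmax(fused$DS, 0); diag(w) <- 0
  ref <- aane_fit(s, (w + t(w)) / 2, d = 6, lambda = 0, max_iter = 50,
                  init = "spectral")
  direct <- embed_nodes(fused$DM, fused$DS, d = 6, lambda = 0, max_iter = 50)
  expect_equal(unname(direct), unname(ref$embedding), tolerance = 1e-10)
})
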