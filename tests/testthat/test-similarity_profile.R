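test_that("GIP bandwidth is the mean squared profile norm", {
  expect_equal(gip_bandwidth(diag(4)), 1)
  set.seed(2)
  b <- matrix(rbinom(60, 1, 0.4), 10, 6)
  expect_equal(gip_bandwidth(b), sum(b^2) / 10)
})

test_that("GIP kernel matches hand-computed values", {
  am <- diag(2)
  dimnames(am) <- list(c("c1", "c2"), c("d1", "d2"))
  # disease profiles are the columns (1,0) and (0,1): mu_bar = 1, gamma = 1
  gd <- gip_kernel(am, "disease")
  expect_equal(unname(diag(gd)), c(1, 1))
  expect_equal(gd[1, 2], exp(-2))
  # literal mode uses mu_bar itself; identical here since mu_bar = 1
  expect_equal(gip_kernel(am, "disease", literal = TRUE)[1, 2], exp(-2))

  am0 <- matrix(0L, 2, 2, dimnames = list(c("c1", "c2"), c("d1", "d2")))
  expect_error(gip_kernel(am0, "disease"), "empty association matrix")
})

test_that("GIP kernel equals a direct summation oracle on random matrices", {
  set.seed(8)
  am <- matrix(rbinom(200, 1, 0.3), 20, 10,
               dimnames = list(paste0("c", 1:20), paste0("d", 1:10)))
  for (axis in c("disease", "circrna")) {
    prof <- if (axis == "disease") t(am) else am
    gamma <- 1 / mean(rowSums(prof^2))
    oracle <- outer(seq_len(nrow(prof)), seq_len(nrow(prof)),
                    Vectorize(function(i, j) {
                      exp(-gamma * sum((prof[i, ] - prof[j, ])^2))
                    }))
    expect_lt(max(abs(gip_kernel(am, axis) - oracle)), 1e-12)
  }
})

test_that("GIP kernel decreases with profile distance and is permutation-equivariant", {
  set.seed(9)
  am <- matrix(rbinom(300, 1, 0.3), 30, 10,
               dimnames = list(paste0("c", 1:30), paste0("d", 1:10)))
  gc <- gip_kernel(am, "circrna")
  d2 <- as.matrix(dist(am))^2
  ut <- upper.tri(gc)
  # strictly smaller squared distance implies strictly larger similarity
  ord <- order(d2[ut])
  gs <- gc[ut][ord]; ds <- d2[ut][ord]
  step_up <- diff(ds) > 0
  expect_true(all(diff(gs)[step_up] < 0))
  expect_true(all(abs(diff(gs)[!step_up]) < 1e-12))

  perm <- sample(30)
  gp <- gip_kernel(am[perm, ], "circrna")
  expect_equal(unname(gp), unname(gc[perm, perm]))
})

test_that("standard Spearman similarity equals a rank-then-Pearson oracle", {
  set.seed(10)
  expr <- matrix(rnorm(15 * 32), 15, 32,
                 dimnames = list(paste0("c", 1:15), NULL))
  se <- expression_similarity(expr)
  n_checked <- 0
  for (i in 1:15) for (j in 1:15) {
    expect_equal(se[i, j],
                 if (i == j) 1 else oracle_spearman(expr[i, ], expr[j, ]),
                 tolerance = 1e-10)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 100)

  rev2 <- rbind(a = 1:10, b = 10:1)
  expect_equal(expression_similarity(rev2)["a", "b"], -1)
})

test_that("constant profiles get zero similarity with a warning", {
  expr <- rbind(flat = rep(2, 6), x = c(1, 3, 2, 5, 4, 6),
                y = c(2, 1, 4, 3, 6, 5))
  expect_warning(se <- expression_similarity(expr), "constant")
  expect_equal(se["flat", "x"], 0)
  expect_equal(se["flat", "flat"], 1)
})

test_that("literal expression mode evaluates the printed formula", {
  set.seed(11)
  expr <- matrix(rnorm(4 * 6), 4, 6, dimnames = list(paste0("c", 1:4), NULL))
  lit <- expression_similarity(expr, mode = "literal")
  k <- 4
  for (i in 1:4) for (j in 1:4) {
    d <- sort(expr[i, ], decreasing = TRUE) - sort(expr[j, ], decreasing = TRUE)
    expect_equal(lit[i, j], 1 - 6 * sum(d^2) / (k * (k - 1)), tolerance = 1e-12)
  }
})

test_that("Jaccard similarity matches set enumeration", {
  am <- matrix(0L, 4, 4, dimnames = list(paste0("c", 1:4), paste0("d", 1:4)))
  am[1, 1] <- am[2, 1] <- 1L          # d1 = {c1, c2}
  am[1, 2] <- am[2, 2] <- 1L          # d2 = {c1, c2}  identical, non-empty
  am[3, 3] <- 1L                       # d3 = {c3}      disjoint from d1
  am[1, 4] <- am[3, 4] <- am[4, 4] <- 1L  # d4 = {c1, c3, c4}: |n d1|=1, |u|=4
  jd <- jaccard(am, "disease")
  expect_equal(jd["d1", "d2"], 1)
  expect_equal(jd["d1", "d3"], 0)
  expect_equal(jd["d1", "d4"], 1 / 4)

  # empty sets score 0, including the diagonal
  am2 <- am; am2[, 3] <- 0L
  jd2 <- jaccard(am2, "disease")
  expect_equal(jd2["d3", "d3"], 0)
  expect_equal(jd2["d3", "d1"], 0)

  set.seed(12)
  amr <- matrix(rbinom(120, 1, 0.4), 12, 10,
                dimnames = list(paste0("c", 1:12), paste0("d", 1:10)))
  jc <- jaccard(amr, "circrna")
  for (i in 1:12) for (j in 1:12) {
    a <- which(amr[i, ] == 1); b <- which(amr[j, ] == 1)
    un <- length(union(a, b))
    expect_equal(jc[i, j], if (un == 0) 0 else length(intersect(a, b)) / un)
  }
})

test_that("the full similarity bundle is symmetric, bounded and well-masked", {
  d <- small_dataset(seed = 6)
  expr_partial <- d$expr[1:30, ]   # leave some circRNAs unprofiled
  sims <- compute_similarities(d$am, d$dag, expr_partial)
  for (nm in c("DSS1", "DSS2", "GD", "GC", "SE", "JD", "JC")) {
    m <- sims[[nm]]
    expect_lt(max(abs(m - t(m)), na.rm = TRUE), 1e-10)
  }
  for (nm in c("GD", "GC", "JD", "JC")) {
    expect_true(all(sims[[nm]] >= 0 & sims[[nm]] <= 1))
  }
  expect_true(all(abs(sims$SE[sims$expression_mask, sims$expression_mask]) <= 1))
  expect_true(all(is.na(sims$SE[!sims$expression_mask, ])))
  expect_equal(unname(diag(sims$GD)), rep(1, ncol(d$am)))
  expect_equal(sum(sims$expression_mask), 30)
})
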