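test_that("extreme densities give a perfect block-diagonal matrix", {
  cfg <- synthetic_config(m = 12, n = 8, blocks = 2, density_in = 1,
                          density_out = 0, seed = 3)
  am <- simulate_associations(cfg)
  cb <- attr(am, "circ_block")
  db <- attr(am, "disease_block")
  expect_equal(matrix(as.integer(am), nrow(am)), outer(cb, db, "==") + 0L,
               ignore_attr = TRUE)
})

test_that("generators are pure functions of config and seed", {
  cfg <- synthetic_config(seed = 11)
  expect_identical(simulate_associations(cfg), simulate_associations(cfg))
  expect_identical(simulate_dag(cfg)$edges, simulate_dag(cfg)$edges)
  expect_identical(simulate_expression(cfg), simulate_expression(cfg))
  cfg2 <- synthetic_config(seed = 12)
  expect_false(identical(simulate_associations(cfg),
                         simulate_associations(cfg2)))
})

test_that("positive count is within 3 sigma of its binomial expectation", {
  cfg <- synthetic_config(m = 80, n = 30, blocks = 4, density_in = 0.3,
                          density_out = 0.02, seed = 17)
  am <- simulate_associations(cfg)
  cb <- attr(am, "circ_block"); db <- attr(am, "disease_block")
  p <- ifelse(outer(cb, db, "=="), 0.3, 0.02)
  mu <- sum(p); sdev <- sqrt(sum(p * (1 - p)))
  expect_lt(abs(sum(am) - mu), 3 * sdev)
})

test_that("zero-density config is rejected", {
  expect_error(synthetic_config(density_in = 0, density_out = 0))
})

test_that("simulated DAGs are acyclic with the expected node count", {
  set.seed(5)
  for (rep in 1:100) {
    cfg <- synthetic_config(n = sample(5:25, 1),
                            blocks = sample(1:4, 1),
                            m = 30,
                            dag_depth = sample(1:4, 1),
                            dag_branching = sample(1:3, 1),
                            seed = rep)
    dag <- simulate_dag(cfg)
    expect_true(oracle_is_dag(dag$edges, dag$nodes))
    extra <- if (cfg$blocks == 1) 1L else cfg$blocks + 1L
    expect_length(dag$nodes, cfg$n + extra)
  }
})

test_that("single-block depth-1 DAG is a star from the synthetic root", {
  dag <- simulate_dag(synthetic_config(n = 8, blocks = 1, dag_depth = 1,
                                       m = 8, seed = 2))
  expect_true(all(dag$edges[, 2] == "disease_root"))
  expect_equal(nrow(dag$edges), 8)
})

test_that("noise-free expression profiles are identical within a block", {
  cfg <- synthetic_config(m = 12, n = 8, blocks = 3, noise_sd = 0, seed = 4)
  expr <- simulate_expression(cfg)
  blocks <- sort(rep_len(1:3, 12))
  for (b in 1:3) {
    rows <- expr[blocks == b, , drop = FALSE]
    expect_lt(max(abs(sweep(rows, 2, rows[1, ]))), 1e-12)
    expect_equal(suppressWarnings(cor(rows[1, ], rows[2, ],
                                      method = "spearman")), 1)
  }
})

test_that("within-block rank correlation exceeds between-block on average", {
  within <- between <- numeric(10)
  for (s in 1:10) {
    cfg <- synthetic_config(seed = 100 + s)
    expr <- simulate_expression(cfg)
    blocks <- sort(rep_len(seq_len(cfg$blocks), cfg$m))
    rho <- cor(t(expr), method = "spearman")
    same <- outer(blocks, blocks, "==") & upper.tri(rho)
    diff <- !outer(blocks, blocks, "==") & upper.tri(rho)
    within[s] <- mean(rho[same]); between[s] <- mean(rho[diff])
  }
  expect_gt(mean(within), mean(between))
})

test_that("negative sampling draws uniformly from the zero cells", {
  cfg <- synthetic_config(m = 6, n = 4, blocks = 2, density_in = 1,
                          density_out = 0, seed = 9)
  am <- simulate_associations(cfg)
  zeros <- which(am == 0)

  all_zero <- sample_negatives(am, n_neg = length(zeros), seed = 1)
  expect_equal(nrow(all_zero), sum(am) + length(zeros))
  expect_true(all(am[cbind(all_zero$circ, all_zero$disease)] == all_zero$label))

  expect_error(sample_negatives(am, n_neg = length(zeros) + 1), "exceeds")

  # frequency of each zero cell over many resamples, uniform within 4 sigma
  counts <- stats::setNames(numeric(length(zeros)), zeros)
  n_rep <- 10000
  for (r in seq_len(n_rep)) {
    neg <- sample_negatives(am, n_neg = 1, seed = r)
    cell <- (neg$disease[neg$label == 0] - 1) * nrow(am) +
      neg$circ[neg$label == 0]
    counts[as.character(cell)] <- counts[as.character(cell)] + 1
  }
  p <- 1 / length(zeros)
  bound <- 4 * sqrt(n_rep * p * (1 - p))
  expect_true(all(abs(counts - n_rep * p) < bound))
})
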