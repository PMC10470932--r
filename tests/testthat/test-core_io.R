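test_that("association TSV reading builds the expected matrix", {
  path <- tmp_tsv(c("circRNA_id\tdisease_id\tlabel",
                    "c1\td1\t1", "c2\td2\t0", "c2\td1\t0"))
  am <- read_associations(path)
  expect_equal(dim(am), c(2, 2))
  expect_equal(rownames(am), c("c1", "c2"))
  expect_equal(colnames(am), c("d1", "d2"))
  expect_equal(sum(am), 1)
  expect_equal(am["c1", "d1"], 1L)
})

test_that("association reading rejects degenerate input", {
  expect_error(read_associations(tmp_tsv("circRNA_id\tdisease_id\tlabel")),
               "no associations")
  expect_error(read_associations(tmp_tsv(c("circRNA_id\tdisease_id\tlabel",
                                           "c1\td1\t2"))),
               "unknown label")
  expect_error(read_associations(tmp_tsv(c("circRNA_id\tdisease_id\tlabel",
                                           "c1\td1\t1", "c1\td1\t0"))),
               "contradictory")
})

test_that("positive count matches an independent line scan at benchmark scale", {
  set.seed(42)
  circ <- sprintf("hsa_circ_%04d", 1:300)
  dis <- sprintf("disease_%03d", 1:60)
  cells <- sample(300 * 60, 739 + 211)
  lab <- rep(c(1L, 0L), c(739, 211))
  lines <- c("circRNA_id\tdisease_id\tlabel",
             sprintf("%s\t%s\t%d", circ[(cells - 1) %% 300 + 1],
                     dis[(cells - 1) %/% 300 + 1], lab))
  path <- tmp_tsv(lines)
  # oracle: count label-1 rows straight off the file text
  raw <- readLines(path)[-1]
  n_pos <- sum(vapply(strsplit(raw, "\t"), `[`, character(1), 3) == "1")
  expect_equal(n_pos, 739L)
  expect_equal(sum(read_associations(path)), n_pos)
})

test_that("DAG reading computes ancestor closures and rejects cycles", {
  dag <- read_dag(tmp_tsv(c("child\tparent", "a\tb")))
  expect_setequal(dag$ancestors[["a"]], c("a", "b"))
  expect_equal(dag$ancestors[["b"]], "b")

  expect_error(read_dag(tmp_tsv(c("a\ta"))), "cycle")
  expect_error(read_dag(tmp_tsv(c("a\tb", "b\tc", "c\ta"))), "cycle")

  diamond <- read_dag(tmp_tsv(c("a\tb", "a\tc", "b\td", "c\td")))
  edges <- matrix(c("a", "b", "a", "c", "b", "d", "c", "d"), ncol = 2,
                  byrow = TRUE)
  expect_setequal(diamond$ancestors[["a"]], oracle_closure(edges, "a"))
  expect_length(diamond$ancestors[["a"]], 4)
})

test_that("random DAG closures agree with brute-force edge following", {
  set.seed(7)
  for (rep in 1:5) {
    edges <- random_dag_edges(7)
    dag <- disease_dag(edges)
    for (v in dag$nodes) {
      expect_setequal(dag$ancestors[[v]], oracle_closure(edges, v))
    }
  }
})

test_that("matrix CSV round-trips exactly", {
  m <- diag(2)
  dimnames(m) <- list(c("r1", "r2"), c("c1", "c2"))
  path <- tempfile(fileext = ".csv")
  write_matrix(m, path)
  expect_identical(read_matrix(path), m)

  set.seed(1)
  big <- matrix(rnorm(50 * 50), 50, 50,
                dimnames = list(sprintf("r%02d", 1:50), sprintf("c%02d", 1:50)))
  write_matrix(big, path)
  expect_lt(max(abs(read_matrix(path) - big)), 1e-12)
})

test_that("non-numeric matrix cells produce located errors", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("id,c1,c2", "r1,1.0,NaN", "r2,0.5,2"), path)
  expect_error(read_matrix(path), "r1.*c2")
})

test_that("expression and association writers round-trip", {
  set.seed(3)
  expr <- matrix(rnorm(12), 4, 3,
                 dimnames = list(paste0("circ", 1:4), paste0("s", 1:3)))
  path <- tempfile(fileext = ".tsv")
  write_expression(expr, path)
  expect_lt(max(abs(read_expression(path) - expr)), 1e-12)

  cfg <- synthetic_config(m = 10, n = 6, blocks = 2, seed = 5)
  am <- simulate_associations(cfg)
  apath <- tempfile(fileext = ".tsv")
  write_associations(am, apath)
  am2 <- read_associations(apath)
  expect_equal(unname(am2[rownames(am), colnames(am)]),
               unname(matrix(as.integer(am), nrow(am))))
})
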