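#' @keywords internal
"_PACKAGE"

# ---- internal checks --------------------------------------------------------

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}

#' Validate a circRNA x disease association matrix
#'
#' The canonical association container is a plain integer matrix with
#' circRNA identifiers as row names and disease identifiers as column names;
#' every entry is 0 (unknown) or 1 (supported association).
#'
#' @param am matrix to validate.
#' @return `am`, invisibly, after validation.
#' @export
validate_assoc_matrix <- function(am) {
  assert_that(is.matrix(am), "association matrix must be a matrix")
  assert_that(nrow(am) >= 1 && ncol(am) >= 1,
              "association matrix must have at least one row and column")
  assert_that(all(am %in% c(0, 1)), "association matrix entries must be 0 or 1")
  assert_that(!is.null(rownames(am)) && !is.null(colnames(am)),
              "association matrix needs circRNA row names and disease column names")
  assert_that(!anyDuplicated(rownames(am)), "duplicate circRNA identifiers")
  assert_that(!anyDuplicated(colnames(am)), "duplicate disease identifiers")
  invisible(am)
}

# ---- association TSV --------------------------------------------------------

#' Read a circRNA-disease association table
#'
#' Reads a long-format TSV with header `circRNA_id<TAB>disease_id<TAB>label`
#' (label 0 or 1) and returns the binary association matrix. Rows are
#' circRNAs, columns are diseases; both axes are sorted lexicographically so
#' the matrix is deterministic for a given file. Identifiers appearing only
#' in label-0 rows still enter the registries (as all-zero profiles).
#'
#' @param path path to the TSV file.
#' @return integer matrix of 0/1 with circRNA row names and disease column
#'   names.
#' @export
read_associations <- function(path) {
  assert_that(file.exists(path), "no such file: '", path, "'")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("circRNA_id", "disease_id", "label")
  assert_that(all(need %in% names(df)),
              "association TSV needs columns circRNA_id, disease_id, label")
  if (nrow(df) == 0) stop("no associations in '", path, "'", call. = FALSE)
  bad <- !df$label %in% c("0", "1")
  if (any(bad)) {
    stop("unknown label value '", df$label[which(bad)[1]], "' at data row ",
         which(bad)[1], call. = FALSE)
  }
  key <- paste(df$circRNA_id, df$disease_id, sep = "\r")
  if (anyDuplicated(key)) {
    labs <- tapply(df$label, key, function(x) length(unique(x)))
    contra <- names(labs)[labs > 1]
    if (length(contra)) {
      pair <- strsplit(contra[1], "\r", fixed = TRUE)[[1]]
      stop("contradictory labels for pair (", pair[1], ", ", pair[2], ")",
           call. = FALSE)
    }
  }
  circ_ids <- sort(unique(df$circRNA_id))
  disease_ids <- sort(unique(df$disease_id))
  am <- matrix(0L, length(circ_ids), length(disease_ids),
               dimnames = list(circ_ids, disease_ids))
  pos <- df[df$label == "1", , drop = FALSE]
  if (nrow(pos)) {
    am[cbind(match(pos$circRNA_id, circ_ids),
             match(pos$disease_id, disease_ids))] <- 1L
  }
  validate_assoc_matrix(am)
  am
}

#' Write a labelled pair set as an association TSV
#'
#' Companion writer for [read_associations()]: emits one row per labelled
#' pair so association data round-trips through the long format.
#'
#' @param am binary association matrix (labels for the 1-cells).
#' @param path output path.
#' @param pairs optional data frame with columns `circ`, `disease`, `label`
#'   (integer indices into `am`); when given, exactly those pairs are
#'   written. Default writes every cell of `am`.
#' @export
write_associations <- function(am, path, pairs = NULL) {
  validate_assoc_matrix(am)
  if (is.null(pairs)) {
    idx <- expand.grid(circ = seq_len(nrow(am)), disease = seq_len(ncol(am)))
    pairs <- data.frame(circ = idx$circ, disease = idx$disease,
                        label = am[cbind(idx$circ, idx$disease)])
  }
  out <- data.frame(circRNA_id = rownames(am)[pairs$circ],
                    disease_id = colnames(am)[pairs$disease],
                    label = as.integer(pairs$label))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

# ---- disease DAG ------------------------------------------------------------

#' Construct a disease ontology DAG
#'
#' Builds the ancestor structure used by the semantic similarity measures
#' from a child-to-parent edge list. Acyclicity is enforced; for every node
#' `d` the closure `N_d` (ancestors of `d` including `d` itself) is
#' precomputed.
#'
#' @param edges two-column character matrix or data frame of (child, parent)
#'   edges.
#' @param nodes optional extra isolated node identifiers.
#' @return object of class `disease_dag` with elements `nodes`, `edges`,
#'   `ancestors` (named list of `N_d`) and the underlying `igraph` graph.
#' @export
disease_dag <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0) edges <- matrix(character(), 0, 2)
  assert_that(ncol(edges) == 2, "edge list must have two columns (child, parent)")
  storage.mode(edges) <- "character"
  self <- edges[, 1] == edges[, 2]
  if (any(self)) {
    stop("cycle detected: self-loop edge ", edges[which(self)[1], 1], " -> ",
         edges[which(self)[1], 2], call. = FALSE)
  }
  all_nodes <- unique(c(edges[, 1], edges[, 2], nodes))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]),
    directed = TRUE, vertices = all_nodes)
  if (!igraph::is_dag(g)) {
    bad <- find_cycle_edge(edges, all_nodes)
    stop("cycle detected involving edge ", bad[1], " -> ", bad[2],
         call. = FALSE)
  }
  anc <- lapply(all_nodes, function(v) {
    names(igraph::subcomponent(g, v, mode = "out"))
  })
  names(anc) <- all_nodes
  structure(list(nodes = all_nodes, edges = edges, ancestors = anc, graph = g),
            class = "disease_dag")
}

# Kahn's elimination just to *name* an offending edge when the graph is
# cyclic; acyclicity itself is decided by igraph::is_dag.
find_cycle_edge <- function(edges, nodes) {
  remaining <- edges
  repeat {
    outdeg <- table(factor(remaining[, 1], levels = nodes))
    sinks <- names(outdeg)[outdeg == 0]
    keep <- !(remaining[, 2] %in% sinks)
    if (all(keep)) break
    remaining <- remaining[keep, , drop = FALSE]
  }
  remaining[1, ]
}

#' @export
print.disease_dag <- function(x, ...) {
  cat("disease_dag:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Read a disease DAG from a child-parent edge list TSV
#'
#' Rows are `child<TAB>parent`; an optional `child  parent` header line is
#' skipped. See [disease_dag()] for the returned structure.
#'
#' @param path path to the edge-list TSV.
#' @return a `disease_dag` object.
#' @export
read_dag <- function(path) {
  assert_that(file.exists(path), "no such file: '", path, "'")
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  assert_that(ncol(df) >= 2, "DAG edge list must have two tab-separated columns")
  if (nrow(df) > 0 && tolower(df[1, 1]) %in% c("child", "#child")) {
    df <- df[-1, , drop = FALSE]
  }
  disease_dag(df[, 1:2])
}

#' Write a disease DAG edge list
#'
#' @param dag a `disease_dag` object.
#' @param path output path.
#' @export
write_dag <- function(dag, path) {
  assert_that(inherits(dag, "disease_dag"), "not a disease_dag")
  utils::write.table(data.frame(child = dag$edges[, 1], parent = dag$edges[, 2]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}

# ---- expression table -------------------------------------------------------

#' Read a circRNA expression profile table
#'
#' TSV with a header; the first column holds circRNA identifiers, the
#' remaining columns numeric expression values (one column per sample).
#'
#' @param path path to the TSV.
#' @return numeric matrix, rows named by circRNA identifier.
#' @export
read_expression <- function(path) {
  assert_that(file.exists(path), "no such file: '", path, "'")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  assert_that(ncol(df) >= 2, "expression table needs an id column and >=1 sample")
  ids <- df[[1]]
  assert_that(!anyDuplicated(ids), "duplicate circRNA identifiers in expression table")
  num <- parse_numeric_block(df[, -1, drop = FALSE], ids)
  rownames(num) <- ids
  num
}

#' Write a circRNA expression profile table
#'
#' @param expr numeric matrix with circRNA row names.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  assert_that(is.matrix(expr) && !is.null(rownames(expr)),
              "expression table must be a matrix with row names")
  cn <- colnames(expr)
  if (is.null(cn)) cn <- paste0("sample_", seq_len(ncol(expr)))
  header <- paste(c("circRNA_id", cn), collapse = "\t")
  body <- vapply(seq_len(nrow(expr)), function(i) {
    paste(c(rownames(expr)[i], sprintf("%.17g", expr[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

parse_numeric_block <- function(df, row_ids) {
  out <- matrix(NA_real_, nrow(df), ncol(df))
  colnames(out) <- names(df)
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop("non-numeric or non-finite value '", df[[j]][bad[1]],
           "' at row '", row_ids[bad[1]], "', column '", names(df)[j], "'",
           call. = FALSE)
    }
    out[, j] <- v
  }
  out
}

# ---- dense matrix CSV -------------------------------------------------------

#' Write a dense matrix as CSV with id headers
#'
#' First row holds column identifiers, first column row identifiers. Values
#' are written with 17 significant digits so [read_matrix()] reproduces them
#' to better than 1e-12.
#'
#' @param mat numeric matrix (dimnames optional; defaults generated).
#' @param path output path.
#' @export
write_matrix <- function(mat, path) {
  assert_that(is.matrix(mat), "write_matrix needs a matrix")
  rn <- rownames(mat) %||% paste0("r", seq_len(nrow(mat)))
  cn <- colnames(mat) %||% paste0("c", seq_len(ncol(mat)))
  header <- paste(c("id", cn), collapse = ",")
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rn[i], sprintf("%.17g", mat[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a dense matrix written by [write_matrix()]
#'
#' @param path path to the CSV.
#' @return numeric matrix with the stored dimnames.
#' @export
read_matrix <- function(path) {
  assert_that(file.exists(path), "no such file: '", path, "'")
  df <- utils::read.csv(path, header = TRUE, colClasses = "character",
                        check.names = FALSE)
  assert_that(ncol(df) >= 2, "matrix CSV needs an id column and >=1 value column")
  ids <- df[[1]]
  num <- parse_numeric_block(df[, -1, drop = FALSE], ids)
  rownames(num) <- ids
  num
}

`%||%` <- function(a, b) if (is.null(a)) b else a
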