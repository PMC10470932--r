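# Multisource similarity fusion: average semantic and kernel similarities
# where both are defined, fall back to the GIP kernel elsewhere, concatenate
# with Jaccard, and reduce by PCA into per-node attribute rows. Per-pair
# feature vectors concatenate the two reduced rows.

#' Fuse disease similarities
#'
#' `DS(i, j)` averages the two semantic similarities where both diseases
#' have DAG entries and falls back to the GIP kernel value otherwise.
#'
#' @param dss1,dss2 semantic similarity matrices (NA outside the mask).
#' @param gd disease GIP kernel matrix.
#' @param semantic_mask logical vector: disease present in the DAG.
#' @return symmetric fused matrix `DS`.
#' @export
fuse_disease <- function(dss1, dss2, gd, semantic_mask) {
  assert_that(all(dim(dss1) == dim(gd)) && all(dim(dss2) == dim(gd)),
              "similarity matrix shape mismatch")
  assert_that(length(semantic_mask) == nrow(gd), "mask length mismatch")
  both <- outer(semantic_mask, semantic_mask, "&")
  ds <- gd
  ds[both] <- (dss1[both] + dss2[both]) / 2
  (ds + t(ds)) / 2
}

#' Fuse circRNA similarities
#'
#' `CS(i, j)` averages expression-profile and GIP kernel similarity where
#' both circRNAs have expression profiles and falls back to the GIP kernel
#' value otherwise.
#'
#' @param se expression-profile similarity matrix (NA outside the mask).
#' @param gc circRNA GIP kernel matrix.
#' @param expression_mask logical vector: circRNA has an expression profile.
#' @return symmetric fused matrix `CS`.
#' @export
fuse_circrna <- function(se, gc, expression_mask) {
  assert_that(all(dim(se) == dim(gc)), "similarity matrix shape mismatch")
  assert_that(length(expression_mask) == nrow(gc), "mask length mismatch")
  both <- outer(expression_mask, expression_mask, "&")
  cs <- gc
  cs[both] <- (se[both] + gc[both]) / 2
  (cs + t(cs)) / 2
}

#' PCA dimensionality reduction with deterministic sign
#'
#' Mean-centers the columns and returns principal-component scores. The
#' number of retained components is the smallest reaching `variance_kept`
#' of the total variance (default 0.95, capped at `max_r`), or a fixed `r`
#' if given. Component sign is fixed by forcing the largest-magnitude
#' loading of each component positive, so results are fully deterministic.
#'
#' @param x numeric matrix (>= 2 rows), e.g. `[DS, JD]` or `[CS, JC]`.
#' @param variance_kept fraction of variance to keep, in (0, 1].
#' @param r optional fixed number of components (overrides `variance_kept`).
#' @param max_r cap on the number of components.
#' @return score matrix with attributes `rotation`, `center` and
#'   `var_explained` (per-component variance fractions).
#' @export
reduce_dims <- function(x, variance_kept = 0.95, r = NULL, max_r = 128) {
  assert_that(is.matrix(x) && nrow(x) >= 2, "need at least 2 rows to reduce")
  assert_that(!anyNA(x), "reduce_dims input contains NA")
  assert_that(variance_kept > 0 && variance_kept <= 1,
              "variance_kept must be in (0, 1]")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  vars <- pc$sdev^2
  total <- sum(vars)
  if (total <= .Machine$double.eps) {
    warning("input has (near-)zero variance; returning a single zero component")
    out <- matrix(0, nrow(x), 1, dimnames = list(rownames(x), "PC1"))
    attr(out, "rotation") <- pc$rotation[, 1, drop = FALSE]
    attr(out, "center") <- pc$center
    attr(out, "var_explained") <- 1
    return(out)
  }
  frac <- vars / total
  keep <- if (!is.null(r)) {
    assert_that(r >= 1 && r <= ncol(pc$x), "fixed r out of range")
    r
  } else {
    which(cumsum(frac) >= variance_kept - 1e-12)[1]
  }
  keep <- min(keep, max_r, ncol(pc$x))
  scores <- pc$x[, seq_len(keep), drop = FALSE]
  rot <- pc$rotation[, seq_len(keep), drop = FALSE]
  for (j in seq_len(keep)) {
    lead <- which.max(abs(rot[, j]))
    if (rot[lead, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(x)
  attr(scores, "rotation") <- rot
  attr(scores, "center") <- pc$center
  attr(scores, "var_explained") <- frac[seq_len(keep)]
  scores
}

#' Build the fused, reduced node attribute matrices
#'
#' Concatenates `[DS, JD]` and `[CS, JC]` and reduces each by
#' [reduce_dims()], yielding the disease attribute matrix `DM` (n x r_d)
#' and the circRNA attribute matrix `CM` (m x r_c).
#'
#' @param sims a `similarity_bundle` from [compute_similarities()].
#' @param variance_kept,max_r passed to [reduce_dims()].
#' @return list with `DS`, `CS`, `DM`, `CM` (reduced), and the masks.
#' @export
fuse_features <- function(sims, variance_kept = 0.95, max_r = 128) {
  stopifnot(inherits(sims, "similarity_bundle"))
  ds <- fuse_disease(sims$DSS1, sims$DSS2, sims$GD, sims$semantic_mask)
  cs <- fuse_circrna(sims$SE, sims$GC, sims$expression_mask)
  dm <- reduce_dims(cbind(ds, sims$JD), variance_kept, max_r = max_r)
  cm <- reduce_dims(cbind(cs, sims$JC), variance_kept, max_r = max_r)
  list(DS = ds, CS = cs, DM = dm, CM = cm,
       semantic_mask = sims$semantic_mask,
       expression_mask = sims$expression_mask)
}

#' Per-pair feature vectors
#'
#' `FV(c(i), d(j))` concatenates row `i` of the reduced circRNA attribute
#' matrix with row `j` of the reduced disease attribute matrix; pair order
#' is preserved.
#'
#' @param cm_reduced reduced circRNA matrix (m x r_c).
#' @param dm_reduced reduced disease matrix (n x r_d).
#' @param pairs data frame with integer columns `circ` and `disease`.
#' @return numeric matrix, one feature row of length `r_c + r_d` per pair.
#' @export
pair_features <- function(cm_reduced, dm_reduced, pairs) {
  assert_that(all(pairs$circ >= 1 & pairs$circ <= nrow(cm_reduced)),
              "circ index out of range")
  assert_that(all(pairs$disease >= 1 & pairs$disease <= nrow(dm_reduced)),
              "disease index out of range")
  fv <- cbind(cm_reduced[pairs$circ, , drop = FALSE],
              dm_reduced[pairs$disease, , drop = FALSE])
  colnames(fv) <- c(paste0("c", seq_len(ncol(cm_reduced))),
                    paste0("d", seq_len(ncol(dm_reduced))))
  rownames(fv) <- NULL
  fv
}
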