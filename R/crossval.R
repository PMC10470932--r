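# Cross-validated evaluation of the full pipeline and candidate ranking.
#
# leakage modes: label-derived similarities (GIP kernels, Jaccard) depend on
# the association matrix, i.e. on the labels themselves. "fold_safe"
# recomputes them per fold from the training fold's matrix (test-pair cells
# zeroed) so no test label can reach the features; "paper_faithful" computes
# them once from the full matrix, which inflates performance and is kept
# only for faithfulness comparisons.

#' Pipeline configuration
#'
#' Collects every stage's hyperparameters plus the global seed. Per-stage
#' seeds are derived from the global seed by fixed offsets (negatives
#' +1000, folds +2000, AANE +3000, DCAE +4000, classifier +5000) so stages
#' can be rerun in isolation.
#'
#' @param mu semantic decay factor.
#' @param dss2_mode,gip_literal,se_mode similarity options (see
#'   [compute_similarities()]).
#' @param variance_kept,max_r PCA options (see [reduce_dims()]).
#' @param aane_dim,aane_lambda,aane_rho,aane_max_iter,aane_tol AANE options;
#'   the pipeline default (`d = 8`, `lambda = 2`) smooths embeddings toward
#'   cluster centroids at this network scale (see the methods vignette).
#' @param dcae a [dcae_config()]; the default here is scaled to the 80 x 30
#'   synthetic study (2/4 channels, hidden 32, lr 0.5, 10 + 20 epochs; see
#'   the methods vignette for the step-size rationale).
#' @param classifier a [classifier_config()].
#' @param k number of cross-validation folds.
#' @param leakage `"fold_safe"` or `"paper_faithful"`.
#' @param ablation feature ablation (see [assemble_features()]).
#' @param top_n candidates to report from [rank_candidates()].
#' @param seed global seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(mu = 0.5, dss2_mode = "information_content",
                            gip_literal = FALSE, se_mode = "standard",
                            variance_kept = 0.95, max_r = 128,
                            aane_dim = 8, aane_lambda = 2, aane_rho = 5,
                            aane_max_iter = 30, aane_tol = 1e-4,
                            dcae = dcae_config(channels = c(2, 4),
                                               hidden_dim = 8,
                                               learning_rate = 0.5,
                                               epochs = 20,
                                               pretrain_epochs = 10,
                                               batch_size = 64),
                            classifier = classifier_config(),
                            k = 5, leakage = c("fold_safe", "paper_faithful"),
                            ablation = "full", top_n = 20, seed = 1) {
  leakage <- match.arg(leakage)
  structure(list(mu = mu, dss2_mode = dss2_mode, gip_literal = gip_literal,
                 se_mode = se_mode, variance_kept = variance_kept,
                 max_r = max_r, aane_dim = aane_dim,
                 aane_lambda = aane_lambda, aane_rho = aane_rho,
                 aane_max_iter = aane_max_iter, aane_tol = aane_tol,
                 dcae = dcae, classifier = classifier, k = as.integer(k),
                 leakage = leakage, ablation = ablation,
                 top_n = as.integer(top_n), seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_seed <- function(config, offset) config$seed + offset

#' Stratified fold assignment
#'
#' @param labels 0/1 vector.
#' @param k number of folds.
#' @param seed seed for the within-class shuffles.
#' @return integer fold id per pair; folds partition the pairs and keep the
#'   class ratio within one sample of balance.
#' @export
stratified_folds <- function(labels, k, seed = 1) {
  assert_that(k >= 2, "need k >= 2 folds")
  folds <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      folds[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
    }
  })
  folds
}

# Label-independent similarity pieces, computed once per dataset.
precompute_static_sims <- function(am, dag, expr, config) {
  diseases <- colnames(am)
  circ <- rownames(am)
  d1 <- dss1(dag, diseases, config$mu)
  d2 <- dss2(dag, diseases, config$mu, mode = config$dss2_mode)
  expr_mask <- stats::setNames(circ %in% rownames(expr), circ)
  se <- matrix(NA_real_, length(circ), length(circ),
               dimnames = list(circ, circ))
  if (any(expr_mask)) {
    se[expr_mask, expr_mask] <-
      expression_similarity(expr[circ[expr_mask], , drop = FALSE],
                            mode = config$se_mode)
  }
  list(DSS1 = d1, DSS2 = d2, SE = se,
       semantic_mask = attr(d1, "semantic_mask"), expression_mask = expr_mask)
}

# Bundle for a (possibly fold-masked) association matrix, reusing the
# precomputed label-independent parts.
bundle_for_am <- function(am_use, pre, config) {
  structure(list(
    DSS1 = pre$DSS1, DSS2 = pre$DSS2,
    GD = gip_kernel(am_use, "disease", literal = config$gip_literal),
    GC = gip_kernel(am_use, "circrna", literal = config$gip_literal),
    SE = pre$SE,
    JD = jaccard(am_use, "disease"),
    JC = jaccard(am_use, "circrna"),
    semantic_mask = pre$semantic_mask,
    expression_mask = pre$expression_mask
  ), class = "similarity_bundle")
}

# Features (FV + optional embeddings + DCAE hidden codes) for one
# association-matrix view, assembled per the configured ablation.
build_feature_matrix <- function(am_use, pre, pairs, train_idx, config) {
  fused <- fuse_features(bundle_for_am(am_use, pre, config),
                         variance_kept = config$variance_kept,
                         max_r = config$max_r)
  fv <- pair_features(fused$CM, fused$DM, pairs)
  aane_c <- aane_d <- NULL
  if (config$ablation %in% c("full", "no_dcae")) {
    aane_c <- embed_nodes(fused$CM, fused$CS, d = config$aane_dim,
                          lambda = config$aane_lambda, rho = config$aane_rho,
                          max_iter = config$aane_max_iter,
                          tol = config$aane_tol,
                          seed = stage_seed(config, 3000))
    aane_d <- embed_nodes(fused$DM, fused$DS, d = config$aane_dim,
                          lambda = config$aane_lambda, rho = config$aane_rho,
                          max_iter = config$aane_max_iter,
                          tol = config$aane_tol,
                          seed = stage_seed(config, 3001))
  }
  hidden <- NULL
  if (config$ablation %in% c("full", "no_aane")) {
    dcfg <- config$dcae
    dcfg$seed <- stage_seed(config, 4000)
    model <- dcae_train(fv[train_idx, , drop = FALSE], dcfg)
    hidden <- dcae_encode(model, fv)
  }
  assemble_features(pairs, aane_c = aane_c, aane_d = aane_d,
                    dcae_hidden = hidden, fv = fv,
                    ablation = config$ablation)
}

#' Cross-validate the association prediction pipeline
#'
#' Stratified pair-level k-fold cross-validation of the full pipeline
#' (similarities -> fusion -> embeddings -> autoencoder -> random forest).
#' See the module note on `leakage`. Setting `permute_seed` permutes the
#' pair labels first (and rebuilds the association matrix from the permuted
#' positives), giving a no-signal control whose AUC should sit near 0.5.
#'
#' @param am binary association matrix.
#' @param dag a [disease_dag()].
#' @param expr expression matrix.
#' @param pairs labelled pair set (columns `circ`, `disease`, `label`).
#' @param config a [pipeline_config()].
#' @param permute_seed optional seed for the permuted-label control.
#' @return object of class `cv_report`: per-fold `eval_report`s, a
#'   `per_fold` metric table and the `mean` metric vector.
#' @export
cross_validate <- function(am, dag, expr, pairs, config = pipeline_config(),
                           permute_seed = NULL) {
  validate_assoc_matrix(am)
  if (!is.null(permute_seed)) {
    pairs$label <- withr::with_seed(as.integer(permute_seed),
                                    sample(pairs$label))
    am2 <- am
    am2[] <- 0L
    pos <- pairs[pairs$label == 1, ]
    am2[cbind(pos$circ, pos$disease)] <- 1L
    am <- am2
  }
  labels <- pairs$label
  folds <- stratified_folds(labels, config$k, seed = stage_seed(config, 2000))
  pre <- precompute_static_sims(am, dag, expr, config)

  fold_reports <- vector("list", config$k)
  if (config$leakage == "paper_faithful") {
    feats_full <- NULL
  }
  for (f in seq_len(config$k)) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    if (config$leakage == "fold_safe") {
      am_use <- am
      test_pos <- pairs[test_idx, ][pairs$label[test_idx] == 1, ]
      am_use[cbind(test_pos$circ, test_pos$disease)] <- 0L
      feats <- build_feature_matrix(am_use, pre, pairs, train_idx, config)
    } else {
      # similarities/embeddings from the full matrix, computed once; only
      # the autoencoder + classifier are refit per fold
      if (is.null(feats_full)) {
        feats_full <- build_feature_matrix(am, pre, pairs, seq_len(nrow(pairs)),
                                           config)
      }
      feats <- feats_full
    }
    ccfg <- config$classifier
    ccfg$seed <- stage_seed(config, 5000 + f)
    scores <- fit_predict(feats[train_idx, , drop = FALSE], labels[train_idx],
                          feats[test_idx, , drop = FALSE], ccfg)
    fold_reports[[f]] <- eval_metrics(labels[test_idx], scores,
                                      threshold = config$classifier$threshold)
  }
  per_fold <- do.call(rbind, lapply(fold_reports, function(r) r$metrics))
  structure(list(folds = fold_reports,
                 per_fold = as.data.frame(per_fold),
                 mean = colMeans(per_fold),
                 fold_assignment = folds,
                 k = config$k, leakage = config$leakage,
                 ablation = config$ablation, seed = config$seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d-fold, %s, ablation %s\n", x$k, x$leakage,
              x$ablation))
  cat("mean:", paste(names(x$mean), sprintf("%.4f", x$mean), collapse = "  "),
      "\n")
  invisible(x)
}

#' Sweep the random forest's feature fraction
#'
#' Runs one cross-validation per candidate `max_feature_fraction` under
#' fixed seeds and reports the mean AUC for each, plus the argmax.
#'
#' @inheritParams cross_validate
#' @param values numeric vector of feature fractions to try.
#' @return data frame (`max_feature_fraction`, `mean_auc`) with the best
#'   value in attribute `best`.
#' @export
sweep_max_feature <- function(am, dag, expr, pairs, values,
                              config = pipeline_config()) {
  assert_that(length(values) >= 1, "no sweep values given")
  aucs <- vapply(values, function(v) {
    cfg <- config
    cfg$classifier$max_feature_fraction <- v
    cross_validate(am, dag, expr, pairs, cfg)$mean[["AUC"]]
  }, numeric(1))
  out <- data.frame(max_feature_fraction = values, mean_auc = aucs)
  attr(out, "best") <- values[which.max(aucs)]
  out
}

#' Rank unconfirmed candidate associations
#'
#' Trains the configured feature pipeline and forest on all labelled pairs
#' (full-matrix similarities) and scores every unknown cell of the
#' association matrix that is not itself a labelled pair. Candidates are
#' returned in descending score order, ties broken lexicographically by
#' (circRNA id, disease id).
#'
#' @inheritParams cross_validate
#' @return data frame with columns `rank`, `circRNA`, `disease`, `score`
#'   (top `config$top_n` rows).
#' @export
rank_candidates <- function(am, dag, expr, pairs, config = pipeline_config()) {
  validate_assoc_matrix(am)
  pre <- precompute_static_sims(am, dag, expr, config)
  labelled <- paste(pairs$circ, pairs$disease)
  zero <- which(am == 0)
  cand <- data.frame(circ = ((zero - 1L) %% nrow(am)) + 1L,
                     disease = ((zero - 1L) %/% nrow(am)) + 1L)
  cand <- cand[!paste(cand$circ, cand$disease) %in% labelled, , drop = FALSE]
  all_pairs <- rbind(pairs[, c("circ", "disease")], cand)
  feats <- build_feature_matrix(am, pre, all_pairs,
                                train_idx = seq_len(nrow(pairs)), config)
  n_lab <- nrow(pairs)
  ccfg <- config$classifier
  ccfg$seed <- stage_seed(config, 5000)
  scores <- fit_predict(feats[seq_len(n_lab), , drop = FALSE], pairs$label,
                        feats[-seq_len(n_lab), , drop = FALSE], ccfg)
  out <- data.frame(circRNA = rownames(am)[cand$circ],
                    disease = colnames(am)[cand$disease],
                    score = scores)
  out <- out[order(-out$score, out$circRNA, out$disease), , drop = FALSE]
  out <- utils::head(out, config$top_n)
  out <- data.frame(rank = seq_len(nrow(out)), out, row.names = NULL)
  out
}
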