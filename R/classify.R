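# Random-forest scoring of circRNA-disease pairs and the evaluation
# metric suite (ACC, Sen, F1, MCC, trapezoid AUC).

#' Classifier configuration
#'
#' @param n_trees number of trees in the forest.
#' @param max_feature_fraction fraction of features tried at each split
#'   (`mtry = ceiling(fraction * n_features)`).
#' @param threshold score threshold for hard calls.
#' @param seed seed for the forest's bootstrap/feature sampling.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(n_trees = 100, max_feature_fraction = 0.2,
                              threshold = 0.5, seed = 1) {
  assert_that(n_trees >= 1, "n_trees must be >= 1")
  assert_that(max_feature_fraction > 0 && max_feature_fraction <= 1,
              "max_feature_fraction must be in (0, 1]")
  structure(list(n_trees = as.integer(n_trees),
                 max_feature_fraction = max_feature_fraction,
                 threshold = threshold, seed = as.integer(seed)),
            class = "classifier_config")
}

#' Assemble per-pair classifier features
#'
#' The full representation concatenates, per pair (i, j), the circRNA's
#' network embedding, the disease's network embedding and the pair's DCAE
#' hidden code. Ablations drop the named block; `"neither"` falls back to
#' the raw fused feature vector FV.
#'
#' @param pairs data frame with integer columns `circ`, `disease`.
#' @param aane_c circRNA embedding matrix (m x d).
#' @param aane_d disease embedding matrix (n x d).
#' @param dcae_hidden hidden-code matrix, one row per pair.
#' @param fv raw fused feature matrix, one row per pair (for `"neither"`).
#' @param ablation one of `"full"`, `"no_aane"`, `"no_dcae"`, `"neither"`.
#' @return numeric feature matrix, one row per pair.
#' @export
assemble_features <- function(pairs, aane_c = NULL, aane_d = NULL,
                              dcae_hidden = NULL, fv = NULL,
                              ablation = c("full", "no_aane", "no_dcae",
                                           "neither")) {
  ablation <- match.arg(ablation)
  emb <- function() {
    cbind(aane_c[pairs$circ, , drop = FALSE],
          aane_d[pairs$disease, , drop = FALSE])
  }
  out <- switch(ablation,
    full = cbind(emb(), dcae_hidden),
    no_aane = dcae_hidden,
    no_dcae = emb(),
    neither = fv)
  assert_that(!is.null(out), "required feature block missing for ablation '",
              ablation, "'")
  out <- as.matrix(out)
  rownames(out) <- NULL
  colnames(out) <- paste0("f", seq_len(ncol(out)))
  out
}

#' Fit a random forest and score test pairs
#'
#' Bootstrap-bagged decision trees with per-split feature subsampling at
#' `ceiling(max_feature_fraction * n_features)`; the score of a test pair is
#' the fraction of trees voting positive. Fully seeded.
#'
#' @param train_x,train_y training features and 0/1 labels.
#' @param test_x features to score.
#' @param cfg a [classifier_config()].
#' @return numeric scores in [0, 1], one per row of `test_x`.
#' @export
fit_predict <- function(train_x, train_y, test_x, cfg = classifier_config()) {
  assert_that(length(unique(train_y)) == 2,
              "training labels contain a single class")
  mtry <- max(1L, as.integer(ceiling(cfg$max_feature_fraction * ncol(train_x))))
  fit <- withr::with_seed(cfg$seed, {
    randomForest::randomForest(
      x = train_x, y = factor(train_y, levels = c(0, 1)),
      ntree = cfg$n_trees, mtry = mtry)
  })
  unname(stats::predict(fit, test_x, type = "prob")[, "1"])
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Classification metrics for scored pairs
#'
#' Confusion counts at the given threshold (score >= threshold is a
#' positive call), then:
#' `ACC = (TP+TN)/(TP+TN+FP+FN)`, `Sen = TP/(TP+FN)`,
#' `F1 = 2TP/(2TP+FP+FN)`, MCC with the square-rooted denominator, and AUC
#' as the trapezoid area under the ROC curve swept across all score
#' thresholds (ties grouped, equivalent to concordance with half credit for
#' tied scores). Degenerate denominators yield 0 with a warning.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores.
#' @param threshold hard-call threshold.
#' @return object of class `eval_report`: `metrics` (named vector with ACC,
#'   Sen, F1, MCC, AUC), `confusion` (TP, FN, TN, FP), `roc` (data frame of
#'   FPR/TPR points).
#' @export
eval_metrics <- function(labels, scores, threshold = 0.5) {
  assert_that(length(labels) == length(scores), "labels/scores length mismatch")
  assert_that(all(labels %in% c(0, 1)), "labels must be 0/1")
  labels <- as.numeric(labels)
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)

  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reporting 0")
      0
    } else num / den
  }
  acc <- safe_div(tp + tn, tp + tn + fp + fn, "ACC")
  sen <- safe_div(tp, tp + fn, "Sen")
  f1 <- safe_div(2 * tp, 2 * tp + fp + fn, "F1")
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) {
    warning("MCC undefined (zero denominator); reporting 0")
    0
  } else (tp * tn - fp * fn) / mcc_den

  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    warning("AUC undefined with a single class; reporting 0")
    auc <- 0
    roc <- data.frame(FPR = c(0, 1), TPR = c(0, 1))
  } else {
    ord <- order(scores, decreasing = TRUE)
    sc <- scores[ord]
    lab <- labels[ord]
    cum_tp <- cumsum(lab)
    cum_fp <- cumsum(1 - lab)
    last_of_tie <- !duplicated(sc, fromLast = TRUE)
    tpr <- c(0, cum_tp[last_of_tie] / npos)
    fpr <- c(0, cum_fp[last_of_tie] / nneg)
    auc <- trapezoid_auc(fpr, tpr)
    roc <- data.frame(FPR = fpr, TPR = tpr)
  }
  structure(list(metrics = c(ACC = acc, Sen = sen, F1 = f1, MCC = mcc,
                             AUC = auc),
                 confusion = c(TP = tp, FN = fn, TN = tn, FP = fp),
                 roc = roc),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report:",
      paste(names(x$metrics), sprintf("%.4f", x$metrics), collapse = "  "),
      "\n")
  invisible(x)
}
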