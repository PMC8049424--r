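# Outcome prediction: random forest with leave-one-out cross-validation and
# scaled variable importance for biomarker discovery.

check_outcomes <- function(table, outcomes) {
  if (is.data.frame(outcomes)) {
    outcomes <- stats::setNames(as.character(outcomes[[2L]]),
                                as.character(outcomes[[1L]]))
  }
  samples <- colnames(table)
  unlab <- setdiff(samples, names(outcomes))
  if (length(unlab)) {
    stop("sample(s) without outcome: ", paste(unlab, collapse = ", "))
  }
  y <- factor(outcomes[samples])
  if (nlevels(y) < 2L) stop("outcomes contain a single class")
  if (nlevels(y) > 2L) stop("only two-class outcomes are supported")
  y
}

#' Leave-one-out cross-validated random-forest accuracy
#'
#' Each sample is predicted by a forest fit on the remaining n - 1 samples;
#' the accuracy is the exact fraction of correct predictions. Deterministic
#' for a fixed seed (the RNG is reseeded per fold).
#'
#' @param table numeric feature matrix (rows = features, cols = samples).
#' @param outcomes named vector (sample -> class) or two-column data.frame;
#'   two classes, both present, n >= 3 samples.
#' @param n_trees trees per forest (default 500).
#' @param seed RNG seed.
#' @return list with `accuracy` (correct / n), `predictions` (named character
#'   vector) and `truth`.
#' @export
rf_loocv <- function(table, outcomes, n_trees = 500L, seed = 1L) {
  y <- check_outcomes(table, outcomes)
  n <- ncol(table)
  if (n < 3L) stop("need at least 3 samples for LOOCV")
  x <- t(table)
  colnames(x) <- make.names(colnames(x))
  pred <- character(n)
  for (i in seq_len(n)) {
    xtrain <- x[-i, , drop = FALSE]
    ytrain <- droplevels(y[-i])
    # degenerate folds (one class left, or nothing to split on): majority
    # vote of the training outcomes, ties to the first factor level
    keep <- which(apply(xtrain, 2L, function(v) any(v != v[1L])))
    if (nlevels(ytrain) < 2L || length(keep) == 0L) {
      tab <- table(ytrain)
      pred[i] <- names(tab)[which.max(tab)]
      next
    }
    set.seed(seed + i)
    fit <- randomForest::randomForest(x = xtrain[, keep, drop = FALSE],
                                      y = ytrain, ntree = n_trees)
    pred[i] <- as.character(stats::predict(fit, x[i, keep, drop = FALSE]))
  }
  names(pred) <- rownames(x)
  list(accuracy = mean(pred == as.character(y)),
       predictions = pred,
       truth = stats::setNames(as.character(y), rownames(x)))
}

#' Random-forest variable importance, scaled to a 0-100 range
#'
#' Fits one forest on all samples and rescales the per-feature importances
#' so the top feature scores 100 (all zeros stay zero). Features above
#' `threshold` are reported as selected, sorted by decreasing importance.
#'
#' @inheritParams rf_loocv
#' @param threshold selection cutoff on the 0-100 scale (default 50).
#' @param type `"impurity"` (mean decrease in Gini, default) or
#'   `"permutation"` (mean decrease in accuracy).
#' @return list with `importances` (named numeric, 0-100) and
#'   `selected_features` (character, importance > threshold, descending).
#' @export
variable_importance <- function(table, outcomes, n_trees = 500L, seed = 1L,
                                threshold = 50, type = c("impurity",
                                                         "permutation")) {
  type <- match.arg(type)
  y <- check_outcomes(table, outcomes)
  x <- t(table)
  colnames(x) <- make.names(colnames(x))
  keep <- which(apply(x, 2L, function(v) any(v != v[1L])))
  imp <- rep(0, ncol(x))
  if (length(keep) > 0L) {
    set.seed(seed)
    fit <- randomForest::randomForest(x = x[, keep, drop = FALSE], y = y,
                                      ntree = n_trees,
                                      importance = (type == "permutation"))
    imp[keep] <- if (type == "permutation") {
      randomForest::importance(fit, type = 1L)[, 1L]
    } else {
      randomForest::importance(fit, type = 2L)[, 1L]
    }
  }
  imp <- pmax(imp, 0)
  if (max(imp) > 0) imp <- imp / max(imp) * 100
  names(imp) <- rownames(table)
  sel <- imp[imp > threshold]
  sel <- sel[order(-sel, names(sel))]
  list(importances = imp, selected_features = names(sel))
}

#' Full prediction report (model, LOOCV accuracy, importances)
#'
#' @inheritParams variable_importance
#' @return list with `model_name`, `n_trees`, `n_features`,
#'   `loocv_accuracy`, `importances`, `selected_features`, `seed`.
#' @export
prediction_report <- function(table, outcomes, n_trees = 500L, seed = 1L,
                              threshold = 50) {
  cv <- rf_loocv(table, outcomes, n_trees = n_trees, seed = seed)
  vi <- variable_importance(table, outcomes, n_trees = n_trees, seed = seed,
                            threshold = threshold)
  list(model_name = "random_forest",
       n_trees = as.integer(n_trees),
       n_features = nrow(table),
       loocv_accuracy = cv$accuracy,
       importances = as.list(vi$importances),
       selected_features = vi$selected_features,
       seed = as.integer(seed))
}
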