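#' Fit a gradient-boosted tree classifier on a binary feature matrix
#'
#' Logistic-objective boosting with depth-limited trees and L2 leaf
#' regularization, in the second-order split-gain formulation. Because all
#' features are binary there is exactly one candidate split per feature, so
#' the greedy search is exact and deterministic; gain ties break on the lowest
#' column index. The initial margin is the logit of the label mean. Boosting
#' stops early when a round produces no usable split.
#'
#' @param x binary integer matrix (observations x features).
#' @param y 0/1 numeric label vector.
#' @param nrounds boosting rounds (default 200).
#' @param max_depth tree depth (default 3).
#' @param eta learning rate (default 0.1).
#' @param lambda L2 leaf regularization (default 1).
#' @param min_child_weight minimum hessian sum per child (default 1).
#' @return A `gbt_model`: flattened forest plus per-feature total split gain.
#' @keywords internal
#' @export
gbt_fit <- function(x, y, nrounds = 200L, max_depth = 3L, eta = 0.1,
                    lambda = 1.0, min_child_weight = 1.0) {
  stopifnot(is.matrix(x), length(y) == nrow(x), all(y %in% c(0, 1)))
  storage.mode(x) <- "integer"
  pbar <- mean(y)
  if (pbar <= 0 || pbar >= 1) stop("degenerate label", call. = FALSE)
  model <- .gbt_fit_cpp(x, as.numeric(y), as.integer(nrounds),
                        as.integer(max_depth), eta, lambda, min_child_weight,
                        stats::qlogis(pbar))
  model$n_features <- ncol(x)
  model$feature_names <- colnames(x)
  names(model$gain) <- colnames(x)
  class(model) <- "gbt_model"
  model
}

#' Predict margins (log-odds) from a fitted [gbt_fit()] model
#'
#' @param object a `gbt_model`.
#' @param x binary feature matrix with the training column layout.
#' @param ... unused.
#' @return Numeric vector of margins; apply `plogis()` for probabilities.
#' @keywords internal
#' @export
predict.gbt_model <- function(object, x, ...) {
  stopifnot(is.matrix(x), ncol(x) == object$n_features)
  storage.mode(x) <- "integer"
  .gbt_predict_cpp(object, x)
}

gbt_features_used <- function(model) {
  f <- model$feature[model$feature >= 0L]
  sort(unique(f)) + 1L
}

#' Area under the ROC curve (Mann-Whitney, mid-rank ties)
#'
#' AUC as the probability that a random positive outscores a random negative,
#' with 0.5 credit for ties — the Mann-Whitney U / (n1*n0) statistic via
#' mid-ranks.
#'
#' @param marker numeric scores.
#' @param label 0/1 labels (both classes required).
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(marker, label) {
  stopifnot(length(marker) == length(label), all(label %in% c(0, 1)))
  n1 <- sum(label == 1)
  n0 <- sum(label == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC", call. = FALSE)
  r <- rank(marker, ties.method = "average")
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Held-out permutation importance: mean decrease in validation AUC when one
# feature column is read through a random row permutation.  Features the
# forest never splits on get importance exactly 0 without prediction work.
# Permutations are drawn from R's RNG (shared across features: the shuffle
# only matters through the shuffled column, and reusing it keeps the cost at
# n_shuffles draws).
gbt_permutation_importance <- function(model, x_valid, y_valid,
                                       n_shuffles = 5L) {
  storage.mode(x_valid) <- "integer"
  n <- nrow(x_valid)
  perms <- vapply(seq_len(n_shuffles), function(s) sample.int(n),
                  integer(n))
  used <- gbt_features_used(model)
  res <- .gbt_perm_importance_cpp(model, x_valid, as.numeric(y_valid),
                                  perms, used)
  imp <- res$importance
  names(imp) <- model$feature_names
  attr(imp, "base_auc") <- res$base_auc
  imp
}
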