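#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: scores are sorted in decreasing order, equal
#' scores are grouped into a single threshold, and the area is the sum over
#' thresholds of (recall increment) x (precision at the threshold).
#' Trapezoidal interpolation is deliberately not used, as it over-estimates
#' precision-recall curves.
#'
#' @param labels binary vector (1 = positive/disease class).
#' @param scores numeric prediction scores, larger = more positive.
#' @return average precision in \[0, 1\].
#' @export
pr_auc <- function(labels, scores) {
  check_metric_input(labels, scores)
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  # ends of tie groups
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last]
  pp <- seq_along(y)[last]
  P <- sum(labels)
  rec_inc <- diff(c(0, tp)) / P
  sum(rec_inc * (tp / pp))
}

#' Area under the ROC curve
#'
#' Mann-Whitney U statistic normalized by n1*n0, with half-credit for tied
#' scores.
#'
#' @inheritParams pr_auc
#' @return ROC AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  check_metric_input(labels, scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

check_metric_input <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop_classed("sigtransfer_metric", "labels and scores differ in length")
  if (!all(labels %in% c(0, 1)))
    stop_classed("sigtransfer_metric", "labels must be binary 0/1")
  if (length(unique(labels)) < 2L)
    stop_classed("sigtransfer_single_class",
                 "both classes must be present to compute a ranking metric")
  invisible(TRUE)
}

#' Confusion-matrix metrics at a fixed probability threshold
#'
#' @inheritParams pr_auc
#' @param threshold decision threshold on the scores (default 0.5).
#' @return named list `accuracy`, `precision`, `recall`; precision is `NA`
#'   when no cell is predicted positive, recall is `NA` without positives.
#' @export
threshold_metrics <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores))
    stop_classed("sigtransfer_metric", "labels and scores differ in length")
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  list(accuracy = mean(pred == labels),
       precision = if (sum(pred) == 0) NA_real_ else tp / sum(pred),
       recall = if (sum(labels) == 0) NA_real_ else tp / sum(labels))
}

#' Full metrics report for one model on one slice
#'
#' @inheritParams pr_auc
#' @return list with `pr_auc`, `roc_auc`, `accuracy`, `precision`, `recall`,
#'   `n_cells`, `positive_fraction`.
#' @export
metrics_report <- function(labels, scores) {
  tm <- threshold_metrics(labels, scores)
  structure(list(pr_auc = pr_auc(labels, scores),
                 roc_auc = roc_auc(labels, scores),
                 accuracy = tm$accuracy,
                 precision = tm$precision,
                 recall = tm$recall,
                 n_cells = length(labels),
                 positive_fraction = mean(labels)),
            class = "metrics_report")
}

#' Transferability-corrected performance score
#'
#' The score between a training dataset X and a test dataset Y is the mean
#' of the two PR AUCs penalized by their absolute difference:
#' `s = (a + b)/2 - |a - b|`. It rewards signatures that perform highly AND
#' consistently across datasets; algebraically `s = min(a, b) - |a - b|/2`,
#' so it never exceeds the weaker of the two AUCs. Symmetric in its
#' arguments.
#'
#' @param auc_train,auc_test PR AUCs in \[0, 1\] (vectorized).
#' @return the score (can be negative for very discordant pairs).
#' @examples
#' transfer_score(0.7, 0.9)  # 0.6 despite a 0.9 test AUC
#' transfer_score(0.8, 0.8)  # 0.8: equal performance is unpenalized
#' @export
transfer_score <- function(auc_train, auc_test) {
  stopifnot(all(auc_train >= 0 & auc_train <= 1),
            all(auc_test >= 0 & auc_test <= 1))
  (auc_train + auc_test) / 2 - abs(auc_train - auc_test)
}

#' Median-conditioned response surface
#'
#' Predicted disease probability as one or two model features vary over
#' their observed range in a slice, with the remaining features fixed at
#' their per-slice median — the standard way to read a small symbolic
#' classifier.
#'
#' @param model a fitted `formula_model`.
#' @param slice a `cell_type_slice` holding the observed expression.
#' @param varied character vector of 1 or 2 feature names to vary.
#' @param n_grid grid points per varied axis.
#' @return list with `varied_features`, `grid` (data.frame of varied
#'   values), `fixed_values` (named medians), `probabilities`.
#' @export
response_surface <- function(model, slice, varied, n_grid = 50) {
  stopifnot(inherits(model, "formula_model"))
  varied <- as.character(varied)
  if (!length(varied) %in% 1:2)
    stop_classed("sigtransfer_surface", "vary 1 or 2 features")
  # a bias-only model has no features to vary over; any slice gene may be
  # swept (yielding the constant surface logistic(bias))
  if (length(model$features) && !all(varied %in% model$features))
    stop_classed("sigtransfer_surface",
                 "varied feature(s) not in the model: %s",
                 paste(setdiff(varied, model$features), collapse = ", "))
  X <- as.matrix(slice$X)
  if (nrow(X) == 0)
    stop_classed("sigtransfer_surface", "slice has no cells")
  axes <- lapply(varied, function(f)
    seq(min(X[, f]), max(X[, f]), length.out = n_grid))
  names(axes) <- varied
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  fixed <- setdiff(model$features, varied)
  med <- vapply(fixed, function(f) stats::median(X[, f]), numeric(1))
  G <- as.matrix(grid)
  for (f in fixed) G <- cbind(G, rep(med[[f]], nrow(G)))
  colnames(G) <- c(varied, fixed)
  list(varied_features = varied,
       grid = grid,
       fixed_values = med,
       probabilities = evaluate_model(model, G))
}
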