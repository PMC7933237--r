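# Evaluation metrics: macro F1 (single-label), averaged class-wise AUC,
# sample-centric Fmax, and the class-averaged F-beta / G-beta scores with
# beta = 2 used by the multi-label challenge evaluations. Undefined
# denominators contribute 0 (documented convention).

#' Macro F1 score
#'
#' Unweighted mean of per-class F1 = 2TP / (2TP + FP + FN) over `classes`.
#' A class absent from both truth and prediction has F1 defined as 0.
#'
#' @param y_true,y_pred vectors of class labels, same length
#' @param classes the class set (defaults to union of observed labels)
#' @return list with `macro_f1` and named `per_class` F1 vector
#' @export
macro_f1 <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("inputs must have the same length")
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  if (!all(c(y_true, y_pred) %in% classes)) stop("labels outside the class set")
  per <- vapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 0)
  names(per) <- classes
  list(macro_f1 = mean(per), per_class = per)
}

#' Averaged class-wise AUC
#'
#' One-vs-rest rank-based AUC per class (midranks for ties, equivalent to
#' the Wilcoxon pair-counting statistic), averaged without weights. Classes
#' lacking a positive or a negative example are excluded.
#'
#' @param y_true 0/1 matrix (n_samples x n_classes)
#' @param scores numeric matrix of the same shape
#' @return mean class-wise AUC in `[0, 1]`
#' @export
mean_classwise_auc <- function(y_true, scores) {
  stopifnot(all(dim(y_true) == dim(scores)))
  aucs <- c()
  for (j in seq_len(ncol(y_true))) {
    pos <- y_true[, j] == 1
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) next
    r <- rank(scores[, j])  # midranks
    aucs <- c(aucs, (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0))
  }
  if (length(aucs) == 0) stop("no class with both positive and negative examples")
  mean(aucs)
}

sample_centric_f1 <- function(y_true, pred) {
  # precision averaged over samples with >=1 predicted label,
  # recall averaged over all samples
  npred <- rowSums(pred)
  ntrue <- rowSums(y_true)
  tp <- rowSums(y_true * pred)
  with_pred <- npred > 0
  if (!any(with_pred)) return(NA_real_)
  prec <- mean(tp[with_pred] / npred[with_pred])
  rec <- mean(ifelse(ntrue > 0, tp / pmax(ntrue, 1), 0))
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

#' Maximum sample-centric F1 over a threshold grid
#'
#' At each threshold the binary prediction is `scores >= t`; precision is
#' averaged over samples with at least one predicted label, recall over all
#' samples, and F = 2PR/(P+R). Thresholds with no prediction anywhere are
#' skipped. Refining the grid can only increase the result.
#'
#' @param y_true 0/1 matrix (n_samples x n_classes)
#' @param scores numeric matrix of the same shape
#' @param grid threshold grid (default 0 to 1 by 0.01)
#' @return maximum F over the grid
#' @export
f_max <- function(y_true, scores, grid = seq(0, 1, by = 0.01)) {
  if (length(grid) == 0) stop("threshold grid must be non-empty")
  best <- 0
  for (t in grid) {
    f <- sample_centric_f1(y_true, (scores >= t) * 1)
    if (!is.na(f) && f > best) best <- f
  }
  best
}

#' Class-averaged F-beta and G-beta scores (beta = 2)
#'
#' Per class: `F_beta = (1+beta^2) TP / ((1+beta^2) TP + FP + beta^2 FN)` and
#' `G_beta = TP / (TP + FP + beta FN)` (the challenge's generalized Jaccard
#' measure, weighting missed positives by beta); the reported value is the unweighted
#' average over classes (a class with zero denominator contributes 0).
#'
#' @param y_true 0/1 matrix (n_samples x n_classes)
#' @param y_pred 0/1 matrix of the same shape (binary decisions)
#' @param beta recall weighting (default 2)
#' @return list with `f_beta` and `g_beta`
#' @export
f_beta_g_beta <- function(y_true, y_pred, beta = 2) {
  stopifnot(all(dim(y_true) == dim(y_pred)))
  fb <- gb <- numeric(ncol(y_true))
  for (j in seq_len(ncol(y_true))) {
    tp <- sum(y_true[, j] == 1 & y_pred[, j] == 1)
    fp <- sum(y_true[, j] == 0 & y_pred[, j] == 1)
    fn <- sum(y_true[, j] == 1 & y_pred[, j] == 0)
    dfb <- (1 + beta^2) * tp + fp + beta^2 * fn
    dgb <- tp + fp + beta * fn
    fb[j] <- if (dfb == 0) 0 else (1 + beta^2) * tp / dfb
    gb[j] <- if (dgb == 0) 0 else tp / dgb
  }
  list(f_beta = mean(fb), g_beta = mean(gb))
}

#' Find the threshold maximizing a metric on (train) data
#'
#' @param y_true 0/1 matrix
#' @param scores numeric matrix
#' @param metric function(y_true, y_pred) returning a scalar (larger better)
#' @param grid threshold grid; ties return the smallest threshold
#' @return the selected threshold
#' @export
threshold_search <- function(y_true, scores, metric, grid = seq(0, 1, by = 0.01)) {
  if (length(grid) == 0) stop("threshold grid must be non-empty")
  vals <- vapply(grid, function(t) metric(y_true, (scores >= t) * 1), 0)
  grid[which.max(vals)]  # first maximum = smallest threshold on ties
}
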