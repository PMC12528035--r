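# Metric suites for both prediction tasks and decision-curve analysis.
# Undefined quantities (e.g. precision with no positive predictions, the
# published tables' em-dash cells) are reported as NA with an explicit
# `undefined` flag rather than silently zeroed.

#' Confusion counts at a probability threshold
#'
#' @param labels Binary labels (factor with the positive level first, or
#'   0/1 numeric with 1 = positive).
#' @param probs Predicted positive-class probabilities in [0, 1].
#' @param threshold Classification threshold; prediction is positive when
#'   `probs >= threshold`. Default 0.5.
#' @return List of class `confusion_counts`: TP, FP, TN, FN, N.
#' @export
confusion_counts <- function(labels, probs, threshold = 0.5) {
  y <- as_binary01(labels)
  if (length(y) != length(probs)) stop("labels and probs differ in length")
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  pred <- as.integer(probs >= threshold)
  structure(list(
    TP = sum(pred == 1 & y == 1), FP = sum(pred == 1 & y == 0),
    TN = sum(pred == 0 & y == 0), FN = sum(pred == 0 & y == 1),
    N = length(y)
  ), class = "confusion_counts")
}

#' Classification metric suite
#'
#' Computes precision, sensitivity, specificity, accuracy, F1, ROC-AUC
#' (rank/trapezoid method, equivalent to the normalised Mann-Whitney U
#' statistic with ties counted 1/2) and PR-AUC (step-wise integration of
#' the precision-recall curve). Precision and F1 are flagged undefined
#' when no positive predictions exist; ROC-AUC and PR-AUC when only one
#' class is present.
#'
#' @inheritParams confusion_counts
#' @return List with `counts` (a `confusion_counts`) and `metrics`, a
#'   one-row data.frame (PRE, SEN, SPE, ACC, F1, ROC_AUC, PR_AUC) with an
#'   `undefined` attribute naming any NA entries.
#' @export
classification_metrics <- function(labels, probs, threshold = 0.5) {
  cc <- confusion_counts(labels, probs, threshold)
  y <- as_binary01(labels)
  undef <- character()
  PRE <- if (cc$TP + cc$FP == 0) { undef <- c(undef, "PRE"); NA_real_ }
         else cc$TP / (cc$TP + cc$FP)
  SEN <- if (cc$TP + cc$FN == 0) { undef <- c(undef, "SEN"); NA_real_ }
         else cc$TP / (cc$TP + cc$FN)
  SPE <- if (cc$TN + cc$FP == 0) { undef <- c(undef, "SPE"); NA_real_ }
         else cc$TN / (cc$TN + cc$FP)
  ACC <- (cc$TP + cc$TN) / cc$N
  F1 <- if (is.na(PRE) || is.na(SEN) || PRE + SEN == 0) {
    undef <- c(undef, "F1"); NA_real_
  } else 2 * PRE * SEN / (PRE + SEN)
  if (length(unique(y)) < 2) {
    undef <- c(undef, "ROC_AUC", "PR_AUC")
    roc <- pr <- NA_real_
  } else {
    roc <- roc_auc(y, probs)
    pr <- pr_auc(y, probs)
  }
  metrics <- data.frame(PRE = PRE, SEN = SEN, SPE = SPE, ACC = ACC, F1 = F1,
                        ROC_AUC = roc, PR_AUC = pr)
  attr(metrics, "undefined") <- unique(undef)
  list(counts = cc, metrics = metrics)
}

#' ROC-AUC as the normalised rank-sum (Mann-Whitney) statistic
#' @param y Binary labels (factor, positive level first, or 0/1).
#' @param probs Predicted scores.
#' @return Area under the ROC curve (ties counted one half).
#' @export
roc_auc <- function(y, probs) {
  y <- as_binary01(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(probs, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' PR-AUC by step integration of the precision-recall curve
#' @inheritParams roc_auc
#' @return Area under the precision-recall curve.
#' @export
pr_auc <- function(y, probs) {
  y <- as_binary01(y)
  n1 <- sum(y == 1)
  if (n1 == 0 || all(y == 1)) return(NA_real_)
  ord <- order(probs, decreasing = TRUE)
  ys <- y[ord]; ps <- probs[ord]
  tp <- cumsum(ys)
  fp <- cumsum(1 - ys)
  last <- !duplicated(ps, fromLast = TRUE) # collapse tied scores
  tp <- tp[last]; fp <- fp[last]
  rec <- tp / n1
  prec <- tp / (tp + fp)
  sum(diff(c(0, rec)) * prec)
}

#' Regression metric suite
#'
#' MSE, RMSE, MAE, coefficient of determination R2 = 1 - SSres/SStot and
#' MAPE in percentage points. Observations with `y == 0` are skipped for
#' MAPE and their count recorded; R2 is flagged undefined when `y` has
#' zero variance.
#'
#' @param y Observed values (length >= 2).
#' @param yhat Predicted values, same length.
#' @return One-row data.frame (MSE, RMSE, MAE, R2, MAPE) with attributes
#'   `undefined` and `mape_skipped`.
#' @export
regression_metrics <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("`y` and `yhat` differ in length")
  if (length(y) < 2) stop("need at least 2 observations")
  e <- y - yhat
  mse <- mean(e^2)
  undef <- character()
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot == 0) { undef <- c(undef, "R2"); NA_real_ }
        else 1 - sum(e^2) / sstot
  nz <- y != 0
  mape <- if (any(nz)) 100 * mean(abs(e[nz] / y[nz])) else {
    undef <- c(undef, "MAPE"); NA_real_
  }
  out <- data.frame(MSE = mse, RMSE = sqrt(mse), MAE = mean(abs(e)),
                    R2 = r2, MAPE = mape)
  attr(out, "undefined") <- undef
  attr(out, "mape_skipped") <- sum(!nz)
  out
}

#' Net benefit at a threshold probability
#'
#' The decision-analytic net benefit
#' \deqn{NB = TP/N - (FP/N) \cdot p_t/(1-p_t),}
#' the value (in true-positive units per patient) of acting on the model's
#' positive calls when a true positive is worth \eqn{(1-p_t)/p_t} times a
#' false positive.
#'
#' @param counts A [confusion_counts()] object.
#' @param p_t Threshold probability in [0, 1).
#' @return Numeric net benefit.
#' @export
net_benefit <- function(counts, p_t) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (p_t < 0 || p_t >= 1) stop("`p_t` must lie in [0, 1)")
  counts$TP / counts$N - (counts$FP / counts$N) * p_t / (1 - p_t)
}

#' Decision curve analysis
#'
#' Net benefit of the model (classifying positive at `probs >= p_t`),
#' of treating everyone, and of treating no one, over a grid of threshold
#' probabilities.
#'
#' @inheritParams confusion_counts
#' @param grid Threshold grid in (0, 1); default 0.01 to 0.99 by 0.01.
#' @return A data.frame of class `decision_curve`: `p_t`, `NB_model`,
#'   `NB_all`, `NB_none`; prevalence attached as an attribute.
#' @export
decision_curve <- function(labels, probs, grid = seq(0.01, 0.99, by = 0.01)) {
  y <- as_binary01(labels)
  if (any(grid <= 0 | grid >= 1)) stop("grid thresholds must lie in (0, 1)")
  n <- length(y)
  prev <- mean(y)
  nb_model <- vapply(grid, function(pt) {
    net_benefit(confusion_counts(y, probs, threshold = pt), pt)
  }, numeric(1))
  nb_all <- prev - (1 - prev) * grid / (1 - grid)
  out <- data.frame(p_t = grid, NB_model = nb_model, NB_all = nb_all,
                    NB_none = 0)
  attr(out, "prevalence") <- prev
  class(out) <- c("decision_curve", "data.frame")
  out
}

#' @export
plot.decision_curve <- function(x, ...) {
  graphics::plot(x$p_t, x$NB_model, type = "l", lwd = 2,
                 xlab = "threshold probability", ylab = "net benefit",
                 ylim = range(c(x$NB_model, x$NB_all, 0), finite = TRUE), ...)
  graphics::lines(x$p_t, x$NB_all, lty = 2)
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", c("model", "treat all", "treat none"),
                   lty = c(1, 2, 3), lwd = c(2, 1, 1), bty = "n")
  invisible(x)
}

as_binary01 <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) > 2) stop("labels must be binary")
    as.integer(labels == levels(labels)[1])
  } else {
    y <- as.integer(labels)
    if (!all(y %in% c(0L, 1L))) stop("numeric labels must be 0/1")
    y
  }
}
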