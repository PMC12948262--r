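# Evaluation metrics. The concordance index and rm-squared are the two
# affinity-specific statistics; the rest are textbook definitions kept
# explicit so each can be cross-checked against brute-force oracles.

#' Concordance index
#'
#' Probability that predictions order a randomly drawn pair of examples
#' with different true labels correctly:
#' `CI = sum over pairs y_i > y_j of [1(yhat_i > yhat_j) + 0.5 * 1(yhat_i =
#' yhat_j)] / #pairs`. Tied predictions count one half (Gonen-Heller
#' convention); pairs with tied labels are excluded.
#'
#' @param y true labels (length >= 2, not all equal).
#' @param yhat predictions.
#' @return CI in `[0, 1]`; 0.5 is random, 1 perfect.
#' @export
concordanceIndex <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2L)
  if (length(unique(y)) < 2L) stop("CI undefined: all labels equal")
  # O(n^2) via outer comparisons; n is fold-sized here
  dy <- outer(y, y, ">")
  dp <- outer(yhat, yhat, "-")
  num <- sum((dp > 0) * dy) + 0.5 * sum((dp == 0) * dy)
  num / sum(dy)
}

#' Squared Pearson correlation through the origin (r0^2)
#' @keywords internal
.r0squared <- function(y, yhat) {
  k <- sum(y * yhat) / sum(yhat^2)
  1 - sum((y - k * yhat)^2) / sum((y - mean(y))^2)
}

#' rm-squared external-validation metric
#'
#' `rm2 = r^2 * (1 - sqrt(|r^2 - r0^2|))`, where `r` is the Pearson
#' correlation of `y` and `yhat` and `r0^2` comes from the through-origin
#' regression of `y` on `yhat` with slope `k = sum(y * yhat) / sum(yhat^2)`
#' (the convention standard in affinity-prediction benchmarks). Penalizes
#' predictions whose agreement with the observations departs from the
#' identity line through the origin. `variant = "average"` computes the
#' symmetrized form `(rm2 + rm2')/2` using the reverse through-origin fit.
#'
#' @param y true labels (length >= 3, nonzero variance).
#' @param yhat predictions (nonzero variance).
#' @param variant `"plain"` (default) or `"average"`.
#' @return rm-squared; at most `r^2`.
#' @export
rmSquared <- function(y, yhat, variant = c("plain", "average")) {
  variant <- match.arg(variant)
  stopifnot(length(y) == length(yhat), length(y) >= 3L)
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0)
    stop("rm2 undefined: zero variance")
  r2 <- stats::cor(y, yhat)^2
  # guard: the sqrt amplifies float noise when r2 and r0^2 coincide exactly
  pen <- function(d) if (abs(d) < 1e-12) 0 else sqrt(abs(d))
  rm2 <- r2 * (1 - pen(r2 - .r0squared(y, yhat)))
  if (variant == "plain") return(rm2)
  rm2p <- r2 * (1 - pen(r2 - .r0squared(yhat, y)))
  (rm2 + rm2p) / 2
}

#' Regression metric panel
#'
#' @param y true labels.
#' @param yhat predictions.
#' @return named list: `mse`, `mae`, `pearson_r`, `ci`, `rm2`.
#' @export
regressionMetrics <- function(y, yhat) {
  list(mse = mean((y - yhat)^2),
       mae = mean(abs(y - yhat)),
       pearson_r = stats::cor(y, yhat),
       ci = concordanceIndex(y, yhat),
       rm2 = rmSquared(y, yhat))
}

#' Classification metric panel
#'
#' Confusion-matrix metrics at threshold 0.5 plus rank-based
#' (Mann-Whitney) AUC with tie correction. Requires both classes present.
#'
#' @param y binary labels in `{0, 1}`.
#' @param p predicted probabilities/scores in `[0, 1]`.
#' @param threshold decision threshold for the thresholded metrics.
#' @return named list: `acc`, `auc`, `ba`, `mcc`, `f1`.
#' @export
classificationMetrics <- function(y, p, threshold = 0.5) {
  stopifnot(length(y) == length(p), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) stop("AUC undefined: only one class present")
  pred <- as.integer(p > threshold)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  acc <- (tp + tn) / length(y)
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  ba <- (sens + spec) / 2
  mccDen <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mccDen > 0) (tp * tn - fp * fn) / mccDen else 0
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  # Mann-Whitney AUC from midranks
  r <- rank(p)[y == 1]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  auc <- (sum(r) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(acc = acc, auc = auc, ba = ba, mcc = mcc, f1 = f1)
}

#' Export evaluation artifacts for a prediction set
#'
#' Writes plottable scatter-density data (observed, predicted, local point
#' density), Gaussian kernel-density curves of both distributions
#' (bandwidth by Scott's rule) and the [regressionMetrics()] panel as JSON.
#'
#' @param y observed labels.
#' @param yhat predictions.
#' @param outDir output directory (created if needed).
#' @return invisible list of the written file paths.
#' @export
evaluationReport <- function(y, yhat, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  scatterFile <- file.path(outDir, "scatter_density.csv")
  kdeFile <- file.path(outDir, "kde_curves.csv")
  metricsFile <- file.path(outDir, "metrics.json")
  # 2-D Gaussian product-kernel density at each point, Scott's rule
  bx <- stats::bw.nrd(y); by <- stats::bw.nrd(yhat)
  dens <- vapply(seq_along(y), function(i)
    mean(stats::dnorm(y - y[i], sd = bx) * stats::dnorm(yhat - yhat[i], sd = by)),
    0)
  utils::write.csv(data.frame(observed = y, predicted = yhat, density = dens),
                   scatterFile, row.names = FALSE)
  kde <- function(v, label) {
    d <- stats::density(v, bw = stats::bw.nrd(v))
    data.frame(series = label, x = d$x, density = d$y)
  }
  utils::write.csv(rbind(kde(y, "observed"), kde(yhat, "predicted")),
                   kdeFile, row.names = FALSE)
  jsonlite::write_json(regressionMetrics(y, yhat), metricsFile,
                       auto_unbox = TRUE, digits = NA)
  invisible(list(scatter = scatterFile, kde = kdeFile, metrics = metricsFile))
}
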