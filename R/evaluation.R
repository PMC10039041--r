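# Diagnostic-performance metrics: ROC/AUC, fixed operating points, PRC,
# bootstrap CIs, confusion matrices, and SERS utility formulas.

#' ROC curve and trapezoidal AUC
#'
#' Curve over all distinct score thresholds (positivity: score > threshold),
#' anchored at (0,0) and (1,1). The trapezoidal area equals the pair-counting
#' concordance statistic with ties counted one half.
#'
#' @param scores Numeric scores.
#' @param labels Binary truth (0/1), both classes present.
#' @return A `roc_result`: `thresholds`, `fpr`, `tpr`, `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (length(unique(labels)) < 2L) stop("both classes must be represented")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tps <- cumsum(y); fps <- cumsum(1 - y)
  last <- which(!duplicated(s, fromLast = TRUE))   # last index of each score
  tpr <- c(0, tps[last] / sum(y))
  fpr <- c(0, fps[last] / sum(1 - y))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = c(Inf, s[last]), fpr = fpr, tpr = tpr,
                 auc = auc),
            class = "roc_result")
}

#' Operating points at fixed sensitivity / specificity targets
#'
#' Conservative (interpolation-free): `sens_at_spec` is the maximum
#' sensitivity over thresholds whose specificity meets or exceeds the target,
#' and symmetrically for `spec_at_sens`. Also reports the closest-to-(0,1)
#' optimal point with accuracy and precision at that cutoff.
#'
#' @param scores,labels As in [roc_auc()].
#' @param sens_at_spec,spec_at_sens Targets (default 0.99 each).
#' @return List with `optimal` (threshold, sensitivity, specificity,
#'   accuracy, precision), `sens_at_spec`, `spec_at_sens`.
#' @export
operating_points <- function(scores, labels, sens_at_spec = 0.99,
                             spec_at_sens = 0.99) {
  labels <- as.numeric(labels)
  r <- roc_auc(scores, labels)
  sens <- r$tpr; spec <- 1 - r$fpr
  ok <- spec >= sens_at_spec
  sas <- if (any(ok)) max(sens[ok]) else { warning("specificity target unattainable"); 0 }
  ok2 <- sens >= spec_at_sens
  ssa <- if (any(ok2)) max(spec[ok2]) else { warning("sensitivity target unattainable"); 0 }
  thr <- choose_cutoff(scores, labels)
  pred <- as.numeric(scores > thr)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  list(optimal = list(threshold = thr,
                      sensitivity = tp / (tp + fn),
                      specificity = tn / (tn + fp),
                      accuracy = (tp + tn) / length(labels),
                      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_),
       sens_at_spec = sas, spec_at_sens = ssa)
}

#' Precision-recall curve, AUPRC and best F1
#'
#' Standard PR construction over distinct thresholds (step integration, as in
#' the usual average-precision estimator); `auprc` is bounded below by the
#' positive prevalence for uninformative scores. `f1` is the maximum F1 over
#' the curve, reported with its threshold.
#'
#' @param scores,labels As in [roc_auc()]; at least one positive.
#' @return List `curve` (threshold, precision, recall), `auprc`, `f1`,
#'   `f1_threshold`.
#' @export
pr_metrics <- function(scores, labels) {
  labels <- as.numeric(labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0L) stop("no positive samples")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tps <- cumsum(y); fps <- cumsum(1 - y)
  last <- which(!duplicated(s, fromLast = TRUE))
  prec <- tps[last] / (tps[last] + fps[last])
  rec <- tps[last] / n_pos
  auprc <- sum(diff(c(0, rec)) * prec)
  f1 <- 2 * prec * rec / pmax(prec + rec, 1e-12)
  best <- which.max(f1)
  list(curve = data.frame(threshold = s[last], precision = prec,
                          recall = rec),
       auprc = auprc, f1 = f1[best], f1_threshold = s[last][best])
}

#' Stratified percentile bootstrap confidence interval
#'
#' Resamples samples (bags) within each class, recomputes the metric, and
#' returns percentile 2.5/97.5 bounds. Deterministic under `seed`; degenerate
#' single-class resamples cannot occur under stratification but are guarded
#' and redrawn.
#'
#' @param scores,labels Sample-level scores and binary truth.
#' @param metric `"auc"`, `"auprc"`, or a `function(scores, labels)`.
#' @param n_boot Number of resamples (>= 100).
#' @param seed Seed.
#' @param level Confidence level (default 0.95).
#' @return `c(lo, hi)`.
#' @export
bootstrap_ci <- function(scores, labels, metric = "auc", n_boot = 2000L,
                         seed = 0L, level = 0.95) {
  if (n_boot < 100L) stop("n_boot must be >= 100")
  labels <- as.numeric(labels)
  f <- if (is.function(metric)) metric
       else switch(metric,
                   auc = function(s, l) roc_auc(s, l)$auc,
                   auprc = function(s, l) pr_metrics(s, l)$auprc,
                   stop("unknown metric id: ", metric))
  set.seed(seed)
  ix0 <- which(labels == 0); ix1 <- which(labels == 1)
  vals <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    repeat {
      ix <- c(sample(ix0, replace = TRUE), sample(ix1, replace = TRUE))
      if (length(unique(labels[ix])) == 2L) break
    }
    vals[b] <- f(scores[ix], labels[ix])
  }
  a <- (1 - level) / 2
  as.numeric(quantile(vals, c(a, 1 - a), names = FALSE, type = 7))
}

#' End-to-end confusion matrix
#'
#' Rows: true class (HC + six types); columns: predicted class (non-cancer +
#' six types). Row sums equal the per-class test bag counts.
#'
#' @param decisions List of `decision_result`s.
#' @param truth Named character vector: `truth[sample_id] = true class`.
#' @return Integer matrix 7 x 7.
#' @export
confusion_matrix <- function(decisions, truth) {
  rows <- all_classes()
  cols <- c("non-cancer", cancer_types())
  M <- matrix(0L, length(rows), length(cols),
              dimnames = list(truth = rows, predicted = cols))
  for (d in decisions) {
    if (!d$sample_id %in% names(truth))
      stop("unknown sample id: ", d$sample_id)
    if (identical(d$status, "unscorable")) next
    M[truth[[d$sample_id]], d$predicted_class] <-
      M[truth[[d$sample_id]], d$predicted_class] + 1L
  }
  M
}

#' SERS enhancement factor
#'
#' Per-molecule intensity ratio `(i_sers / n_sers) / (i_ref / n_ref)` between
#' the plasmonically enhanced and the spontaneous-Raman measurement.
#'
#' @param i_sers,i_ref Band intensities (> 0).
#' @param n_sers,n_ref Numbers of probed molecules (> 0).
#' @return Scalar enhancement factor.
#' @export
enhancement_factor <- function(i_sers, n_sers, i_ref, n_ref) {
  if (any(c(i_sers, n_sers, i_ref, n_ref) <= 0))
    stop("all inputs must be positive")
  (i_sers / n_sers) / (i_ref / n_ref)
}

#' Coefficient of variation, in percent
#'
#' `100 * sd(values) / mean(values)` -- the acquisition-uniformity statistic
#' reported for repeated band intensities across a detection spot.
#'
#' @param values Numeric vector, `n >= 2`, positive mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) stop("need at least two values")
  m <- mean(values)
  if (m <= 0) stop("mean must be positive")
  100 * sd(values) / m
}
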