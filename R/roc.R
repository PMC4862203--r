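## DeLong placement values: psi(x, y) = 1, 1/2, 0 as x >, =, < y.
## Returns per-positive (V10) and per-negative (V01) placements.
.delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  psi <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
  list(v10 = rowMeans(psi), v01 = colMeans(1 - psi), auc = mean(psi))
}

.check_binary_labels <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)) || length(unique(labels)) < 2)
    stop_tg("labels must contain both classes, coded 0/1")
  labels
}

#' ROC curve, AUC and DeLong confidence interval
#'
#' The AUC is the Mann-Whitney concordance probability (ties count 1/2); the
#' 95 % confidence interval uses the DeLong variance estimator. The ROC is
#' evaluated at cutoffs midway between consecutive distinct scores (plus
#' sentinels below and above all scores), with a sample called positive when
#' its score is greater than or equal to the cutoff.
#'
#' @param probabilities Numeric scores (higher = more positive).
#' @param labels Binary 0/1 vector, 1 = positive class.
#' @return List of class `tg_roc` with `roc` (data frame: cutoff, tpr, fpr),
#'   `auc`, `ci` (length 2), `var`, and sample counts.
#' @export
roc_auc <- function(probabilities, labels) {
  labels <- .check_binary_labels(labels)
  if (length(probabilities) != length(labels))
    stop_tg("scores and labels differ in length")
  pl <- .delong_placements(probabilities, labels)
  m <- sum(labels == 1); n0 <- sum(labels == 0)
  v <- stats::var(pl$v10) / m + stats::var(pl$v01) / n0
  se <- sqrt(v)
  ci <- pmin(pmax(pl$auc + stats::qnorm(c(0.025, 0.975)) * se, 0), 1)
  s <- sort(unique(probabilities))
  cutoffs <- c(min(s) - 1,
               if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
               max(s) + 1)
  tpr <- vapply(cutoffs, function(ct) mean(probabilities[labels == 1] >= ct), 0)
  fpr <- vapply(cutoffs, function(ct) mean(probabilities[labels == 0] >= ct), 0)
  structure(list(roc = data.frame(cutoff = cutoffs, tpr = tpr, fpr = fpr),
                 auc = pl$auc, ci = ci, var = v, n_pos = m, n_neg = n0),
            class = "tg_roc")
}

#' @export
print.tg_roc <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auc, x$ci[1], x$ci[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two classifiers scored on the same samples, using the
#' DeLong covariance of the paired placement values. Identical score vectors
#' give z = 0, p = 1.
#'
#' @param probsA,probsB Paired score vectors.
#' @param labels Binary 0/1 labels shared by both.
#' @return List with `auc_a`, `auc_b`, `z`, `p` (two-sided normal).
#' @export
delong_test <- function(probsA, probsB, labels) {
  if (length(probsA) != length(probsB) || length(probsA) != length(labels))
    stop_tg("probsA, probsB and labels must have equal length")
  labels <- .check_binary_labels(labels)
  a <- .delong_placements(probsA, labels)
  b <- .delong_placements(probsB, labels)
  m <- sum(labels == 1); n0 <- sum(labels == 0)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  d <- a$auc - b$auc
  z <- if (d == 0 || !is.finite(v) || v <= 0) 0 else d / sqrt(v)
  list(auc_a = a$auc, auc_b = b$auc, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Top-left ROC threshold
#'
#' Returns the score cutoff minimising the squared distance to the top-left
#' corner of the ROC plane, `(1 - TPR)^2 + FPR^2`. Ties are broken toward
#' the smaller cutoff (higher sensitivity). Samples at or above the cutoff
#' are called positive.
#'
#' @param roc A `tg_roc` from [roc_auc()] or a data frame with columns
#'   `cutoff`, `tpr`, `fpr`.
#' @return The selected cutoff (numeric scalar).
#' @export
select_threshold <- function(roc) {
  df <- if (inherits(roc, "tg_roc")) roc$roc else roc
  if (!nrow(df)) stop_tg("empty ROC")
  d2 <- (1 - df$tpr)^2 + df$fpr^2
  cand <- df$cutoff[d2 <= min(d2) + 1e-12]
  min(cand)
}
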