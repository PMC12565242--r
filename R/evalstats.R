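## Evaluation metrics and uncertainty statistics for binary case-level
## predictions: threshold metrics, rank-based AUROC, step-wise AUPRC
## (average precision), paired stratified bootstrap CIs, the DeLong test
## for correlated AUROCs, and a paired permutation test for AUPRC.

#' Threshold-based classification metrics
#'
#' Scores at or above the threshold are called positive. Undefined ratios
#' (zero denominators) are reported as \code{NA}, never as 0.
#'
#' @param pred a \linkS4class{PredictionSet} or list with \code{labels} and
#'   \code{scores}.
#' @param threshold decision threshold (default the PredictionSet's, else
#'   0.5).
#' @return named list: accuracy, sensitivity, specificity, f1, confusion
#'   (tp/fp/tn/fn).
#' @export
thresholdMetrics <- function(pred, threshold = NULL) {
  if (is(pred, "PredictionSet")) {
    if (is.null(threshold)) threshold <- pred@threshold
    labels <- pred@labels; scores <- pred@scores
  } else {
    if (is.null(threshold)) threshold <- 0.5
    labels <- pred$labels; scores <- pred$scores
  }
  yhat <- as.integer(scores >= threshold)
  tp <- sum(yhat == 1L & labels == 1L)
  fp <- sum(yhat == 1L & labels == 0L)
  tn <- sum(yhat == 0L & labels == 0L)
  fn <- sum(yhat == 0L & labels == 1L)
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- rat(tp, tp + fp)
  recall <- rat(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || (precision + recall) == 0) {
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  list(accuracy = rat(tp + tn, length(labels)),
       sensitivity = recall,
       specificity = rat(tn, tn + fp),
       precision = precision,
       f1 = f1,
       confusion = c(tp = tp, fp = fp, tn = tn, fn = fn))
}

#' Area under the ROC curve
#'
#' Rank-based (midranks for ties); equals the Mann-Whitney probability that
#' a random positive outscores a random negative, ties counting one half.
#' Errors if either class is absent.
#'
#' @param labels binary 0/1 labels.
#' @param scores numeric scores.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(labels, scores) {
  labels <- as.integer(labels)
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("AUROC undefined: need both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: sum over distinct score thresholds, in
#' decreasing order, of (recall increment) x (precision at that threshold).
#'
#' @inheritParams auroc
#' @return AUPRC in (0, 1].
#' @export
auprc <- function(labels, scores) {
  labels <- as.integer(labels)
  nPos <- sum(labels == 1L)
  if (nPos == 0L || all(labels == 1L))
    stop("AUPRC undefined: need both classes present")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  tp <- cumsum(lab)
  fp <- cumsum(1L - lab)
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)  # last index of each threshold
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / nPos
  dRec <- diff(c(0, rec))
  sum(dRec * prec)
}

#' Paired bootstrap confidence interval for a metric difference
#'
#' Resamples cases with replacement, stratified by label (positives and
#' negatives drawn separately so both classes always survive), using the
#' same resampled indices for both models, and returns the percentile CI
#' of metric(A) - metric(B).
#'
#' @param labels binary labels shared by both models.
#' @param scoresA,scoresB paired score vectors.
#' @param metric function(labels, scores), e.g. \code{\link{auroc}}.
#' @param B bootstrap replicates (default 5000).
#' @param conf confidence level (default 0.95).
#' @param seed RNG seed.
#' @return list: diff, lower, upper, B, replicates.
#' @export
pairedBootstrapDiffCI <- function(labels, scoresA, scoresB, metric = auroc,
                                  B = 5000L, conf = 0.95, seed = 1L) {
  labels <- as.integer(labels)
  stopifnot(length(scoresA) == length(labels),
            length(scoresB) == length(labels))
  posIdx <- which(labels == 1L); negIdx <- which(labels == 0L)
  if (length(posIdx) == 0L || length(negIdx) == 0L)
    stop("need both classes present")
  obs <- metric(labels, scoresA) - metric(labels, scoresB)
  reps <- withSeed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- c(posIdx[sample.int(length(posIdx), replace = TRUE)],
               negIdx[sample.int(length(negIdx), replace = TRUE)])
      metric(labels[idx], scoresA[idx]) - metric(labels[idx], scoresB[idx])
    }, numeric(1))
  })
  a <- (1 - conf) / 2
  ci <- stats::quantile(reps, c(a, 1 - a), names = FALSE, type = 7)
  list(diff = obs, lower = ci[1], upper = ci[2], B = as.integer(B),
       replicates = reps)
}

#' @keywords internal
#' @noRd
.delongPlacements <- function(labels, scores) {
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  m <- length(pos); n <- length(neg)
  ## V10[i] = mean_j psi(pos_i, neg_j); V01[j] = mean_i psi(pos_i, neg_j)
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), V10 = rowMeans(psi), V01 = colMeans(psi),
       m = m, n = n)
}

#' DeLong test for two correlated AUROCs
#'
#' Placement-value implementation of DeLong, DeLong & Clarke-Pearson
#' (1988) for two models scored on the same cases; two-sided normal
#' p-value. If the variance of the difference is zero (e.g. identical
#' scores) the test is degenerate: a warning is raised and p = 1 is
#' returned.
#'
#' @param labels binary labels shared by both models.
#' @param scoresA,scoresB paired score vectors.
#' @return list: aucA, aucB, diff, varDiff, z, pValue.
#' @export
delongTest <- function(labels, scoresA, scoresB) {
  labels <- as.integer(labels)
  pa <- .delongPlacements(labels, scoresA)
  pb <- .delongPlacements(labels, scoresB)
  m <- pa$m; n <- pa$n
  S10 <- stats::cov(cbind(pa$V10, pb$V10))
  S01 <- stats::cov(cbind(pa$V01, pb$V01))
  S <- S10 / m + S01 / n
  varDiff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- pa$auc - pb$auc
  if (varDiff <= 0 || !is.finite(varDiff)) {
    warning("degenerate DeLong variance; returning p = 1")
    return(list(aucA = pa$auc, aucB = pb$auc, diff = d, varDiff = varDiff,
                z = NA_real_, pValue = 1))
  }
  z <- d / sqrt(varDiff)
  list(aucA = pa$auc, aucB = pb$auc, diff = d, varDiff = varDiff, z = z,
       pValue = 2 * stats::pnorm(-abs(z)))
}

#' Paired permutation test for an AUPRC difference
#'
#' Null hypothesis: the two models' scores are exchangeable within each
#' case. Each permutation swaps the paired scores of a random subset of
#' cases and recomputes the AUPRC difference. With \code{nPerm >= 2^N}
#' (N = number of cases) the 2^N swap patterns are enumerated exhaustively
#' and the p-value is exact; otherwise a Monte-Carlo estimate with the
#' add-one correction (b + 1) / (nPerm + 1) is returned.
#'
#' @param labels binary labels.
#' @param scoresA,scoresB paired score vectors.
#' @param nPerm permutations requested (default 2000).
#' @param seed RNG seed (Monte-Carlo branch only).
#' @return list: diff, pValue, exact, nPerm.
#' @export
auprcPermutationTest <- function(labels, scoresA, scoresB, nPerm = 2000L,
                                 seed = 1L) {
  labels <- as.integer(labels)
  N <- length(labels)
  stopifnot(length(scoresA) == N, length(scoresB) == N)
  obs <- auprc(labels, scoresA) - auprc(labels, scoresB)
  statFor <- function(swap) {
    a <- ifelse(swap, scoresB, scoresA)
    b <- ifelse(swap, scoresA, scoresB)
    auprc(labels, a) - auprc(labels, b)
  }
  if (nPerm >= 2^N) {
    stats <- vapply(seq_len(2^N) - 1L, function(code) {
      statFor(as.logical(bitwAnd(code, bitwShiftL(1L, 0:(N - 1L))) != 0L))
    }, numeric(1))
    p <- mean(abs(stats) >= abs(obs) - 1e-12)
    return(list(diff = obs, pValue = p, exact = TRUE,
                nPerm = as.integer(2^N)))
  }
  hits <- withSeed(seed, {
    sum(vapply(seq_len(nPerm), function(b) {
      abs(statFor(stats::runif(N) < 0.5)) >= abs(obs) - 1e-12
    }, logical(1)))
  })
  list(diff = obs, pValue = (hits + 1) / (nPerm + 1), exact = FALSE,
       nPerm = as.integer(nPerm))
}

#' Summarise a model's predictions
#'
#' Convenience wrapper computing threshold metrics plus AUROC and AUPRC.
#'
#' @param pred a \linkS4class{PredictionSet}.
#' @return named list.
#' @export
evaluatePredictions <- function(pred) {
  stopifnot(is(pred, "PredictionSet"))
  m <- thresholdMetrics(pred)
  m$auroc <- auroc(pred@labels, pred@scores)
  m$auprc <- auprc(pred@labels, pred@scores)
  m
}
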