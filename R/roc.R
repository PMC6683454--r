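#' ROC curve with DeLong inference
#'
#' Builds the empirical ROC curve of a continuous score against a binary
#' outcome. A subject is test-positive when their score is at or above the
#' cut-off; the curve is evaluated at every distinct observed score plus an
#' upper sentinel, so the (sensitivity, 1 - specificity) path always runs
#' from (0, 0) to (1, 1). The AUC is the Mann-Whitney pairwise estimate (ties
#' count one half) and its standard error and the p-value against AUC = 0.5
#' use the DeLong placement-value variance.
#'
#' @param scores Numeric score vector (higher = more suspicious of the
#'   outcome). Pairs with a missing score or label are dropped.
#' @param labels Logical (or 0/1) outcome vector; both classes must occur.
#' @return An object of class `roc_curve`: list with `thresholds`
#'   (decreasing), `sensitivity`, `specificity`, `auc`, `auc_se`, `auc_p`,
#'   `n_pos`, `n_neg`, and the (cleaned) `scores` and `labels` used.
#' @examples
#' r <- roc_curve(c(3, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
#' r$auc  # 0.875
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- as.numeric(scores[keep])
  labels <- labels[keep]
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both outcome classes must be present to build a ROC curve", call. = FALSE)

  cuts <- sort(unique(scores), decreasing = TRUE)
  thresholds <- c(Inf, cuts)
  sens <- vapply(thresholds, function(t) sum(labels & scores >= t) / n_pos, 0)
  spec <- vapply(thresholds, function(t) sum(!labels & scores < t) / n_neg, 0)

  pl <- delong_placements(scores, labels)
  auc <- mean(pl$v10)
  var_auc <- stats::var(pl$v10) / n_pos + stats::var(pl$v01) / n_neg
  auc_se <- sqrt(var_auc)
  auc_p <- if (var_auc <= 0) {
    if (auc == 0.5) 1 else 0
  } else {
    2 * stats::pnorm(-abs((auc - 0.5) / auc_se))
  }

  structure(list(thresholds = thresholds, sensitivity = sens,
                 specificity = spec, auc = auc, auc_se = auc_se,
                 auc_p = auc_p, n_pos = n_pos, n_neg = n_neg,
                 scores = scores, labels = labels),
            class = "roc_curve")
}

# DeLong placement values: v10[i] = P-hat(score_i beats a random control),
# v01[j] = P-hat(a random case beats score_j); ties count one half.
delong_placements <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  m <- length(pos); n <- length(neg)
  list(v10 = (r_all[seq_len(m)] - r_pos) / n,
       v01 = 1 - (r_all[m + seq_len(n)] - r_neg) / m)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d cases / %d controls, AUC = %.3f (SE %.3f, p = %.3g)\n",
              x$n_pos, x$n_neg, x$auc, x$auc_se, x$auc_p))
  invisible(x)
}

#' Youden-optimal operating point
#'
#' Selects the cut-off maximising the Youden index
#' J = sensitivity + specificity - 1 over all cut-offs of the curve. Ties on
#' J are broken towards higher specificity, then towards the higher
#' threshold.
#'
#' @param curve A [roc_curve()].
#' @return List with `threshold`, `sensitivity`, `specificity` and `youden`.
#' @export
youden_optimal <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  j <- curve$sensitivity + curve$specificity - 1
  best <- which(j == max(j))
  if (length(best) > 1L) {
    best <- best[curve$specificity[best] == max(curve$specificity[best])]
    best <- best[which.max(curve$thresholds[best])]
  }
  list(threshold = curve$thresholds[best],
       sensitivity = curve$sensitivity[best],
       specificity = curve$specificity[best],
       youden = j[best])
}

#' DeLong test for the difference of two AUCs
#'
#' Compares the areas under two ROC curves. In the paired form both curves
#' must come from the same subjects in the same order (identical outcome
#' vectors); the covariance of the two AUCs is then estimated from the joint
#' placement values. In the unpaired form the curves are independent and the
#' variances add. Comparing a curve with itself yields a difference of zero
#' and p = 1.
#'
#' @param curve_a,curve_b [roc_curve()] objects.
#' @param paired Do both curves score the same subjects?
#' @return List with `auc_a`, `auc_b`, `difference`, `se`, `z` and `p`
#'   (two-sided).
#' @export
compare_roc <- function(curve_a, curve_b, paired = FALSE) {
  stopifnot(inherits(curve_a, "roc_curve"), inherits(curve_b, "roc_curve"))
  d <- curve_a$auc - curve_b$auc
  if (paired) {
    if (curve_a$n_pos != curve_b$n_pos || curve_a$n_neg != curve_b$n_neg ||
        length(curve_a$labels) != length(curve_b$labels) ||
        !all(curve_a$labels == curve_b$labels))
      stop("paired comparison requires identical subjects (same labels, same order)",
           call. = FALSE)
    pa <- delong_placements(curve_a$scores, curve_a$labels)
    pb <- delong_placements(curve_b$scores, curve_b$labels)
    s10 <- stats::cov(cbind(pa$v10, pb$v10))
    s01 <- stats::cov(cbind(pa$v01, pb$v01))
    var_d <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / curve_a$n_pos +
             (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / curve_a$n_neg
  } else {
    var_d <- curve_a$auc_se^2 + curve_b$auc_se^2
  }
  if (var_d <= 0) {
    z <- if (d == 0) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(var_d)
  }
  list(auc_a = curve_a$auc, auc_b = curve_b$auc, difference = d,
       se = sqrt(max(var_d, 0)), z = z, p = 2 * stats::pnorm(-abs(z)))
}
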