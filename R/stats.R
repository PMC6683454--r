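#' Mann-Whitney U test for two groups
#'
#' Computes the U statistic for group `a` against group `b` by midranks
#' (U counts pairs where a beats b, ties counting one half) and a two-sided
#' p-value via [stats::wilcox.test()] (exact distribution at small samples
#' without ties, otherwise the tie-corrected normal approximation).
#'
#' @param a,b Numeric vectors, both non-empty.
#' @return List with `u` (for group `a`), `p` and the group sizes.
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(a, b), ties.method = "average")
  u <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  wt <- suppressWarnings(stats::wilcox.test(
    a, b, exact = min(length(a), length(b)) <= 8 && !ties,
    correct = FALSE))
  list(u = u, p = wt$p.value, n_a = length(a), n_b = length(b))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value (sum of hypergeometric probabilities of tables,
#'   at fixed margins, no more probable than the observed one).
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop("'table' must be 2x2", call. = FALSE)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers", call. = FALSE)
  stats::fisher.test(table)$p.value
}

#' Prevalence-adjusted predictive values
#'
#' Positive and negative predictive values from sensitivity, specificity and
#' an externally supplied prevalence (Bayes' identities):
#' `ppv = se p / (se p + (1 - sp)(1 - p))` and
#' `npv = sp (1 - p) / (sp (1 - p) + (1 - se) p)`.
#'
#' @param sensitivity,specificity Proportions in \[0, 1\] (vectorised).
#' @param prevalence Outcome prevalence in (0, 1) used for the adjustment.
#' @return List with `ppv` and `npv` (proportions).
#' @examples
#' adjusted_ppv_npv(0.5, 0.5, 0.2)  # ppv 0.2, npv 0.8
#' @export
adjusted_ppv_npv <- function(sensitivity, specificity, prevalence) {
  if (any(sensitivity < 0 | sensitivity > 1) || any(specificity < 0 | specificity > 1))
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  if (any(prevalence <= 0 | prevalence >= 1))
    stop("prevalence must lie strictly between 0 and 1", call. = FALSE)
  se <- sensitivity; sp <- specificity; p <- prevalence
  list(ppv = se * p / (se * p + (1 - sp) * (1 - p)),
       npv = sp * (1 - p) / (sp * (1 - p) + (1 - se) * p))
}

#' Odds ratio with Woolf confidence interval
#'
#' Builds the 2x2 table of test call against outcome and returns the
#' cross-product odds ratio with a 95% confidence interval by Woolf's logit
#' method. When any cell is zero, the Haldane-Anscombe correction (+0.5 to
#' every cell) is applied so that the estimate and interval stay finite.
#'
#' @param test_calls Logical vector of dichotomised test results, or a 2x2
#'   count matrix (rows: test positive/negative; columns: outcome
#'   present/absent) in which case `outcomes` is ignored.
#' @param outcomes Logical outcome vector, same length as `test_calls`.
#' @param conf_level Confidence level for the Woolf interval.
#' @return Object of class `odds_ratio`: list with `odds_ratio`, `ci_low`,
#'   `ci_high`, `table` and `corrected`.
#' @examples
#' odds_ratio(matrix(c(10, 2, 5, 8), 2))  # OR = 8
#' @export
odds_ratio <- function(test_calls, outcomes = NULL, conf_level = 0.95) {
  if (is.matrix(test_calls)) {
    tab <- test_calls
    if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0))
      stop("'table' must be a non-negative 2x2 matrix", call. = FALSE)
  } else {
    if (length(test_calls) == 0L)
      stop("empty input", call. = FALSE)
    if (length(test_calls) != length(outcomes))
      stop("'test_calls' and 'outcomes' must have the same length", call. = FALSE)
    tc <- factor(as.logical(test_calls), levels = c(TRUE, FALSE))
    oc <- factor(as.logical(outcomes), levels = c(TRUE, FALSE))
    tab <- table(test = tc, outcome = oc)
  }
  tab <- unclass(tab)
  corrected <- any(tab == 0)
  w <- if (corrected) tab + 0.5 else tab
  a <- w[1, 1]; b <- w[1, 2]; cc <- w[2, 1]; d <- w[2, 2]
  or <- (a * d) / (b * cc)
  se_log <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(odds_ratio = or,
                 ci_low = exp(log(or) - z * se_log),
                 ci_high = exp(log(or) + z * se_log),
                 table = tab, corrected = corrected),
            class = "odds_ratio")
}

#' @export
print.odds_ratio <- function(x, ...) {
  cat(sprintf("OR = %.2f [%.2f-%.2f]%s\n", x$odds_ratio, x$ci_low, x$ci_high,
              if (x$corrected) " (Haldane-Anscombe corrected)" else ""))
  invisible(x)
}

apply_transform <- function(x, transform) {
  switch(transform,
    identity = x,
    log10 = log10(x),
    # methylation levels: 0 is a real value; offset of 0.01 (half the 0.1%
    # calling threshold scaled by 1/5) keeps zeros finite and order intact
    log10_offset = log10(x + 0.01),
    log10_odds = log10(x / (1 - x)),
    stop("unknown transform '", transform, "'", call. = FALSE))
}

#' Fit a logistic combined score
#'
#' Combines several biomarkers into a single score by binomial logistic
#' regression on monotonically transformed features; the model's linear
#' predictor is the combined score (so the combined ROC of a single feature
#' is identical to the feature's own ROC). Coefficients are deterministic
#' given the data. Complete or quasi-complete separation (detected by
#' non-convergence or exploding coefficients) triggers a ridge-penalised
#' refit with a small fixed penalty, flagged in the result.
#'
#' @param features Data frame or matrix of per-patient feature values.
#' @param labels Logical outcome vector.
#' @param transforms Character vector (recycled) of per-feature transforms:
#'   `"identity"`, `"log10"`, `"log10_offset"` (log10(x + 0.01), for
#'   methylation levels containing zeros) or `"log10_odds"` (for
#'   probabilities).
#' @param ridge Penalty used by the separation fallback.
#' @return Object of class `combined_score_model` with `feature_names`,
#'   `coefficients` (intercept first), `transforms` and `separation`.
#' @export
fit_combined_score <- function(features, labels, transforms = "identity",
                               ridge = 1e-3) {
  features <- as.data.frame(features)
  labels <- as.logical(labels)
  keep <- stats::complete.cases(features) & !is.na(labels)
  features <- features[keep, , drop = FALSE]
  labels <- labels[keep]
  if (length(unique(labels)) < 2L)
    stop("labels are constant; cannot fit a combined score", call. = FALSE)
  if (sum(labels) < 2L || sum(!labels) < 2L)
    stop("at least 2 patients per class are required", call. = FALSE)
  transforms <- rep_len(transforms, ncol(features))
  x <- mapply(apply_transform, features, transforms)
  x <- matrix(x, ncol = ncol(features),
              dimnames = list(NULL, colnames(features)))

  fit <- suppressWarnings(stats::glm.fit(cbind(1, x), as.numeric(labels),
                                         family = stats::binomial()))
  coefs <- fit$coefficients
  separated <- !fit$converged || any(!is.finite(coefs)) ||
    any(abs(coefs[-1]) > 15 / pmax(apply(x, 2, stats::sd), 1e-12))
  if (separated)
    coefs <- ridge_logistic(cbind(1, x), labels, lambda = ridge)
  names(coefs) <- c("(Intercept)", colnames(features))

  structure(list(feature_names = colnames(features), coefficients = coefs,
                 transforms = stats::setNames(transforms, colnames(features)),
                 separation = separated),
            class = "combined_score_model")
}

# Newton iterations for logistic log-likelihood with an L2 penalty on the
# non-intercept coefficients; small fixed lambda, used only as a separation
# fallback so coefficients stay finite and deterministic.
ridge_logistic <- function(X, y, lambda = 1e-3, max_iter = 200, tol = 1e-10) {
  p <- ncol(X)
  beta <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- crossprod(X, y - mu) - pen %*% beta
    hess <- crossprod(X * w, X) + pen
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  drop(beta)
}

#' Combined score of new patients
#'
#' @param object A [fit_combined_score()] model.
#' @param newdata Data frame containing the model's feature columns.
#' @param ... Unused.
#' @return Numeric linear-predictor scores.
#' @export
predict.combined_score_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$feature_names, names(newdata))
  if (length(missing))
    stop("newdata lacks feature columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  x <- mapply(apply_transform,
              newdata[object$feature_names],
              object$transforms[object$feature_names])
  x <- matrix(x, ncol = length(object$feature_names))
  drop(cbind(1, x) %*% object$coefficients)
}

outcome_column <- function(outcome) {
  switch(outcome,
         upgrading = "upgraded",
         upstaging = "upstaged",
         risk_increase = "risk_increased",
         stop("unknown outcome '", outcome, "'", call. = FALSE))
}

default_transform <- function(marker) {
  if (marker %in% target_genes || endsWith(marker, "_level")) "log10_offset"
  else if (marker == "psa") "log10"
  else if (marker == "partin_prob") "log10_odds"
  else "identity"
}

marker_column <- function(cohort, marker) {
  if (!is.null(cohort[[marker]])) return(cohort[[marker]])
  lev <- paste0(marker, "_level")
  if (!is.null(cohort[[lev]])) return(cohort[[lev]])
  stop("cohort has no column for biomarker '", marker, "'", call. = FALSE)
}

#' End-to-end biomarker evaluation
#'
#' Evaluates a single biomarker or a logistic combination against one of the
#' misclassification outcomes on a classified cohort: builds the score, the
#' ROC curve with DeLong inference, selects the Youden-optimal threshold,
#' adjusts PPV/NPV to the designated prevalence, and computes the odds ratio
#' of the dichotomised test. Patients with a missing score or outcome are
#' excluded from the evaluation (and counted).
#'
#' @param cohort Cohort classified by [classify_cohort()], carrying marker
#'   columns (gene levels as `<GENE>_level` or bare gene names, `psa`,
#'   `partin_prob`).
#' @param markers Character vector of marker names; more than one triggers
#'   the logistic combination.
#' @param outcome `"upgrading"`, `"upstaging"` or `"risk_increase"`.
#' @param prevalence Prevalence for the PPV/NPV adjustment; defaults to the
#'   observed outcome rate in `cohort` (supply the full-cohort rate to mimic
#'   the prevalence-adjusted reporting).
#' @param transforms Optional per-marker transforms; defaults are log10 for
#'   PSA, log10-odds for Partin probabilities, log10(x + 0.01) for
#'   methylation levels.
#' @return Object of class `biomarker_evaluation`: list with `markers`,
#'   `outcome`, `n_used`, `n_excluded`, `roc`, `model` (NULL for single
#'   markers), `threshold`, `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `prevalence` and `odds_ratio`.
#' @export
evaluate_biomarker <- function(cohort, markers, outcome,
                               prevalence = NULL, transforms = NULL) {
  if (is.null(cohort$upgraded))
    stop("run classify_cohort() first", call. = FALSE)
  y <- cohort[[outcome_column(outcome)]]
  if (is.null(transforms))
    transforms <- vapply(markers, default_transform, "")
  feat <- as.data.frame(lapply(markers, function(m) marker_column(cohort, m)))
  names(feat) <- markers
  keep <- stats::complete.cases(feat) & !is.na(y)
  n_excluded <- sum(!keep)
  feat <- feat[keep, , drop = FALSE]
  y <- as.logical(y[keep])

  if (length(markers) == 1L) {
    model <- NULL
    score <- apply_transform(feat[[1]], transforms[[1]])
  } else {
    model <- fit_combined_score(feat, y, transforms)
    score <- predict(model, feat)
  }
  curve <- roc_curve(score, y)
  opt <- youden_optimal(curve)
  if (is.null(prevalence)) prevalence <- mean(y)
  pv <- adjusted_ppv_npv(opt$sensitivity, opt$specificity, prevalence)
  calls <- score >= opt$threshold
  or <- odds_ratio(calls, y)

  structure(list(markers = markers, outcome = outcome,
                 n_used = length(y), n_excluded = n_excluded,
                 roc = curve, model = model,
                 threshold = opt$threshold,
                 sensitivity = opt$sensitivity,
                 specificity = opt$specificity,
                 ppv = pv$ppv, npv = pv$npv, prevalence = prevalence,
                 odds_ratio = or),
            class = "biomarker_evaluation")
}

#' @export
print.biomarker_evaluation <- function(x, ...) {
  cat(sprintf("Biomarker evaluation: %s vs %s (n = %d, prevalence %.3f)\n",
              paste(x$markers, collapse = " + "), x$outcome, x$n_used,
              x$prevalence))
  cat(sprintf("  AUC %.3f (p = %.3g); Youden threshold %.4g\n",
              x$roc$auc, x$roc$auc_p, x$threshold))
  cat(sprintf("  sens %.1f%%, spec %.1f%%, PPV %.1f%%, NPV %.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity,
              100 * x$ppv, 100 * x$npv))
  print(x$odds_ratio)
  invisible(x)
}

#' Reported operating characteristics of the urinary biomarkers
#'
#' Published sensitivity, specificity, PPV and NPV (percent) of the urinary
#' methylation markers, PSA and Partin nomogram values for predicting
#' upstaging, upgrading and risk-group change in the voided and catheterized
#' urine cohorts. Used to check that the prevalence-adjusted predictive
#' values are recomputable from their sensitivity/specificity inputs and the
#' full-cohort outcome rates.
#'
#' @return Data frame with columns `cohort`, `outcome`, `biomarker`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `consistent` (FALSE for the
#'   rows whose printed predictive values are not reproducible from their own
#'   printed inputs under any single prevalence; see the vignette).
#' @export
reported_test_performance <- function() {
  path <- system.file("extdata", "reported_test_performance.csv",
                      package = "urimeth", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
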