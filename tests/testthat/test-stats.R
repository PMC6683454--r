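test_that("Mann-Whitney U matches pair enumeration, with midrank ties", {
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$u, 4.5)
  expect_gt(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 0.99)
  expect_equal(mann_whitney(c(5, 6, 7), c(1, 2, 3))$u, 9)
  set.seed(13)
  for (i in 1:10) {
    a <- sample(1:4, sample(3:9, 1), replace = TRUE)   # tie-heavy
    b <- sample(1:4, sample(3:9, 1), replace = TRUE)
    expect_equal(mann_whitney(a, b)$u, brute_force_u(a, b))
  }
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Fisher exact p equals full enumeration for small margins", {
  expect_equal(fisher_exact(matrix(1, 2, 2)), 1)
  expect_equal(fisher_exact(matrix(c(0, 5, 5, 0), 2)), 2 / 252,
               tolerance = 1e-6)
  set.seed(17)
  for (i in 1:25) {
    tab <- matrix(sample(0:6, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact(tab), enumerate_fisher(tab), tolerance = 1e-9,
                 label = paste(tab, collapse = ","))
  }
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("prevalence-adjusted PPV/NPV satisfy the Bayes identities", {
  un <- adjusted_ppv_npv(0.5, 0.5, 0.2)
  expect_equal(un$ppv, 0.2)   # uninformative test returns the prevalence
  expect_equal(un$npv, 0.8)
  perfect <- adjusted_ppv_npv(1, 1, 0.3)
  expect_equal(perfect$ppv, 1)
  expect_equal(perfect$npv, 1)
  pv <- adjusted_ppv_npv(0.867, 0.279, 214 / 1056)
  expect_equal(round(100 * pv$ppv, 1), 23.4)
  expect_error(adjusted_ppv_npv(0.5, 0.5, 0), "between 0 and 1")
  expect_error(adjusted_ppv_npv(1.2, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("odds ratios use the cross product with Woolf intervals", {
  or <- odds_ratio(matrix(c(10, 2, 5, 8), 2))
  expect_equal(or$odds_ratio, 8)
  expect_false(or$corrected)
  expect_true(or$ci_low <= or$odds_ratio && or$odds_ratio <= or$ci_high)
  expect_equal(odds_ratio(matrix(1, 2, 2))$odds_ratio, 1)
  zero <- odds_ratio(matrix(c(4, 0, 1, 7), 2))
  expect_true(zero$corrected)
  expect_true(is.finite(zero$odds_ratio) && is.finite(zero$ci_high))
  # vector interface builds the same table
  calls <- rep(c(TRUE, TRUE, FALSE, FALSE), c(10, 5, 2, 8))
  outc <- rep(c(TRUE, FALSE, TRUE, FALSE), c(10, 5, 2, 8))
  expect_equal(odds_ratio(calls, outc)$odds_ratio, 8)
  expect_error(odds_ratio(logical(0), logical(0)), "empty")
})

test_that("a single-feature combined score preserves the feature's ROC", {
  set.seed(31)
  x <- rlnorm(120)
  y <- runif(120) < plogis(log(x))
  if (sum(y) < 2 || sum(!y) < 2) skip("degenerate draw")
  m <- fit_combined_score(data.frame(x = x), y, transforms = "log10")
  r_feat <- roc_curve(log10(x), y)
  r_comb <- roc_curve(predict(m, data.frame(x = x)), y)
  expect_equal(r_comb$auc, r_feat$auc)
  expect_equal(r_comb$sensitivity, r_feat$sensitivity)
})

test_that("combining two informative features does not lose training AUC", {
  set.seed(33)
  n <- 300
  y <- runif(n) < 0.4
  f1 <- rnorm(n, mean = y * 0.8)
  f2 <- rnorm(n, mean = y * 0.8)
  m <- fit_combined_score(data.frame(f1 = f1, f2 = f2), y)
  auc_comb <- roc_curve(predict(m, data.frame(f1 = f1, f2 = f2)), y)$auc
  auc_single <- max(roc_curve(f1, y)$auc, roc_curve(f2, y)$auc)
  expect_gte(auc_comb, auc_single)
  expect_false(m$separation)
})

test_that("constant labels are rejected and separation falls back to ridge", {
  expect_error(fit_combined_score(data.frame(x = 1:10), rep(TRUE, 10)),
               "constant")
  x <- c(1:5, 11:15)
  y <- rep(c(FALSE, TRUE), each = 5)
  m <- fit_combined_score(data.frame(x = x), y)
  expect_true(m$separation)
  expect_true(all(is.finite(m$coefficients)))
  expect_equal(roc_curve(predict(m, data.frame(x = x)), y)$auc, 1)
})

test_that("biomarker evaluation is coherent end to end on synthetic cohorts", {
  cl <- make_classified(n = 400, seed = 19)
  ev <- evaluate_biomarker(cl, c("RASSF1", "psa"), "upgrading")
  expect_equal(ev$n_used + ev$n_excluded, nrow(cl))
  expect_true(ev$roc$auc >= 0 && ev$roc$auc <= 1)
  pv <- adjusted_ppv_npv(ev$sensitivity, ev$specificity, ev$prevalence)
  expect_equal(ev$ppv, pv$ppv)
  expect_equal(ev$npv, pv$npv)
  # a supplied prevalence overrides the cohort rate
  ev2 <- evaluate_biomarker(cl, "psa", "upstaging", prevalence = 214 / 1056)
  expect_equal(ev2$prevalence, 214 / 1056)
})

test_that("a null marker is uninformative and a strong marker near-perfect", {
  set.seed(41)
  cl <- make_classified(n = 500, seed = 23)
  cl$noise_level <- rlnorm(nrow(cl))
  ev_null <- evaluate_biomarker(cl, "noise", "upgrading")
  expect_lt(abs(ev_null$roc$auc - 0.5), 0.08)
  cl$oracle_level <- ifelse(cl$upgraded %in% TRUE, 10, 1) * rlnorm(nrow(cl), sd = 0.05)
  ev_strong <- evaluate_biomarker(cl, "oracle", "upgrading")
  expect_gt(ev_strong$roc$auc, 0.95)
})
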