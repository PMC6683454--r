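test_that("Gleason patterns map to ISUP grade groups", {
  # oracle: the ISUP 2014 table over all 25 pattern pairs
  gg_lookup <- function(p, s) {
    if (p + s <= 6) 1L
    else if (p == 3 && s == 4) 2L
    else if (p == 4 && s == 3) 3L
    else if (p + s == 8) 4L
    else 5L
  }
  grid <- expand.grid(p = 1:5, s = 1:5)
  expect_equal(gleason_to_gg(grid$p, grid$s),
               mapply(gg_lookup, grid$p, grid$s))
  expect_equal(gleason_to_gg(3, 4), 2L)
  expect_equal(gleason_to_gg(4, 3), 3L)
  expect_equal(gleason_to_gg(3, 3), 1L)
  expect_error(gleason_to_gg(0, 3), "1..5")
})

test_that("upgrading is pGG > cGG, with exactly one state per patient", {
  expect_equal(classify_upgrade(1, 2), "upgraded")
  expect_equal(classify_upgrade(3, 3), "unchanged")
  expect_equal(classify_upgrade(4, 2), "downgraded")
  expect_true(is.na(classify_upgrade(2, NA)))
  # antisymmetry under swapping clinical and pathological grades
  grid <- expand.grid(c = 1:5, p = 1:5)
  fwd <- classify_upgrade(grid$c, grid$p)
  rev <- classify_upgrade(grid$p, grid$c)
  expect_equal(fwd == "upgraded", rev == "downgraded")
  expect_equal(fwd == "unchanged", rev == "unchanged")
})

test_that("upstaging is pT >= T3a when clinically organ-confined", {
  expect_equal(classify_upstage("T2a", "T3a"), "upstaged")
  expect_equal(classify_upstage("T3a", "T3a"), "unchanged")
  expect_equal(classify_upstage("T1c", "T2c"), "unchanged")
  expect_equal(classify_upstage("T3a", "T2c"), "downstaged")
  expect_error(classify_upstage("T2", "T3a"), "substage")
  # antisymmetry under swapping clinical and pathological stages
  grid <- expand.grid(c = stage_levels(), p = stage_levels(),
                      stringsAsFactors = FALSE)
  fwd <- classify_upstage(grid$c, grid$p)
  rev <- classify_upstage(grid$p, grid$c)
  expect_equal(fwd == "upstaged", rev == "downstaged")
})

test_that("pre-operative risk grouping follows highest-wins rules", {
  expect_equal(as.character(preop_risk(1, "T2a")), "low")
  expect_equal(as.character(preop_risk(2, "T1c")), "intermediate")
  expect_equal(as.character(preop_risk(1, "T2c")), "high")
  expect_equal(as.character(preop_risk(1, "T2b")), "intermediate")
  expect_equal(as.character(preop_risk(5, "T1a")), "high")
})

test_that("post-operative risk grouping follows highest-wins rules", {
  expect_equal(as.character(postop_risk(1, "T2c")), "low")
  expect_equal(as.character(postop_risk(3, "T2b")), "intermediate")
  expect_equal(as.character(postop_risk(1, "T3a")), "high")
  expect_equal(as.character(postop_risk(NA, "T3a")), "high")
  expect_true(is.na(postop_risk(NA, "T2a")))
})

test_that("risk groups are monotone in grade and stage", {
  for (ct in stage_levels()) {
    pre <- preop_risk(1:5, ct)
    post <- postop_risk(1:5, ct)
    expect_true(all(diff(as.integer(pre)) >= 0))
    expect_true(all(diff(as.integer(post)) >= 0))
  }
  for (gg in 1:5) {
    pre <- preop_risk(rep(gg, 9), stage_levels())
    post <- postop_risk(rep(gg, 9), stage_levels())
    expect_true(all(diff(as.integer(pre)) >= 0))
    expect_true(all(diff(as.integer(post)) >= 0))
  }
})

test_that("classify_patient composes migration and risk rules", {
  r <- classify_patient(1, 2, "T1c", "T2c")
  expect_true(r$upgraded); expect_false(r$upstaged); expect_true(r$misclassified)
  r <- classify_patient(2, 2, "T2a", "T3a")
  expect_true(r$upstaged); expect_true(r$misclassified); expect_true(r$risk_increased)
  r <- classify_patient(1, 1, "T1c", "T2a")
  expect_false(r$upgraded); expect_false(r$upstaged); expect_false(r$misclassified)
  expect_equal(as.character(r$preop_risk), "low")
  expect_equal(as.character(r$postop_risk), "low")
})

test_that("exactly one migration state holds per patient on random cohorts", {
  cl <- make_classified(n = 300, seed = 7)
  expect_false(any(cl$upgraded & cl$downgraded, na.rm = TRUE))
  expect_false(any(cl$upstaged & cl$downstaged))
  expect_equal(cl$misclassified, cl$upgraded | cl$upstaged)
})

test_that("summarize_rates uses mixed denominators for gradable patients", {
  cohort <- data.frame(
    patient_id = c("a", "b", "c", "d"),
    cgg = c(1, 1, 2, 2), pgg = c(2, NA, 2, 2),
    ct = c("T1c", "T2a", "T2a", "T2a"),
    pt = c("T2a", "T3a", "T2a", "T2a"),
    stringsAsFactors = FALSE)
  s <- summarize_rates(classify_cohort(cohort))
  expect_equal(s$n_total, 4L)
  expect_equal(s$n_gradable, 3L)        # patient b has no pGG
  expect_equal(s$upgraded, 1L)
  expect_equal(s$upstaged, 1L)          # the ungradable patient still counts
  expect_equal(s$upgraded_pct, 100 / 3)
  expect_equal(s$upstaged_pct, 25)
  expect_equal(s$misclassified, 1L)
})

test_that("a single unchanged patient yields all-zero rates", {
  s <- summarize_rates(classify_cohort(data.frame(
    patient_id = "a", cgg = 2, pgg = 2, ct = "T2a", pt = "T2a")))
  expect_equal(s$upgraded_pct, 0)
  expect_equal(s$upstaged_pct, 0)
  expect_equal(s$misclassified_pct, 0)
})

test_that("transition-matrix margins and triangles agree with the flag counts", {
  expect_equal(unclass(transition_matrix(classify_cohort(data.frame(
    patient_id = "a", cgg = 1, pgg = 1, ct = "T1c", pt = "T1c"))))["1", "1"], 1L,
    ignore_attr = TRUE)
  for (seed in 1:3) {
    cl <- make_classified(n = 250, seed = seed)
    tm <- transition_matrix(cl, "grade")
    expect_equal(rowSums(tm), table(factor(cl$cgg[!is.na(cl$pgg)], 1:5)),
                 ignore_attr = TRUE)
    expect_equal(sum(tm[upper.tri(tm)]), sum(cl$upgraded, na.rm = TRUE))
    expect_equal(sum(tm[lower.tri(tm)]), sum(cl$downgraded, na.rm = TRUE))
    st <- transition_matrix(cl, "stage")
    t3 <- match("T3a", stage_levels())
    expect_equal(sum(st[1:(t3 - 1), t3:9]), sum(cl$upstaged))
  }
})
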