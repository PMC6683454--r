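test_that("replicate aggregation averages amplified wells and reports absence", {
  expect_equal(aggregate_replicates(c(30, 30, 30)), 30)
  expect_equal(aggregate_replicates(c(29, 31)), 30)
  expect_equal(aggregate_replicates(c(NA, 29, 31)), 30)
  expect_true(is.na(aggregate_replicates(c(NA, NA, NA))))
  expect_error(aggregate_replicates(numeric(0)), "at least one")
  expect_error(aggregate_replicates(c(30, 30, 30, 30)), "at most 3")
  expect_error(aggregate_replicates(c(55, 30)), "0, 50")
})

test_that("run validity requires MC amplification and a clean NTC", {
  expect_true(validate_run(mc_cqs = 27, ntc_cqs = NA))
  expect_false(validate_run(mc_cqs = 27, ntc_cqs = 38))
  expect_false(validate_run(mc_cqs = NA, ntc_cqs = NA))
  expect_true(validate_run(mc_cqs = c(NA, 28, 27), ntc_cqs = c(NA, NA, NA)))
  expect_error(validate_run(numeric(0), NA), "required")
})

test_that("sample validity needs ACTB < 40 in all three replicates", {
  expect_true(validate_sample(c(32, 33, 31)))
  expect_false(validate_sample(c(39, 41, 38)))
  expect_false(validate_sample(c(32, 33)))
  expect_false(validate_sample(c(32, NA, 33)))
  expect_false(validate_sample(c(40, 39, 39)))
})

test_that("delta-delta-Cq levels match hand calculations", {
  expect_equal(methylation_level(30, 25, 26, 25), 6.25)
  expect_equal(methylation_level(27, 25, 26, 25), 50)
  # identical target/control differences give exactly 100% of MC
  expect_equal(methylation_level(26, 25, 26, 25), 100)
  expect_warning(lvl <- methylation_level(25, 25, 26, 25), "above 100")
  expect_equal(lvl, 200)
  expect_error(methylation_level(NA, 25, 26, 25), "finite")
})

test_that("each extra target cycle halves the level (strict monotonicity)", {
  cqs <- seq(24, 36, by = 1)
  levels <- suppressWarnings(methylation_level(cqs, 25, 26, 25))
  expect_true(all(diff(levels) < 0))
  expect_equal(levels[-length(levels)] / levels[-1], rep(2, length(cqs) - 1))
})

test_that("calls are invariant to a common shift of both ACTB anchors", {
  # normalisation property: the level itself is unchanged when the same
  # constant is added to the sample and MC ACTB Cqs
  for (shift in c(-3, 0, 2.5)) {
    a <- methylation_level(30, 25, 26, 25)
    b <- methylation_level(30, 25 + shift, 26, 25 + shift)
    expect_equal(a, b)
    expect_equal(dichotomize(a), dichotomize(b))
  }
})

test_that("dichotomisation uses an inclusive 0.1% boundary", {
  expect_false(dichotomize(0.05))
  expect_true(dichotomize(0.1))
  expect_false(dichotomize(0))
  expect_true(dichotomize(0.05, threshold = 0.01))
  expect_error(dichotomize(-1), "non-negative")
})

test_that("panel positivity is any-of over the three genes", {
  expect_true(panel_positive(c(RARB = FALSE, RASSF1 = TRUE, GSTP1 = FALSE)))
  expect_false(panel_positive(c(RARB = FALSE, RASSF1 = FALSE, GSTP1 = FALSE)))
  expect_true(panel_positive(c(RARB = TRUE, RASSF1 = TRUE, GSTP1 = TRUE)))
  expect_error(panel_positive(c(RARB = TRUE, RASSF1 = TRUE)), "GSTP1")
})

make_plate <- function(samples, mc_gene_cq = 26, mc_actb_cq = 25,
                       ntc_gene_cq = NA, genes = c("RARB", "RASSF1", "GSTP1")) {
  rows <- list()
  add <- function(id, gene, role, cqs)
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = id, gene = gene, well_role = role,
      rep1_cq = cqs[1], rep2_cq = cqs[2], rep3_cq = cqs[3],
      stringsAsFactors = FALSE)
  for (g in genes) {
    add("MC", g, "MC", rep(mc_gene_cq, 3))
    add("NTC", g, "NTC", rep(ntc_gene_cq, 3))
  }
  add("MC", "ACTB", "MC", rep(mc_actb_cq, 3))
  for (id in names(samples)) {
    s <- samples[[id]]
    add(id, "ACTB", "sample", s$actb)
    for (g in genes) add(id, g, "sample", s[[g]])
  }
  do.call(rbind, rows)
}

test_that("plate quantification round-trips known levels and flags validity", {
  plate <- make_plate(list(
    s1 = list(actb = c(30, 30, 30),
              RARB = rep(level_to_cq(6.25), 3),
              RASSF1 = rep(level_to_cq(0.05), 3),
              GSTP1 = rep(NA_real_, 3)),
    s2 = list(actb = c(41, 39, 39),    # invalid sample: one ACTB >= 40
              RARB = c(30, 30, 30), RASSF1 = c(30, 30, 30),
              GSTP1 = c(30, 30, 30))))
  res <- quantify_run(plate)
  s1 <- res[res$sample_id == "s1", ]
  expect_true(s1$sample_valid)
  expect_equal(s1$RARB_level, 6.25)
  expect_equal(s1$RASSF1_level, 0.05, tolerance = 1e-12)
  expect_equal(s1$GSTP1_level, 0)          # no amplification is a true zero
  expect_true(s1$RARB_call)
  expect_false(s1$RASSF1_call)             # below the 0.1% threshold
  expect_false(s1$GSTP1_call)
  expect_true(s1$panel_positive)
  s2 <- res[res$sample_id == "s2", ]
  expect_false(s2$sample_valid)
  expect_true(all(is.na(s2[, c("RARB_level", "RASSF1_level", "GSTP1_level")])))
})

test_that("a failed run control invalidates only that gene's assay", {
  plate <- make_plate(list(
    s1 = list(actb = c(30, 30, 30), RARB = c(32, 32, 32),
              RASSF1 = c(32, 32, 32), GSTP1 = c(32, 32, 32))))
  # contaminate the RASSF1 NTC only
  plate$rep1_cq[plate$gene == "RASSF1" & plate$well_role == "NTC"] <- 38
  expect_message(res <- quantify_run(plate), "RASSF1")
  expect_true(is.na(res$RASSF1_level))
  expect_false(is.na(res$RARB_level))
  expect_false(is.na(res$GSTP1_level))
  expect_equal(attr(res, "run_valid"),
               c(RARB = TRUE, RASSF1 = FALSE, GSTP1 = TRUE))
})

test_that("quantify_plates rejects duplicate sample ids across runs", {
  plate <- make_plate(list(s1 = list(actb = c(30, 30, 30),
                                     RARB = c(32, 32, 32),
                                     RASSF1 = c(32, 32, 32),
                                     GSTP1 = c(32, 32, 32))))
  expect_error(quantify_plates(list(plate, plate)), "duplicate")
})

test_that("level_to_cq inverts methylation_level", {
  levels <- c(0.01, 0.1, 1, 6.25, 50, 100)
  cq <- level_to_cq(levels, sample_actb_cq = 30)
  back <- methylation_level(cq, 30, 26, 25)
  expect_equal(back, levels)
  expect_true(is.na(level_to_cq(0)))
})
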