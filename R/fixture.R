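#' Published cohort counts
#'
#' The integer counts reported for the 1056-patient radical-prostatectomy
#' cohort: total and gradable patients, upgrading/upstaging/misclassification
#' counts with their grade- and stage-origin breakdowns, the risk-increase
#' decomposition, and urine panel positivity by collection route. These are
#' the constraints [build_printed_fixture()] solves.
#'
#' @return Named list of counts.
#' @export
fixture_spec <- function() {
  list(
    total = 1056L,            # patients with stages
    gradable = 1025L,         # patients with both grade groups
    upgraded = 279L,
    upgraded_from_cgg1 = 241L,
    cgg1_to_pgg2 = 208L,
    upstaged = 214L,
    upstaged_from_ct1c = 105L,
    misclassified = 400L,
    risk_increased = 245L,
    risk_increase_grade_only = 111L,
    risk_increase_both = 55L,
    risk_increase_stage_only = 79L,
    risk_increase_from_preop_low = 171L,
    voided_n = 188L, voided_panel_pos = 151L,
    cath_n = 326L, cath_panel_pos = 273L
  )
}

fixture_fail <- function(identity) {
  stop("inconsistent fixture specification: ", identity, call. = FALSE)
}

#' Deterministic cohort reproducing the published counts
#'
#' Builds a cohort of exactly `spec$total` patients whose classification by
#' [classify_cohort()] reproduces every published count: upgrading,
#' upstaging and total misclassification with their denominators, the
#' cGG1-origin and cGG1-to-pGG2 upgrade breakdown, the cT1c-origin upstaging
#' breakdown, the risk-increase decomposition (grade-only / both /
#' stage-only, and the pre-operatively low-risk share) and per-route urine
#' panel positivity. The construction is purely arithmetic (no randomness):
#' patients are laid out in blocks of minimal grade/stage templates, the
#' upgraded-and-upstaged overlap is fixed by
#' `upgraded + upstaged - misclassified` (all upstaged patients being
#' gradable), and every count budget must be consumed exactly or the
#' function stops naming the violated identity.
#'
#' Patients not constrained by any published count receive neutral values
#' (cGG2/pGG2, cT2a/pT2a, PSA 7 ng/mL). Panel-positive urine samples carry a
#' RASSF1 level of 5% of MC; panel-negative samples carry zero levels;
#' patients without urine carry `NA` levels and route.
#'
#' @param spec Count list as returned by [fixture_spec()].
#' @return Cohort data frame ready for [classify_cohort()].
#' @export
build_printed_fixture <- function(spec = fixture_spec()) {
  overlap <- spec$upgraded + spec$upstaged - spec$misclassified
  if (overlap < 0)
    fixture_fail("upgraded + upstaged - misclassified >= 0")
  if (overlap < spec$risk_increase_both)
    fixture_fail("risk_increase_both <= upgraded-and-upstaged overlap")
  if (spec$cgg1_to_pgg2 > spec$upgraded_from_cgg1 ||
      spec$upgraded_from_cgg1 > spec$upgraded)
    fixture_fail("cgg1_to_pgg2 <= upgraded_from_cgg1 <= upgraded")
  if (spec$upstaged_from_ct1c > spec$upstaged)
    fixture_fail("upstaged_from_ct1c <= upstaged")
  if (spec$risk_increase_grade_only + spec$risk_increase_both +
      spec$risk_increase_stage_only != spec$risk_increased)
    fixture_fail("grade_only + both + stage_only = risk_increased")
  if (spec$gradable > spec$total)
    fixture_fail("gradable <= total")
  if (spec$voided_panel_pos > spec$voided_n || spec$cath_panel_pos > spec$cath_n)
    fixture_fail("panel-positive counts cannot exceed route totals")
  if (spec$voided_n + spec$cath_n > spec$total)
    fixture_fail("urine samples cannot exceed the cohort size")

  # remaining budgets, consumed exactly during construction
  budget <- list(
    cgg1_pgg2 = spec$cgg1_to_pgg2,
    cgg1_other = spec$upgraded_from_cgg1 - spec$cgg1_to_pgg2,
    noncgg1_up = spec$upgraded - spec$upgraded_from_cgg1,
    ct1c_up = spec$upstaged_from_ct1c,
    other_up = spec$upstaged - spec$upstaged_from_ct1c,
    preop_low = spec$risk_increase_from_preop_low
  )
  take <- function(what, n, identity) {
    if (budget[[what]] < n) fixture_fail(identity)
    budget[[what]] <<- budget[[what]] - n
    n
  }

  blocks <- list()
  block <- function(n, cgg, pgg, ct, pt) {
    if (n > 0)
      blocks[[length(blocks) + 1L]] <<- data.frame(
        cgg = rep(cgg, n), pgg = rep(pgg, n), ct = rep(ct, n),
        pt = rep(pt, n), stringsAsFactors = FALSE)
  }

  # both upgraded and upstaged, risk increased: preoperatively low risk
  n_a1 <- spec$risk_increase_both
  take("cgg1_pgg2", n_a1, "risk_increase_both <= cgg1_to_pgg2")
  take("ct1c_up", n_a1, "risk_increase_both <= upstaged_from_ct1c")
  take("preop_low", n_a1, "risk_increase_both <= risk_increase_from_preop_low")
  block(n_a1, 1L, 2L, "T1c", "T3a")

  # both, but already high risk preoperatively (no risk increase):
  # non-cGG1 upgrades with clinically high-risk organ-confined stage
  n_a2 <- overlap - spec$risk_increase_both
  take("noncgg1_up", n_a2,
       "both-without-risk-increase requires enough non-cGG1 upgrades")
  take("other_up", n_a2,
       "both-without-risk-increase requires enough non-cT1c upstages")
  block(n_a2, 4L, 5L, "T2c", "T3a")

  # upgraded only, risk increased: low -> intermediate
  n_b1 <- spec$risk_increase_grade_only
  take("cgg1_pgg2", n_b1, "risk_increase_grade_only <= remaining cGG1->pGG2")
  take("preop_low", n_b1,
       "grade-only risk increases fit the preop-low budget")
  block(n_b1, 1L, 2L, "T1c", "T2a")

  # upstaged only, risk increased: remaining preop-low cases first
  n_c1_low <- budget$preop_low
  n_c1 <- spec$risk_increase_stage_only
  if (n_c1_low > n_c1)
    fixture_fail("preop-low budget exceeds available stage-only risk increases")
  take("ct1c_up", n_c1_low, "preop-low stage-only increases need cT1c origins")
  take("preop_low", n_c1_low, "preop-low budget")
  block(n_c1_low, 1L, 1L, "T1c", "T3a")
  n_c1_mid <- n_c1 - n_c1_low
  n_c1_t1c <- min(budget$ct1c_up, n_c1_mid)
  take("ct1c_up", n_c1_t1c, "cT1c upstage budget")
  block(n_c1_t1c, 2L, 2L, "T1c", "T3a")
  n_c1_t2a <- n_c1_mid - n_c1_t1c
  take("other_up", n_c1_t2a, "stage-only risk increases fit the upstage budget")
  block(n_c1_t2a, 2L, 2L, "T2a", "T3a")

  # upgraded only, no risk change: intermediate preop via cT2b
  n_b2 <- spec$upgraded - overlap - spec$risk_increase_grade_only
  if (n_b2 < 0)
    fixture_fail("upgraded >= overlap + risk_increase_grade_only")
  if (budget$cgg1_pgg2 + budget$cgg1_other + budget$noncgg1_up != n_b2)
    fixture_fail("remaining upgrade budgets must equal upgraded-only-without-risk-increase count")
  n_b2a <- budget$cgg1_pgg2
  take("cgg1_pgg2", n_b2a, "cGG1->pGG2 budget")
  block(n_b2a, 1L, 2L, "T2b", "T2b")
  n_b2b <- budget$cgg1_other
  take("cgg1_other", n_b2b, "cGG1->pGG3 budget")
  block(n_b2b, 1L, 3L, "T2b", "T2b")
  n_b2c <- budget$noncgg1_up
  take("noncgg1_up", n_b2c, "non-cGG1 upgrade budget")
  block(n_b2c, 2L, 3L, "T2a", "T2a")

  # upstaged only, no risk change: already high risk preoperatively
  n_c2 <- spec$upstaged - overlap - spec$risk_increase_stage_only
  if (n_c2 < 0)
    fixture_fail("upstaged >= overlap + risk_increase_stage_only")
  n_c2_t1c <- budget$ct1c_up      # leftover cT1c origins, if any
  take("ct1c_up", n_c2_t1c, "cT1c upstage budget")
  block(n_c2_t1c, 4L, 4L, "T1c", "T3a")
  take("other_up", n_c2 - n_c2_t1c,
       "upstage budgets must cover the upstaged-only-without-risk-increase count")
  block(n_c2 - n_c2_t1c, 4L, 4L, "T2c", "T3a")

  # unconstrained gradable patients: neutral, no migration
  n_d <- spec$gradable - spec$misclassified
  block(n_d, 2L, 2L, "T2a", "T2a")
  # patients without an evaluable pathological grade
  n_u <- spec$total - spec$gradable
  block(n_u, 2L, NA_integer_, "T2a", "T2a")

  leftovers <- vapply(budget, identity, 0L)
  if (any(leftovers != 0))
    fixture_fail(paste0("unconsumed count budget: ",
                        paste(names(leftovers)[leftovers != 0], collapse = ", ")))

  cohort <- do.call(rbind, blocks)
  if (nrow(cohort) != spec$total)
    fixture_fail("block sizes must sum to the cohort total")
  cohort <- data.frame(patient_id = sprintf("P%04d", seq_len(nrow(cohort))),
                       age = 65, psa = 7.0, cohort,
                       stringsAsFactors = FALSE)

  # urine routes and three-gene panel calls, matched to the printed
  # per-route panel positivity; patients without urine carry NA
  n <- spec$total
  cohort$route <- c(rep("voided", spec$voided_n), rep("catheterized", spec$cath_n),
                    rep(NA_character_, n - spec$voided_n - spec$cath_n))
  panel_pos <- c(rep(c(TRUE, FALSE), c(spec$voided_panel_pos,
                                       spec$voided_n - spec$voided_panel_pos)),
                 rep(c(TRUE, FALSE), c(spec$cath_panel_pos,
                                       spec$cath_n - spec$cath_panel_pos)),
                 rep(NA, n - spec$voided_n - spec$cath_n))
  cohort$RARB_level <- ifelse(is.na(panel_pos), NA_real_, 0)
  cohort$RASSF1_level <- ifelse(is.na(panel_pos), NA_real_,
                                ifelse(panel_pos, 5, 0))
  cohort$GSTP1_level <- ifelse(is.na(panel_pos), NA_real_, 0)
  cohort$partin_prob <- NA_real_
  rownames(cohort) <- NULL
  cohort
}
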