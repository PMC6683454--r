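#' Ordered tumour-stage scale
#'
#' The TNM substage scale used throughout:
#' T1a < T1b < T1c < T2a < T2b < T2c < T3a < T3b < T4. Substage letters are
#' required (a bare "T2" is rejected) because the risk-group rules reference
#' substages.
#'
#' @return Character vector of stage labels in increasing order.
#' @export
stage_levels <- function() {
  c("T1a", "T1b", "T1c", "T2a", "T2b", "T2c", "T3a", "T3b", "T4")
}

stage_index <- function(stage) {
  idx <- match(stage, stage_levels())
  bad <- !is.na(stage) & is.na(idx)
  if (any(bad))
    stop("unknown tumour stage label(s): ",
         paste(unique(stage[bad]), collapse = ", "),
         " (substage letters are required)", call. = FALSE)
  idx
}

#' ISUP grade group from Gleason patterns
#'
#' Maps a Gleason primary + secondary pattern pair to the ISUP 2014 grade
#' group: GG1 for Gleason sum <= 6, GG2 for 3+4, GG3 for 4+3, GG4 for sum 8,
#' GG5 for sum 9-10.
#'
#' @param primary,secondary Gleason patterns, integers 1-5 (vectorised; NA
#'   propagates).
#' @return Integer grade group 1-5.
#' @examples
#' gleason_to_gg(3, 4)  # 2
#' gleason_to_gg(4, 3)  # 3
#' @export
gleason_to_gg <- function(primary, secondary) {
  ok <- function(x) is.na(x) | (x %in% 1:5)
  if (!all(ok(primary)) || !all(ok(secondary)))
    stop("Gleason patterns must be integers in 1..5", call. = FALSE)
  s <- primary + secondary
  gg <- ifelse(s <= 6, 1L,
        ifelse(primary == 3 & secondary == 4, 2L,
        ifelse(primary == 4 & secondary == 3, 3L,
        ifelse(s == 8, 4L, 5L))))
  as.integer(gg)
}

#' Grade migration between biopsy and prostatectomy
#'
#' Upgrading is any increase of ISUP grade group between biopsy (cGG) and
#' radical-prostatectomy pathology (pGG), i.e. pGG > cGG; downgrading is the
#' symmetric decrease.
#'
#' @param cgg,pgg Clinical and pathological grade groups (1-5; NA pGG yields
#'   NA: the patient is not gradable).
#' @return Character vector: `"upgraded"`, `"downgraded"` or `"unchanged"`.
#' @export
classify_upgrade <- function(cgg, pgg) {
  check_gg(cgg); check_gg(pgg)
  ifelse(is.na(cgg) | is.na(pgg), NA_character_,
         ifelse(pgg > cgg, "upgraded",
                ifelse(pgg < cgg, "downgraded", "unchanged")))
}

check_gg <- function(gg) {
  if (!all(is.na(gg) | gg %in% 1:5))
    stop("grade groups must be integers in 1..5", call. = FALSE)
}

#' Stage migration between biopsy and prostatectomy
#'
#' Upstaging is pathologically advanced disease (pT >= T3a) that was
#' clinically unsuspected (cT < T3a); downstaging is the reverse.
#'
#' @param ct,pt_stage Clinical and pathological stage labels from
#'   [stage_levels()].
#' @return Character vector: `"upstaged"`, `"downstaged"` or `"unchanged"`.
#' @export
classify_upstage <- function(ct, pt_stage) {
  ci <- stage_index(ct)
  pi <- stage_index(pt_stage)
  t3 <- match("T3a", stage_levels())
  ifelse(is.na(ci) | is.na(pi), NA_character_,
         ifelse(pi >= t3 & ci < t3, "upstaged",
                ifelse(ci >= t3 & pi < t3, "downstaged", "unchanged")))
}

risk_levels <- c("low", "intermediate", "high")

#' Pre-operative risk group
#'
#' D'Amico-style grouping from biopsy grade group and clinical stage:
#' high if cGG 4-5 or >= cT2c; otherwise intermediate if cGG 2-3 or cT2b;
#' otherwise low (cGG 1 and <= cT2a). Overlapping "and/or" clauses are
#' resolved highest-wins.
#'
#' @param cgg Clinical grade group 1-5.
#' @param ct Clinical stage label.
#' @return Ordered factor with levels low < intermediate < high.
#' @export
preop_risk <- function(cgg, ct) {
  check_gg(cgg)
  ci <- stage_index(ct)
  t2c <- match("T2c", stage_levels())
  t2b <- match("T2b", stage_levels())
  risk <- ifelse(is.na(cgg) | is.na(ci), NA_character_,
          ifelse(cgg >= 4 | ci >= t2c, "high",
          ifelse(cgg >= 2 | ci == t2b, "intermediate", "low")))
  factor(risk, levels = risk_levels, ordered = TRUE)
}

#' Post-operative risk group
#'
#' High if pGG 4-5 or >= pT3a; otherwise intermediate if pGG 2-3; otherwise
#' low (pGG 1 and <= pT2c). A patient with unknown pGG is still high-risk
#' when pT >= T3a; otherwise the risk is unknown.
#'
#' @param pgg Pathological grade group 1-5 (NA allowed).
#' @param pt_stage Pathological stage label.
#' @return Ordered factor with levels low < intermediate < high.
#' @export
postop_risk <- function(pgg, pt_stage) {
  check_gg(pgg)
  pi <- stage_index(pt_stage)
  t3 <- match("T3a", stage_levels())
  risk <- ifelse(is.na(pi), NA_character_,
          ifelse(pi >= t3, "high",
          ifelse(is.na(pgg), NA_character_,
          ifelse(pgg >= 4, "high",
          ifelse(pgg >= 2, "intermediate", "low")))))
  factor(risk, levels = risk_levels, ordered = TRUE)
}

#' Classify one patient's grade/stage migration and risk change
#'
#' Scalar convenience wrapper around the classification rules; see
#' [classify_cohort()] for the vectorised cohort interface.
#'
#' @param cgg,pgg Clinical and pathological grade groups (pGG may be NA).
#' @param ct,pt_stage Clinical and pathological stage labels.
#' @return A list with `cgg`, `pgg`, migration flags (`upgraded`,
#'   `downgraded`, `upstaged`, `downstaged`, `misclassified`), the risk
#'   groups and `risk_increased`.
#' @export
classify_patient <- function(cgg, pgg, ct, pt_stage) {
  df <- classify_cohort(data.frame(
    patient_id = "p", cgg = cgg, pgg = pgg, ct = ct, pt = pt_stage,
    stringsAsFactors = FALSE))
  as.list(df[1, c("cgg", "pgg", "upgraded", "downgraded", "upstaged",
                  "downstaged", "misclassified", "preop_risk", "postop_risk",
                  "risk_increased")])
}

#' Classify a cohort of patients
#'
#' Applies the grade-migration, stage-migration and risk-group rules to every
#' patient. Grade groups are taken from `cgg`/`pgg` columns when present,
#' otherwise derived from Gleason pattern columns `c_gleason_primary`,
#' `c_gleason_secondary`, `p_gleason_primary`, `p_gleason_secondary`.
#' Misclassification is upgrading and/or upstaging; a patient without pGG is
#' not gradable and is excluded from grade-based denominators but keeps their
#' staging classification.
#'
#' @param cohort Data frame with at least grade and stage columns (`ct`,
#'   `pt`); other columns are carried through.
#' @return The input with classification columns appended: `cgg`, `pgg`,
#'   `upgraded`, `downgraded`, `upstaged`, `downstaged`, `misclassified`,
#'   `preop_risk`, `postop_risk`, `risk_increased`.
#' @export
classify_cohort <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop("'cohort' must be a non-empty data frame", call. = FALSE)
  if (is.null(cohort$cgg)) {
    if (is.null(cohort$c_gleason_primary))
      stop("cohort needs either 'cgg' or Gleason pattern columns", call. = FALSE)
    cohort$cgg <- gleason_to_gg(cohort$c_gleason_primary, cohort$c_gleason_secondary)
  }
  if (is.null(cohort$pgg)) {
    if (!is.null(cohort$p_gleason_primary))
      cohort$pgg <- gleason_to_gg(cohort$p_gleason_primary, cohort$p_gleason_secondary)
    else cohort$pgg <- NA_integer_
  }
  if (is.null(cohort$ct) || is.null(cohort$pt))
    stop("cohort needs stage columns 'ct' and 'pt'", call. = FALSE)

  grade <- classify_upgrade(cohort$cgg, cohort$pgg)
  stage <- classify_upstage(cohort$ct, cohort$pt)
  cohort$upgraded <- grade == "upgraded"
  cohort$downgraded <- grade == "downgraded"
  cohort$upstaged <- stage == "upstaged"
  cohort$downstaged <- stage == "downstaged"
  cohort$misclassified <- ifelse(is.na(cohort$upgraded), NA,
                                 cohort$upgraded | (cohort$upstaged %in% TRUE))
  cohort$preop_risk <- preop_risk(cohort$cgg, cohort$ct)
  cohort$postop_risk <- postop_risk(cohort$pgg, cohort$pt)
  cohort$risk_increased <- as.logical(cohort$postop_risk > cohort$preop_risk)
  cohort
}

pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_

#' Cohort-level migration and risk-change rates
#'
#' Summarises a classified cohort: upgrading / downgrading (denominator:
#' patients with both grade groups), upstaging / downstaging (denominator:
#' all patients with both stages), total misclassification (gradable
#' patients), risk increase (patients with both risk groups known), the
#' decomposition of risk increase into grade-only / both / stage-only causes,
#' and the share of risk-increased patients who were pre-operatively low
#' risk.
#'
#' @param classified A cohort classified by [classify_cohort()].
#' @return An object of class `rate_summary`: a list of counts,
#'   denominators and percentages.
#' @export
summarize_rates <- function(classified) {
  if (!is.data.frame(classified) || nrow(classified) == 0L)
    stop("'classified' must be a non-empty data frame", call. = FALSE)
  if (is.null(classified$upgraded))
    stop("run classify_cohort() first", call. = FALSE)

  n_total <- sum(!is.na(classified$upstaged))
  gradable <- !is.na(classified$upgraded)
  n_gradable <- sum(gradable)
  up <- sum(classified$upgraded, na.rm = TRUE)
  down <- sum(classified$downgraded, na.rm = TRUE)
  ust <- sum(classified$upstaged, na.rm = TRUE)
  dst <- sum(classified$downstaged, na.rm = TRUE)
  mis <- sum(classified$misclassified, na.rm = TRUE)

  risk_known <- !is.na(classified$risk_increased)
  n_risk <- sum(risk_known)
  rinc <- classified$risk_increased %in% TRUE
  n_rinc <- sum(rinc)
  grade_only <- sum(rinc & classified$upgraded %in% TRUE & !(classified$upstaged %in% TRUE))
  both <- sum(rinc & classified$upgraded %in% TRUE & classified$upstaged %in% TRUE)
  stage_only <- sum(rinc & !(classified$upgraded %in% TRUE) & classified$upstaged %in% TRUE)
  from_low <- sum(rinc & classified$preop_risk == "low", na.rm = TRUE)

  structure(list(
    n_total = n_total, n_gradable = n_gradable, n_risk_evaluable = n_risk,
    upgraded = up, upgraded_pct = pct(up, n_gradable),
    downgraded = down, downgraded_pct = pct(down, n_gradable),
    upstaged = ust, upstaged_pct = pct(ust, n_total),
    downstaged = dst, downstaged_pct = pct(dst, n_total),
    misclassified = mis, misclassified_pct = pct(mis, n_gradable),
    risk_increased = n_rinc, risk_increased_pct = pct(n_rinc, n_risk),
    risk_increase_grade_only = grade_only,
    risk_increase_grade_only_pct = pct(grade_only, n_rinc),
    risk_increase_both = both,
    risk_increase_both_pct = pct(both, n_rinc),
    risk_increase_stage_only = stage_only,
    risk_increase_stage_only_pct = pct(stage_only, n_rinc),
    risk_increase_from_low = from_low,
    risk_increase_from_low_pct = pct(from_low, n_rinc)
  ), class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  f <- function(lab, n, d, p) cat(sprintf("  %-22s %4d / %4d  (%.1f%%)\n", lab, n, d, p))
  cat("Cohort migration rates\n")
  f("upgrading", x$upgraded, x$n_gradable, x$upgraded_pct)
  f("downgrading", x$downgraded, x$n_gradable, x$downgraded_pct)
  f("upstaging", x$upstaged, x$n_total, x$upstaged_pct)
  f("downstaging", x$downstaged, x$n_total, x$downstaged_pct)
  f("misclassification", x$misclassified, x$n_gradable, x$misclassified_pct)
  f("risk increase", x$risk_increased, x$n_risk_evaluable, x$risk_increased_pct)
  cat(sprintf("  risk increase causes:  grade only %.1f%%, both %.1f%%, stage only %.1f%%\n",
              x$risk_increase_grade_only_pct, x$risk_increase_both_pct,
              x$risk_increase_stage_only_pct))
  cat(sprintf("  preop low among risk-increased: %.1f%%\n", x$risk_increase_from_low_pct))
  invisible(x)
}

#' Clinical-by-pathological transition matrix
#'
#' Cross-tabulates clinical (rows) against pathological (columns) grade
#' groups or tumour stages. Patients with a missing value on either axis are
#' omitted.
#'
#' @param classified A cohort classified by [classify_cohort()].
#' @param axis `"grade"` (GG 1-5) or `"stage"` (the full substage scale).
#' @return A `table` (class `transition_matrix`) with clinical rows and
#'   pathological columns.
#' @export
transition_matrix <- function(classified, axis = c("grade", "stage")) {
  axis <- match.arg(axis)
  if (axis == "grade") {
    cl <- factor(classified$cgg, levels = 1:5)
    pa <- factor(classified$pgg, levels = 1:5)
    dn <- list(cGG = 1:5, pGG = 1:5)
  } else {
    cl <- factor(classified$ct, levels = stage_levels())
    pa <- factor(classified$pt, levels = stage_levels())
    dn <- list(cT = stage_levels(), pT = stage_levels())
  }
  tab <- table(cl, pa, dnn = names(dn))
  class(tab) <- c("transition_matrix", class(tab))
  tab
}
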