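default_gene_params <- function() {
  # zero-inflated log10-normal levels (% of MC), differing by collection
  # route; means span roughly 0.5-15% as seen in urinary qMSP panels
  list(
    RARB = list(detection = c(voided = 0.55, catheterized = 0.58),
                log_mean = c(voided = 0.0, catheterized = 0.1),
                log_sd = c(voided = 0.8, catheterized = 0.8),
                effect_shift = 0.05),
    RASSF1 = list(detection = c(voided = 0.50, catheterized = 0.60),
                  log_mean = c(voided = 0.7, catheterized = 0.3),
                  log_sd = c(voided = 0.8, catheterized = 0.8),
                  effect_shift = 0.15),
    GSTP1 = list(detection = c(voided = 0.22, catheterized = 0.38),
                 log_mean = c(voided = -0.3, catheterized = -0.6),
                 log_sd = c(voided = 0.9, catheterized = 0.9),
                 effect_shift = 0.15)
  )
}

default_grade_transition <- function() {
  m <- rbind(
    c(0.65, 0.27, 0.05, 0.02, 0.01),
    c(0.10, 0.60, 0.22, 0.06, 0.02),
    c(0.02, 0.15, 0.58, 0.18, 0.07),
    c(0.01, 0.05, 0.15, 0.59, 0.20),
    c(0.00, 0.02, 0.08, 0.20, 0.70))
  dimnames(m) <- list(cGG = 1:5, pGG = 1:5)
  m
}

default_stage_transition <- function() {
  s <- stage_levels()
  m <- matrix(0, 9, 9, dimnames = list(cT = s, pT = s))
  organ_confined <- c("T1a", "T1b", "T1c", "T2a", "T2b", "T2c")
  for (ct in organ_confined) {
    # ~20% emerge as pT3 disease; organ-confined mass spread over pT2
    m[ct, c("T2a", "T2b", "T2c")] <- c(0.30, 0.25, 0.25)
    m[ct, c("T3a", "T3b")] <- c(0.15, 0.05)
  }
  m["T3a", c("T2c", "T3a", "T3b")] <- c(0.10, 0.70, 0.20)
  m["T3b", c("T3a", "T3b", "T4")] <- c(0.10, 0.80, 0.10)
  m["T4", c("T3b", "T4")] <- c(0.20, 0.80)
  m
}

#' Parameters of the synthetic cohort generator
#'
#' Bundles and validates everything [generate_cohort()] needs: cohort size
#' and urine-route mix, per-gene zero-inflated log10-normal level
#' distributions by route with an additive log10 shift in the adverse-outcome
#' group, log-normal PSA, a synthetic Partin probability model, and
#' row-stochastic clinical-to-pathological grade and stage transition
#' matrices. Defaults emulate the study conditions: 514 urine samples with a
#' 188/326 voided/catheterized split, panel positivity near 80-84%, mean
#' levels in the 0.6-15% range, weakly informative single markers, an
#' upgrade rate near 0.27 and an upstage rate near 0.20.
#'
#' @param n_patients Number of patients to simulate.
#' @param voided_prob Probability a patient contributes voided (vs
#'   catheterized) urine.
#' @param genes Per-gene list: `detection` (probability the level is
#'   non-zero, by route), `log_mean`, `log_sd` (log10 %-of-MC scale, by
#'   route) and `effect_shift` (additive log10 shift in the adverse group).
#' @param psa_log_mean,psa_log_sd PSA distribution on the log10 ng/mL scale.
#' @param psa_effect_shift Additive log10 PSA shift in the adverse group.
#' @param cgg_prior Categorical prior over clinical grade groups 1-5.
#' @param grade_transition 5x5 row-stochastic cGG-to-pGG matrix.
#' @param ct_prior Prior over the 9 clinical stage labels.
#' @param stage_transition 9x9 row-stochastic cT-to-pT matrix.
#' @param adverse Which classification flag defines the adverse group that
#'   receives the level/PSA shifts: `"misclassified"`, `"upgraded"`,
#'   `"upstaged"` or `"risk_increased"`.
#' @param partin_effect,partin_sd Synthetic Partin model: logit-scale shift
#'   for truly upstaged patients and noise SD.
#' @param seed Default seed used by [generate_cohort()].
#' @return Object of class `synthetic_params`.
#' @export
synthetic_params <- function(n_patients = 514,
                             voided_prob = 188 / 514,
                             genes = default_gene_params(),
                             psa_log_mean = log10(7), psa_log_sd = 0.25,
                             psa_effect_shift = 0.08,
                             cgg_prior = c(0.45, 0.30, 0.12, 0.08, 0.05),
                             grade_transition = default_grade_transition(),
                             ct_prior = c(0.01, 0.01, 0.50, 0.20, 0.12,
                                          0.10, 0.04, 0.02, 0.00),
                             stage_transition = default_stage_transition(),
                             adverse = "misclassified",
                             partin_effect = 1.0, partin_sd = 0.9,
                             seed = 20190805L) {
  p <- list(n_patients = n_patients, voided_prob = voided_prob, genes = genes,
            psa_log_mean = psa_log_mean, psa_log_sd = psa_log_sd,
            psa_effect_shift = psa_effect_shift,
            cgg_prior = cgg_prior, grade_transition = grade_transition,
            ct_prior = ct_prior, stage_transition = stage_transition,
            adverse = adverse, partin_effect = partin_effect,
            partin_sd = partin_sd, seed = as.integer(seed))
  validate_params(p)
  structure(p, class = "synthetic_params")
}

validate_params <- function(p) {
  stopifnot(p$n_patients >= 1, p$voided_prob >= 0, p$voided_prob <= 1)
  check_stochastic <- function(m, n, what) {
    if (!is.matrix(m) || !all(dim(m) == n) || any(m < 0) ||
        any(abs(rowSums(m) - 1) > 1e-9))
      stop(what, " must be a ", n, "x", n,
           " row-stochastic matrix (rows summing to 1)", call. = FALSE)
  }
  check_stochastic(p$grade_transition, 5L, "'grade_transition'")
  check_stochastic(p$stage_transition, 9L, "'stage_transition'")
  if (abs(sum(p$cgg_prior) - 1) > 1e-9 || abs(sum(p$ct_prior) - 1) > 1e-9)
    stop("grade/stage priors must sum to 1", call. = FALSE)
  for (g in names(p$genes)) {
    gp <- p$genes[[g]]
    if (any(gp$detection < 0 | gp$detection > 1))
      stop("detection probabilities must lie in [0, 1] (gene ", g, ")",
           call. = FALSE)
    if (any(gp$log_sd <= 0))
      stop("log_sd must be positive (gene ", g, ")", call. = FALSE)
  }
  if (!p$adverse %in% c("misclassified", "upgraded", "upstaged", "risk_increased"))
    stop("unknown adverse-outcome flag '", p$adverse, "'", call. = FALSE)
  invisible(p)
}

#' Generate a synthetic patient cohort
#'
#' Simulates a cohort with the statistical structure the analysis assumes:
#' clinical grade group and stage from categorical priors, pathological
#' counterparts from row-stochastic transition matrices, zero-inflated
#' log10-normal per-gene methylation levels that differ by urine-collection
#' route and are shifted upward in the adverse-outcome group, log-normal
#' PSA, and a noisy synthetic Partin probability. Output is reproducible
#' given the seed.
#'
#' @param params A [synthetic_params()] object.
#' @param seed Integer seed (defaults to `params$seed`). The function calls
#'   `set.seed()` internally.
#' @return Classified cohort data frame (see [classify_cohort()]) with
#'   columns `patient_id`, `age`, `psa`, `cgg`, `pgg`, `ct`, `pt`, `route`,
#'   `partin_prob` and `<GENE>_level` per gene.
#' @export
generate_cohort <- function(params = synthetic_params(), seed = params$seed) {
  validate_params(params)
  set.seed(seed)
  n <- params$n_patients
  s <- stage_levels()

  route <- ifelse(stats::runif(n) < params$voided_prob, "voided", "catheterized")
  cgg <- sample.int(5L, n, replace = TRUE, prob = params$cgg_prior)
  pgg <- vapply(cgg, function(g)
    sample.int(5L, 1L, prob = params$grade_transition[g, ]), 0L)
  ct <- sample(s, n, replace = TRUE, prob = params$ct_prior)
  pt <- vapply(ct, function(x)
    sample(s, 1L, prob = params$stage_transition[x, ]), "")

  cohort <- data.frame(
    patient_id = sprintf("S%04d", seq_len(n)),
    age = round(stats::rnorm(n, 64, 6), 1),
    cgg = cgg, pgg = pgg, ct = ct, pt = pt, route = route,
    stringsAsFactors = FALSE)
  cohort <- classify_cohort(cohort)
  adverse <- cohort[[params$adverse]] %in% TRUE

  cohort$psa <- round(10^stats::rnorm(n, params$psa_log_mean +
                                        params$psa_effect_shift * adverse,
                                      params$psa_log_sd), 2)
  for (g in names(params$genes)) {
    gp <- params$genes[[g]]
    detected <- stats::runif(n) < gp$detection[route]
    level <- ifelse(detected,
                    10^stats::rnorm(n, gp$log_mean[route] +
                                      gp$effect_shift * adverse,
                                    gp$log_sd[route]),
                    0)
    cohort[[paste0(g, "_level")]] <- level
  }
  cohort$partin_prob <- stats::plogis(
    stats::qlogis(0.2) + params$partin_effect * (cohort$upstaged %in% TRUE) +
      stats::rnorm(n, 0, params$partin_sd))
  cohort
}

#' Recover generator parameters from a cohort
#'
#' Empirical estimates of the quantities [generate_cohort()] draws from:
#' per-gene, per-route detection probability (fraction of non-zero levels)
#' and log10-level moments over detected samples, and the empirical grade
#' and stage transition matrices. Estimates converge to the generating
#' values as the cohort grows.
#'
#' @param cohort A cohort data frame with `route`, grade/stage columns and
#'   `<GENE>_level` columns.
#' @param genes Gene symbols to summarise.
#' @return List with `detection`, `log_mean`, `log_sd` (gene x route
#'   matrices) and `grade_transition`, `stage_transition` (row-normalised
#'   empirical matrices; rows with no observations are NA).
#' @export
recover_parameters <- function(cohort, genes = target_genes) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop("'cohort' must be a non-empty data frame", call. = FALSE)
  routes <- c("voided", "catheterized")
  det <- lm <- ls <- matrix(NA_real_, length(genes), 2,
                            dimnames = list(genes, routes))
  for (g in genes) {
    level <- cohort[[paste0(g, "_level")]]
    for (r in routes) {
      x <- level[cohort$route == r & !is.na(level)]
      if (!length(x)) next
      det[g, r] <- mean(x > 0)
      pos <- log10(x[x > 0])
      if (length(pos) > 1L) {
        lm[g, r] <- mean(pos)
        ls[g, r] <- stats::sd(pos)
      }
    }
  }
  row_norm <- function(tab) {
    m <- unclass(tab)
    sweep(m, 1, pmax(rowSums(m), 1), "/") * ifelse(rowSums(m) > 0, 1, NA)
  }
  gt <- row_norm(table(factor(cohort$cgg, 1:5), factor(cohort$pgg, 1:5)))
  st <- row_norm(table(factor(cohort$ct, stage_levels()),
                       factor(cohort$pt, stage_levels())))
  list(detection = det, log_mean = lm, log_sd = ls,
       grade_transition = gt, stage_transition = st)
}
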