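#' Merge methylation results into a clinical cohort
#'
#' Left-joins per-sample methylation results (as produced by
#' [quantify_plates()]) onto a clinical cohort table by patient/sample id.
#' Patients without a valid methylation result keep their clinical record
#' but carry `NA` levels, so they drop out of methylation-based evaluations
#' only; the number of such patients is reported.
#'
#' @param cohort Clinical cohort data frame with a `patient_id` column.
#' @param methylation Methylation table with `sample_id`, per-gene
#'   `<GENE>_level` / `<GENE>_call` columns and `sample_valid`.
#' @return The cohort with methylation columns appended and attribute
#'   `n_without_methylation`.
#' @export
merge_methylation <- function(cohort, methylation) {
  if (anyDuplicated(cohort$patient_id))
    stop("duplicate patient ids in cohort", call. = FALSE)
  if (anyDuplicated(methylation$sample_id))
    stop("duplicate sample ids in methylation table", call. = FALSE)
  meth <- methylation
  meth <- meth[meth$sample_valid %in% TRUE, , drop = FALSE]
  idx <- match(cohort$patient_id, meth$sample_id)
  for (col in setdiff(names(meth), c("sample_id", "sample_valid")))
    cohort[[col]] <- meth[[col]][idx]
  attr(cohort, "n_without_methylation") <- sum(is.na(idx))
  cohort
}

#' Read a clinical cohort CSV
#'
#' Expected columns: `patient_id`, `age`, `psa`, grade columns (`cgg`/`pgg`
#' or Gleason pattern pairs), `ct`, `pt`, optional `route`, `partin_prob`
#' and methylation level columns. Empty cells are missing values.
#'
#' @param path Path to the cohort CSV.
#' @return Cohort data frame.
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE,
                            na.strings = c("", "NA"))
  if (nrow(cohort) == 0L)
    stop("cohort file ", path, " contains no patients", call. = FALSE)
  if (is.null(cohort$patient_id))
    stop("cohort file ", path, " lacks a 'patient_id' column", call. = FALSE)
  cohort
}

#' Pipeline configuration
#'
#' @param cohort_file Path to the clinical cohort CSV ([read_cohort()]).
#' @param plate_files Optional character vector of qMSP plate CSVs; when
#'   given, methylation is quantified and merged before classification.
#' @param out_dir Output directory (created if needed).
#' @param threshold Methylation-call threshold (% of MC), > 0.
#' @param outcomes Outcomes to evaluate.
#' @param marker_sets Named list of marker-name vectors to evaluate against
#'   every outcome.
#' @param prevalence Optional named numeric vector of outcome prevalences
#'   for the PPV/NPV adjustment; default uses the rates observed in the
#'   supplied cohort.
#' @param seed Seed recorded in the report (the pipeline itself is
#'   deterministic).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_file, plate_files = NULL,
                            out_dir = "urimeth-out", threshold = 0.1,
                            outcomes = c("upgrading", "upstaging", "risk_increase"),
                            marker_sets = list(
                              PSA = "psa",
                              three_gene = target_genes,
                              three_gene_psa = c(target_genes, "psa")),
                            prevalence = NULL, seed = 1L) {
  if (threshold <= 0) stop("'threshold' must be positive", call. = FALSE)
  if (length(outcomes) == 0L) stop("'outcomes' must be non-empty", call. = FALSE)
  structure(list(cohort_file = cohort_file, plate_files = plate_files,
                 out_dir = out_dir, threshold = threshold,
                 outcomes = outcomes, marker_sets = marker_sets,
                 prevalence = prevalence, seed = as.integer(seed)),
            class = "pipeline_config")
}

write_out <- function(df, out_dir, name) {
  path <- file.path(out_dir, name)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

#' Run the full analysis pipeline
#'
#' Executes quantify (optional) -> merge -> classify -> summarize ->
#' evaluate, writing CSV outputs (classification, rates, grade/stage
#' transition matrices, biomarker performance, ROC coordinates) to the
#' configured directory and returning a run report that reconciles record
#' counts per stage. Repeated runs with the same configuration produce
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `run_report`: per-stage counts, output manifest
#'   and the configuration echo.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  stages <- list()

  cohort <- read_cohort(config$cohort_file)
  stages$cohort <- list(read = nrow(cohort), valid = nrow(cohort), excluded = 0L)

  if (!is.null(config$plate_files)) {
    plates <- lapply(config$plate_files, read_plate)
    meth <- quantify_plates(plates, threshold = config$threshold)
    stages$quantify <- list(read = nrow(meth),
                            valid = sum(meth$sample_valid),
                            excluded = sum(!meth$sample_valid))
    manifest <- c(manifest, write_out(meth, config$out_dir, "methylation.csv"))
    cohort <- merge_methylation(cohort, meth)
  }

  classified <- classify_cohort(cohort)
  gradable <- sum(!is.na(classified$upgraded))
  stages$classify <- list(read = nrow(classified), valid = gradable,
                          excluded = nrow(classified) - gradable)
  manifest <- c(manifest, write_out(classified, config$out_dir, "classification.csv"))

  rates <- summarize_rates(classified)
  rates_df <- data.frame(quantity = names(unclass(rates)),
                         value = unlist(rates, use.names = FALSE))
  manifest <- c(manifest, write_out(rates_df, config$out_dir, "rates.csv"))
  for (axis in c("grade", "stage")) {
    tm <- as.data.frame.matrix(transition_matrix(classified, axis))
    manifest <- c(manifest,
                  write_out(cbind(clinical = rownames(tm), tm), config$out_dir,
                            paste0("transitions_", axis, ".csv")))
  }

  perf <- list(); roc_coords <- list()
  for (outcome in config$outcomes) {
    prev <- config$prevalence[[outcome]]
    for (set_name in names(config$marker_sets)) {
      markers <- config$marker_sets[[set_name]]
      ev <- tryCatch(
        evaluate_biomarker(classified, markers, outcome, prevalence = prev),
        error = function(e) NULL)
      if (is.null(ev)) next
      perf[[length(perf) + 1L]] <- data.frame(
        outcome = outcome, biomarkers = set_name, n = ev$n_used,
        auc = ev$roc$auc, auc_p = ev$roc$auc_p,
        threshold = ev$threshold,
        sensitivity = 100 * ev$sensitivity, specificity = 100 * ev$specificity,
        ppv = 100 * ev$ppv, npv = 100 * ev$npv,
        prevalence = ev$prevalence,
        odds_ratio = ev$odds_ratio$odds_ratio,
        or_ci_low = ev$odds_ratio$ci_low, or_ci_high = ev$odds_ratio$ci_high)
      roc_coords[[length(roc_coords) + 1L]] <- data.frame(
        outcome = outcome, biomarkers = set_name,
        threshold = ev$roc$thresholds,
        sensitivity = ev$roc$sensitivity, specificity = ev$roc$specificity)
    }
  }
  if (length(perf)) {
    manifest <- c(manifest,
                  write_out(do.call(rbind, perf), config$out_dir, "performance.csv"),
                  write_out(do.call(rbind, roc_coords), config$out_dir,
                            "roc_coordinates.csv"))
    stages$evaluate <- list(read = length(perf), valid = length(perf), excluded = 0L)
  }

  report <- structure(list(stages = stages, manifest = manifest,
                           config = config,
                           version = as.character(utils::packageVersion("urimeth"))),
                      class = "run_report")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("urimeth pipeline run (version ", x$version, ")\n", sep = "")
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    cat(sprintf("  %-10s read %5d, valid %5d, excluded %5d\n",
                s, st$read, st$valid, st$excluded))
  }
  cat("  outputs:\n")
  for (m in x$manifest) cat("    ", m, "\n", sep = "")
  invisible(x)
}
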