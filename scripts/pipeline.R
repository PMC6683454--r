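#!/usr/bin/env Rscript
# Thin command-line wrapper over the urimeth package.
#
#   Rscript scripts/pipeline.R quantify --plates a.csv,b.csv [--threshold 0.1] --out meth.csv
#   Rscript scripts/pipeline.R classify --cohort cohort.csv --out-prefix out/run
#   Rscript scripts/pipeline.R evaluate --cohort cohort.csv --outcome upgrading \
#           --biomarkers RASSF1,GSTP1,psa [--prevalence 0.272] --out perf.csv
#   Rscript scripts/pipeline.R simulate --n 514 [--seed 20190805] --out cohort.csv
#   Rscript scripts/pipeline.R fixture --out fixture.csv
#   Rscript scripts/pipeline.R run --cohort cohort.csv [--plates ...] --out-dir out

suppressPackageStartupMessages(library(urimeth))

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) == 0L || argv[1] %in% c("-h", "--help")) {
  lines <- grep("^#", readLines(sub("--file=", "",
    grep("^--file=", commandArgs(), value = TRUE))), value = TRUE)
  writeLines(sub("^# ?", "", lines[-1]))
  quit(status = if (length(argv)) 0 else 1)
}
if (argv[1] == "--version") {
  cat("urimeth", as.character(packageVersion("urimeth")), "\n")
  quit(status = 0)
}
cmd <- argv[1]
args <- argv[-1]
opt <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}
req <- function(flag) {
  v <- opt(flag)
  if (is.null(v)) stop("missing required option ", flag, call. = FALSE)
  v
}

if (cmd == "quantify") {
  plates <- lapply(strsplit(req("--plates"), ",")[[1]], read_plate)
  res <- quantify_plates(plates, threshold = as.numeric(opt("--threshold", "0.1")))
  write.csv(res, req("--out"), row.names = FALSE, na = "")

} else if (cmd == "classify") {
  classified <- classify_cohort(read_cohort(req("--cohort")))
  prefix <- req("--out-prefix")
  write.csv(classified, paste0(prefix, "_classification.csv"),
            row.names = FALSE, na = "")
  s <- unclass(summarize_rates(classified))
  write.csv(data.frame(quantity = names(s), value = unlist(s, use.names = FALSE)),
            paste0(prefix, "_rates.csv"), row.names = FALSE)
  for (axis in c("grade", "stage")) {
    tm <- as.data.frame.matrix(transition_matrix(classified, axis))
    write.csv(cbind(clinical = rownames(tm), tm),
              paste0(prefix, "_transitions_", axis, ".csv"), row.names = FALSE)
  }

} else if (cmd == "evaluate") {
  classified <- classify_cohort(read_cohort(req("--cohort")))
  markers <- strsplit(req("--biomarkers"), ",")[[1]]
  prev <- opt("--prevalence")
  ev <- evaluate_biomarker(classified, markers, req("--outcome"),
                           prevalence = if (!is.null(prev)) as.numeric(prev))
  out <- data.frame(biomarkers = paste(markers, collapse = "+"),
                    outcome = ev$outcome, n = ev$n_used,
                    auc = ev$roc$auc, auc_p = ev$roc$auc_p,
                    threshold = ev$threshold,
                    sensitivity = 100 * ev$sensitivity,
                    specificity = 100 * ev$specificity,
                    ppv = 100 * ev$ppv, npv = 100 * ev$npv,
                    odds_ratio = ev$odds_ratio$odds_ratio,
                    or_ci_low = ev$odds_ratio$ci_low,
                    or_ci_high = ev$odds_ratio$ci_high)
  write.csv(out, req("--out"), row.names = FALSE)
  print(ev)

} else if (cmd == "simulate") {
  p <- synthetic_params(n_patients = as.integer(opt("--n", "514")))
  cohort <- generate_cohort(p, seed = as.integer(opt("--seed", p$seed)))
  write.csv(cohort, req("--out"), row.names = FALSE, na = "")

} else if (cmd == "fixture") {
  write.csv(build_printed_fixture(), req("--out"), row.names = FALSE, na = "")

} else if (cmd == "run") {
  plates <- opt("--plates")
  cfg <- pipeline_config(
    cohort_file = req("--cohort"),
    plate_files = if (!is.null(plates)) strsplit(plates, ",")[[1]],
    out_dir = opt("--out-dir", "urimeth-out"),
    threshold = as.numeric(opt("--threshold", "0.1")),
    seed = as.integer(opt("--seed", "1")))
  print(run_pipeline(cfg))

} else {
  stop("unknown subcommand '", cmd, "'; see --help", call. = FALSE)
}
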