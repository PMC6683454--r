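#' Aggregate replicate Cq values
#'
#' Collapses up to three replicate quantification-cycle (Cq) values from one
#' well group into a single Cq by taking the arithmetic mean of the replicates
#' that amplified. A replicate that did not amplify is encoded as `NA`.
#'
#' @param replicate_cqs Numeric vector of length 1 to 3; `NA` marks a
#'   replicate with no amplification. Finite values must lie in (0, 50]
#'   (50-cycle protocol).
#' @return A single Cq value, or `NA_real_` when no replicate amplified.
#' @examples
#' aggregate_replicates(c(29, 31))        # 30
#' aggregate_replicates(c(NA, NA, NA))    # NA: no amplification
#' @export
aggregate_replicates <- function(replicate_cqs) {
  if (length(replicate_cqs) == 0L)
    stop("'replicate_cqs' must contain at least one replicate", call. = FALSE)
  if (length(replicate_cqs) > 3L)
    stop("at most 3 replicates per well group", call. = FALSE)
  replicate_cqs <- as.numeric(replicate_cqs)
  ok <- is.finite(replicate_cqs)
  if (any(replicate_cqs[ok] <= 0 | replicate_cqs[ok] > 50))
    stop("Cq values must lie in (0, 50]", call. = FALSE)
  if (!any(ok)) return(NA_real_)
  mean(replicate_cqs[ok])
}

#' Run validity from control wells
#'
#' A qMSP run is valid for a given assay when the fully methylated control
#' (MC) gave a positive signal (any finite Cq among its replicates) and the
#' no-template control (NTC) did not amplify at all.
#'
#' @param mc_cqs Numeric vector of MC replicate Cq values (`NA` = no
#'   amplification).
#' @param ntc_cqs Numeric vector of NTC replicate Cq values.
#' @return `TRUE` if the run is valid for this assay.
#' @export
validate_run <- function(mc_cqs, ntc_cqs) {
  if (length(mc_cqs) == 0L || length(ntc_cqs) == 0L)
    stop("MC and NTC control records are required", call. = FALSE)
  any(is.finite(as.numeric(mc_cqs))) && !any(is.finite(as.numeric(ntc_cqs)))
}

#' Sample validity from the ACTB endogenous control
#'
#' A sample is valid when the endogenous control *ACTB* amplified with
#' Cq < 40 in all three replicates. Fewer than three replicates, a failed
#' replicate, or any Cq at or above 40 renders the sample invalid.
#'
#' @param actb_cqs Numeric vector of ACTB replicate Cq values (`NA` = no
#'   amplification).
#' @return `TRUE` if the sample passes the endogenous-control criterion.
#' @export
validate_sample <- function(actb_cqs) {
  actb_cqs <- as.numeric(actb_cqs)
  length(actb_cqs) == 3L && all(is.finite(actb_cqs)) && all(actb_cqs < 40)
}

#' Methylation level by the delta-delta-Cq method
#'
#' Computes the methylation level of a target gene as a percentage of the
#' fully methylated control (MC):
#' `100 * 2^-dddCq` with
#' `dddCq = (sample_gene_cq - sample_actb_cq) - (mc_gene_cq - mc_actb_cq)`.
#' A sample whose target/control Cq difference equals the MC's scores exactly
#' 100%. Levels above 100% are possible and are reported with a warning
#' rather than capped.
#'
#' @param sample_gene_cq,sample_actb_cq Aggregated Cq of the target gene and
#'   of ACTB in the sample.
#' @param mc_gene_cq,mc_actb_cq Aggregated Cq of the target gene and of ACTB
#'   in the MC calibrator.
#' @return Methylation level in percent of MC (vectorised).
#' @examples
#' methylation_level(30, 25, 26, 25)  # 6.25
#' methylation_level(27, 25, 26, 25)  # 50
#' @export
methylation_level <- function(sample_gene_cq, sample_actb_cq,
                              mc_gene_cq, mc_actb_cq) {
  args <- cbind(sample_gene_cq, sample_actb_cq, mc_gene_cq, mc_actb_cq)
  if (!all(is.finite(args)))
    stop("all four Cq values must be finite; use the detected = FALSE path for failed wells",
         call. = FALSE)
  ddcq <- (sample_gene_cq - sample_actb_cq) - (mc_gene_cq - mc_actb_cq)
  level <- 100 * 2^(-ddcq)
  if (any(level > 100))
    warning("methylation level above 100% of the methylated control", call. = FALSE)
  level
}

#' Dichotomise a methylation level
#'
#' Converts a quantitative level (% of MC) to a binary methylated /
#' unmethylated call. The default threshold is 0.1% and the boundary is
#' inclusive (a level exactly at the threshold is called methylated).
#'
#' @param level Numeric methylation level(s), >= 0 (NA allowed, propagated).
#' @param threshold Calling threshold in percent of MC; default 0.1.
#' @return Logical vector of methylation calls.
#' @export
dichotomize <- function(level, threshold = 0.1) {
  if (any(level < 0, na.rm = TRUE))
    stop("methylation levels must be non-negative", call. = FALSE)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("'threshold' must be a single positive number", call. = FALSE)
  level >= threshold
}

#' Panel-level methylation positivity
#'
#' The three-gene panel is positive when methylation of at least one of
#' RARB, RASSF1 or GSTP1 is called.
#'
#' @param calls Named logical vector containing one call per target gene.
#' @param genes Gene symbols required in `calls`.
#' @return `TRUE` if any gene in the panel is methylated.
#' @export
panel_positive <- function(calls, genes = target_genes) {
  if (!all(genes %in% names(calls)))
    stop("calls are required for all panel genes: ",
         paste(setdiff(genes, names(calls)), collapse = ", "), call. = FALSE)
  any(as.logical(calls[genes]))
}

#' Read a qMSP plate CSV
#'
#' Expected columns: `sample_id`, `gene`, `well_role`
#' (`sample` / `MC` / `NTC`), `rep1_cq`, `rep2_cq`, `rep3_cq`. Empty cells
#' mean no amplification.
#'
#' @param path Path to the plate CSV.
#' @return A plate data frame.
#' @export
read_plate <- function(path) {
  plate <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "gene", "well_role", "rep1_cq", "rep2_cq", "rep3_cq")
  missing <- setdiff(required, names(plate))
  if (length(missing))
    stop("plate file ", path, " lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in c("rep1_cq", "rep2_cq", "rep3_cq"))
    plate[[col]] <- suppressWarnings(as.numeric(plate[[col]]))
  plate
}

plate_replicates <- function(plate, id, gene, role) {
  rows <- plate$sample_id == id & plate$gene == gene & plate$well_role == role
  if (!any(rows)) return(NULL)
  as.numeric(unlist(plate[rows, c("rep1_cq", "rep2_cq", "rep3_cq")]))
}

control_replicates <- function(plate, gene, role) {
  rows <- plate$gene == gene & plate$well_role == role
  if (!any(rows)) return(NULL)
  as.numeric(unlist(plate[rows, c("rep1_cq", "rep2_cq", "rep3_cq")]))
}

#' Quantify methylation from one qMSP run
#'
#' Processes one plate (one run): checks run validity per assay from the MC
#' and NTC wells, checks sample validity from ACTB, and derives
#' delta-delta-Cq methylation levels and binary calls for every valid sample.
#' An assay whose run controls fail invalidates only that gene's results on
#' the plate; invalid samples keep their row with `sample_valid = FALSE` and
#' `NA` levels so that exclusions remain auditable. A target gene that did
#' not amplify in a valid sample is a true zero (`level = 0`,
#' call `FALSE`), not a missing value.
#'
#' @param plate Plate data frame as returned by [read_plate()].
#' @param threshold Methylation-call threshold in percent of MC.
#' @param genes Target gene symbols assayed on the plate.
#' @return Data frame with one row per sample: per-gene levels
#'   (`<gene>_level`), calls (`<gene>_call`), `panel_positive` and
#'   `sample_valid`.
#' @export
quantify_run <- function(plate, threshold = 0.1, genes = target_genes) {
  ids <- unique(plate$sample_id[plate$well_role == "sample"])
  if (length(ids) == 0L)
    stop("plate contains no sample wells", call. = FALSE)

  run_valid <- logical(0)
  mc_gene_cq <- numeric(0)
  mc_actb <- control_replicates(plate, "ACTB", "MC")
  if (is.null(mc_actb))
    stop("MC control wells for ACTB are missing", call. = FALSE)
  mc_actb_cq <- aggregate_replicates(mc_actb)
  for (g in genes) {
    mc <- control_replicates(plate, g, "MC")
    ntc <- control_replicates(plate, g, "NTC")
    if (is.null(mc) || is.null(ntc))
      stop("MC/NTC control wells missing for gene ", g, call. = FALSE)
    run_valid[g] <- validate_run(mc, ntc)
    mc_gene_cq[g] <- if (run_valid[g]) aggregate_replicates(mc) else NA_real_
  }
  if (any(!run_valid))
    message("run controls failed for: ", paste(genes[!run_valid], collapse = ", "),
            "; these assays are reported as NA for this plate")

  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (g in genes) {
    out[[paste0(g, "_level")]] <- NA_real_
    out[[paste0(g, "_call")]] <- NA
  }
  out$panel_positive <- NA
  out$sample_valid <- FALSE

  for (i in seq_along(ids)) {
    actb <- plate_replicates(plate, ids[i], "ACTB", "sample")
    if (is.null(actb)) actb <- NA_real_
    valid <- validate_sample(actb)
    out$sample_valid[i] <- valid
    if (!valid) next
    actb_cq <- aggregate_replicates(actb)
    for (g in genes) {
      if (!run_valid[g]) next
      reps <- plate_replicates(plate, ids[i], g, "sample")
      cq <- if (is.null(reps)) NA_real_ else aggregate_replicates(reps)
      level <- if (is.na(cq)) 0 else
        methylation_level(cq, actb_cq, mc_gene_cq[g], mc_actb_cq)
      out[[paste0(g, "_level")]][i] <- level
      out[[paste0(g, "_call")]][i] <- dichotomize(level, threshold)
    }
    calls <- vapply(genes, function(g) out[[paste0(g, "_call")]][i], NA)
    out$panel_positive[i] <- if (any(is.na(calls))) NA else panel_positive(calls, genes)
  }
  attr(out, "run_valid") <- run_valid
  out
}

#' Quantify methylation from one or more plates
#'
#' @param plates A plate data frame or a list of plate data frames (one per
#'   run); each run carries its own MC/NTC controls.
#' @inheritParams quantify_run
#' @return Row-bound per-sample methylation table; see [quantify_run()].
#' @export
quantify_plates <- function(plates, threshold = 0.1, genes = target_genes) {
  if (is.data.frame(plates)) plates <- list(plates)
  res <- lapply(plates, quantify_run, threshold = threshold, genes = genes)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (anyDuplicated(out$sample_id))
    stop("duplicate sample ids across plates: ",
         paste(unique(out$sample_id[duplicated(out$sample_id)]), collapse = ", "),
         call. = FALSE)
  out
}

#' Convert a methylation level back to a synthetic gene Cq
#'
#' Inverse of [methylation_level()]: given a level (% of MC), the sample's
#' ACTB Cq and the MC calibrator Cqs, returns the gene Cq that reproduces the
#' level. A level of zero maps to `NA` (no amplification). Used to build
#' synthetic plates for round-trip testing of the quantification path.
#'
#' @param level Methylation level in percent of MC.
#' @param sample_actb_cq,mc_gene_cq,mc_actb_cq Anchor Cq values.
#' @return Gene Cq (vectorised), `NA` where `level == 0`.
#' @export
level_to_cq <- function(level, sample_actb_cq = 30, mc_gene_cq = 26, mc_actb_cq = 25) {
  ifelse(level <= 0, NA_real_,
         sample_actb_cq + (mc_gene_cq - mc_actb_cq) - log2(level / 100))
}
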