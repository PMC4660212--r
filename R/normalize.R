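## Screen normalization: per-well viability correction, ratio to the
## non-targeting control, and per-(assay, cell line, condition) z-scores.

#' Transfection efficiency from siUBB knockdown
#'
#' `1 - Luminescence_siUBB / Luminescence_siCTRL`: the fraction of viability
#' signal lost when transfecting siRNA against the essential ubiquitin-B
#' gene, the standard per-line transfection QC for arrayed screens.
#'
#' @param lum_siUBB luminescence of siUBB wells.
#' @param lum_siCTRL luminescence of non-targeting control wells; must be > 0.
#' @return efficiency in (-Inf, 1]; vectorized.
#' @export
transfection_efficiency <- function(lum_siUBB, lum_siCTRL) {
  if (any(!is.finite(lum_siCTRL)) || any(lum_siCTRL <= 0))
    stop("control luminescence must be positive and finite", call. = FALSE)
  if (any(!is.finite(lum_siUBB)) || any(lum_siUBB < 0))
    stop("siUBB luminescence must be non-negative and finite", call. = FALSE)
  1 - lum_siUBB / lum_siCTRL
}

#' Correct assay readouts for viability defects
#'
#' Divides each well's readout by its paired viability readout (CTG taken in
#' parallel, or renilla luciferase for dual-luciferase reporter screens), so
#' cell loss does not masquerade as a signalling phenotype.
#'
#' @param values raw assay readouts.
#' @param paired_viability_values paired viability readouts, aligned per
#'   well; all must be positive. `NULL` passes `values` through unchanged
#'   (assays without a paired channel).
#' @return corrected values.
#' @export
viability_correct <- function(values, paired_viability_values = NULL) {
  if (is.null(paired_viability_values)) return(values)
  if (length(paired_viability_values) != length(values))
    stop("paired viability values must align with values", call. = FALSE)
  if (any(!is.finite(paired_viability_values)) || any(paired_viability_values <= 0))
    stop("missing or non-positive paired viability value", call. = FALSE)
  values / paired_viability_values
}

#' Normalize gene-level values to the non-targeting control
#'
#' @param gene_values numeric vector (or per-gene list) of replicate-mean
#'   values.
#' @param control_values replicate-level values of the non-targeting control
#'   wells in the same stratum; their mean defines the denominator.
#' @return ratios; the control itself maps to 1.
#' @export
normalize_to_control <- function(gene_values, control_values) {
  if (length(control_values) < 1)
    stop("at least one control well is required", call. = FALSE)
  ctrl <- mean(control_values)
  if (!is.finite(ctrl) || ctrl <= 0)
    stop("control mean must be positive", call. = FALSE)
  gene_values / ctrl
}

#' z-scores of control-normalized ratios within one stratum
#'
#' Standardizes over the gene set of one (assay, cell line, condition)
#' stratum using the sample (n - 1) standard deviation. Control reagents
#' must be excluded before calling.
#'
#' @param ratios named numeric vector, one entry per gene.
#' @return z-scores with mean 0 and sample s.d. 1 (all zero, with a warning,
#'   when the ratios are constant).
#' @export
compute_zscores <- function(ratios) {
  if (length(ratios) < 3)
    stop("need at least 3 genes per stratum to compute z-scores", call. = FALSE)
  s <- stats::sd(ratios)
  if (!is.finite(s) || s == 0) {
    warning("zero spread in stratum; all z-scores set to 0")
    return(ratios * 0)
  }
  (ratios - mean(ratios)) / s
}

#' Process a screen measurement table into a z-score table
#'
#' Per (assay, cell line, condition) stratum: each well is viability
#' corrected where a paired readout exists, replicates are collapsed by
#' arithmetic mean, gene means are divided by the non-targeting control
#' mean, and z-scores are computed across the gene set (pooled reagents
#' only; controls and single siRNAs are reported with ratios but excluded
#' from the z standardization). Vehicle and ligand conditions of reporter
#' assays are processed as separate strata.
#'
#' @param measurements a MeasurementTable data.frame (see
#'   [validate_measurements()]).
#' @param correct_after_normalize if `TRUE`, divide by the control mean
#'   before the viability correction instead of after (alternative reading
#'   of the processing order; the default corrects each well first).
#' @param log_ratios if `TRUE`, z-scores are computed on log2 ratios.
#' @return data.frame of class `zscore_table`: one row per (assay,
#'   cell_line, condition, gene, reagent) with columns mean_raw,
#'   mean_corrected, ratio, zscore, n_replicates. Strata without a
#'   non-targeting control are skipped with a warning.
#' @export
process_screen <- function(measurements, correct_after_normalize = FALSE,
                           log_ratios = FALSE) {
  measurements <- validate_measurements(measurements)
  strata <- unique(measurements[, c("assay", "cell_line", "condition")])
  out <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    s <- measurements[measurements$assay == strata$assay[i] &
                        measurements$cell_line == strata$cell_line[i] &
                        measurements$condition == strata$condition[i], ]
    is_ctrl <- s$reagent_type == "control_nt"
    if (!any(is_ctrl)) {
      warning(sprintf("stratum %s/%s/%s has no non-targeting control; skipped",
                      strata$assay[i], strata$cell_line[i], strata$condition[i]))
      next
    }
    paired <- any(is.finite(s$paired_viability_value))
    corrected <- if (paired && !correct_after_normalize)
      viability_correct(s$raw_value, s$paired_viability_value)
    else s$raw_value

    ## controls are aggregated across their wells, so the non-targeting
    ## control maps to a ratio of exactly 1
    rid <- ifelse(s$reagent_type %in% c("control_nt", "control_ubb"),
                  s$reagent_type, s$reagent_id)
    key <- paste(s$gene, s$reagent_type, rid, sep = "\r")
    mean_raw <- tapply(s$raw_value, key, mean)
    mean_corr <- tapply(corrected, key, mean)
    n_rep <- tapply(corrected, key, length)
    ratio <- normalize_to_control(mean_corr, corrected[is_ctrl])
    if (paired && correct_after_normalize) {
      viab_mean <- tapply(s$paired_viability_value, key, mean)
      viab_ratio <- normalize_to_control(viab_mean, s$paired_viability_value[is_ctrl])
      ratio <- ratio / viab_ratio
    }
    parts <- do.call(rbind, strsplit(names(mean_raw), "\r", fixed = TRUE))
    tab <- data.frame(assay = strata$assay[i], cell_line = strata$cell_line[i],
                      condition = strata$condition[i],
                      gene = parts[, 1], reagent_type = parts[, 2],
                      reagent_id = parts[, 3],
                      n_replicates = as.integer(n_rep),
                      mean_raw = as.numeric(mean_raw),
                      mean_corrected = as.numeric(mean_corr),
                      ratio = as.numeric(ratio), zscore = NA_real_)
    pool <- tab$reagent_type == "pool"
    if (sum(pool) >= 3) {
      vals <- if (log_ratios) log2(tab$ratio[pool]) else tab$ratio[pool]
      tab$zscore[pool] <- compute_zscores(vals)
    }
    out[[i]] <- tab
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no processable strata in measurement table", call. = FALSE)
  res <- res[order(res$assay, res$cell_line, res$condition,
                   res$reagent_type, res$gene, res$reagent_id), ]
  rownames(res) <- NULL
  class(res) <- c("zscore_table", "data.frame")
  res
}

#' Per-line transfection QC from screen measurements
#'
#' Computes [transfection_efficiency()] per (assay, cell line) block from
#' the mean raw values of siUBB versus non-targeting control wells.
#'
#' @param measurements a MeasurementTable containing `control_ubb` wells.
#' @return data.frame with assay, cell_line, efficiency.
#' @export
transfection_qc <- function(measurements) {
  measurements <- validate_measurements(measurements)
  m <- measurements[measurements$reagent_type %in% c("control_nt", "control_ubb") &
                      measurements$condition %in% c("na", "vehicle"), ]
  blocks <- unique(m[, c("assay", "cell_line")])
  eff <- vapply(seq_len(nrow(blocks)), function(i) {
    b <- m[m$assay == blocks$assay[i] & m$cell_line == blocks$cell_line[i], ]
    ubb <- b$raw_value[b$reagent_type == "control_ubb"]
    nt <- b$raw_value[b$reagent_type == "control_nt"]
    if (!length(ubb) || !length(nt)) return(NA_real_)
    transfection_efficiency(mean(ubb), mean(nt))
  }, numeric(1))
  data.frame(blocks, efficiency = eff, row.names = NULL)
}
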