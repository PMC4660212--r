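## Rule-based hit calling: cell-biological outliers with t-test
## significance, reporter penetrance rules, retest selection, single-siRNA
## deconvolution and per-gene Kolmogorov-Smirnov effect comparisons.

#' Hit-calling configuration
#'
#' Thresholds for every decision rule, with the screen's printed defaults:
#' z beyond 2 for cell-biological outliers, P <= 0.05 by unpaired Student's
#' t-test, reporter positives at >60\% reduction in a single line or >30\%
#' in more than two lines, retest selection at 1.5 s.d., and pool
#' validation at two or more active singles.
#'
#' @param z_threshold |z| beyond which a cell-biological pool is an outlier.
#' @param retest_sd_threshold s.d. from the CTA mean used to pick genes for
#'   single-siRNA retest (the screen used a looser cut here than for
#'   outlier calling; both are exposed rather than reconciled).
#' @param p_threshold t-test significance cut.
#' @param reporter_single_line_reduction fractional reduction that makes a
#'   reporter positive in one line (default 0.60).
#' @param reporter_multi_line_reduction reduction per line for the
#'   multi-line clause (default 0.30).
#' @param reporter_min_lines lines required by the multi-line clause;
#'   "more than two cell lines" is read literally as >= 3, configurable to
#'   2 for the "two or more" reading.
#' @param deconv_min_active active singles required to validate a pool.
#' @param deconv_activity_threshold fraction of the pool's observed effect a
#'   single must reach, in the pool's direction, to count as active.
#' @param assay_class named character vector mapping assay names to classes
#'   `apoptosis`, `viability`, `proliferation` (cell-biological) or
#'   `reporter`.
#' @return an object of class `hit_call_config`.
#' @export
hit_call_config <- function(z_threshold = 2.0,
                            retest_sd_threshold = 1.5,
                            p_threshold = 0.05,
                            reporter_single_line_reduction = 0.60,
                            reporter_multi_line_reduction = 0.30,
                            reporter_min_lines = 3,
                            deconv_min_active = 2,
                            deconv_activity_threshold = 0.5,
                            assay_class = c(viability = "viability",
                                            apoptosis = "apoptosis",
                                            proliferation = "proliferation",
                                            hif = "reporter", wnt = "reporter",
                                            tgfb = "reporter", nfkb = "reporter")) {
  stopifnot_scalar_number(z_threshold, "z_threshold", positive = TRUE)
  stopifnot_scalar_number(retest_sd_threshold, "retest_sd_threshold", positive = TRUE)
  stopifnot_probability(p_threshold, "p_threshold")
  stopifnot_probability(reporter_single_line_reduction, "reporter_single_line_reduction")
  stopifnot_probability(reporter_multi_line_reduction, "reporter_multi_line_reduction")
  if (reporter_min_lines < 1 || deconv_min_active < 1)
    stop("minimum counts must be >= 1", call. = FALSE)
  structure(list(z_threshold = z_threshold,
                 retest_sd_threshold = retest_sd_threshold,
                 p_threshold = p_threshold,
                 reporter_single_line_reduction = reporter_single_line_reduction,
                 reporter_multi_line_reduction = reporter_multi_line_reduction,
                 reporter_min_lines = as.integer(reporter_min_lines),
                 deconv_min_active = as.integer(deconv_min_active),
                 deconv_activity_threshold = deconv_activity_threshold,
                 assay_class = assay_class),
            class = "hit_call_config")
}

## Expected direction of a hit per cell-biological assay class: apoptosis
## hits elevate caspase signal (z > +t), viability/proliferation hits
## suppress theirs (z < -t).
cellbio_direction <- function(class) {
  switch(class, apoptosis = "increase",
         viability = , proliferation = "decrease",
         stop("not a cell-biological assay class: ", class, call. = FALSE))
}

## Unpaired two-sample Student's t-test (pooled variance, two-sided) of
## gene replicate values against control replicate values.
stratum_t_pvalue <- function(gene_values, control_values) {
  if (length(gene_values) < 2 || length(control_values) < 2) return(NA_real_)
  stats::t.test(gene_values, control_values, var.equal = TRUE)$p.value
}

#' Call cell-biological hits (apoptosis, viability, proliferation)
#'
#' A pool is an outlier when its z-score exceeds `+z_threshold` in the
#' apoptosis screen or falls below `-z_threshold` in the viability and
#' proliferation screens; only outliers with a statistically significant
#' change versus the non-targeting control (P <= `p_threshold`, unpaired
#' Student's t-test on viability-corrected replicate values) are called
#' hits. Strata with fewer than two replicates on either side are
#' `unresolved`, never silently hit.
#'
#' @param ztab a `zscore_table` from [process_screen()].
#' @param measurements the MeasurementTable the table was computed from
#'   (supplies replicate-level values for the t-test).
#' @param config a [hit_call_config()].
#' @return a `hit_table` data.frame: one row per (gene, assay, cell_line)
#'   with z, ratio, p_value, call in {hit, not_hit, unresolved} and the rule
#'   that fired.
#' @export
call_cellbio_hits <- function(ztab, measurements, config = hit_call_config()) {
  measurements <- validate_measurements(measurements)
  cb_assays <- names(config$assay_class)[config$assay_class %in%
                                           c("apoptosis", "viability", "proliferation")]
  z <- ztab[ztab$assay %in% cb_assays & ztab$reagent_type == "pool", ]
  if (nrow(z) == 0)
    return(empty_hit_table())
  rows <- vector("list", 0L)
  strata <- unique(z[, c("assay", "cell_line", "condition")])
  for (i in seq_len(nrow(strata))) {
    a <- strata$assay[i]; cl <- strata$cell_line[i]; cond <- strata$condition[i]
    zs <- z[z$assay == a & z$cell_line == cl & z$condition == cond, ]
    s <- measurements[measurements$assay == a & measurements$cell_line == cl &
                        measurements$condition == cond, ]
    paired <- any(is.finite(s$paired_viability_value))
    corrected <- if (paired) viability_correct(s$raw_value, s$paired_viability_value)
    else s$raw_value
    ctrl_vals <- corrected[s$reagent_type == "control_nt"]
    direction <- cellbio_direction(config$assay_class[[a]])
    outlier <- if (direction == "increase") zs$zscore > config$z_threshold
    else zs$zscore < -config$z_threshold
    p <- vapply(seq_len(nrow(zs)), function(j) {
      if (!isTRUE(outlier[j])) return(NA_real_)  # t-test only needed for outliers
      stratum_t_pvalue(corrected[s$gene == zs$gene[j] & s$reagent_type == "pool"],
                       ctrl_vals)
    }, numeric(1))
    call <- rep("not_hit", nrow(zs))
    rule <- rep("none", nrow(zs))
    unresolved <- outlier & is.na(p)
    hit <- outlier & !is.na(p) & p <= config$p_threshold
    call[unresolved] <- "unresolved"
    call[hit] <- "hit"
    rule[hit] <- sprintf("z %s %s%.1f & p<=%.2f",
                         if (direction == "increase") ">" else "<",
                         if (direction == "increase") "+" else "-",
                         config$z_threshold, config$p_threshold)
    rule[outlier & !is.na(p) & p > config$p_threshold] <- "outlier_failed_ttest"
    rows[[length(rows) + 1L]] <- data.frame(
      gene = zs$gene, assay = a, assay_class = config$assay_class[[a]],
      cell_line = cl, condition = cond, direction = direction,
      zscore = zs$zscore, ratio = zs$ratio, p_value = p,
      call = call, rule = rule)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("hit_table", "data.frame")
  out
}

empty_hit_table <- function() {
  out <- data.frame(gene = character(), assay = character(),
                    assay_class = character(), cell_line = character(),
                    condition = character(), direction = character(),
                    zscore = numeric(), ratio = numeric(), p_value = numeric(),
                    call = character(), rule = character())
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Call reporter-screen positives from percent reductions
#'
#' A pool is positive when it reduces reporter activity by more than
#' `reporter_single_line_reduction` in a single cell line, or by more than
#' `reporter_multi_line_reduction` in at least `reporter_min_lines` lines.
#' For screens scored in both basal and ligand-induced conditions, meeting
#' either condition's clause suffices; the provenance records which.
#'
#' @param reductions gene x line matrix of fractional reductions
#'   (1 - control-normalized ratio), or a named list of such matrices, one
#'   per condition (e.g. `list(vehicle = ..., ligand = ...)`).
#' @param config a [hit_call_config()].
#' @param assay label recorded in the output.
#' @return a `hit_table` with one row per gene: call, the clause and
#'   condition that fired, the maximum reduction and the number of lines
#'   past the multi-line cut. Genes measured in no line are `unresolved`.
#' @export
call_reporter_hits <- function(reductions, config = hit_call_config(),
                               assay = "reporter") {
  if (is.matrix(reductions)) reductions <- list(na = reductions)
  genes <- unique(unlist(lapply(reductions, rownames)))
  if (is.null(genes)) stop("reduction matrices must carry gene rownames", call. = FALSE)
  rows <- lapply(genes, function(g) {
    best <- list(call = "unresolved", rule = "no_measurements", condition = NA_character_,
                 max_reduction = NA_real_, n_lines_multi = NA_integer_)
    for (cond in names(reductions)) {
      m <- reductions[[cond]]
      if (!g %in% rownames(m)) next
      r <- m[g, ]
      r <- r[is.finite(r)]
      if (!length(r)) next
      max_r <- max(r)
      n_multi <- sum(r > config$reporter_multi_line_reduction)
      if (best$call == "unresolved") {
        best$call <- "not_hit"; best$rule <- "none"
        best$max_reduction <- max_r; best$n_lines_multi <- n_multi
      } else {
        best$max_reduction <- max(best$max_reduction, max_r)
        best$n_lines_multi <- max(best$n_lines_multi, n_multi)
      }
      if (max_r > config$reporter_single_line_reduction) {
        best$call <- "hit"
        best$rule <- sprintf("reduction>%.0f%%_single_line",
                             100 * config$reporter_single_line_reduction)
        best$condition <- cond
        break
      }
      if (n_multi >= config$reporter_min_lines) {
        best$call <- "hit"
        best$rule <- sprintf("reduction>%.0f%%_in_%d+_lines",
                             100 * config$reporter_multi_line_reduction,
                             config$reporter_min_lines)
        best$condition <- cond
        break
      }
    }
    data.frame(gene = g, assay = assay, assay_class = "reporter",
               cell_line = NA_character_,
               condition = best$condition, direction = "decrease",
               zscore = NA_real_, ratio = NA_real_, p_value = NA_real_,
               call = best$call, rule = best$rule,
               max_reduction = best$max_reduction,
               n_lines_multi = best$n_lines_multi)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Reporter reduction matrices from a processed z-score table
#'
#' @param ztab a `zscore_table`.
#' @param assay reporter assay name.
#' @return named list of gene x line matrices of `1 - ratio`, one per
#'   condition present for the assay.
#' @export
reporter_reductions <- function(ztab, assay) {
  z <- ztab[ztab$assay == assay & ztab$reagent_type == "pool", ]
  if (nrow(z) == 0) stop("no pooled measurements for assay ", assay, call. = FALSE)
  conds <- unique(z$condition)
  out <- lapply(conds, function(cond) {
    zc <- z[z$condition == cond, ]
    genes <- sort(unique(zc$gene)); lines <- sort(unique(zc$cell_line))
    m <- matrix(NA_real_, length(genes), length(lines),
                dimnames = list(genes, lines))
    m[cbind(zc$gene, zc$cell_line)] <- 1 - zc$ratio
    m
  })
  names(out) <- conds
  out
}

#' Select genes for single-siRNA retest
#'
#' Genes whose z-score lies beyond `retest_sd_threshold` standard deviations
#' from the CTA mean, in the phenotype direction of any apoptosis,
#' viability or proliferation stratum.
#'
#' @param ztab a `zscore_table`.
#' @param config a [hit_call_config()].
#' @return sorted character vector of gene identifiers.
#' @export
select_retest <- function(ztab, config = hit_call_config()) {
  cb <- names(config$assay_class)[config$assay_class %in%
                                    c("apoptosis", "viability", "proliferation")]
  z <- ztab[ztab$assay %in% cb & ztab$reagent_type == "pool" &
              is.finite(ztab$zscore), ]
  if (nrow(z) == 0) return(character())
  dir_up <- vapply(z$assay, function(a)
    cellbio_direction(config$assay_class[[a]]) == "increase", logical(1))
  sel <- ifelse(dir_up, z$zscore > config$retest_sd_threshold,
                z$zscore < -config$retest_sd_threshold)
  sort(unique(z$gene[sel]))
}

#' Deconvolve one pool hit against its single siRNAs
#'
#' Computes each constituent single's control-normalized effect in the cell
#' line where the pool scored, calls a single active when its effect reaches
#' `deconv_activity_threshold` times the pool's observed effect in the same
#' direction, and validates the pool (on-target activity) when at least
#' `deconv_min_active` singles are active.
#'
#' @param pool_hit one row of a `hit_table` (gene, assay, cell_line,
#'   direction, ratio).
#' @param singles MeasurementTable of single-siRNA wells (e.g. from
#'   [generate_singles_data()]).
#' @param config a [hit_call_config()].
#' @return an object of class `deconvolution_result` with per-single effects
#'   and active flags, `n_active`, `validated`, and a `partial` flag when
#'   fewer than the expected singles were measured.
#' @export
deconvolve <- function(pool_hit, singles, config = hit_call_config()) {
  stopifnot(nrow(pool_hit) == 1)
  singles <- validate_measurements(singles)
  gene <- pool_hit$gene
  s <- singles[singles$assay == pool_hit$assay &
                 singles$cell_line == pool_hit$cell_line &
                 (singles$gene == gene | singles$reagent_type == "control_nt"), ]
  if (!any(s$reagent_type == "single"))
    stop("no single-siRNA measurements for gene ", gene, call. = FALSE)
  ztab <- suppressWarnings(process_screen(s))
  sz <- ztab[ztab$reagent_type == "single", ]
  pool_effect <- if (pool_hit$direction == "decrease") 1 - pool_hit$ratio
  else pool_hit$ratio - 1
  effect <- if (pool_hit$direction == "decrease") 1 - sz$ratio else sz$ratio - 1
  names(effect) <- sz$reagent_id
  threshold <- config$deconv_activity_threshold * pool_effect
  active <- effect >= threshold
  structure(list(gene = gene, assay = pool_hit$assay,
                 cell_line = pool_hit$cell_line,
                 pool_effect = pool_effect, effect = effect, active = active,
                 threshold = threshold, n_active = sum(active),
                 validated = sum(active) >= config$deconv_min_active,
                 partial = length(effect) < 4),
            class = "deconvolution_result")
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat(sprintf("%s [%s/%s]: %d/%d singles active (threshold %.3f) -> %s%s\n",
              x$gene, x$assay, x$cell_line, x$n_active, length(x$effect),
              x$threshold, if (x$validated) "validated" else "not validated",
              if (x$partial) " (partial)" else ""))
  invisible(x)
}

#' Classify single-siRNA activity from effect sizes
#'
#' The bare deconvolution rule, for effects computed elsewhere: active iff
#' effect >= threshold; validated iff at least `deconv_min_active` are.
#'
#' @param effects per-single effects in the pool's direction.
#' @param threshold absolute activity threshold.
#' @param config a [hit_call_config()].
#' @return list with `active`, `n_active`, `validated`.
#' @export
classify_singles <- function(effects, threshold, config = hit_call_config()) {
  active <- effects >= threshold
  list(active = active, n_active = sum(active),
       validated = sum(active) >= config$deconv_min_active)
}

#' Two-sample Kolmogorov-Smirnov comparison of one gene's effects
#'
#' Compares the distribution of one gene's effects (e.g. viability ratios
#' across cell lines) against the pooled effects of all other genes:
#' D = sup |F1 - F2|. By default the p-value follows the standard
#' two-sample policy: the exact null distribution for small tie-free
#' samples (where it coincides with the full permutation distribution) and
#' the asymptotic Kolmogorov distribution otherwise.
#'
#' @param gene_effects numeric vector, length >= 3.
#' @param other_effects numeric vector, length >= 3.
#' @param alternative "two.sided" (default), "less" or "greater", as in
#'   [stats::ks.test()].
#' @param exact `NULL` (default policy), `TRUE` or `FALSE` (force the
#'   asymptotic p-value).
#' @return list with `D`, `p_value`, `n1`, `n2`.
#' @export
ks_compare_gene <- function(gene_effects, other_effects,
                            alternative = "two.sided", exact = NULL) {
  if (length(gene_effects) < 3 || length(other_effects) < 3)
    stop("need at least 3 values per sample", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(gene_effects, other_effects,
                                        alternative = alternative,
                                        exact = exact))
  list(D = unname(kt$statistic), p_value = kt$p.value,
       n1 = length(gene_effects), n2 = length(other_effects))
}

#' Integrate hit tables into a gene-by-screen summary
#'
#' @param ... `hit_table` data.frames (cell-biological and/or reporter).
#' @return data.frame, one row per gene in deterministic order: `n_hits`
#'   (penetrance: number of (assay, cell line) hit calls), `max_abs_z`, and
#'   a comma-separated list of the screens in which the gene scored.
#' @export
integrate_hits <- function(...) {
  tabs <- list(...)
  tabs <- tabs[vapply(tabs, function(x) !is.null(x) && nrow(x) > 0, logical(1))]
  if (!length(tabs))
    return(data.frame(gene = character(), n_hits = integer(),
                      max_abs_z = numeric(), screens = character()))
  common <- c("gene", "assay", "cell_line", "zscore", "call")
  all_rows <- do.call(rbind, lapply(tabs, function(x) x[, common]))
  genes <- sort(unique(all_rows$gene))
  out <- do.call(rbind, lapply(genes, function(g) {
    r <- all_rows[all_rows$gene == g, ]
    hits <- r[r$call == "hit", ]
    data.frame(gene = g, n_hits = nrow(hits),
               max_abs_z = if (any(is.finite(r$zscore)))
                 max(abs(r$zscore), na.rm = TRUE) else NA_real_,
               screens = paste(sort(unique(hits$assay)), collapse = ","))
  }))
  rownames(out) <- NULL
  out
}
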