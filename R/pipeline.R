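## End-to-end pipeline: simulate -> presence -> panel -> normalize ->
## call hits -> retest/deconvolve -> integrate -> overlap, with every
## threshold and seed echoed into the output directory.

#' Assemble a pipeline run configuration
#'
#' All thresholds default to the screen's printed values (1,000 counts,
#' Ct 35, z 2, 1.5 s.d. retest, P 0.05, 60\% / 30\% reporter reductions,
#' panel of 11, two active singles).
#'
#' @param seed master seed; stage-specific seeds are derived from it.
#' @param expression an [expression_sim_config()] (its seed is overridden by
#'   `seed`).
#' @param screen a [screen_sim_config()] (ditto).
#' @param hits a [hit_call_config()].
#' @param panel_size testbed size.
#' @param panel_solver "greedy" or "exact".
#' @param count_threshold,ct_threshold presence-calling thresholds.
#' @param correct_after_normalize,log_ratios normalization switches, see
#'   [process_screen()].
#' @return a list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       expression = expression_sim_config(),
                       screen = screen_sim_config(),
                       hits = hit_call_config(),
                       panel_size = 11,
                       panel_solver = c("greedy", "exact"),
                       count_threshold = 1000,
                       ct_threshold = 35,
                       correct_after_normalize = FALSE,
                       log_ratios = FALSE) {
  panel_solver <- match.arg(panel_solver)
  expression$seed <- as.integer(stream_seed(seed, "stage/expression"))
  screen$seed <- as.integer(stream_seed(seed, "stage/screen"))
  structure(list(seed = as.integer(seed), expression = expression,
                 screen = screen, hits = hits,
                 panel_size = as.integer(panel_size),
                 panel_solver = panel_solver,
                 count_threshold = count_threshold,
                 ct_threshold = ct_threshold,
                 correct_after_normalize = correct_after_normalize,
                 log_ratios = log_ratios),
            class = "run_config")
}

## Serializable view of a config (drops classes, keeps values) for the
## echoed YAML sidecar.
config_as_list <- function(x) {
  if (is.list(x)) lapply(unclass(x), config_as_list) else x
}

#' Run the full screen-analysis pipeline
#'
#' Executes, in dependency order: expression simulation, presence calling,
#' testbed panel selection, screen simulation on the selected panel,
#' normalization and z-scoring, cell-biological and reporter hit calling,
#' retest selection with single-siRNA deconvolution, hit integration, and a
#' hypergeometric overlap test of the called cell-biological hit genes
#' against the planted truth. All stage outputs are written as plain-text
#' tables under `out_dir`, together with the effective configuration
#' (`config_echo.yml`) and a manifest of row counts and file checksums.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output.
#' @return an object of class `screen_run` holding every stage result and
#'   the manifest.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  outputs <- character()
  emit <- function(writer, x, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    path <- file.path(out_dir, name)
    writer(x, path)
    outputs[[name]] <<- path
  }

  ## 1. expression data and presence calls
  expr <- generate_expression_data(config$expression)
  emit(write_counts, expr$counts, "counts.csv")
  emit(write_tsv, expr$qpcr, "qpcr.tsv")
  presence <- call_presence(expr$counts, expr$qpcr,
                            count_threshold = config$count_threshold,
                            ct_threshold = config$ct_threshold)
  emit(write_presence, presence, "presence.csv")

  ## 2. testbed selection
  solver <- switch(config$panel_solver, greedy = select_panel_greedy,
                   exact = select_panel_exact)
  panel <- solver(presence, config$panel_size)
  emit(write_tsv, data.frame(cell_line = panel$selected,
                             order = seq_along(panel$selected)), "panel.tsv")

  ## 3. screen on the selected panel
  panel_presence <- presence_calls(presence, unresolved_as = FALSE)[, panel$selected,
                                                                   drop = FALSE]
  sim <- generate_screen_data(config$screen, panel_presence)
  emit(write_measurements, sim$measurements, "measurements.tsv")
  emit(write_tsv, sim$truth$hits, "truth_hits.tsv")
  qc <- transfection_qc(sim$measurements)
  emit(write_tsv, qc, "transfection_qc.tsv")

  ## 4. normalization and z-scores
  ztab <- process_screen(sim$measurements,
                         correct_after_normalize = config$correct_after_normalize,
                         log_ratios = config$log_ratios)
  emit(write_tsv, ztab, "zscores.tsv")

  ## 5. hit calling
  cellbio <- call_cellbio_hits(ztab, sim$measurements, config$hits)
  reporter_assays <- names(config$hits$assay_class)[config$hits$assay_class == "reporter"]
  reporter_assays <- intersect(reporter_assays, unique(ztab$assay))
  reporter <- do.call(rbind, lapply(reporter_assays, function(a)
    call_reporter_hits(reporter_reductions(ztab, a), config$hits, assay = a)))
  hit_rows <- rbind(cellbio,
                    if (!is.null(reporter)) reporter[, names(cellbio)])
  ## hits.tsv lists positives only; every call with provenance goes to
  ## calls_full.tsv
  emit(write_tsv, hit_rows[hit_rows$call == "hit", ], "hits.tsv")
  emit(write_tsv, hit_rows, "calls_full.tsv")

  ## 6. retest + deconvolution
  retest <- select_retest(ztab, config$hits)
  deconv <- NULL
  if (length(retest)) {
    retest_known <- intersect(retest, rownames(sim$truth$singles_active))
    singles <- generate_singles_data(sim$truth, config$screen, genes = retest_known)
    pool_rows <- cellbio[cellbio$call == "hit" & cellbio$gene %in% retest_known, ]
    pool_rows <- pool_rows[!duplicated(pool_rows[, c("gene", "assay")]), ]
    keep <- vapply(seq_len(nrow(pool_rows)), function(i)
      any(singles$gene == pool_rows$gene[i] & singles$assay == pool_rows$assay[i] &
            singles$cell_line == pool_rows$cell_line[i]), logical(1))
    pool_rows <- pool_rows[keep, , drop = FALSE]
    if (nrow(pool_rows)) {
      deconv <- do.call(rbind, lapply(seq_len(nrow(pool_rows)), function(i) {
        d <- deconvolve(pool_rows[i, ], singles, config$hits)
        data.frame(gene = d$gene, assay = d$assay, cell_line = d$cell_line,
                   n_active = d$n_active, validated = d$validated,
                   partial = d$partial)
      }))
      emit(write_tsv, deconv, "deconvolution.tsv")
    }
  }

  ## 7. integration and truth-overlap audit
  integration <- integrate_hits(cellbio, reporter)
  emit(write_tsv, integration, "integration_matrix.tsv")
  called_genes <- unique(hit_rows$gene[hit_rows$call == "hit"])
  truth_genes <- unique(sim$truth$hits$gene)
  overlap <- if (length(called_genes) && length(truth_genes)) {
    ov <- overlap_analysis(called_genes, truth_genes,
                           universe = rownames(panel_presence))
    data.frame(N = ov$N, K = ov$K, n = ov$n, k = ov$k,
               fraction = ov$fraction, p_value = ov$p_value)
  } else NULL
  if (!is.null(overlap)) emit(write_tsv, overlap, "overlap.tsv")

  ## 8. manifest + config echo
  if (!is.null(out_dir)) {
    yaml::write_yaml(config_as_list(config), file.path(out_dir, "config_echo.yml"))
    outputs[["config_echo.yml"]] <- file.path(out_dir, "config_echo.yml")
  }
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("ctascreen")),
    row_counts = list(measurements = nrow(sim$measurements),
                      zscores = nrow(ztab), hits = nrow(hit_rows),
                      truth_hits = nrow(sim$truth$hits),
                      deconvolution = if (is.null(deconv)) 0L else nrow(deconv),
                      integration = nrow(integration)),
    checksums = if (length(outputs))
      as.list(tools::md5sum(unlist(outputs))) else list()
  )
  if (!is.null(out_dir))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))

  structure(list(config = config, expression = expr, presence = presence,
                 panel = panel, screen = sim, zscores = ztab,
                 hits = hit_rows, cellbio_hits = cellbio,
                 reporter_hits = reporter, retest = retest,
                 deconvolution = deconv, integration = integration,
                 overlap = overlap, transfection_qc = qc,
                 manifest = manifest),
            class = "screen_run")
}

#' @export
print.screen_run <- function(x, ...) {
  cat("ctascreen pipeline run (seed", x$config$seed, ")\n")
  cat(sprintf("  panel: %d lines, coverage %d/%d genes\n",
              length(x$panel$selected), x$panel$coverage, x$panel$n_genes))
  cat(sprintf("  measurements: %d wells -> %d z-score rows\n",
              nrow(x$screen$measurements), nrow(x$zscores)))
  cat(sprintf("  hit calls: %d across (gene, assay, line) cells; %d planted gene-assay hits\n",
              sum(x$hits$call == "hit"), nrow(x$screen$truth$hits)))
  if (!is.null(x$deconvolution))
    cat(sprintf("  deconvolution: %d/%d pools validated\n",
                sum(x$deconvolution$validated), nrow(x$deconvolution)))
  if (!is.null(x$overlap))
    cat(sprintf("  called-vs-truth overlap: k=%d, P=%.3g\n",
                x$overlap$k, x$overlap$p_value))
  invisible(x)
}

#' @export
summary.screen_run <- function(object, ...) {
  truth <- object$screen$truth$hits
  cb <- object$cellbio_hits
  key <- function(g, a, l) paste(g, a, l, sep = "/")
  truth_cells <- unlist(lapply(seq_len(nrow(truth)), function(i) {
    lines <- colnames(object$screen$truth$presence)[
      object$screen$truth$presence[truth$gene[i], ] %in% TRUE]
    key(truth$gene[i], truth$assay[i], lines)
  }))
  cb_cells <- key(cb$gene, cb$assay, cb$cell_line)
  called <- cb_cells[cb$call == "hit"]
  cb_truth <- intersect(truth_cells, cb_cells)
  sens <- if (length(cb_truth)) mean(cb_truth %in% called) else NA_real_
  null_cells <- setdiff(cb_cells, truth_cells)
  fpr <- if (length(null_cells)) mean(null_cells %in% called) else NA_real_
  out <- list(sensitivity = sens, fpr = fpr,
              n_truth = length(cb_truth), n_null = length(null_cells),
              n_called = length(called))
  class(out) <- "summary.screen_run"
  out
}

#' @export
print.summary.screen_run <- function(x, ...) {
  cat(sprintf("cell-biological recovery: sensitivity %.3f (n=%d), FPR %.4f (n=%d)\n",
              x$sensitivity, x$n_truth, x$fpr, x$n_null))
  invisible(x)
}
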