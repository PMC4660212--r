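## Synthetic-data generators: NanoString-like expression counts with qPCR
## rescue structure, and multi-assay arrayed siRNA screen plates with planted
## hits and per-single activity flags.

#' Configuration for the expression-data simulator
#'
#' Emulates a NanoString-style gene-by-cell-line counting experiment over a
#' candidate cell-line panel, together with the follow-up qPCR that the
#' presence-calling rule uses to rescue ambiguous probes. Expressed cells draw
#' counts around `count_scale_present`, silent cells around
#' `count_scale_absent`, both with multiplicative log-normal noise.
#'
#' Defaults mirror a screen-sized study: 150 cancer-testis antigen probes
#' measured across 19 candidate tumour lines, with roughly half of the
#' gene-by-line cells expressed.
#'
#' @param n_genes number of gene probes.
#' @param n_lines number of candidate cell lines.
#' @param presence_prob per-cell probability that a gene is expressed in a line.
#' @param count_scale_present mean count for expressed gene/line cells.
#' @param count_scale_absent mean count for silent cells.
#' @param ct_mean_present mean qPCR Ct (cycles) where the gene is expressed.
#' @param ct_mean_absent mean Ct where it is not; values drawn above 40 are
#'   reported as undetected.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed; a fixed seed makes output bit-identical.
#' @return an object of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_genes = 150, n_lines = 19,
                                  presence_prob = 0.5,
                                  count_scale_present = 5000,
                                  count_scale_absent = 150,
                                  ct_mean_present = 28,
                                  ct_mean_absent = 38,
                                  noise_cv = 0.25,
                                  seed = 1L) {
  if (n_genes < 1 || n_lines < 1)
    stop("n_genes and n_lines must be positive", call. = FALSE)
  stopifnot_probability(presence_prob, "presence_prob")
  stopifnot_scalar_number(count_scale_present, "count_scale_present", positive = TRUE)
  stopifnot_scalar_number(count_scale_absent, "count_scale_absent", positive = TRUE)
  stopifnot_scalar_number(noise_cv, "noise_cv")
  structure(list(n_genes = as.integer(n_genes), n_lines = as.integer(n_lines),
                 presence_prob = presence_prob,
                 count_scale_present = count_scale_present,
                 count_scale_absent = count_scale_absent,
                 ct_mean_present = ct_mean_present,
                 ct_mean_absent = ct_mean_absent,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "expression_sim_config")
}

#' Describe one screen assay
#'
#' @param name assay name (e.g. "viability", "apoptosis", "hif").
#' @param direction expected direction of a hit's phenotype on the raw
#'   readout: `"decrease"` or `"increase"`.
#' @param paired_viability does each well carry a parallel viability readout
#'   (CTG, or renilla for dual-luciferase reporters) used for correction?
#' @param reporter is this a ligand-induced reporter assay measured in paired
#'   vehicle/ligand conditions?
#' @param viability_channel label for the paired channel ("ctg" or "renilla").
#' @return a list describing the assay.
#' @export
screen_assay <- function(name, direction = c("decrease", "increase"),
                         paired_viability = FALSE, reporter = FALSE,
                         viability_channel = "ctg") {
  direction <- match.arg(direction)
  list(name = name, direction = direction,
       paired_viability = isTRUE(paired_viability),
       reporter = isTRUE(reporter),
       viability_channel = viability_channel)
}

## The seven-assay screen design: three cell-biological assays (ATP
## viability, caspase-3/7 apoptosis, EdU proliferation) and four
## ligand-induced signalling reporters.
default_screen_assays <- function() {
  list(
    screen_assay("viability", "decrease"),
    screen_assay("apoptosis", "increase", paired_viability = TRUE),
    screen_assay("proliferation", "decrease"),
    screen_assay("hif",  "decrease", paired_viability = TRUE, reporter = TRUE,
                 viability_channel = "renilla"),
    screen_assay("wnt",  "decrease", paired_viability = TRUE, reporter = TRUE),
    screen_assay("tgfb", "decrease", paired_viability = TRUE, reporter = TRUE),
    screen_assay("nfkb", "decrease", paired_viability = TRUE, reporter = TRUE)
  )
}

#' Configuration for the screen simulator
#'
#' Describes an arrayed siRNA screen: one pooled reagent per gene plus
#' non-targeting (siNT) and ubiquitin-B (siUBB) control wells in every
#' (assay, cell line) block, replicated wells, multiplicative log-normal
#' noise, and hits planted at a known fractional effect wherever the gene is
#' expressed. Reporter assays get paired vehicle/ligand wells with the ligand
#' mean at `induction_fold` times the vehicle mean; planted reporter hits act
#' on the induced signal by default (`reporter_hit_on = "basal"` flips this).
#'
#' @param n_genes,n_lines gene and cell-line universe sizes.
#' @param assays list of [screen_assay()] descriptors.
#' @param n_replicates replicate wells per reagent per block (>= 2).
#' @param hit_fraction probability a gene is planted as a hit in an assay.
#' @param effect_size fractional change for true hits in decrease-direction
#'   assays (0.5 = 50\% reduction); must lie in [0, 1). Increase-direction
#'   hits use the log-symmetric factor 1 / (1 - effect_size).
#' @param noise_cv coefficient of variation of well noise.
#' @param singles_per_pool constituent single siRNAs per pool (default 4).
#' @param p_active_on_target probability a single from a true hit pool is
#'   phenotypically active.
#' @param p_active_off_target same for pools that are not true hits.
#' @param induction_fold ligand / vehicle mean ratio for reporters (>= 1).
#' @param reporter_hit_on condition on which planted reporter hits act.
#' @param baseline mean raw luminescence of a neutral well.
#' @param viability_baseline mean of the paired viability channel.
#' @param ubb_kill fractional viability loss of siUBB transfection controls.
#' @param n_control_wells non-targeting control wells per block and condition.
#' @param seed integer seed.
#' @return an object of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_genes = 150, n_lines = 11,
                              assays = default_screen_assays(),
                              n_replicates = 2,
                              hit_fraction = 0.05,
                              effect_size = 0.5,
                              noise_cv = 0.1,
                              singles_per_pool = 4,
                              p_active_on_target = 0.75,
                              p_active_off_target = 0.05,
                              induction_fold = 8,
                              reporter_hit_on = c("induced", "basal"),
                              baseline = 10000,
                              viability_baseline = 8000,
                              ubb_kill = 0.85,
                              n_control_wells = 8,
                              seed = 1L) {
  if (n_genes < 1 || n_lines < 1)
    stop("n_genes and n_lines must be positive", call. = FALSE)
  if (n_replicates < 2) stop("n_replicates must be >= 2", call. = FALSE)
  stopifnot_probability(hit_fraction, "hit_fraction")
  stopifnot_scalar_number(effect_size, "effect_size")
  if (effect_size < 0 || effect_size >= 1)
    stop("effect_size must lie in [0, 1)", call. = FALSE)
  if (induction_fold < 1) stop("induction_fold must be >= 1", call. = FALSE)
  stopifnot_probability(p_active_on_target, "p_active_on_target")
  stopifnot_probability(p_active_off_target, "p_active_off_target")
  reporter_hit_on <- match.arg(reporter_hit_on)
  names(assays) <- vapply(assays, `[[`, "", "name")
  structure(list(n_genes = as.integer(n_genes), n_lines = as.integer(n_lines),
                 assays = assays, n_replicates = as.integer(n_replicates),
                 hit_fraction = hit_fraction, effect_size = effect_size,
                 noise_cv = noise_cv,
                 singles_per_pool = as.integer(singles_per_pool),
                 p_active_on_target = p_active_on_target,
                 p_active_off_target = p_active_off_target,
                 induction_fold = induction_fold,
                 reporter_hit_on = reporter_hit_on,
                 baseline = baseline,
                 viability_baseline = viability_baseline,
                 ubb_kill = ubb_kill,
                 n_control_wells = as.integer(n_control_wells),
                 seed = as.integer(seed)),
            class = "screen_sim_config")
}

gene_ids <- function(n) sprintf("CTA%03d", seq_len(n))
line_ids <- function(n) sprintf("L%02d", seq_len(n))

#' Simulate expression counts with a qPCR companion table
#'
#' Draws a true presence state per gene-by-line cell, NanoString-like counts
#' around the present/absent count scales, and a Ct table covering exactly
#' the cells of ambiguous probes (genes whose counts stay below the 1,000
#' count threshold in every line), i.e. the cells the presence caller will
#' need qPCR for. Ct values above 40 cycles are flagged undetected.
#'
#' @param config an [expression_sim_config()].
#' @return a list of class `expression_sim` with elements `counts` (gene x
#'   line numeric matrix), `qpcr` (data.frame gene, cell_line, Ct,
#'   undetected), `truth` (logical gene x line presence matrix) and `config`.
#' @export
generate_expression_data <- function(config) {
  stopifnot(inherits(config, "expression_sim_config"))
  genes <- gene_ids(config$n_genes)
  lines <- line_ids(config$n_lines)
  set.seed(stream_seed(config$seed, "expression/presence"))
  truth <- matrix(stats::runif(config$n_genes * config$n_lines) < config$presence_prob,
                  nrow = config$n_genes, dimnames = list(genes, lines))
  set.seed(stream_seed(config$seed, "expression/counts"))
  scale <- ifelse(truth, config$count_scale_present, config$count_scale_absent)
  counts <- scale * matrix(rlnorm_cv(length(scale), config$noise_cv),
                           nrow = nrow(scale))
  dimnames(counts) <- dimnames(truth)

  ## qPCR follow-up is run per ambiguous probe, across all lines
  ambiguous <- rowSums(counts >= 1000) == 0
  qpcr <- data.frame(gene = character(), cell_line = character(),
                     Ct = numeric(), undetected = logical())
  if (any(ambiguous)) {
    set.seed(stream_seed(config$seed, "expression/qpcr"))
    amb_genes <- genes[ambiguous]
    grid <- expand.grid(gene = amb_genes, cell_line = lines,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mean_ct <- ifelse(truth[cbind(grid$gene, grid$cell_line)],
                      config$ct_mean_present, config$ct_mean_absent)
    ct <- stats::rnorm(nrow(grid), mean_ct, sd = 1)
    undetected <- ct > 40
    qpcr <- data.frame(grid, Ct = ifelse(undetected, NA_real_, round(ct, 2)),
                       undetected = undetected)
    qpcr <- qpcr[order(qpcr$gene, qpcr$cell_line), ]
    rownames(qpcr) <- NULL
  }
  structure(list(counts = counts, qpcr = qpcr, truth = truth, config = config),
            class = "expression_sim")
}

## Effect multiplier on the raw readout for a planted hit.
hit_multiplier <- function(direction, effect_size) {
  if (direction == "decrease") 1 - effect_size else 1 / (1 - effect_size)
}

## One block = all wells of one (assay, line, condition) stratum.
simulate_block <- function(assay, line, condition, cfg, genes, effect_mult,
                           base_mean, screen_id) {
  n_rep <- cfg$n_replicates
  reagents <- data.frame(
    gene = c(genes, rep("NT", cfg$n_control_wells), rep("UBB", 2L)),
    reagent_type = c(rep("pool", length(genes)),
                     rep("control_nt", cfg$n_control_wells),
                     rep("control_ubb", 2L)),
    reagent_id = c(paste0("pool_", genes),
                   paste0("siNT_", seq_len(cfg$n_control_wells)),
                   paste0("siUBB_", 1:2)),
    mult = c(effect_mult, rep(1, cfg$n_control_wells), rep(1 - cfg$ubb_kill, 2L))
  )
  n_wells <- nrow(reagents) * n_rep
  idx <- rep(seq_len(nrow(reagents)), each = n_rep)
  paired <- cfg$assays[[assay]]$paired_viability
  raw <- base_mean * reagents$mult[idx] * rlnorm_cv(n_wells, cfg$noise_cv)
  viab <- if (paired) {
    ## siUBB kills cells, which the paired channel sees too
    v_mult <- ifelse(reagents$reagent_type[idx] == "control_ubb",
                     1 - cfg$ubb_kill, 1)
    cfg$viability_baseline * v_mult * rlnorm_cv(n_wells, cfg$noise_cv)
  } else rep(NA_real_, n_wells)
  data.frame(
    screen_id = screen_id,
    cell_line = line,
    assay = assay,
    condition = condition,
    gene = reagents$gene[idx],
    reagent_type = reagents$reagent_type[idx],
    reagent_id = reagents$reagent_id[idx],
    replicate = rep(seq_len(n_rep), nrow(reagents)),
    raw_value = raw,
    paired_viability_value = viab,
    plate = paste(screen_id, assay, line, sep = "_"),
    well = sprintf("W%04d", seq_len(n_wells))
  )
}

#' Simulate a multi-assay arrayed siRNA screen
#'
#' Plants hits only in (gene, line) cells where the gene is present in the
#' supplied presence matrix — a phenotype requires expression of the target.
#' Planted decrease-direction hits have expected control-normalized ratio
#' `1 - effect_size`. Per-single activity flags for later pool deconvolution
#' are drawn here and recorded in the truth object.
#'
#' @param config a [screen_sim_config()].
#' @param presence logical gene x line matrix (or a `presence_matrix`); its
#'   dimensions override `config$n_genes` / `config$n_lines`.
#' @return list of class `screen_sim` with `measurements` (MeasurementTable
#'   data.frame), `truth` (a `screen_truth`), and `config`.
#' @export
generate_screen_data <- function(config, presence) {
  stopifnot(inherits(config, "screen_sim_config"))
  if (inherits(presence, "presence_matrix")) presence <- presence_calls(presence)
  if (!is.matrix(presence) || !is.logical(presence) || length(presence) == 0)
    stop("presence must be a non-empty logical gene x line matrix", call. = FALSE)
  genes <- rownames(presence) %||% gene_ids(nrow(presence))
  lines <- colnames(presence) %||% line_ids(ncol(presence))
  dimnames(presence) <- list(genes, lines)

  ## Plant hits per (gene, assay class); only expressible genes qualify
  set.seed(stream_seed(config$seed, "screen/truth"))
  expressible <- rowSums(presence, na.rm = TRUE) > 0
  hits <- do.call(rbind, lapply(config$assays, function(a) {
    is_hit <- expressible & (stats::runif(length(genes)) < config$hit_fraction)
    if (!any(is_hit)) return(NULL)
    data.frame(gene = genes[is_hit], assay = a$name, direction = a$direction,
               effect_size = config$effect_size)
  }))
  if (is.null(hits))
    hits <- data.frame(gene = character(), assay = character(),
                       direction = character(), effect_size = numeric())
  rownames(hits) <- NULL

  ## Per-single activity flags, one draw per (gene, single); a gene that is
  ## a hit in any assay carries on-target singles
  set.seed(stream_seed(config$seed, "screen/singles"))
  hit_any <- genes %in% hits$gene
  p_active <- ifelse(hit_any, config$p_active_on_target, config$p_active_off_target)
  singles_active <- matrix(
    stats::runif(length(genes) * config$singles_per_pool) < rep(p_active, config$singles_per_pool),
    nrow = length(genes),
    dimnames = list(genes, paste0("s", seq_len(config$singles_per_pool))))

  truth <- structure(list(hits = hits, singles_active = singles_active,
                          presence = presence, config = config),
                     class = "screen_truth")

  blocks <- list()
  for (a in config$assays) {
    for (line in lines) {
      ## effect applies where the gene is a planted hit AND present in line
      mult <- rep(1, length(genes))
      a_hits <- hits$gene[hits$assay == a$name]
      active_here <- genes %in% a_hits & presence[, line] %in% TRUE
      mult[active_here] <- hit_multiplier(a$direction, config$effect_size)
      set.seed(stream_seed(config$seed, paste("screen", a$name, line, sep = "/")))
      if (a$reporter) {
        cond_mult <- list(vehicle = rep(1, length(genes)), ligand = mult)
        if (config$reporter_hit_on == "basal")
          cond_mult <- list(vehicle = mult, ligand = rep(1, length(genes)))
        for (cond in names(cond_mult)) {
          base <- config$baseline * if (cond == "ligand") config$induction_fold else 1
          blocks[[length(blocks) + 1L]] <-
            simulate_block(a$name, line, cond, config, genes,
                           cond_mult[[cond]], base, "screen1")
        }
      } else {
        blocks[[length(blocks) + 1L]] <-
          simulate_block(a$name, line, "na", config, genes, mult,
                         config$baseline, "screen1")
      }
    }
  }
  measurements <- do.call(rbind, blocks)
  rownames(measurements) <- NULL
  structure(list(measurements = validate_measurements(measurements),
                 truth = truth, config = config),
            class = "screen_sim")
}

#' @export
print.screen_truth <- function(x, ...) {
  cat("Planted screen truth:", nrow(x$hits), "gene-assay hits over",
      nrow(x$singles_active), "genes x", ncol(x$presence), "lines\n")
  invisible(x)
}

#' Simulate single-siRNA deconvolution plates
#'
#' For each retested gene, generates measurements for its constituent single
#' siRNAs (plus fresh non-targeting controls) in every cell line where the
#' gene is present, for each assay in which it was planted as a hit. A
#' single reproduces the pool's planted effect if and only if its activity
#' flag in the truth object is set.
#'
#' @param truth a `screen_truth` from [generate_screen_data()].
#' @param config the same [screen_sim_config()].
#' @param genes genes to retest; default all planted hit genes. A gene not in
#'   the truth universe is an error.
#' @return a MeasurementTable data.frame of single-siRNA wells.
#' @export
generate_singles_data <- function(truth, config, genes = NULL) {
  stopifnot(inherits(truth, "screen_truth"), inherits(config, "screen_sim_config"))
  universe <- rownames(truth$singles_active)
  if (is.null(genes)) genes <- unique(truth$hits$gene)
  unknown <- setdiff(genes, universe)
  if (length(unknown))
    stop("genes absent from truth: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  n_s <- config$singles_per_pool
  blocks <- list()
  for (gene in genes) {
    gene_hits <- truth$hits[truth$hits$gene == gene, , drop = FALSE]
    if (nrow(gene_hits) == 0)  # off-target retest: measure in viability-like assay
      gene_hits <- data.frame(gene = gene, assay = config$assays[[1]]$name,
                              direction = config$assays[[1]]$direction,
                              effect_size = config$effect_size)
    present_lines <- colnames(truth$presence)[truth$presence[gene, ] %in% TRUE]
    for (i in seq_len(nrow(gene_hits))) {
      a <- gene_hits$assay[i]
      mult_active <- hit_multiplier(gene_hits$direction[i], gene_hits$effect_size[i])
      for (line in present_lines) {
        set.seed(stream_seed(config$seed, paste("singles", gene, a, line, sep = "/")))
        n_rep <- config$n_replicates
        active <- truth$singles_active[gene, ]
        mult <- c(ifelse(active, mult_active, 1), rep(1, config$n_control_wells))
        reagent_type <- c(rep("single", n_s), rep("control_nt", config$n_control_wells))
        reagent_id <- c(sprintf("%s_s%d", gene, seq_len(n_s)),
                        paste0("siNT_", seq_len(config$n_control_wells)))
        idx <- rep(seq_along(mult), each = n_rep)
        n_wells <- length(idx)
        paired <- config$assays[[a]]$paired_viability
        blocks[[length(blocks) + 1L]] <- data.frame(
          screen_id = "deconv1",
          cell_line = line, assay = a, condition = "na",
          gene = c(rep(gene, n_s), rep("NT", config$n_control_wells))[idx],
          reagent_type = reagent_type[idx],
          reagent_id = reagent_id[idx],
          replicate = rep(seq_len(n_rep), length(mult)),
          raw_value = config$baseline * mult[idx] * rlnorm_cv(n_wells, config$noise_cv),
          paired_viability_value = if (paired)
            config$viability_baseline * rlnorm_cv(n_wells, config$noise_cv)
          else NA_real_,
          plate = paste("deconv1", a, line, sep = "_"),
          well = sprintf("W%04d", seq_len(n_wells))
        )
      }
    }
  }
  if (!length(blocks))
    return(validate_measurements(
      stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(MEASUREMENT_COLUMNS))),
                      MEASUREMENT_COLUMNS)))
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  validate_measurements(out)
}
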