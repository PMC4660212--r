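test_that("expression simulator honours degenerate presence probabilities", {
  all_on <- generate_expression_data(expression_sim_config(
    n_genes = 20, n_lines = 4, presence_prob = 1, count_scale_present = 5000,
    noise_cv = 0.1, seed = 3))
  expect_true(all(all_on$truth))
  expect_true(all(all_on$counts > 1000))
  expect_equal(nrow(all_on$qpcr), 0)

  all_off <- generate_expression_data(expression_sim_config(
    n_genes = 20, n_lines = 4, presence_prob = 0, seed = 3))
  expect_false(any(all_off$truth))
  expect_error(expression_sim_config(n_genes = 0), "positive")
})

test_that("fixed seeds make generators bit-identical and qPCR covers ambiguous cells", {
  cfg <- expression_sim_config(n_genes = 40, n_lines = 6, seed = 7)
  a <- generate_expression_data(cfg)
  b <- generate_expression_data(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$qpcr, b$qpcr)
  expect_identical(a$truth, b$truth)

  ## the Ct table covers exactly the cells of probes that are ambiguous
  ## (below 1000 counts in every line)
  ambiguous <- rownames(a$counts)[rowSums(a$counts >= 1000) == 0]
  expect_setequal(unique(a$qpcr$gene), ambiguous)
  expect_equal(nrow(a$qpcr), length(ambiguous) * ncol(a$counts))
  expect_true(all(a$counts > 0))

  scfg <- screen_sim_config(n_genes = 25, n_lines = 3, assays = cellbio_assays(),
                            seed = 7)
  pres <- all_present(25, 3)
  s1 <- generate_screen_data(scfg, pres)
  s2 <- generate_screen_data(scfg, pres)
  expect_identical(s1$measurements, s2$measurements)
  expect_identical(s1$truth$hits, s2$truth$hits)
  expect_identical(s1$truth$singles_active, s2$truth$singles_active)
})

test_that("random streams are split per assay: adding an assay leaves other draws alone", {
  pres <- all_present(15, 2)
  two <- screen_sim_config(n_genes = 15, n_lines = 2, seed = 5,
                           assays = cellbio_assays()[1:2], hit_fraction = 0)
  three <- screen_sim_config(n_genes = 15, n_lines = 2, seed = 5,
                             assays = cellbio_assays(), hit_fraction = 0)
  m2 <- generate_screen_data(two, pres)$measurements
  m3 <- generate_screen_data(three, pres)$measurements
  m3 <- m3[m3$assay %in% c("viability", "apoptosis"), ]
  rownames(m3) <- NULL
  expect_identical(m2, m3)
})

test_that("screen generator plants the configured structure", {
  pres <- all_present(30, 2)
  no_hits <- generate_screen_data(
    screen_sim_config(n_genes = 30, n_lines = 2, assays = cellbio_assays(),
                      hit_fraction = 0, seed = 2), pres)
  expect_equal(nrow(no_hits$truth$hits), 0)

  sim <- generate_screen_data(
    screen_sim_config(n_genes = 30, n_lines = 2, assays = cellbio_assays(),
                      hit_fraction = 0.3, seed = 2), pres)
  expect_true(all(sim$truth$hits$gene %in% rownames(pres)))
  expect_true(all(sim$truth$hits$gene %in% sim$measurements$gene))
  ## every block carries controls and one pool per gene, with replicates
  blk <- sim$measurements[sim$measurements$assay == "viability" &
                            sim$measurements$cell_line == "L01", ]
  expect_equal(sum(blk$reagent_type == "pool"), 30 * 2)
  expect_true(any(blk$reagent_type == "control_nt"))

  expect_error(generate_screen_data(
    screen_sim_config(n_genes = 5, n_lines = 1), matrix(TRUE, 0, 0)), "non-empty")
})

test_that("reporter assays emit paired vehicle/ligand wells at the induction fold", {
  cfg <- screen_sim_config(
    n_genes = 40, n_lines = 1, n_replicates = 4, hit_fraction = 0,
    noise_cv = 0.05, induction_fold = 8,
    assays = list(screen_assay("tgfb", "decrease", paired_viability = TRUE,
                               reporter = TRUE)),
    seed = 11)
  m <- generate_screen_data(cfg, all_present(40, 1))$measurements
  expect_setequal(unique(m$condition), c("vehicle", "ligand"))
  fold <- mean(m$raw_value[m$condition == "ligand"]) /
    mean(m$raw_value[m$condition == "vehicle"])
  expect_equal(fold, 8, tolerance = 0.05)
  expect_true(all(is.finite(m$paired_viability_value)))
})

test_that("planted decrease hits calibrate to 1 - effect_size", {
  ## Monte-Carlo mean of the control-normalized ratio at high replication
  cfg <- screen_sim_config(n_genes = 40, n_lines = 1,
                           assays = list(screen_assay("viability", "decrease")),
                           n_replicates = 50, hit_fraction = 0.5,
                           effect_size = 0.5, noise_cv = 0.01, seed = 13)
  sim <- generate_screen_data(cfg, all_present(40, 1))
  ztab <- process_screen(sim$measurements)
  hit_ratio <- ztab$ratio[ztab$gene %in% sim$truth$hits$gene &
                            ztab$reagent_type == "pool"]
  expect_gt(length(hit_ratio), 5)
  expect_equal(mean(hit_ratio), 0.5, tolerance = 0.02)
  ## inactive genes stay at the control level
  null_ratio <- ztab$ratio[!(ztab$gene %in% sim$truth$hits$gene) &
                             ztab$reagent_type == "pool"]
  expect_equal(mean(null_ratio), 1, tolerance = 0.02)
})

test_that("single-siRNA generator follows the truth activity flags", {
  pres <- all_present(20, 2)
  base <- screen_sim_config(n_genes = 20, n_lines = 2, assays = cellbio_assays(),
                            hit_fraction = 0.4, seed = 4)
  for (p_active in c(0, 1)) {
    cfg <- base; cfg$p_active_on_target <- p_active
    sim <- generate_screen_data(cfg, pres)
    hit_genes <- unique(sim$truth$hits$gene)
    expect_true(all(rowSums(sim$truth$singles_active[hit_genes, , drop = FALSE]) ==
                      (p_active * 4)))
  }
  sim <- generate_screen_data(base, pres)
  singles <- generate_singles_data(sim$truth, base)
  expect_equal(sort(unique(singles$gene[singles$reagent_type == "single"])),
               sort(unique(sim$truth$hits$gene)))
  ## 4 singles per retested gene per line where present
  g <- sim$truth$hits$gene[1]
  a <- sim$truth$hits$assay[1]
  sub <- singles[singles$gene == g & singles$assay == a &
                   singles$cell_line == "L01" & singles$reagent_type == "single", ]
  expect_equal(length(unique(sub$reagent_id)), 4)
  expect_error(generate_singles_data(sim$truth, base, genes = "NOPE"),
               "absent from truth")
})

test_that("active singles carry the pool effect and inactive ones do not", {
  cfg <- screen_sim_config(n_genes = 10, n_lines = 1,
                           assays = list(screen_assay("viability", "decrease")),
                           n_replicates = 40, hit_fraction = 1, effect_size = 0.5,
                           noise_cv = 0.02, p_active_on_target = 0.5, seed = 21)
  sim <- generate_screen_data(cfg, all_present(10, 1))
  singles <- generate_singles_data(sim$truth, cfg)
  ztab <- suppressWarnings(process_screen(singles))
  sz <- ztab[ztab$reagent_type == "single", ]
  sz$single <- sub(".*_(s\\d)$", "\\1", sz$reagent_id)
  truth_active <- sim$truth$singles_active[cbind(sz$gene, sz$single)]
  expect_equal(mean(sz$ratio[truth_active]), 0.5, tolerance = 0.02)
  expect_equal(mean(sz$ratio[!truth_active]), 1.0, tolerance = 0.02)
})
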