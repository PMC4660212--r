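## Build a one-stratum z-table + measurements pair where gene effects and
## replicate spreads are chosen by hand, so every rule clause is exercised
## deterministically.
cellbio_fixture <- function(assay = "viability", gene_means, gene_sds,
                            n_rep = 3, ctrl_mean = 1000, n_ctrl = 8) {
  genes <- names(gene_means)
  set.seed(101)
  rows <- list()
  for (g in genes) {
    vals <- gene_means[[g]] + gene_sds[[g]] * scale(rnorm(n_rep))  # exact mean/sd
    rows[[g]] <- data.frame(gene = g, reagent_type = "pool",
                            reagent_id = paste0("pool_", g),
                            replicate = seq_len(n_rep), raw_value = as.numeric(vals))
  }
  ctrl <- data.frame(gene = "NT", reagent_type = "control_nt",
                     reagent_id = paste0("siNT_", seq_len(n_ctrl)),
                     replicate = 1L,
                     raw_value = as.numeric(ctrl_mean + 20 * scale(rnorm(n_ctrl))))
  df <- do.call(rbind, c(rows, list(ctrl)))
  df <- data.frame(screen_id = "fx", cell_line = "L01", assay = assay,
                   condition = "na", df[, c("gene", "reagent_type", "reagent_id",
                                            "replicate")],
                   raw_value = df$raw_value,
                   paired_viability_value = NA_real_, plate = "p",
                   well = sprintf("W%03d", seq_len(nrow(df))))
  rownames(df) <- NULL
  df
}

test_that("cell-biological hits need both the z outlier and the t-test", {
  ## one strong clean hit, one strong noisy gene, many nulls
  means <- c(hitA = 400, noisy = 400,
             setNames(rep(1000, 20), sprintf("n%02d", 1:20)))
  sds <- c(hitA = 10, noisy = 1200, setNames(rep(10, 20), sprintf("n%02d", 1:20)))
  m <- cellbio_fixture("viability", means, sds)
  ztab <- process_screen(m)
  hits <- call_cellbio_hits(ztab, m, hit_call_config())
  get <- function(g) hits[hits$gene == g, ]
  expect_equal(get("hitA")$call, "hit")
  expect_lt(get("hitA")$zscore, -2)
  expect_lte(get("hitA")$p_value, 0.05)
  ## same depletion but replicates too scattered for Student's t
  expect_lt(get("noisy")$zscore, -2)
  expect_gt(get("noisy")$p_value, 0.05)
  expect_equal(get("noisy")$call, "not_hit")
  expect_equal(get("noisy")$rule, "outlier_failed_ttest")
  expect_true(all(get("n01")$call == "not_hit"))
})

test_that("direction matters: apoptosis hits go up, viability hits go down", {
  means <- c(up = 1600, down = 100,
             setNames(rep(1000, 30), sprintf("n%02d", 1:30)))
  sds <- setNames(rep(15, 32), names(means))
  m_apo <- cellbio_fixture("apoptosis", means, sds)
  z_apo <- process_screen(m_apo)
  hits_apo <- call_cellbio_hits(z_apo, m_apo)
  expect_equal(hits_apo$call[hits_apo$gene == "up"], "hit")
  ## a decrease is never an apoptosis hit, however extreme
  expect_equal(hits_apo$call[hits_apo$gene == "down"], "not_hit")

  m_via <- cellbio_fixture("viability", means, sds)
  hits_via <- call_cellbio_hits(process_screen(m_via), m_via)
  expect_equal(hits_via$call[hits_via$gene == "down"], "hit")
  expect_equal(hits_via$call[hits_via$gene == "up"], "not_hit")
})

test_that("outliers with too few replicates are unresolved, never hits", {
  means <- c(hitA = 300, setNames(rep(1000, 10), sprintf("n%02d", 1:10)))
  sds <- setNames(rep(10, 11), names(means))
  m <- cellbio_fixture("viability", means, sds, n_rep = 3)
  m <- m[!(m$gene == "hitA" & m$replicate > 1), ]  # leave a single replicate
  ztab <- process_screen(m)
  hits <- call_cellbio_hits(ztab, m)
  expect_equal(hits$call[hits$gene == "hitA"], "unresolved")
})

test_that("raising thresholds never adds a hit", {
  cfg <- screen_sim_config(n_genes = 60, n_lines = 2, assays = cellbio_assays(),
                           hit_fraction = 0.15, noise_cv = 0.15, seed = 29)
  sim <- generate_screen_data(cfg, all_present(60, 2))
  ztab <- process_screen(sim$measurements)
  loose <- call_cellbio_hits(ztab, sim$measurements,
                             hit_call_config(z_threshold = 1.5, p_threshold = 0.1))
  strict <- call_cellbio_hits(ztab, sim$measurements,
                              hit_call_config(z_threshold = 2.5, p_threshold = 0.01))
  loose_hits <- with(loose, paste(gene, assay, cell_line)[call == "hit"])
  strict_hits <- with(strict, paste(gene, assay, cell_line)[call == "hit"])
  expect_true(all(strict_hits %in% loose_hits))
})

test_that("reporter rules: single-line >60% or >30% in three or more lines", {
  red <- rbind(single = c(0.65, 0.10, 0.05),
               multi = c(0.35, 0.32, 0.31),
               sub = c(0.55, 0.28, 0.10),
               none = c(0.05, 0.02, 0.01))
  colnames(red) <- paste0("L", 1:3)
  hits <- call_reporter_hits(red, assay = "tgfb")
  call_of <- function(g) hits[hits$gene == g, ]
  expect_equal(call_of("single")$call, "hit")
  expect_match(call_of("single")$rule, "single_line")
  expect_equal(call_of("multi")$call, "hit")
  expect_match(call_of("multi")$rule, "3\\+_lines")
  expect_equal(call_of("sub")$call, "not_hit")
  expect_equal(call_of("none")$call, "not_hit")

  ## two lines past 30% are not enough under the >2-lines reading
  red2 <- rbind(two = c(0.35, 0.32))
  colnames(red2) <- paste0("L", 1:2)
  expect_equal(call_reporter_hits(red2)$call, "not_hit")
  ## ... but qualify under the configurable >=2 reading
  expect_equal(call_reporter_hits(red2,
                                  hit_call_config(reporter_min_lines = 2))$call,
               "hit")
})

test_that("reporter screens accept either basal or induced positives", {
  basal <- rbind(gA = c(0.70, 0.0), gB = c(0.0, 0.0))
  induced <- rbind(gA = c(0.0, 0.0), gB = c(0.72, 0.1))
  colnames(basal) <- colnames(induced) <- c("L1", "L2")
  hits <- call_reporter_hits(list(vehicle = basal, ligand = induced))
  expect_equal(hits$call[hits$gene == "gA"], "hit")
  expect_equal(hits$condition[hits$gene == "gA"], "vehicle")
  expect_equal(hits$call[hits$gene == "gB"], "hit")
  expect_equal(hits$condition[hits$gene == "gB"], "ligand")
  ## a gene with no finite measurement anywhere is unresolved
  nome <- rbind(gC = c(NA_real_, NA_real_))
  colnames(nome) <- c("L1", "L2")
  expect_equal(call_reporter_hits(nome)$call, "unresolved")
})

test_that("retest selection uses the looser 1.5 s.d. cut in the assay direction", {
  ztab <- data.frame(assay = "viability", cell_line = "L01", condition = "na",
                     gene = c("a", "b", "c"), reagent_type = "pool",
                     reagent_id = paste0("pool_", c("a", "b", "c")),
                     n_replicates = 3L, mean_raw = 1, mean_corrected = 1,
                     ratio = 1, zscore = c(-1.6, -1.4, 1.8))
  expect_equal(select_retest(ztab), "a")  # -1.6 passes; +1.8 is the wrong tail
  ztab$zscore <- c(0, 0, 0)
  expect_equal(select_retest(ztab), character())
  ztab$assay <- "apoptosis"
  ztab$zscore <- c(1.7, -1.9, 0.2)
  expect_equal(select_retest(ztab), "a")  # apoptosis selects the upper tail
})

test_that("deconvolution validates pools with two or more active singles", {
  cs <- function(effects, thr = 0.3)
    classify_singles(effects, thr)
  expect_equal(cs(c(0.6, 0.55, 0.5, 0.05))$n_active, 3)
  expect_true(cs(c(0.6, 0.55, 0.5, 0.05))$validated)
  r1 <- cs(c(0.6, 0.05, 0.04, 0.02))
  expect_equal(r1$n_active, 1); expect_false(r1$validated)
  expect_equal(cs(c(0, 0, 0, 0))$n_active, 0)
  ## monotone: increasing a single's effect cannot invalidate a pool
  base_val <- cs(c(0.35, 0.31, 0.1, 0.1))$validated
  expect_true(base_val)
  expect_true(cs(c(0.35, 0.65, 0.1, 0.1))$validated)
})

test_that("deconvolve recovers planted single activity from measurements", {
  cfg <- screen_sim_config(n_genes = 60, n_lines = 1,
                           assays = list(screen_assay("viability", "decrease")),
                           n_replicates = 6, hit_fraction = 0.1, effect_size = 0.6,
                           noise_cv = 0.03, p_active_on_target = 0.5, seed = 37)
  sim <- generate_screen_data(cfg, all_present(60, 1))
  ztab <- process_screen(sim$measurements)
  hits <- call_cellbio_hits(ztab, sim$measurements)
  hits <- hits[hits$call == "hit", ]
  expect_gt(nrow(hits), 0)
  singles <- generate_singles_data(sim$truth, cfg)
  for (i in seq_len(nrow(hits))) {
    d <- deconvolve(hits[i, ], singles)
    truth_n <- sum(sim$truth$singles_active[d$gene, ])
    expect_equal(d$n_active, truth_n)
    expect_equal(d$validated, truth_n >= 2)
  }
})

test_that("KS comparison matches hand-computed D on toy samples", {
  same <- ks_compare_gene(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$D, 0)
  apart <- ks_compare_gene(c(1, 2, 3), c(10, 11, 12))
  expect_equal(apart$D, 1)
  toy <- ks_compare_gene(c(0.1, 0.2, 0.3), c(0.2, 0.3, 0.4))
  expect_equal(toy$D, 1 / 3)
  expect_error(ks_compare_gene(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("hit integration tallies penetrance across assays and lines", {
  empty <- integrate_hits(empty_tab = NULL)
  expect_equal(nrow(empty), 0)
  tab <- data.frame(gene = c("a", "a", "b", "c"),
                    assay = c("viability", "apoptosis", "viability", "tgfb"),
                    cell_line = c("L1", "L1", "L2", "L1"),
                    assay_class = "x", condition = "na", direction = "decrease",
                    zscore = c(-3, 2.5, -2.2, NA), ratio = 1, p_value = 0.01,
                    call = c("hit", "hit", "hit", "not_hit"), rule = "r")
  class(tab) <- c("hit_table", "data.frame")
  out <- integrate_hits(tab)
  expect_equal(out$n_hits[out$gene == "a"], 2)
  expect_equal(out$n_hits[out$gene == "b"], 1)
  expect_equal(out$n_hits[out$gene == "c"], 0)
  expect_equal(out$max_abs_z[out$gene == "a"], 3)
  expect_equal(out$screens[out$gene == "a"], "apoptosis,viability")
})
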