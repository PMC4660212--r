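## Shared fixtures: small seeded configs and hand-built tables.

## Three cell-biological assays only (no reporters) for recovery tests.
cellbio_assays <- function() {
  list(screen_assay("viability", "decrease"),
       screen_assay("apoptosis", "increase", paired_viability = TRUE),
       screen_assay("proliferation", "decrease"))
}

all_present <- function(n_genes, n_lines) {
  matrix(TRUE, n_genes, n_lines,
         dimnames = list(sprintf("CTA%03d", seq_len(n_genes)),
                         sprintf("L%02d", seq_len(n_lines))))
}

## A deterministic 5-gene, one-stratum measurement table with two replicates
## per pool and two non-targeting control wells; values chosen for hand
## computation (control mean 1000).
toy_measurements <- function() {
  rows <- list(
    c("g1", "pool", "pool_g1", 1, 580), c("g1", "pool", "pool_g1", 2, 620),
    c("g2", "pool", "pool_g2", 1, 980), c("g2", "pool", "pool_g2", 2, 1020),
    c("g3", "pool", "pool_g3", 1, 1380), c("g3", "pool", "pool_g3", 2, 1420),
    c("g4", "pool", "pool_g4", 1, 1900), c("g4", "pool", "pool_g4", 2, 2100),
    c("g5", "pool", "pool_g5", 1, 480), c("g5", "pool", "pool_g5", 2, 520),
    c("NT", "control_nt", "siNT_1", 1, 950), c("NT", "control_nt", "siNT_1", 2, 1050)
  )
  df <- do.call(rbind.data.frame, lapply(rows, function(r)
    data.frame(screen_id = "toy", cell_line = "L01", assay = "viability",
               condition = "na", gene = r[1], reagent_type = r[2],
               reagent_id = r[3], replicate = as.integer(r[4]),
               raw_value = as.numeric(r[5]),
               paired_viability_value = NA_real_,
               plate = "p1", well = sprintf("W%s%s", r[1], r[4]))))
  rownames(df) <- NULL
  df
}

## Independent oracle: upper-tail hypergeometric probability by direct
## summation of the pmf written with exact choose() terms.
hyper_upper_oracle <- function(N, K, n, k) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

## Independent oracle: permutation p-value for the two-sample KS D.
ks_perm_p <- function(a, b, B = 4000, seed = 1) {
  set.seed(seed)
  obs <- suppressWarnings(stats::ks.test(a, b, exact = FALSE)$statistic)
  pool <- c(a, b)
  d <- replicate(B, {
    i <- sample(length(pool), length(a))
    suppressWarnings(stats::ks.test(pool[i], pool[-i], exact = FALSE)$statistic)
  })
  mean(d >= obs - 1e-12)
}

## Independent oracle: best coverage over all panels of a given size by
## explicit subset enumeration (no shared code with the solvers).
brute_force_coverage <- function(m, size) {
  best <- 0L
  for (idx in utils::combn(ncol(m), size, simplify = FALSE)) {
    cov <- sum(rowSums(m[, idx, drop = FALSE]) > 0)
    if (cov > best) best <- cov
  }
  best
}

random_presence_instance <- function(n_genes, n_lines, p = 0.5) {
  matrix(stats::runif(n_genes * n_lines) < p, n_genes,
         dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                         sprintf("L%02d", seq_len(n_lines))))
}
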