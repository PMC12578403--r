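# Shared fixtures, all built in code.

# Three cells on a line: reference at 0, IL6+ fibroblast at 10 um,
# IL6- fibroblast at 100 um.
toy3 <- function() {
  list(xy = cbind(x = c(0, 10, 100), y = c(0, 0, 0)),
       labels = c("reference", "il6pos_fib", "il6neg_fib"))
}

# Six-cell QC toy with per-cell totals [12, 9, 30, 10, 11, 20]; after the
# 10-counts/cell filter, gene A is detected in all 5 survivors, gene B in 3,
# gene C in 2.
toy6_qc <- function() {
  counts <- cbind(A = c(10, 8, 20, 9, 10, 15),
                  B = c(2, 0, 10, 0, 1, 0),
                  C = c(0, 1, 0, 1, 0, 5))
  cell_map(sprintf("c%d", 1:6), x = seq(0, 50, by = 10), y = rep(0, 6),
           genes = colnames(counts), counts = counts)
}

# Small cell map with a full marker panel and hand-set marker counts.
toy_marker_map <- function(marker_rows) {
  genes <- c("ARG1", "IL6", "COL1A1", "CTHRC1", "EPCAM", "BG01")
  counts <- matrix(0, nrow(marker_rows), length(genes),
                   dimnames = list(NULL, genes))
  counts[, colnames(marker_rows)] <- marker_rows
  counts[, "BG01"] <- 12  # keep every cell above the QC depth threshold
  n <- nrow(counts)
  cell_map(sprintf("m%d", seq_len(n)), x = seq_len(n) * 10, y = rep(0, n),
           genes = genes, counts = counts)
}

# Random labeled point configuration for property tests; guarantees at
# least one reference cell.
random_instance <- function(n, extent = 100,
                            probs = c(0.15, 0.3, 0.3, 0.25)) {
  xy <- cbind(x = runif(n, 0, extent), y = runif(n, 0, extent))
  labels <- sample(CATEGORY_LEVELS, n, replace = TRUE, prob = probs)
  labels[sample.int(n, 1)] <- "reference"
  list(xy = xy, labels = labels)
}

# Independent closed-form paired t computation (test-side oracle; no calls
# into the package's inference code).
closed_form_paired_t <- function(b, c) {
  d <- b - c
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

# Simulation config used by the planted-enrichment recovery checks.
recovery_config <- function(seed = 1) {
  simulation_config(domain_width = 500, domain_height = 500,
                    n_reference = 50, n_fib = 500, frac_il6pos = 0.5,
                    n_other = 200, enrichment_radius = 25,
                    enrichment_frac = 0.6, dropout_prob = 0,
                    n_qc_fail_cells = 0, n_rare_genes = 0, seed = seed)
}

# Per-sample configuration of the nine-patient cohort emulation: 2000 cells
# in a 400 x 400 um domain, so a 25 um ball holds ~25 cells.
cohort_config <- function(seed = 1, enrichment_frac = 0) {
  simulation_config(domain_width = 400, domain_height = 400,
                    n_reference = 100, n_fib = 1000, frac_il6pos = 0.5,
                    n_other = 900, enrichment_radius = 25,
                    enrichment_frac = enrichment_frac, dropout_prob = 0.1,
                    n_qc_fail_cells = 0, n_rare_genes = 0, seed = seed)
}

# Ratio difference and paired p for one simulated cohort (CIs skipped for
# speed in replicate loops).
cohort_paired_p <- function(base_seed, effect, n_samples = 9) {
  cfg <- cohort_config(seed = base_seed)
  sims <- simulate_cohort(cfg, n_samples, effect_b_minus_c = effect)
  res <- run_cohort_analysis(lapply(sims, `[[`, "map"), compute_ci = FALSE,
                             seed = base_seed)
  s <- summary(res)
  list(p = res$paired$p_value, diffs = s$per_sample$difference)
}
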