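test_that("identical config and seed reproduce the identical sample", {
  cfg <- simulation_config(n_reference = 40, n_fib = 200, n_other = 150,
                           n_qc_fail_cells = 4, n_rare_genes = 2, seed = 99)
  a <- simulate_cell_map(cfg)
  b <- simulate_cell_map(cfg)
  expect_identical(a$map$x, b$map$x)
  expect_identical(as.matrix(a$map$counts), as.matrix(b$map$counts))
  expect_identical(a$truth, b$truth)
  # and the generator does not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_cell_map(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("geometry invariants: domain bounds and cluster radii", {
  cfg <- simulation_config(domain_width = 300, domain_height = 200,
                           n_reference = 30, n_fib = 200, frac_il6pos = 0.6,
                           n_other = 100, enrichment_frac = 0.7,
                           enrichment_radius = 25, seed = 5)
  sim <- simulate_cell_map(cfg)
  expect_true(all(sim$map$x >= 0 & sim$map$x <= 300))
  expect_true(all(sim$map$y >= 0 & sim$map$y <= 200))
  cl <- sim$truth[sim$truth$placement == "clustered", ]
  expect_identical(nrow(cl), 84L)  # round(0.7 * round(0.6 * 200))
  idx <- match(cl$cell_id, sim$map$cell_ids)
  par <- match(cl$parent_id, sim$map$cell_ids)
  d <- sqrt((sim$map$x[idx] - sim$map$x[par])^2 +
              (sim$map$y[idx] - sim$map$y[par])^2)
  expect_true(all(d <= 25 + 1e-9))
  expect_true(all(sim$truth$true_type[par] == "reference"))
})

test_that("marker positivity is consistent with ground truth absent dropout", {
  cfg <- recovery_config(seed = 12)  # dropout_prob = 0
  sim <- simulate_cell_map(cfg)
  cats <- assign_categories(sim$map)
  expect_identical(as.character(cats), sim$truth$true_type)
  # with dropout, mismatches happen but only "downward" (lost positivity)
  cfg2 <- simulation_config(n_reference = 50, n_fib = 400, n_other = 100,
                            dropout_prob = 0.3, n_qc_fail_cells = 0,
                            n_rare_genes = 0, seed = 13)
  sim2 <- simulate_cell_map(cfg2)
  cats2 <- as.character(assign_categories(sim2$map))
  truth2 <- sim2$truth$true_type
  expect_true(any(cats2 != truth2))
  # a true reference can only lose ARG1, never gain a fibroblast identity
  expect_true(all(cats2[truth2 == "reference"] %in% c("reference", "other")))
  expect_true(all(cats2[truth2 == "il6pos_fib"] %in%
                    c("il6pos_fib", "il6neg_fib", "other")))
})

test_that("QC-failing cells and rare genes are planted exactly as configured", {
  cfg <- simulation_config(n_reference = 20, n_fib = 100, n_other = 80,
                           n_qc_fail_cells = 3, n_rare_genes = 2, seed = 8)
  sim <- simulate_cell_map(cfg)
  totals <- Matrix::rowSums(sim$map$counts)
  expect_identical(sum(totals < 10), 3L)
  expect_identical(unname(which(totals < 10)), which(sim$truth$qc_fail))
  rare <- grep("^RAREG", sim$map$genes, value = TRUE)
  expect_length(rare, 2L)
  detected <- Matrix::colSums(sim$map$counts[, rare, drop = FALSE] > 0)
  expect_true(all(detected >= 1 & detected < 5))
  # the QC filter removes exactly the planted failures
  qc <- qc_filter(sim$map)
  expect_identical(length(qc$cell_ids), 200L)
  expect_false(any(grepl("^RAREG", qc$genes)))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_reference = -1),
               class = "proxratio_bad_config")
  expect_error(simulation_config(frac_il6pos = 1.5),
               class = "proxratio_bad_config")
  expect_error(simulation_config(domain_width = 0),
               class = "proxratio_bad_config")
  cfg <- simulation_config(n_reference = 0, enrichment_frac = 0.5)
  expect_error(simulate_cell_map(cfg),
               class = "proxratio_inconsistent_config")
  # CSR with no reference cells is fine to simulate
  cfg0 <- simulation_config(n_reference = 0, n_fib = 30, n_other = 20,
                            enrichment_frac = 0, n_qc_fail_cells = 0,
                            n_rare_genes = 0)
  expect_identical(length(simulate_cell_map(cfg0)$map$cell_ids), 50L)
})

test_that("cohorts share the config but differ by derived per-sample seeds", {
  cfg <- cohort_config(seed = 55)
  a <- simulate_cohort(cfg, 3, effect_b_minus_c = 0.4)
  b <- simulate_cohort(cfg, 3, effect_b_minus_c = 0.4)
  expect_identical(names(a), c("sample_01", "sample_02", "sample_03"))
  expect_identical(a$sample_02$map$x, b$sample_02$map$x)
  expect_identical(as.matrix(a$sample_03$map$counts),
                   as.matrix(b$sample_03$map$counts))
  expect_false(identical(a$sample_01$map$x, a$sample_02$map$x))
  # the effect argument controls clustering of IL6+ fibroblasts only
  tr <- a$sample_01$truth
  expect_true(all(tr$true_type[tr$placement == "clustered"] == "il6pos_fib"))
})

test_that("CSR generator centers the ratio on 1 at a bias-negligible radius", {
  # 30 reference cells and a 250 um radius (ball of ~390 expected neighbors)
  # keep the self-inclusion bias ~E[1/(B+1)] well below 2 Monte-Carlo SE
  ratios <- vapply(1:20, function(i) {
    cfg <- simulation_config(n_reference = 30, n_fib = 1000, n_other = 970,
                             enrichment_frac = 0, n_qc_fail_cells = 0,
                             n_rare_genes = 0, seed = derive_seed(600, i))
    sim <- simulate_cell_map(cfg)
    keep <- !sim$truth$qc_fail
    cooccurrence_ratio(cbind(sim$map$x, sim$map$y)[keep, ],
                       sim$truth$true_type[keep], "il6pos_fib", 250)$ratio
  }, numeric(1))
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 1), 2 * se)
})

test_that("planted-ratio oracle behaves under null and full enrichment", {
  cfg0 <- simulation_config(n_reference = 25, n_fib = 300, n_other = 275,
                            domain_width = 500, domain_height = 500,
                            enrichment_frac = 0, dropout_prob = 0,
                            n_qc_fail_cells = 0, n_rare_genes = 0, seed = 42)
  # 180 um balls (~250 expected neighbors): self-inclusion bias negligible
  # next to 2 SE per the null-calibration analysis in the methods vignette
  o0 <- planted_ratio_oracle(cfg0, radius = 180, n_reps = 20)
  expect_lt(abs(o0$mean - 1), 2 * o0$se)
  cfg1 <- simulation_config(n_reference = 25, n_fib = 300, n_other = 0,
                            domain_width = 500, domain_height = 500,
                            enrichment_frac = 1, dropout_prob = 0,
                            n_qc_fail_cells = 0, n_rare_genes = 0, seed = 43)
  o1 <- planted_ratio_oracle(cfg1, radius = 25, n_reps = 20)
  expect_true(all(o1$ratios > 1))
})
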