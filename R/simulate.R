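# Marker genes whose zero/nonzero pattern drives categorization; the
# generator zero-truncates their counts in expressing cell types (then
# applies dropout) so positivity matches the ground-truth type.
MARKER_GENES <- c("ARG1", "IL6", "COL1A1", "CTHRC1")

# Counts-per-cell threshold the generator guarantees: every regular cell is
# topped up to at least this total, and QC-fail cells are forced below it.
QC_MIN_TOTAL <- 10

#' Default per-type mean expression for the synthetic gene panel
#'
#' A small Xenium-like panel: the four category markers (ARG1, IL6, COL1A1,
#' CTHRC1), an epithelial marker (EPCAM, expressed by "other" cells), and
#' `n_background` housekeeping-like background genes expressed by every cell
#' type. Means are per expressing cell; marker genes are listed only for the
#' types that truly express them, so marker positivity encodes the
#' ground-truth type.
#'
#' @param n_background Number of background genes (default 10).
#' @param background_mean Mean counts per background gene (default 2).
#' @return Named list (one element per cell type) of named mean vectors.
#' @export
default_count_means <- function(n_background = 10, background_mean = 2) {
  bg <- stats::setNames(rep(background_mean, n_background),
                        sprintf("BG%02d", seq_len(n_background)))
  list(
    reference  = c(c(ARG1 = 3), bg),
    il6pos_fib = c(c(IL6 = 2, COL1A1 = 4, CTHRC1 = 2), bg),
    il6neg_fib = c(c(COL1A1 = 4, CTHRC1 = 2), bg),
    other      = c(c(EPCAM = 3), bg))
}

#' Configuration of the synthetic spatial cohort
#'
#' Fully parameterizes one synthetic sample: a rectangular tissue domain,
#' counts of reference (ARG1+) cells, fibroblasts and other cells, the
#' planted paracrine enrichment (a fraction of IL6+ fibroblasts placed
#' uniformly within `enrichment_radius` of a random reference cell;
#' IL6- fibroblasts are always placed uniformly), a negative-binomial count
#' model with Bernoulli dropout on marker genes, and deliberately
#' QC-failing cells/genes. Identical config + seed reproduces the identical
#' sample bit for bit.
#'
#' @param domain_width,domain_height Domain extent in um.
#' @param n_reference Number of reference (ARG1+) cells.
#' @param n_fib Number of fibroblasts.
#' @param frac_il6pos Fraction of fibroblasts that are IL6+.
#' @param n_other Number of non-fibroblast, non-reference cells.
#' @param enrichment_radius Radius (um) of the planted clusters (default 25,
#'   the paracrine scale).
#' @param enrichment_frac Fraction of IL6+ fibroblasts placed clustered
#'   around reference cells; 0 gives complete spatial randomness.
#' @param count_means Named list (per type) of named gene mean vectors; see
#'   [default_count_means()].
#' @param nb_dispersion Negative-binomial dispersion alpha (variance
#'   `mu + alpha * mu^2`); 0 gives Poisson counts.
#' @param dropout_prob Probability a truly expressed marker gene reads zero.
#' @param n_qc_fail_cells Cells appended with forced total counts below 10.
#' @param n_rare_genes Genes appended detected in fewer than 5 cells.
#' @param seed Integer seed.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(domain_width = 1000, domain_height = 1000,
                              n_reference = 100, n_fib = 1000,
                              frac_il6pos = 0.5, n_other = 900,
                              enrichment_radius = 25, enrichment_frac = 0,
                              count_means = default_count_means(),
                              nb_dispersion = 0.5, dropout_prob = 0.1,
                              n_qc_fail_cells = 20, n_rare_genes = 3,
                              seed = 1) {
  cfg <- list(domain_width = domain_width, domain_height = domain_height,
              n_reference = n_reference, n_fib = n_fib,
              frac_il6pos = frac_il6pos, n_other = n_other,
              enrichment_radius = enrichment_radius,
              enrichment_frac = enrichment_frac, count_means = count_means,
              nb_dispersion = nb_dispersion, dropout_prob = dropout_prob,
              n_qc_fail_cells = n_qc_fail_cells, n_rare_genes = n_rare_genes,
              seed = seed)
  counts_ok <- function(v) length(v) == 1 && !is.na(v) && v >= 0 &&
    v == round(v)
  frac_ok <- function(v) length(v) == 1 && !is.na(v) && v >= 0 && v <= 1
  if (!(domain_width > 0 && domain_height > 0))
    prox_error("bad_config", "domain area must be positive")
  if (!all(vapply(cfg[c("n_reference", "n_fib", "n_other",
                        "n_qc_fail_cells", "n_rare_genes")],
                  counts_ok, logical(1))))
    prox_error("bad_config", "cell/gene counts must be nonnegative integers")
  if (!frac_ok(frac_il6pos) || !frac_ok(enrichment_frac) ||
      !frac_ok(dropout_prob))
    prox_error("bad_config", "fractions must lie in [0, 1]")
  if (enrichment_radius <= 0 || nb_dispersion < 0)
    prox_error("bad_config",
               "enrichment_radius must be positive, dispersion nonnegative")
  for (ty in names(count_means)) {
    mu <- count_means[[ty]]
    if (is.null(names(mu)) || any(mu < 0))
      prox_error("bad_config", "count_means must be named, nonnegative")
    if (!length(setdiff(names(mu), MARKER_GENES)))
      prox_error("bad_config", sprintf(
        "type '%s' needs at least one non-marker gene for depth top-up", ty))
  }
  structure(cfg, class = "simulation_config")
}

# Zero-truncated NB/Poisson draw: redraw zeros so an expressing cell always
# has a nonzero marker count before dropout.
rcount <- function(k, mu, disp, truncate = FALSE) {
  draw <- function(m) if (disp > 0) rnbinom(m, size = 1 / disp, mu = mu)
  else rpois(m, mu)
  x <- draw(k)
  if (truncate && k > 0) {
    for (it in seq_len(1000)) {
      z <- which(x == 0)
      if (!length(z)) break
      x[z] <- draw(length(z))
    }
    x[x == 0] <- 1L
  }
  x
}

#' Simulate one spatial sample with known ground truth
#'
#' Places reference cells, fibroblasts and other cells in the rectangular
#' domain (reference/other/IL6- fibroblasts uniformly; a fraction
#' `enrichment_frac` of IL6+ fibroblasts uniformly within
#' `enrichment_radius` of a uniformly chosen reference cell, with offsets
#' falling outside the domain rejection-sampled), then draws counts per cell
#' type from the negative-binomial model. Marker genes of each expressing
#' type are zero-truncated and then subjected to Bernoulli dropout, so
#' marker positivity matches the ground-truth type except where dropout
#' struck. Regular cells are depth-topped-up (on a background gene) to at
#' least 10 total counts; `n_qc_fail_cells` extra cells are forced below 10
#' and `n_rare_genes` extra genes are detected in fewer than 5 cells.
#'
#' @param config A [simulation_config()].
#' @return A list with `map` (a [cell_map]) and `truth` (data frame:
#'   `cell_id`, `true_type`, `placement` = background|clustered,
#'   `parent_id`, `qc_fail`).
#' @export
simulate_cell_map <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  W <- config$domain_width; H <- config$domain_height
  n_pos <- round(config$frac_il6pos * config$n_fib)
  n_neg <- config$n_fib - n_pos
  n_clust <- round(config$enrichment_frac * n_pos)
  if (n_clust > 0 && config$n_reference == 0)
    prox_error("inconsistent_config",
               "clustered placement requested with no reference cells")

  with_seed(config$seed, {
    unif_xy <- function(k) cbind(runif(k, 0, W), runif(k, 0, H))
    ref_xy <- unif_xy(config$n_reference)

    parent <- integer(0)
    clust_xy <- matrix(numeric(0), 0, 2)
    if (n_clust > 0) {
      parent <- sample.int(config$n_reference, n_clust, replace = TRUE)
      clust_xy <- t(vapply(parent, function(p) {
        repeat {
          r <- config$enrichment_radius * sqrt(runif(1))
          th <- runif(1, 0, 2 * pi)
          xy <- ref_xy[p, ] + r * c(cos(th), sin(th))
          if (xy[1] >= 0 && xy[1] <= W && xy[2] >= 0 && xy[2] <= H)
            return(xy)
        }
      }, numeric(2)))
    }

    blocks <- list(
      reference  = list(n = config$n_reference, xy = ref_xy),
      il6pos_fib = list(n = n_pos,
                        xy = rbind(clust_xy, unif_xy(n_pos - n_clust))),
      il6neg_fib = list(n = n_neg, xy = unif_xy(n_neg)),
      other      = list(n = config$n_other, xy = unif_xy(config$n_other)))

    types <- rep(names(blocks), vapply(blocks, `[[`, 0, "n"))
    xy <- do.call(rbind, lapply(blocks, `[[`, "xy"))
    n_reg <- length(types)
    placement <- rep("background", n_reg)
    parent_id <- rep(NA_integer_, n_reg)
    if (n_clust > 0) {
      ip <- which(types == "il6pos_fib")[seq_len(n_clust)]
      placement[ip] <- "clustered"
      parent_id[ip] <- parent
    }

    genes <- unique(unlist(lapply(config$count_means, names)))
    counts <- matrix(0L, n_reg, length(genes), dimnames = list(NULL, genes))
    for (ty in unique(types)) {
      rows <- which(types == ty)
      mu <- config$count_means[[ty]]
      if (is.null(mu))
        prox_error("bad_config",
                   sprintf("no count_means entry for type '%s'", ty))
      for (g in names(mu)) {
        is_marker <- g %in% MARKER_GENES
        x <- rcount(length(rows), mu[[g]], config$nb_dispersion,
                    truncate = is_marker)
        if (is_marker && config$dropout_prob > 0)
          x[rbinom(length(x), 1, config$dropout_prob) == 1] <- 0L
        counts[rows, g] <- x
      }
      # depth top-up so only forced QC-fail cells sit below the threshold
      topup_gene <- setdiff(names(mu), MARKER_GENES)[1]
      tot <- rowSums(counts[rows, , drop = FALSE])
      low <- tot < QC_MIN_TOTAL
      counts[rows[low], topup_gene] <-
        counts[rows[low], topup_gene] + (QC_MIN_TOTAL - tot[low])
    }

    # QC-failing cells: uniform placement, tiny totals on background genes
    n_fail <- config$n_qc_fail_cells
    if (n_fail > 0) {
      bg_genes <- setdiff(genes, c(MARKER_GENES, "EPCAM"))
      if (!length(bg_genes)) bg_genes <- setdiff(genes, MARKER_GENES)
      fail_tot <- sample(3:(QC_MIN_TOTAL - 1), n_fail, replace = TRUE)
      fail_counts <- matrix(0L, n_fail, length(genes),
                            dimnames = list(NULL, genes))
      for (i in seq_len(n_fail))
        fail_counts[i, bg_genes] <-
          as.integer(rmultinom(1, fail_tot[i],
                               rep(1, length(bg_genes))))
      counts <- rbind(counts, fail_counts)
      xy <- rbind(xy, unif_xy(n_fail))
      types <- c(types, rep("other", n_fail))
      placement <- c(placement, rep("background", n_fail))
      parent_id <- c(parent_id, rep(NA_integer_, n_fail))
    }
    qc_fail <- c(rep(FALSE, n_reg), rep(TRUE, n_fail))
    n <- nrow(counts)

    # sparsely detected genes, below the 5-cells/gene filter
    if (config$n_rare_genes > 0) {
      rare <- sprintf("RAREG%02d", seq_len(config$n_rare_genes))
      rc <- matrix(0L, n, config$n_rare_genes, dimnames = list(NULL, rare))
      regular <- which(!qc_fail)
      for (j in seq_len(config$n_rare_genes)) {
        k <- sample(1:4, 1)
        rc[sample(regular, min(k, length(regular))), j] <- 1L
      }
      counts <- cbind(counts, rc)
      genes <- c(genes, rare)
    }

    ids <- sprintf("cell_%05d", seq_len(n))
    truth <- data.frame(
      cell_id = ids, true_type = types, placement = placement,
      parent_id = ifelse(is.na(parent_id), NA_character_,
                         sprintf("cell_%05d", parent_id)),
      qc_fail = qc_fail, stringsAsFactors = FALSE)
    list(map = cell_map(ids, xy[, 1], xy[, 2], colnames(counts), counts),
         truth = truth)
  })
}

#' Monte-Carlo oracle for the planted co-occurrence ratio
#'
#' Independently estimates the expected inclusive co-occurrence ratio under
#' a [simulation_config()] by simulating `n_reps` replicate samples and
#' computing the ratio on each with the exhaustive [brute_force_ratio()]
#' path, using the ground-truth labels (QC-fail cells excluded). Serves as
#' the reference band in planted-enrichment recovery tests; it never touches
#' the accelerated estimator.
#'
#' @param config A [simulation_config()]; replicate seeds are derived from
#'   `config$seed` with [derive_seed()].
#' @param radius Radius in um (default 25).
#' @param n_reps Number of replicates (>= 20).
#' @param exp_category Category whose ratio is tracked (default
#'   `"il6pos_fib"`).
#' @return A list with `mean`, `se` (Monte-Carlo standard error), `ratios`
#'   and `n_reps`.
#' @export
planted_ratio_oracle <- function(config, radius = 25, n_reps = 50,
                                 exp_category = "il6pos_fib") {
  stopifnot(inherits(config, "simulation_config"))
  if (n_reps < 20)
    prox_error("bad_n_reps", "oracle needs at least 20 replicates")
  ratios <- vapply(seq_len(n_reps), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, i)
    sim <- simulate_cell_map(cfg)
    keep <- !sim$truth$qc_fail
    brute_force_ratio(coords_matrix(sim$map)[keep, , drop = FALSE],
                      sim$truth$true_type[keep], exp_category,
                      radius)$ratio
  }, numeric(1))
  list(mean = mean(ratios), se = sd(ratios) / sqrt(n_reps),
       ratios = ratios, n_reps = n_reps)
}

#' Simulate a cohort of samples
#'
#' Generates `n_samples` independent samples sharing one configuration, with
#' per-sample seeds derived deterministically from `config$seed`. The
#' planted enrichment of IL6+ fibroblasts is set by `effect_b_minus_c`
#' (their clustered fraction; IL6- fibroblasts are always uniform), so 0
#' gives a null cohort and values near 1 a strong between-category
#' difference.
#'
#' @param config A [simulation_config()].
#' @param n_samples Number of samples (>= 2); default 9.
#' @param effect_b_minus_c Clustered fraction of IL6+ fibroblasts applied to
#'   every sample (overrides `config$enrichment_frac`).
#' @return Named list (`sample_01`, ...) of `list(map, truth)` samples.
#' @export
simulate_cohort <- function(config, n_samples = 9,
                            effect_b_minus_c = config$enrichment_frac) {
  stopifnot(inherits(config, "simulation_config"))
  if (n_samples < 2)
    prox_error("bad_n_samples", "a cohort needs at least 2 samples")
  out <- lapply(seq_len(n_samples), function(i) {
    cfg <- config
    cfg$enrichment_frac <- effect_b_minus_c
    cfg <- do.call(simulation_config, cfg[setdiff(names(cfg), "")])
    cfg$seed <- derive_seed(config$seed, i)
    simulate_cell_map(cfg)
  })
  names(out) <- sprintf("sample_%02d", seq_len(n_samples))
  out
}
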