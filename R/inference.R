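#' Subsampling min/max interval for the co-occurrence ratio
#'
#' Draws `n_subsamples` random subsamples of the QC-passing cells (uniformly,
#' without replacement, all categories jointly, size
#' `floor(fraction * n)`), recomputes the inclusive co-occurrence ratio on
#' each, and reports the minimum and maximum of the subsample ratios as the
#' interval bounds. Note this is a range statistic over 5 half-data
#' replicates, not a calibrated confidence interval; no coverage is claimed.
#' A subsample that retains no reference cell (or yields an undefined ratio)
#' is redrawn, up to `max_retries` attempts.
#'
#' @inheritParams cooccurrence_ratio
#' @param fraction Fraction of cells per subsample, in (0, 1] (default 0.5).
#' @param n_subsamples Number of subsamples (default 5).
#' @param seed Integer seed; fixed seed reproduces the interval exactly.
#' @param max_retries Redraw budget per subsample (default 100).
#' @return A `subsample_ci`: list with `ratios` (length `n_subsamples`),
#'   `ci_low` (min), `ci_high` (max), plus the parameters.
#' @export
subsample_ci <- function(coords, labels, exp_category, radius = 25,
                         fraction = 0.5, n_subsamples = 5, seed = 1,
                         max_retries = 100) {
  coords <- resolve_coords(coords)
  n <- nrow(coords)
  labels <- as_label_factor(labels, n)
  if (fraction <= 0 || fraction > 1)
    prox_error("bad_fraction", "fraction must be in (0, 1]")
  if (n_subsamples < 2)
    prox_error("bad_n_subsamples", "need at least 2 subsamples")
  size <- max(1L, floor(fraction * n))
  ratios <- with_seed(seed, {
    vapply(seq_len(n_subsamples), function(i) {
      for (try in seq_len(max_retries)) {
        idx <- if (size == n) seq_len(n) else sample.int(n, size)
        if (!any(labels[idx] == "reference")) next
        r <- cooccurrence_ratio(coords[idx, , drop = FALSE], labels[idx],
                                exp_category, radius)
        if (!r$undefined) return(r$ratio)
      }
      prox_error("sparse_reference",
                 "reference cells too sparse: subsample retries exhausted")
    }, numeric(1))
  })
  structure(list(ratios = ratios, ci_low = min(ratios), ci_high = max(ratios),
                 exp_category = exp_category, radius = radius,
                 fraction = fraction, n_subsamples = n_subsamples,
                 seed = seed),
            class = "subsample_ci")
}

#' @export
print.subsample_ci <- function(x, ...) {
  cat(sprintf("subsampling interval (%d x %.0f%%) for '%s' at %g um\n",
              x$n_subsamples, 100 * x$fraction, x$exp_category, x$radius))
  cat(sprintf("  ratios: %s\n", paste(signif(x$ratios, 6), collapse = ", ")))
  cat(sprintf("  [min, max] = [%.6g, %.6g]\n", x$ci_low, x$ci_high))
  invisible(x)
}

#' Paired Student's t test on per-sample ratio pairs
#'
#' Classical two-sided paired t test on the differences `ratios_b -
#' ratios_c`, one pair per sample, with `n - 1` degrees of freedom. Two
#' degenerate cases are resolved explicitly rather than raised: all
#' differences identical and zero gives `t = 0, p = 1`; identical and
#' nonzero gives `p = 0` with `degenerate = TRUE` (the statistic is
#' unbounded).
#'
#' @param ratios_b,ratios_c Numeric vectors of equal length >= 2, aligned by
#'   sample.
#' @return A `paired_t_result`: list with `statistic`, `df`, `p_value`,
#'   `mean_diff`, `pairs` (two-column matrix) and `degenerate`.
#' @examples
#' paired_t_test(c(1.5, 1.2, 1.3), c(1.0, 0.9, 1.1))
#' @export
paired_t_test <- function(ratios_b, ratios_c) {
  if (length(ratios_b) != length(ratios_c))
    prox_error("length_mismatch", "paired vectors must have equal length")
  if (length(ratios_b) < 2)
    prox_error("too_few_pairs", "paired t test needs at least 2 pairs")
  if (anyNA(ratios_b) || anyNA(ratios_c))
    prox_error("na_ratios", "paired t test input contains NA")
  d <- ratios_b - ratios_c
  n <- length(d)
  if (sd(d) == 0) {
    if (mean(d) == 0)
      out <- list(statistic = 0, df = n - 1L, p_value = 1,
                  degenerate = FALSE)
    else
      out <- list(statistic = sign(mean(d)) * Inf, df = n - 1L, p_value = 0,
                  degenerate = TRUE)
  } else {
    tt <- t.test(ratios_b, ratios_c, paired = TRUE)
    out <- list(statistic = unname(tt$statistic),
                df = as.integer(unname(tt$parameter)),
                p_value = tt$p.value, degenerate = FALSE)
  }
  structure(c(out, list(mean_diff = mean(d),
                        pairs = cbind(b = ratios_b, c = ratios_c))),
            class = "paired_t_result")
}

#' @export
print.paired_t_result <- function(x, ...) {
  cat(sprintf("paired t test on %d sample pairs\n", nrow(x$pairs)))
  cat(sprintf("  mean difference (b - c): %.6g\n", x$mean_diff))
  cat(sprintf("  t = %.6g, df = %d, two-sided p = %.6g%s\n",
              x$statistic, x$df, x$p_value,
              if (x$degenerate) " (zero-variance differences)" else ""))
  invisible(x)
}

#' Full cohort proximity analysis
#'
#' Runs the whole per-sample pipeline — QC filter, marker categorization,
#' inclusive co-occurrence ratio for the IL6+ and IL6- fibroblast categories
#' at each grid radius, and (optionally) the subsampling min/max interval —
#' then compares the two categories' ratios across samples at the primary
#' radius with a paired Student's t test.
#'
#' @param samples Named list of [cell_map] objects, one per sample/patient.
#' @param rule A [category_rule()].
#' @param radii Radial grid in um (default 25).
#' @param primary_radius Radius at which the paired test is run (default
#'   25, the paracrine scale).
#' @param min_counts_per_cell,min_cells_per_gene QC thresholds (defaults 10
#'   and 5).
#' @param categories The two categories compared (default
#'   `c("il6pos_fib", "il6neg_fib")`; the paired test is first minus
#'   second).
#' @param subsample_fraction,n_subsamples Subsampling interval parameters
#'   (defaults 0.5 and 5); set `compute_ci = FALSE` to skip intervals.
#' @param compute_ci Compute subsampling intervals per (sample, category,
#'   radius) (default `TRUE`).
#' @param seed Base seed; per-sample subsampling seeds are derived with
#'   [derive_seed()].
#' @return A `cohort_result`: list with `results` (one row per sample x
#'   category x radius: `sample`, `category`, `radius`, `numerator`,
#'   `denominator`, `ratio`, `n_centers`, `ci_low`, `ci_high`), `paired`
#'   (a `paired_t_result`), `primary_radius` and `categories`.
#' @export
run_cohort_analysis <- function(samples, rule = category_rule(), radii = 25,
                                primary_radius = 25,
                                min_counts_per_cell = 10,
                                min_cells_per_gene = 5,
                                categories = c("il6pos_fib", "il6neg_fib"),
                                subsample_fraction = 0.5, n_subsamples = 5,
                                compute_ci = TRUE, seed = 1) {
  if (length(samples) < 2)
    prox_error("too_few_samples", "cohort analysis needs at least 2 samples")
  if (!primary_radius %in% radii)
    radii <- sort(c(radii, primary_radius))
  if (is.null(names(samples)))
    names(samples) <- sprintf("sample_%02d", seq_along(samples))
  if (length(categories) != 2)
    prox_error("bad_categories", "exactly two categories are compared")

  rows <- list()
  for (si in seq_along(samples)) {
    sid <- names(samples)[si]
    res <- tryCatch({
      m <- qc_filter(samples[[si]], min_counts_per_cell, min_cells_per_gene)
      lab <- assign_categories(m, rule)
      xy <- coords_matrix(m)
      per <- list()
      for (r in radii) for (ci in seq_along(categories)) {
        cat_i <- categories[ci]
        cr <- cooccurrence_ratio(xy, lab, cat_i, r)
        band <- c(NA_real_, NA_real_)
        if (compute_ci) {
          sc <- subsample_ci(xy, lab, cat_i, r,
                             fraction = subsample_fraction,
                             n_subsamples = n_subsamples,
                             seed = derive_seed(seed, si * 1000 + ci * 100 +
                                                  match(r, radii)))
          band <- c(sc$ci_low, sc$ci_high)
        }
        per[[length(per) + 1L]] <- data.frame(
          sample = sid, category = cat_i, radius = r,
          numerator = cr$numerator, denominator = cr$denominator,
          ratio = cr$ratio, n_centers = cr$n_centers,
          ci_low = band[1], ci_high = band[2], stringsAsFactors = FALSE)
      }
      do.call(rbind, per)
    }, proxratio_error = function(e) {
      prox_error("sample_failed",
                 sprintf("sample '%s': %s", sid, conditionMessage(e)))
    })
    rows[[si]] <- res
  }
  results <- do.call(rbind, rows)

  prim <- results[results$radius == primary_radius, ]
  rb <- prim$ratio[prim$category == categories[1]]
  rc <- prim$ratio[prim$category == categories[2]]
  paired <- paired_t_test(rb, rc)
  structure(list(results = results, paired = paired,
                 primary_radius = primary_radius, categories = categories),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  ns <- length(unique(x$results$sample))
  cat(sprintf("cohort proximity analysis: %d samples, primary radius %g um\n",
              ns, x$primary_radius))
  prim <- x$results[x$results$radius == x$primary_radius, ]
  for (cat_i in x$categories) {
    r <- prim$ratio[prim$category == cat_i]
    cat(sprintf("  %s ratio: mean %.4g (range %.4g-%.4g)\n",
                cat_i, mean(r), min(r), max(r)))
  }
  print(x$paired)
  invisible(x)
}

#' @export
summary.cohort_result <- function(object, ...) {
  prim <- object$results[object$results$radius == object$primary_radius, ]
  wide <- stats::reshape(
    prim[, c("sample", "category", "ratio")], direction = "wide",
    idvar = "sample", timevar = "category")
  names(wide) <- sub("^ratio\\.", "", names(wide))
  wide$difference <- wide[[object$categories[1]]] - wide[[object$categories[2]]]
  structure(list(per_sample = wide, paired = object$paired,
                 primary_radius = object$primary_radius),
            class = "summary.cohort_result")
}

#' @export
print.summary.cohort_result <- function(x, ...) {
  cat(sprintf("per-sample ratios at %g um:\n", x$primary_radius))
  print(x$per_sample, row.names = FALSE)
  print(x$paired)
  invisible(x)
}
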