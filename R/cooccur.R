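#' Cell categories used by the proximity statistic
#'
#' The four mutually exclusive labels assigned by [assign_categories()]:
#' `reference` (ARG1+ cells, the conditioning category), `il6pos_fib`
#' (IL6+ fibroblasts), `il6neg_fib` (IL6- fibroblasts) and `other`.
#' @export
CATEGORY_LEVELS <- c("reference", "il6pos_fib", "il6neg_fib", "other")

# Normalize a label vector to a factor over CATEGORY_LEVELS (extra levels kept).
as_label_factor <- function(labels, n) {
  if (length(labels) != n)
    prox_error("label_length", "one label per cell is required")
  if (!is.factor(labels)) {
    lev <- union(CATEGORY_LEVELS, unique(as.character(labels)))
    labels <- factor(as.character(labels), levels = lev)
  }
  if (anyNA(labels)) prox_error("label_na", "labels contain NA")
  labels
}

resolve_coords <- function(coords) {
  if (inherits(coords, "cell_map")) coords <- coords_matrix(coords)
  coords <- as.matrix(coords)
  if (ncol(coords) != 2 || !is.numeric(coords) || !all(is.finite(coords)))
    prox_error("bad_coords", "coords must be a finite numeric n x 2 matrix")
  coords
}

#' Cells within a radial distance of a center cell
#'
#' Returns the indices of every cell whose Euclidean distance to the chosen
#' center is at most `radius` (the closed-ball convention; the center itself
#' is at distance 0 and is always included).
#'
#' @param coords An n x 2 numeric matrix of centroid coordinates (um), or a
#'   [cell_map].
#' @param center_index Index of the center cell.
#' @param radius Search radius in um; positive.
#' @param strict If `TRUE` use the open ball (distance strictly less than
#'   `radius`) instead of the default closed ball.
#' @return Integer vector of cell indices, in increasing order.
#' @examples
#' xy <- cbind(c(0, 10, 100), 0)
#' neighbors_within(xy, 1, 15)  # cells at 0 and 10
#' @export
neighbors_within <- function(coords, center_index, radius, strict = FALSE) {
  coords <- resolve_coords(coords)
  if (radius <= 0) prox_error("bad_radius", "radius must be positive")
  dx <- coords[, 1] - coords[center_index, 1]
  dy <- coords[, 2] - coords[center_index, 2]
  d2 <- dx * dx + dy * dy
  which(if (strict) d2 < radius * radius else d2 <= radius * radius)
}

# Per-center (exp count, total count) within the ball, via the grid kernel.
# Returns list(exp =, tot =) integer vectors of length n.
ball_counts <- function(coords, labels, exp_category, radius, strict = FALSE) {
  lab_int <- as.integer(labels)
  cnt <- label_counts_within(coords[, 1], coords[, 2], lab_int,
                             nlevels(labels), radius, strict)
  k <- match(exp_category, levels(labels))
  list(exp = cnt[, k], tot = as.integer(rowSums(cnt)))
}

# Build a cooccur_result from per-center counts. Centers with an empty
# neighborhood (total 0, possible in annulus mode) are dropped from the
# averages; the mean of per-center fractions -- not pooled counts -- is the
# estimator, for both the conditional numerator and the everywhere-centered
# denominator.
ratio_from_counts <- function(exp_cnt, tot_cnt, is_ref, exp_category,
                              radius, mode) {
  keep <- tot_cnt > 0L
  frac <- exp_cnt[keep] / tot_cnt[keep]
  ref_keep <- is_ref[keep]
  n_centers <- sum(ref_keep)
  if (n_centers == 0L)
    prox_error("no_reference_centers",
               "no reference cell has a nonempty neighborhood at this radius")
  numerator <- mean(frac[ref_keep])
  denominator <- mean(frac)
  undefined <- denominator == 0
  structure(
    list(radius = radius, exp_category = exp_category,
         numerator = numerator, denominator = denominator,
         ratio = if (undefined) NA_real_ else numerator / denominator,
         n_centers = n_centers, mode = mode, undefined = undefined),
    class = "cooccur_result")
}

#' Co-occurrence probability ratio at one radial distance
#'
#' The proximity statistic: for every reference cell, the fraction of all
#' cells within `radius` (center included, closed ball) that belong to
#' `exp_category`; the numerator P(exp | reference) is the mean of these
#' fractions over reference cells, and the denominator P(exp) is the mean of
#' the same per-center fraction computed around every cell in the sample.
#' Values above 1 indicate spatial enrichment of `exp_category` near the
#' reference cells. `mode = "annulus"` reproduces the legacy discrete-bin
#' variant; for a single radius its bin is the full ball `[0, radius]`, so it
#' differs from inclusive mode only on a radial grid
#' (see [cooccurrence_profile()]).
#'
#' @param coords An n x 2 coordinate matrix (um) or a [cell_map].
#' @param labels Per-cell category labels (factor or character); level
#'   `"reference"` marks the conditioning cells.
#' @param exp_category The category whose enrichment is measured
#'   (e.g. `"il6pos_fib"`).
#' @param radius Radial distance in um (default 25, the paracrine scale).
#' @param mode `"inclusive"` (all cells within the radius) or `"annulus"`.
#' @param include_center Count the center cell in its own neighborhood
#'   (default `TRUE`).
#' @param strict Use an open ball instead of the default closed ball.
#' @return A `cooccur_result`: list with `radius`, `exp_category`,
#'   `numerator`, `denominator`, `ratio`, `n_centers`, `mode`, `undefined`.
#'   When the denominator is zero the ratio is `NA` and `undefined` is
#'   `TRUE`; this is reported, not raised.
#' @examples
#' xy <- cbind(c(0, 10, 100), 0)
#' lab <- c("reference", "il6pos_fib", "il6neg_fib")
#' cooccurrence_ratio(xy, lab, "il6pos_fib", radius = 15)
#' @export
cooccurrence_ratio <- function(coords, labels, exp_category, radius = 25,
                               mode = c("inclusive", "annulus"),
                               include_center = TRUE, strict = FALSE) {
  mode <- match.arg(mode)
  coords <- resolve_coords(coords)
  labels <- as_label_factor(labels, nrow(coords))
  if (!exp_category %in% levels(labels))
    prox_error("unknown_category",
               sprintf("unknown category '%s'", exp_category))
  is_ref <- labels == "reference"
  if (!any(is_ref)) prox_error("no_reference", "sample has no reference cells")
  if (radius <= 0) prox_error("bad_radius", "radius must be positive")
  bc <- ball_counts(coords, labels, exp_category, radius, strict)
  exp_cnt <- bc$exp
  tot_cnt <- bc$tot
  if (!include_center) {
    exp_cnt <- exp_cnt - as.integer(labels == exp_category)
    tot_cnt <- tot_cnt - 1L
  }
  ratio_from_counts(exp_cnt, tot_cnt, is_ref, exp_category, radius, mode)
}

#' Co-occurrence profile over a radial grid
#'
#' Evaluates the co-occurrence probability ratio for every combination of
#' grid radius and category. In inclusive mode each radius is self-contained
#' and identical to a single-radius [cooccurrence_ratio()] call. In annulus
#' mode the neighborhood at grid radius r_k is the half-open annulus
#' (r_{k-1}, r_k] (first bin `[0, r_1]`, center included); centers whose
#' annulus is empty are excluded from both averages at that radius.
#'
#' @inheritParams cooccurrence_ratio
#' @param grid Strictly increasing positive radii (um).
#' @param categories Categories to profile; defaults to the two fibroblast
#'   categories.
#' @return A data frame with one row per (radius, category): columns
#'   `radius`, `category`, `numerator`, `denominator`, `ratio`, `n_centers`,
#'   `mode`, `undefined`.
#' @export
cooccurrence_profile <- function(coords, labels, grid = 25,
                                 categories = c("il6pos_fib", "il6neg_fib"),
                                 mode = c("inclusive", "annulus"),
                                 include_center = TRUE, strict = FALSE) {
  mode <- match.arg(mode)
  grid <- as.numeric(grid)
  if (length(grid) == 0 || any(grid <= 0) || is.unsorted(grid, strictly = TRUE))
    prox_error("bad_grid", "grid must be strictly increasing positive radii")
  coords <- resolve_coords(coords)
  labels <- as_label_factor(labels, nrow(coords))
  is_ref <- labels == "reference"
  if (!any(is_ref)) prox_error("no_reference", "sample has no reference cells")

  rows <- list()
  prev <- NULL  # annulus mode: per-label counts at the previous radius
  for (r in grid) {
    cnt <- label_counts_within(coords[, 1], coords[, 2], as.integer(labels),
                               nlevels(labels), r, strict)
    shell <- if (mode == "annulus" && !is.null(prev)) cnt - prev else cnt
    for (cat in categories) {
      if (!cat %in% levels(labels))
        prox_error("unknown_category", sprintf("unknown category '%s'", cat))
      k <- match(cat, levels(labels))
      exp_cnt <- shell[, k]
      tot_cnt <- as.integer(rowSums(shell))
      if (!include_center && (mode == "inclusive" || is.null(prev))) {
        exp_cnt <- exp_cnt - as.integer(labels == cat)
        tot_cnt <- tot_cnt - 1L
      }
      res <- ratio_from_counts(exp_cnt, tot_cnt, is_ref, cat, r, mode)
      rows[[length(rows) + 1L]] <- data.frame(
        radius = res$radius, category = res$exp_category,
        numerator = res$numerator, denominator = res$denominator,
        ratio = res$ratio, n_centers = res$n_centers,
        mode = res$mode, undefined = res$undefined,
        stringsAsFactors = FALSE)
    }
    if (mode == "annulus") prev <- cnt
  }
  do.call(rbind, rows)
}

#' Exhaustive-search oracle for the inclusive co-occurrence ratio
#'
#' Independent O(n^2) implementation of the inclusive-mode statistic built on
#' a full pairwise distance computation, sharing no code with the accelerated
#' grid-index path. Used as the reference in equivalence tests; guarded to
#' small samples.
#'
#' @inheritParams cooccurrence_ratio
#' @param max_n Guard on sample size (default 5000).
#' @return A `cooccur_result`, bitwise-identical to
#'   `cooccurrence_ratio(..., mode = "inclusive")` on the same input.
#' @export
brute_force_ratio <- function(coords, labels, exp_category, radius = 25,
                              include_center = TRUE, strict = FALSE,
                              max_n = 5000) {
  coords <- resolve_coords(coords)
  n <- nrow(coords)
  if (n > max_n)
    prox_error("oracle_guard",
               sprintf("brute-force oracle limited to %d cells", max_n))
  labels <- as_label_factor(labels, n)
  if (!exp_category %in% levels(labels))
    prox_error("unknown_category",
               sprintf("unknown category '%s'", exp_category))
  is_ref <- labels == "reference"
  if (!any(is_ref)) prox_error("no_reference", "sample has no reference cells")
  if (radius <= 0) prox_error("bad_radius", "radius must be positive")

  dx <- outer(coords[, 1], coords[, 1], "-")
  dy <- outer(coords[, 2], coords[, 2], "-")
  d2 <- dx * dx + dy * dy
  within <- if (strict) d2 < radius * radius else d2 <= radius * radius
  if (!include_center) diag(within) <- FALSE
  is_exp <- labels == exp_category
  exp_cnt <- as.integer(within %*% is_exp)
  tot_cnt <- as.integer(rowSums(within))

  # Final averaging duplicated on purpose: the oracle shares no code with the
  # accelerated path beyond base R.
  keep <- tot_cnt > 0L
  frac <- exp_cnt[keep] / tot_cnt[keep]
  ref_keep <- is_ref[keep]
  if (!any(ref_keep))
    prox_error("no_reference_centers",
               "no reference cell has a nonempty neighborhood at this radius")
  numerator <- mean(frac[ref_keep])
  denominator <- mean(frac)
  undefined <- denominator == 0
  structure(
    list(radius = radius, exp_category = exp_category,
         numerator = numerator, denominator = denominator,
         ratio = if (undefined) NA_real_ else numerator / denominator,
         n_centers = sum(ref_keep), mode = "inclusive",
         undefined = undefined),
    class = "cooccur_result")
}

#' @export
print.cooccur_result <- function(x, ...) {
  cat(sprintf("co-occurrence ratio (%s mode) at %g um\n", x$mode, x$radius))
  cat(sprintf("  category: %s\n", x$exp_category))
  cat(sprintf("  P(exp | reference) = %.6g over %d reference centers\n",
              x$numerator, x$n_centers))
  cat(sprintf("  P(exp)             = %.6g\n", x$denominator))
  if (x$undefined) cat("  ratio: undefined (zero denominator)\n")
  else cat(sprintf("  ratio: %.6g\n", x$ratio))
  invisible(x)
}
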