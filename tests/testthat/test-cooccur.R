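test_that("neighbors_within uses the closed-ball convention", {
  xy <- cbind(c(0, 10, 100), 0)
  expect_identical(neighbors_within(xy, 1, 15), c(1L, 2L))
  expect_identical(neighbors_within(xy, 1, 1000), 1:3)
  # boundary tie at distance exactly equal to the radius is included
  expect_identical(neighbors_within(xy, 1, 10), c(1L, 2L))
  expect_identical(neighbors_within(xy, 1, 10, strict = TRUE), 1L)
})

test_that("the 3-cell line toy reproduces the hand-enumerated ratios", {
  t3 <- toy3()
  r15 <- cooccurrence_ratio(t3$xy, t3$labels, "il6pos_fib", 15)
  expect_identical(r15$numerator, 0.5)
  expect_identical(r15$denominator, 1 / 3)
  expect_identical(r15$ratio, 1.5)
  expect_identical(r15$n_centers, 1L)
  # radius covering the whole sample: every neighborhood is everything
  expect_identical(cooccurrence_ratio(t3$xy, t3$labels, "il6pos_fib",
                                      200)$ratio, 1)
  # radius 5: the reference neighborhood is itself only
  r5 <- cooccurrence_ratio(t3$xy, t3$labels, "il6pos_fib", 5)
  expect_identical(r5$numerator, 0)
  expect_identical(r5$ratio, 0)
})

test_that("degenerate inputs are handled as specified", {
  t3 <- toy3()
  expect_error(cooccurrence_ratio(t3$xy, c("other", "il6pos_fib", "other"),
                                  "il6pos_fib", 15),
               class = "proxratio_no_reference")
  # single reference-only cell: numerator and denominator both zero
  r <- cooccurrence_ratio(cbind(0, 0), "reference", "il6pos_fib", 10)
  expect_true(r$undefined)
  expect_true(is.na(r$ratio))
  b <- brute_force_ratio(cbind(0, 0), "reference", "il6pos_fib", 10)
  expect_true(b$undefined)
  expect_error(cooccurrence_ratio(t3$xy, t3$labels, "nonsense", 15),
               class = "proxratio_unknown_category")
})

test_that("accelerated path equals the brute-force oracle bitwise", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(5:300, 1)
    inst <- random_instance(n, extent = stats::runif(1, 20, 200))
    radius <- stats::runif(1, 1, 150)
    for (cat_i in c("il6pos_fib", "il6neg_fib", "other")) {
      a <- cooccurrence_ratio(inst$xy, inst$labels, cat_i, radius)
      b <- brute_force_ratio(inst$xy, inst$labels, cat_i, radius)
      expect_identical(a$numerator, b$numerator)
      expect_identical(a$denominator, b$denominator)
      expect_identical(a$ratio, b$ratio)
      expect_identical(a$n_centers, b$n_centers)
    }
  }
})

test_that("full coverage gives ratio exactly 1", {
  set.seed(202)
  for (i in 1:20) {
    inst <- random_instance(sample(10:200, 1))
    r <- cooccurrence_ratio(inst$xy, inst$labels, "il6pos_fib",
                            radius = 150)  # > domain diameter 100*sqrt(2)
    expect_true(abs(r$ratio - 1) < 1e-12)
  }
})

test_that("results are exactly invariant under translation and joint scaling", {
  set.seed(303)
  inst <- random_instance(120)
  base <- cooccurrence_ratio(inst$xy, inst$labels, "il6pos_fib", 20)
  for (shift in list(c(137.25, -50), c(-1000, 4.5))) {
    tr <- cooccurrence_ratio(sweep(inst$xy, 2, shift, "+"), inst$labels,
                             "il6pos_fib", 20)
    expect_identical(tr$ratio, base$ratio)
    expect_identical(tr$numerator, base$numerator)
  }
  for (s in c(0.5, 1024, 3.7)) {
    sc <- cooccurrence_ratio(inst$xy * s, inst$labels, "il6pos_fib", 20 * s)
    expect_identical(sc$ratio, base$ratio)
    expect_identical(sc$denominator, base$denominator)
  }
})

test_that("permuting labels over fixed positions centers the ratio on 1", {
  # Geometry chosen so the self-inclusion bias ~E[1/(B+1)] is well below the
  # Monte-Carlo resolution: large balls (most of the domain), few reference
  # cells (noisy per-permutation ratios).
  set.seed(404)
  n <- 250
  xy <- cbind(runif(n, 0, 300), runif(n, 0, 300))
  labels <- c(rep("reference", 4), rep("il6pos_fib", 75),
              rep("other", n - 79))
  ratios <- vapply(1:200, function(i) {
    cooccurrence_ratio(xy, sample(labels), "il6pos_fib", 150)$ratio
  }, numeric(1))
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 1), 2 * se)
})

test_that("profile is consistent with single-radius calls and counts pairs", {
  set.seed(505)
  inst <- random_instance(150)
  prof <- cooccurrence_profile(inst$xy, inst$labels, grid = c(10, 25, 50),
                               categories = c("il6pos_fib", "il6neg_fib"))
  expect_identical(nrow(prof), 6L)
  single <- cooccurrence_ratio(inst$xy, inst$labels, "il6pos_fib", 25)
  row <- prof[prof$radius == 25 & prof$category == "il6pos_fib", ]
  expect_identical(row$ratio, single$ratio)
  expect_identical(row$numerator, single$numerator)
})

test_that("annulus mode matches hand enumeration and drops empty annuli", {
  # reference at 0, il6pos at 10, il6neg at 40, other at 100
  xy <- cbind(c(0, 10, 40, 100), 0)
  labels <- c("reference", "il6pos_fib", "il6neg_fib", "other")
  prof <- cooccurrence_profile(xy, labels, grid = c(15, 50),
                               categories = "il6pos_fib", mode = "annulus")
  # first bin [0, 15]: balls around each center:
  #   ref {ref, pos} -> 1/2; pos {ref, pos} -> 1/2; neg {neg} -> 0;
  #   other {other} -> 0; numerator 1/2, denominator 1/4
  expect_identical(prof$numerator[1], 0.5)
  expect_identical(prof$denominator[1], 0.25)
  expect_identical(prof$ratio[1], 2)
  # annulus (15, 50]: ref {neg}; pos {neg}; neg {ref, pos};
  #   other {} -> dropped from the average
  expect_identical(prof$numerator[2], 0)
  expect_identical(prof$denominator[2], (0 + 0 + 1 / 2) / 3)
  expect_identical(prof$n_centers[2], 1L)
  # 3-cell toy, annulus (15, 50] empty around every center incl. the
  # reference -> no reference center remains
  t3 <- toy3()
  expect_error(cooccurrence_profile(t3$xy, t3$labels, grid = c(15, 50),
                                    categories = "il6pos_fib",
                                    mode = "annulus"),
               class = "proxratio_no_reference_centers")
})

test_that("inclusive and annulus modes differ as documented on a grid", {
  set.seed(606)
  inst <- random_instance(200)
  inc <- cooccurrence_profile(inst$xy, inst$labels, grid = c(10, 40),
                              categories = "il6pos_fib", mode = "inclusive")
  ann <- cooccurrence_profile(inst$xy, inst$labels, grid = c(10, 40),
                              categories = "il6pos_fib", mode = "annulus")
  # first bin identical ([0, r1] in both conventions) ...
  expect_identical(inc$ratio[1], ann$ratio[1])
  # ... later bins differ (ball vs shell)
  expect_false(identical(inc$ratio[2], ann$ratio[2]))
})
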