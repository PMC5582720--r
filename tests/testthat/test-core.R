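test_that("stratify orders categories by ascending mean and reports sums", {
  s <- stratify(c(1, 2, 3, 10), c("A", "B", "B", "A"))
  expect_s3_class(s, "ha_strata")
  expect_identical(s$status, "ok")
  expect_identical(s$order, c("B", "A"))       # means B = 2.5 < A = 5.5
  expect_equal(s$means, c(2.5, 5.5))
  expect_equal(s$sums, c(5, 11))
  expect_equal(s$counts, c(2, 2))
  expect_equal(s$y, 16)
})

test_that("stratify signals the degenerate statuses instead of crashing", {
  # equal sums over equal sizes -> tied means
  expect_identical(stratify(c(1, 4, 2, 3), c("A", "A", "B", "B"))$status,
                   "undefined_tied_means")
  # constant vector forces equal means
  expect_identical(stratify(c(5, 5, 5, 5), c("A", "A", "B", "B"))$status,
                   "undefined_tied_means")
  expect_identical(stratify(c(1, 2, 3), c("A", "A", "A"))$status,
                   "undefined_single_category")
  expect_identical(stratify(c(1, -2, 3), c("A", "B", "A"))$status,
                   "invalid_observations")
  expect_identical(stratify(c(1, 0, 3), c("A", "B", "A"))$status,
                   "invalid_observations")
  # near-ties within the relative tolerance count as tied
  expect_identical(
    stratify(c(1, 1 + 1e-15), c("A", "B"), tie_tol = 1e-12)$status,
    "undefined_tied_means")
})

test_that("prehierarchical mode takes the order as given, unvalidated", {
  obs <- c(10, 9, 2, 1)
  s <- stratify(obs, c("A", "A", "B", "B"), category_order = c("A", "B"))
  expect_identical(s$status, "ok")
  expect_identical(s$order, c("A", "B"))       # despite mean A > mean B
  expect_identical(s$mode, "prehierarchical")
  expect_error(stratify(obs, c("A", "A", "B", "B"),
                        category_order = c("A", "C")),
               "permutation")
})

test_that("boundary decomposition brackets the observed sum by the extremes", {
  obs <- c(1, 2, 3, 10)
  s <- stratify(obs, c("A", "B", "B", "A"))
  d <- boundary_decompose(s, obs, 1)
  expect_equal(d$m, 2L)          # right subset = category A = {1, 10}
  expect_equal(d$r1, 11)
  expect_equal(d$g1, 13)         # two largest: 3 + 10
  expect_equal(d$g2, 3)
  expect_equal(d$btm, 3)         # two smallest: 1 + 2
  expect_equal(d$y, 16)
  expect_true(d$btm <= d$r1 && d$r1 <= d$g1)
  expect_error(boundary_decompose(s, obs, 2), "1..n-1")
})

test_that("fully sorted data sit exactly at the extremes of every boundary", {
  obs <- c(1, 2, 3, 4, 5, 6)
  cats <- rep(c("A", "B", "C"), each = 2)
  s <- stratify(obs, cats)
  for (k in 1:2) {
    d <- boundary_decompose(s, obs, k)
    expect_identical(d$r1, d$g1)               # ascending data: observed = top
  }
  # descending data under a fixed order: observed = bottom
  s2 <- stratify(rev(obs), cats, category_order = c("A", "B", "C"))
  for (k in 1:2) {
    d <- boundary_decompose(s2, rev(obs), k)
    expect_identical(d$r1, d$btm)
  }
})

test_that("distance curve matches the printed fixture and its limits", {
  expect_equal(hierarchical_distance(40, fix1), 1)
  expect_equal(hierarchical_distance(25, fix1), 2.4)
  expect_equal(hierarchical_distance(10, fix1), 8)
  expect_error(hierarchical_distance(0, fix1), "positive")
  expect_error(hierarchical_distance(-3, fix1), "positive")
  expect_error(hierarchical_distance(10, list(g1 = 70, g2 = 0, y = 70)), "g2")
})

test_that("closed-form areas agree with adaptive quadrature on the fixture", {
  W <- area_between(fix1, fix1$btm, fix1$g1)
  R <- area_between(fix1, fix1$btm, fix1$r1)
  expect_equal(W, quad_area(fix1, 10, 40), tolerance = 1e-8)
  expect_equal(R, quad_area(fix1, 10, 25), tolerance = 1e-8)
  expect_equal(W, 89.3875, tolerance = 1e-4)
  expect_equal(R, 65.5205, tolerance = 1e-4)
  expect_equal(area_between(fix1, 17, 17), 0)
  expect_error(area_between(fix1, 0, 10), "positive")
})

test_that("boundary ratio hits its endpoints and the fixture value", {
  d <- c(fix1, list(k = 1L, m = 2L, r2 = 45))
  class(d) <- "ha_boundary"
  expect_equal(boundary_ratio(d), 65.5205 / 89.3875, tolerance = 1e-4)
  d$r1 <- d$g1; expect_equal(boundary_ratio(d), 1)
  d$r1 <- d$btm; expect_equal(boundary_ratio(d), 0)
})

test_that("ha_coefficient reproduces hand-checked single-boundary cases", {
  # observed arrangement already top-sorted -> exactly 1
  r <- ha_coefficient(c(1, 2, 3, 4), c("A", "A", "B", "B"))
  expect_identical(r$status, "ok")
  expect_equal(r$ha_geometric, 1)
  expect_equal(r$ha_arithmetic, 1)

  # y=16, g1=13, g2=3, btm=3, r1=11; checked against quadrature
  r2 <- ha_coefficient(c(1, 2, 3, 10), c("A", "B", "B", "A"))
  d <- list(g1 = 13, g2 = 3, y = 16)
  expect_equal(r2$ha_geometric,
               quad_area(d, 3, 11) / quad_area(d, 3, 13), tolerance = 1e-8)
  expect_equal(r2$ha_geometric, 0.9500, tolerance = 1e-4)

  # two categories: one boundary, both aggregates identical
  expect_identical(r2$ha_geometric, r2$ha_arithmetic)
})

test_that("ha_coefficient propagates statuses and respects the shift opt-in", {
  expect_identical(ha_coefficient(c(1, 4, 2, 3), c("A", "A", "B", "B"))$status,
                   "undefined_tied_means")
  expect_identical(ha_coefficient(c(1, 2), c("A", "A"))$status,
                   "undefined_single_category")
  bad <- ha_coefficient(c(-1, 2, 3, 4), c("A", "A", "B", "B"))
  expect_identical(bad$status, "invalid_observations")
  expect_true(is.na(bad$ha_geometric))

  # opt-in shift makes nonpositive inputs computable (and is logged)
  options(hacoef.verbose = TRUE)
  expect_message(
    shifted <- ha_coefficient(c(-1, 2, 3, 4), c("A", "A", "B", "B"),
                              shift_nonpositive = TRUE),
    "shifting")
  options(hacoef.verbose = FALSE)
  expect_identical(shifted$status, "ok")
  expect_true(shifted$ha_geometric > 0 && shifted$ha_geometric <= 1)
})

test_that("worked 7-member example realizes the printed fixture end to end", {
  s <- stratify(fix1_obs, fix1_cats)
  d <- boundary_decompose(s, fix1_obs, 1)
  expect_equal(unclass(d)[c("g1", "g2", "y", "btm", "r1")],
               fix1[c("g1", "g2", "y", "btm", "r1")])
  r <- ha_coefficient(fix1_obs, fix1_cats)
  expect_equal(r$ha_geometric, 0.7330, tolerance = 1e-4)
})
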