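# Mamdani core: membership algebra, weighted firing, implication,
# aggregation, centroid defuzzification, and the full inference pass.

test_that("trapezoidal membership is piecewise linear with unit plateau", {
  mf <- trapmf(0, 1, 2, 3)
  expect_equal(membership(mf, 1.5), 1)
  expect_equal(membership(mf, 0.5), 0.5)
  expect_equal(membership(mf, -1), 0)
  expect_equal(membership(mf, 3.5), 0)
  expect_equal(membership(mf, 2.25), 0.75)
  # vectorised, bounded, continuous on a fine grid
  x <- seq(-1, 4, length.out = 5001)
  y <- membership(mf, x)
  expect_true(all(y >= 0 & y <= 1))
  expect_lt(max(abs(diff(y))), 2e-3)
  # degenerate shoulders are crisp
  expect_equal(membership(trapmf(0, 0, 1, 1), c(0, 1)), c(1, 1))
  expect_error(trapmf(1, 0, 2, 3), "a <= b")
})

test_that("rule activation is weight times the min of antecedent degrees", {
  v1 <- lingvar("u", c(0, 1), radonwatch:::partition3(0, 1))
  v2 <- lingvar("w", c(0, 1), radonwatch:::partition3(0, 1))
  out <- lingvar("y", c(0, 10), radonwatch:::partition3(0, 10))
  mk <- function(w) fis(list(v1, v2), out,
                        fuzzy_rule(c(u = "high", w = "high"), "high",
                                   weight = w))
  # pick inputs with known high-memberships 0.7 and 0.4
  hi <- v1$levels$high
  x07 <- hi[["a"]] + 0.7 * (hi[["b"]] - hi[["a"]])
  x04 <- hi[["a"]] + 0.4 * (hi[["b"]] - hi[["a"]])
  sys1 <- mk(1)
  r <- sys1$rules[1, ]
  expect_equal(rule_activation(r, c(u = x07, w = x04), sys1), 0.4)
  r$weight <- 0
  expect_equal(rule_activation(r, c(u = x07, w = x04), sys1), 0)
  r$weight <- 0.25
  expect_equal(rule_activation(r, c(u = 1, w = 1), sys1), 0.25)
  expect_error(rule_activation(r, c(u = 1), sys1), "no crisp value")
})

test_that("implication clips and aggregation takes the upper envelope", {
  grid <- seq(0, 3, length.out = 301)
  mf <- trapmf(0, 1, 2, 3)
  expect_equal(implicate(mf, 0, grid), numeric(301))
  expect_equal(implicate(mf, 1, grid), membership(mf, grid))
  half <- implicate(mf, 0.5, grid)
  expect_equal(max(half), 0.5)
  expect_equal(half, pmin(membership(mf, grid), 0.5))
  # envelope of two disjoint clipped rectangles
  a <- implicate(trapmf(0, 0, 1, 1), 0.3, grid)
  b <- implicate(trapmf(2, 2, 3, 3), 0.8, grid)
  agg <- fuzzy_aggregate(list(a, b))
  expect_equal(agg, pmax(a, b))
  expect_equal(fuzzy_aggregate(list(a)), a)
  expect_equal(fuzzy_aggregate(list(), grid_n = 301), numeric(301))
  expect_error(fuzzy_aggregate(list(a, numeric(100))), "mismatched")
})

test_that("centroid matches symmetry and the analytic triangle value", {
  grid <- seq(0, 10, length.out = 1001)
  rect <- as.numeric(grid >= 2 & grid <= 4) * 0.6
  expect_equal(defuzzify_centroid(grid, rect), 3, tolerance = 1e-9)
  sym <- membership(trapmf(2, 4, 6, 8), grid)
  expect_equal(defuzzify_centroid(grid, sym), 5, tolerance = 1e-9)
  tri_grid <- seq(0, 3, length.out = 3001)
  tri <- pmax(0, 1 - tri_grid / 3)
  expect_equal(defuzzify_centroid(tri_grid, tri), 1, tolerance = 1e-3)
  expect_error(defuzzify_centroid(grid, numeric(1001)), "no rule fired")
})

test_that("single-rule inference matches the closed-form clipped-trapezoid
           centroid within 1e-3 at grid 1001", {
  set.seed(42)
  for (i in 1:25) {
    p <- sort(stats::runif(4, 0, 10))
    v <- lingvar("x", c(0, 1), radonwatch:::partition3(0, 1))
    out <- lingvar("y", c(0, 10),
                   list(low = trapmf(0, 0, 1, 2),
                        medium = do.call(trapmf, as.list(p)),
                        high = trapmf(8, 9, 10, 10)))
    sys <- fis(list(v), out,
               fuzzy_rule(c(x = "medium"), "medium", weight = 1),
               grid_n = 1001)
    x <- stats::runif(1, 0.36, 0.62)   # inside medium's support
    act <- membership(v$levels$medium, x)
    if (act < 0.05) next
    expect_equal(as.numeric(fis_infer(sys, c(x = x))),
                 clipped_trapezoid_centroid(p[1], p[2], p[3], p[4], act),
                 tolerance = 1e-3)
  }
})

test_that("inference stays inside the output domain on randomized configs", {
  set.seed(7)
  for (rep in 1:20) {
    w <- stats::runif(3)
    sys <- toy_fis(weight = w, grid_n = 501)
    x <- stats::runif(25, -0.2, 1.2)   # includes out-of-domain (clamped)
    vals <- radonwatch:::fis_infer_batch(sys, data.frame(x = x))$value
    expect_true(all(vals >= 0 & vals <= 10))
  }
})

test_that("inference is monotone on a monotone single-input config", {
  sys <- toy_fis()
  x <- seq(0, 1, length.out = 101)
  v <- radonwatch:::fis_infer_batch(sys, data.frame(x = x))$value
  expect_true(all(diff(v) > -1e-9))
  expect_lt(v[1], v[101])
})

test_that("symmetric firing gives the midpoint and all-zero weights flag
           the no-rule-fired fallback", {
  sys <- toy_fis()
  # plateau midpoint of medium fires only the medium rule
  mid <- fis_infer(sys, c(x = 0.5), details = TRUE)
  expect_equal(mid$value, 5, tolerance = 1e-9)
  expect_false(mid$no_rule_fired)
  dead <- toy_fis(weight = c(0, 0, 0))
  r <- fis_infer(dead, c(x = 0.5), details = TRUE)
  expect_true(r$no_rule_fired)
  expect_equal(r$value, 5)  # output-domain midpoint fallback
  # the engine-level primitive itself refuses an empty aggregate
  expect_error(defuzzify_centroid(c(0, 1), c(0, 0)), "no rule fired")
})

test_that("scaling all rule weights by a common factor leaves the output
           unchanged on a fixed equal-activation config", {
  sys1 <- toy_fis(weight = c(0.4, 0.4, 0.4))
  sys2 <- toy_fis(weight = c(0.8, 0.8, 0.8))
  # these inputs fire only the medium rule, whose consequent is symmetric,
  # so the centroid is pinned regardless of the common clip level
  xs <- c(0.45, 0.5, 0.55)
  for (x in xs)
    expect_equal(as.numeric(fis_infer(sys1, c(x = x))),
                 as.numeric(fis_infer(sys2, c(x = x))),
                 tolerance = 1e-6)
})

test_that("out-of-domain inputs are clamped and flagged", {
  sys <- toy_fis()
  r <- fis_infer(sys, c(x = 1.7), details = TRUE)
  expect_true(r$clamped)
  expect_equal(r$value,
               as.numeric(fis_infer(sys, c(x = 1))), tolerance = 1e-12)
})

test_that("configuration rejects unknown variables and qualifiers", {
  v <- lingvar("x", c(0, 1), radonwatch:::partition3(0, 1))
  out <- lingvar("y", c(0, 10), radonwatch:::partition3(0, 10))
  expect_error(fis(list(v), out, fuzzy_rule(c(z = "low"), "low")),
               "unknown variable")
  expect_error(fis(list(v), out, fuzzy_rule(c(x = "tiny"), "low")),
               "no qualifier")
  expect_error(fis(list(v), out, fuzzy_rule(c(x = "low"), "huge")),
               "no qualifier")
  expect_error(fuzzy_rule(c(x = "low"), "low", weight = 1.2), "weight")
})
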