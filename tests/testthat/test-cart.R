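# CART regression trees: impurity, splitting, growing, prediction, RMSE
# monitoring, forest training and the retraining trigger.

test_that("impurity reproduces the worked RSS values and its invariances", {
  expect_equal(impurity(c(3, 3, 3)), 0)
  expect_equal(impurity(c(1, 2, 3)), 2)
  expect_equal(impurity(c(0, 0, 5, 5)), 25)
  expect_error(impurity(numeric(0)), "empty")
  set.seed(13)
  for (i in 1:10) {
    y <- stats::rnorm(sample(2:30, 1))
    cc <- stats::rnorm(1); a <- stats::runif(1, 0.1, 5)
    expect_equal(impurity(y + cc), impurity(y), tolerance = 1e-9)
    expect_equal(impurity(a * y), a^2 * impurity(y), tolerance = 1e-9)
  }
})

test_that("best_split finds the midpoint cut that zeroes child RSS and
           declines hopeless nodes", {
  sp <- best_split(matrix(0:3, ncol = 1), c(0, 0, 5, 5))
  expect_equal(sp$feature, 1)
  expect_equal(sp$threshold, 1.5)
  expect_equal(sp$impurity_decrease, 25)   # parent RSS 25 -> children 0
  expect_null(best_split(matrix(0:3, ncol = 1), rep(4, 4)))
  expect_null(best_split(matrix(rep(2, 4), ncol = 1), c(0, 0, 5, 5)))
  expect_null(best_split(matrix(1, 1, 1), 3))
  # min_leaf constraint vetoes otherwise attractive cuts
  expect_null(best_split(matrix(c(0, 1, 1, 1), ncol = 1), c(9, 1, 1, 1),
                         min_leaf = 2))
  # tie-break: identical features -> lowest feature index wins
  X <- cbind(a = c(0, 0, 1, 1), b = c(0, 0, 1, 1))
  sp2 <- best_split(X, c(0, 0, 5, 5))
  expect_equal(sp2$feature, 1)
})

test_that("grow reproduces piecewise-constant targets, respects the depth
           budget, and is invariant to row order", {
  X <- matrix(seq(0, 7), ncol = 1)
  y <- c(0, 0, 2, 2, 5, 5, 5, 9)
  cfg <- tree_config(max_depth = 4, min_leaf = 1)
  tr <- grow(X, y, cfg)
  expect_equal(predict(tr, X), y)
  stump <- grow(X, y, tree_config(max_depth = 1, min_leaf = 1))
  expect_lte(radonwatch:::tree_depth(stump), 1)
  set.seed(17)
  X2 <- cbind(stats::rnorm(40), stats::rnorm(40))
  y2 <- ifelse(X2[, 1] > 0, 3, 0) + ifelse(X2[, 2] > 0.5, 1, 0)
  t_ref <- grow(X2, y2, cfg)
  for (i in 1:5) {
    p <- sample(40)
    t_perm <- grow(X2[p, , drop = FALSE], y2[p], cfg)
    expect_equal(predict(t_perm, X2), predict(t_ref, X2))
  }
})

test_that("prediction descends thresholds and stays within the training
           target range", {
  X <- matrix(0:3, ncol = 1)
  y <- c(0, 0, 5, 5)
  stump <- grow(X, y, tree_config(max_depth = 1, min_leaf = 1))
  expect_equal(predict(stump, matrix(1)), 0)
  expect_equal(predict(stump, matrix(2)), 5)
  leafy <- grow(matrix(1), 7, tree_config())
  expect_equal(predict(leafy, matrix(123)), 7)
  set.seed(19)
  Xr <- matrix(stats::rnorm(60), ncol = 2)
  yr <- stats::rnorm(30)
  tr <- grow(Xr, yr, tree_config(max_depth = 6, min_leaf = 1))
  probe <- matrix(stats::rnorm(200), ncol = 2)
  pr <- predict(tr, probe)
  expect_true(all(pr >= min(yr) - 1e-12 & pr <= max(yr) + 1e-12))
})

test_that("rmse reproduces the worked value, is symmetric, and zero on
           identical vectors", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(rmse(c(3, 4), c(0, 0)), rmse(c(0, 0), c(3, 4)))
  expect_error(rmse(1:3, 1:2), "equal-length")
})

test_that("grown trees match an independent exhaustive split-enumeration
           oracle for total training RSS on small datasets", {
  set.seed(29)
  for (i in 1:40) {
    n <- sample(3:8, 1)
    p <- sample(1:2, 1)
    X <- matrix(stats::rnorm(n * p), ncol = p)
    y <- round(stats::rnorm(n), 2)
    tr <- grow(X, y, tree_config(max_depth = 2, min_leaf = 1))
    expect_equal(tree_rss(tr, X, y), oracle_rss(X, y, max_depth = 2),
                 tolerance = 1e-9)
  }
})

test_that("an established tree learner agrees on a clean stump problem", {
  # independent cross-check, not the implementation: rpart on a one-cut
  # dataset recovers the same threshold region means
  set.seed(37)
  x <- stats::runif(120)
  y <- ifelse(x > 0.6, 4, 1)
  ours <- grow(matrix(x, ncol = 1), y, tree_config(max_depth = 1,
                                                   min_leaf = 5))
  rp <- rpart::rpart(y ~ x, data = data.frame(x = x, y = y),
                     method = "anova",
                     control = rpart::rpart.control(maxdepth = 1,
                                                    minbucket = 5,
                                                    minsplit = 10,
                                                    cp = 0, xval = 0))
  probe <- data.frame(x = c(0.2, 0.9))
  expect_equal(as.numeric(predict(ours, matrix(probe$x, ncol = 1))),
               as.numeric(predict(rp, probe)), tolerance = 1e-9)
})

test_that("training RMSE is non-increasing in max_depth", {
  set.seed(41)
  X <- matrix(stats::rnorm(200 * 3), ncol = 3)
  y <- X[, 1] + sin(3 * X[, 2]) + stats::rnorm(200, 0, 0.3)
  errs <- vapply(1:6, function(d) {
    tr <- grow(X, y, tree_config(max_depth = d, min_leaf = 2))
    rmse(predict(tr, X), y)
  }, 0)
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("training RMSE recovers the injected noise level within
           [0.5, 1.5] sigma over 20 seeds at n = 200", {
  sigma <- 0.5
  for (seed in 1:20) {
    set.seed(seed)
    X <- matrix(stats::runif(200 * 2), ncol = 2)
    policy <- ifelse(X[, 1] > 0.5, 4, 1) + ifelse(X[, 2] > 0.7, 1, 0)
    y <- policy + stats::rnorm(200, 0, sigma)
    tr <- grow(X, y, tree_config(max_depth = 5, min_leaf = 2))
    e <- rmse(predict(tr, X), y)
    expect_gte(e, 0.5 * sigma)
    expect_lte(e, 1.5 * sigma)
  }
})

test_that("the retraining trigger fires at 14 accumulated records", {
  expect_false(should_retrain(0))
  expect_false(should_retrain(13))
  expect_true(should_retrain(14))
  expect_true(should_retrain(30))
  expect_true(should_retrain(7, threshold = 7))
})

test_that("forest training grows six named trees with six RMSEs and
           refuses unlabelled or insufficient data", {
  kb <- knowledge_base(simulate_series(sim_params(n_days = 20, seed = 5)))
  kb <- infer_history(kb, default_fc_config(grid_n = 501),
                      default_rr_config(grid_n = 501))
  expect_error(train_forest(kb), "insufficient data")
  # constant labels -> six single-leaf trees, all RMSE zero
  for (k in seq_along(radonwatch:::REC_NAMES))
    kb$data[[radonwatch:::REC_NAMES[k]]] <- c(3, 1, 2, 0, 0, 0)[k]
  f <- train_forest(kb)
  expect_named(f$trees, radonwatch:::REC_NAMES)
  expect_length(f$rmse, 6)
  expect_equal(unname(f$rmse), rep(0, 6))
  expect_equal(f$training_size, 40)
  # a depth-2 threshold policy on radon and rainfall is recovered exactly
  kb$data$activate_forced <-
    ifelse(kb$data$radon > stats::median(kb$data$radon),
           ifelse(kb$data$rainfall > 0.5, 2, 5), 0)
  f2 <- train_forest(kb, tree_config(max_depth = 3, min_leaf = 1))
  X <- as.matrix(kb$data[radonwatch:::FEATURE_ORDER])
  expect_equal(unname(f2$rmse[["activate_forced"]]), 0, tolerance = 1e-9)
  expect_equal(predict(f2$trees$activate_forced, X),
               kb$data$activate_forced)
})

test_that("forests serialize to portable JSON and back without changing
           predictions", {
  kb <- knowledge_base(simulate_series(sim_params(n_days = 20, seed = 9)))
  kb <- infer_history(kb, default_fc_config(grid_n = 501),
                      default_rr_config(grid_n = 501))
  kb <- label_records(kb)
  f <- train_forest(kb)
  path <- withr::local_tempfile(fileext = ".json")
  write_forest(f, path)
  back <- read_forest(path)
  X <- as.matrix(kb$data[radonwatch:::FEATURE_ORDER])
  for (nm in names(f$trees))
    expect_equal(predict(back$trees[[nm]], X), predict(f$trees[[nm]], X))
  expect_identical(back$feature_hash, f$feature_hash)
  expect_equal(back$rmse, f$rmse)
})
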