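# Independent oracles used across the suite. These deliberately share no
# code with the implementation paths they check.

# Exact integrals of a piecewise-linear membership curve given its vertex
# list (x, y): returns the analytic centroid integral pair.
piecewise_centroid <- function(xs, ys) {
  stopifnot(length(xs) == length(ys), !is.unsorted(xs))
  area <- 0; moment <- 0
  for (i in seq_len(length(xs) - 1)) {
    x0 <- xs[i]; x1 <- xs[i + 1]; y0 <- ys[i]; y1 <- ys[i + 1]
    h <- x1 - x0
    if (h <= 0) next
    m <- (y1 - y0) / h
    q <- y0 - m * x0
    area <- area + m * (x1^2 - x0^2) / 2 + q * h
    moment <- moment + m * (x1^3 - x0^3) / 3 + q * (x1^2 - x0^2) / 2
  }
  moment / area
}

# Analytic centroid of a trapezoid (a,b,c,d) clipped at activation level h.
clipped_trapezoid_centroid <- function(a, b, c, d, h) {
  xs <- c(a, if (b > a) a + (b - a) * h else a,
          if (d > c) d - (d - c) * h else d, d)
  ys <- c(0, h, h, 0)
  piecewise_centroid(xs, ys)
}

# Textbook Pearson correlation coded from the covariance definition,
# independent of stats::cor.
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  cov <- sum((x - mx) * (y - my)) / (n - 1)
  sx <- sqrt(sum((x - mx)^2) / (n - 1))
  sy <- sqrt(sum((y - my)^2) / (n - 1))
  cov / (sx * sy)
}

# Brute-force recursive CART oracle: enumerates every candidate split
# (all features, all midpoints between consecutive distinct sorted values)
# at every node, scores each by direct two-pass RSS computation, applies
# the same criterion (min child RSS; ties -> lowest feature, then lowest
# threshold) and recurses. Returns total training RSS of the grown tree.
oracle_rss <- function(X, y, max_depth, min_leaf = 1L, depth = 0L) {
  node_rss <- sum((y - mean(y))^2)
  n <- length(y)
  if (depth >= max_depth || n < 2 * min_leaf || node_rss <= 1e-12)
    return(node_rss)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    v <- sort(unique(X[, j]))
    if (length(v) < 2) next
    for (k in seq_len(length(v) - 1)) {
      thr <- (v[k] + v[k + 1]) / 2
      l <- X[, j] <= thr
      if (sum(l) < min_leaf || sum(!l) < min_leaf) next
      rss <- sum((y[l] - mean(y[l]))^2) + sum((y[!l] - mean(y[!l]))^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        best <- list(rss = rss, j = j, thr = thr, l = l)
      }
    }
  }
  if (is.null(best) || node_rss - best$rss < 1e-12) return(node_rss)
  oracle_rss(X[best$l, , drop = FALSE], y[best$l], max_depth, min_leaf,
             depth + 1L) +
    oracle_rss(X[!best$l, , drop = FALSE], y[!best$l], max_depth, min_leaf,
               depth + 1L)
}

# total training RSS achieved by a grown cart_tree
tree_rss <- function(tree, X, y) sum((predict(tree, X) - y)^2)

# A minimal symmetric single-input system over output [0, 10] used in
# several engine tests: one variable on [0, 1] with the standard partition.
toy_fis <- function(weight = c(1, 1, 1), grid_n = 1001) {
  v <- lingvar("x", c(0, 1), radonwatch:::partition3(0, 1))
  out <- lingvar("y", c(0, 10), radonwatch:::partition3(0, 10))
  rules <- rbind(
    fuzzy_rule(c(x = "low"), "low", weight = weight[1]),
    fuzzy_rule(c(x = "medium"), "medium", weight = weight[2]),
    fuzzy_rule(c(x = "high"), "high", weight = weight[3]))
  fis(list(v), out, rules, grid_n = grid_n)
}

# a valid measurement record row for reuse
demo_record <- function(radon = 84) {
  measurement_record(44075, 12, radon, 29.6, 6.5, pressure = 1014.8,
                     wind = 9.5, rainfall = 1.2, humidity = 62.3)
}
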