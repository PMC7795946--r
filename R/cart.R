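# CART regression trees, written out in full: RSS node impurity, recursive
# binary splitting over midpoint thresholds, leaf prediction by the region
# mean, RMSE monitoring, and the six-tree forest with its 14-record
# retraining trigger.

#' RSS node impurity
#'
#' Sum of squared deviations of a node's target values from their mean;
#' zero exactly when the node is pure.
#'
#' @param values Numeric vector, length >= 1.
#' @return Non-negative impurity.
#' @examples
#' impurity(c(1, 2, 3))  # 2
#' @export
impurity <- function(values) {
  if (length(values) < 1) stop("impurity of an empty node is undefined")
  sum((values - mean(values))^2)
}

#' Tree-growing configuration
#'
#' @param max_depth Maximum tree depth (root = depth 0), >= 1.
#' @param min_leaf Minimum observations per leaf, >= 1.
#' @param min_impurity_decrease Minimum RSS reduction for a split to be
#'   admissible, >= 0.
#' @return Object of class \code{"tree_config"}.
#' @export
tree_config <- function(max_depth = 5L, min_leaf = 2L,
                        min_impurity_decrease = 0) {
  stopifnot(max_depth >= 1, min_leaf >= 1, min_impurity_decrease >= 0)
  structure(list(max_depth = as.integer(max_depth),
                 min_leaf = as.integer(min_leaf),
                 min_impurity_decrease = min_impurity_decrease),
            class = "tree_config")
}

#' Best binary split of a node
#'
#' Scans every feature and every midpoint between consecutive distinct
#' sorted values of that feature, and returns the split minimising the
#' total child RSS. Ties are broken by lowest feature index, then lowest
#' threshold, which makes growing invariant to row order. Returns
#' \code{NULL} when no admissible split reduces the impurity by at least
#' \code{min_impurity_decrease} (or would leave a child below
#' \code{min_leaf}).
#'
#' @param X Numeric matrix or data frame of features (rows = cases).
#' @param y Numeric targets.
#' @param min_leaf Minimum child size.
#' @param min_impurity_decrease Minimum admissible RSS reduction.
#' @return List \code{(feature, threshold, impurity_decrease)} or
#'   \code{NULL}.
#' @export
best_split <- function(X, y, min_leaf = 1L, min_impurity_decrease = 0) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) return(NULL)
  parent <- impurity(y)
  best <- NULL
  best_rss <- Inf
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    ord <- order(xj, y)
    xs <- xj[ord]; ys <- y[ord]
    # cumulative sums give child RSS at every cut in O(n)
    cs <- cumsum(ys); css <- cumsum(ys^2)
    tot <- cs[n]; tots <- css[n]
    distinct <- which(diff(xs) > 0)        # cut after position i
    for (i in distinct) {
      if (i < min_leaf || n - i < min_leaf) next
      rss_l <- css[i] - cs[i]^2 / i
      rss_r <- (tots - css[i]) - (tot - cs[i])^2 / (n - i)
      rss <- rss_l + rss_r
      if (rss < best_rss - 1e-12) {
        thr <- (xs[i] + xs[i + 1]) / 2
        best_rss <- rss
        best <- list(feature = j, threshold = thr,
                     impurity_decrease = parent - rss)
      }
    }
  }
  if (is.null(best)) return(NULL)
  if (best$impurity_decrease < max(min_impurity_decrease, 1e-12))
    return(NULL)
  best
}

#' Grow a regression tree
#'
#' Recursive binary splitting: each node takes the \code{\link{best_split}}
#' of its region and recurses until the node is pure, the depth budget or
#' leaf-size floor is hit, or no split reduces the RSS enough. Leaves
#' predict the mean of their region's targets. Deterministic for fixed
#' inputs, and invariant to row order thanks to the split tie-break.
#'
#' @param X Feature matrix/data frame.
#' @param y Numeric targets, one per row of \code{X}.
#' @param cfg A \code{\link{tree_config}}.
#' @return Nested node list of class \code{"cart_tree"}: internal nodes
#'   carry \code{feature}, \code{threshold}, \code{left}, \code{right};
#'   leaves carry \code{prediction} and \code{n}.
#' @export
grow <- function(X, y, cfg = tree_config()) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) >= 1)
  node <- grow_node(X, y, cfg, depth = 0L)
  structure(node, class = "cart_tree",
            features = colnames(X))
}

grow_node <- function(X, y, cfg, depth) {
  leaf <- list(prediction = mean(y), n = length(y))
  if (depth >= cfg$max_depth) return(leaf)
  if (length(y) < 2 * cfg$min_leaf) return(leaf)
  if (impurity(y) <= 1e-12) return(leaf)
  sp <- best_split(X, y, cfg$min_leaf, cfg$min_impurity_decrease)
  if (is.null(sp)) return(leaf)
  go_left <- X[, sp$feature] <= sp$threshold
  list(feature = sp$feature, threshold = sp$threshold,
       left = grow_node(X[go_left, , drop = FALSE], y[go_left], cfg,
                        depth + 1L),
       right = grow_node(X[!go_left, , drop = FALSE], y[!go_left], cfg,
                         depth + 1L))
}

#' Predict from a grown tree
#'
#' Threshold descent (\code{x <= threshold} goes left) down to a leaf mean.
#'
#' @param object A \code{cart_tree}.
#' @param newdata Feature matrix/data frame (or single numeric row).
#' @param ... Unused.
#' @return Numeric predictions, one per row.
#' @export
predict.cart_tree <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  apply(newdata, 1, function(x) descend(object, x))
}

descend <- function(node, x) {
  while (is.null(node$prediction)) {
    if (node$feature > length(x) || is.na(x[node$feature]))
      stop("feature ", node$feature, " missing from prediction row")
    node <- if (x[node$feature] <= node$threshold) node$left else node$right
  }
  node$prediction
}

tree_depth <- function(node) {
  if (!is.null(node$prediction)) return(0L)
  1L + max(tree_depth(node$left), tree_depth(node$right))
}

#' Root-mean-square error
#'
#' @param pred,actual Equal-length numeric vectors.
#' @return \code{sqrt(mean((pred - actual)^2))}.
#' @export
rmse <- function(pred, actual) {
  if (length(pred) != length(actual) || length(pred) < 1)
    stop("rmse needs two equal-length, non-empty vectors")
  sqrt(mean((pred - actual)^2))
}

#' Retraining trigger
#'
#' The trees are retrained when 14 new records have accumulated since the
#' last training (twice-daily sampling makes that one week of data); the
#' threshold is configurable.
#'
#' @param new_records Records since last training, >= 0.
#' @param threshold Trigger count (default 14).
#' @return \code{TRUE} when retraining is due.
#' @export
should_retrain <- function(new_records, threshold = 14L) {
  stopifnot(new_records >= 0)
  new_records >= threshold
}

#' Train the six-tree recommendation forest
#'
#' Grows one regression tree per recommendation on the shared 12-feature
#' table (timestamp, sensor channels, fc, rr), using every record whose
#' six labels are all present. Per-tree RMSE is computed on the training
#' window as the monitoring statistic.
#'
#' @param kb A \code{radon_kb} with inferred fc/rr and labels, or a plain
#'   data frame with the same columns.
#' @param cfg A \code{\link{tree_config}}.
#' @return Object of class \code{"radon_forest"}: named trees, named
#'   \code{rmse} vector (length 6), \code{training_size}, the frozen
#'   feature order and its hash.
#' @export
train_forest <- function(kb, cfg = tree_config()) {
  df <- if (inherits(kb, "radon_kb")) kb$data else kb
  need <- c(FEATURE_ORDER, REC_NAMES)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("training data lacks columns: ", paste(miss, collapse = ", "))
  ok <- stats::complete.cases(df[need])
  df <- df[ok, ]
  if (nrow(df) < 2 * cfg$min_leaf)
    stop("insufficient data: ", nrow(df), " fully labelled records, need ",
         2 * cfg$min_leaf, call. = FALSE)
  X <- as.matrix(df[FEATURE_ORDER])
  trees <- lapply(REC_NAMES, function(lbl) grow(X, df[[lbl]], cfg))
  names(trees) <- REC_NAMES
  errs <- vapply(REC_NAMES, function(lbl)
    rmse(predict(trees[[lbl]], X), df[[lbl]]), 0)
  structure(list(trees = trees, rmse = errs,
                 training_size = nrow(df), features = FEATURE_ORDER,
                 feature_hash = feature_hash(FEATURE_ORDER), cfg = cfg),
            class = "radon_forest")
}

#' @export
print.radon_forest <- function(x, ...) {
  cat("Recommendation forest:", length(x$trees), "trees on",
      x$training_size, "records\n")
  cat("training RMSE:",
      paste(sprintf("%s=%.4g", names(x$rmse), x$rmse), collapse = ", "),
      "\n")
  invisible(x)
}

# ---- forest serialization (portable structured text) -----------------

node_to_list <- function(node) {
  if (!is.null(node$prediction))
    list(prediction = node$prediction, n = node$n)
  else
    list(feature = node$feature, threshold = node$threshold,
         left = node_to_list(node$left), right = node_to_list(node$right))
}

list_to_node <- function(x) {
  if (!is.null(x$prediction))
    list(prediction = as.numeric(x$prediction), n = as.integer(x$n))
  else
    list(feature = as.integer(x$feature),
         threshold = as.numeric(x$threshold),
         left = list_to_node(x$left), right = list_to_node(x$right))
}

#' Write a trained forest to JSON
#'
#' Nested nodes with feature names, thresholds, leaf means, the growing
#' configuration and the frozen feature-order hash.
#'
#' @param forest A \code{radon_forest}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_forest <- function(forest, path) {
  obj <- list(features = forest$features, feature_hash = forest$feature_hash,
              training_size = forest$training_size,
              cfg = unclass(forest$cfg), rmse = as.list(forest$rmse),
              trees = lapply(forest$trees, node_to_list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a trained forest from JSON
#'
#' @param path Path written by \code{\link{write_forest}}.
#' @return A \code{radon_forest}.
#' @export
read_forest <- function(path) {
  obj <- jsonlite::read_json(path)
  trees <- lapply(obj$trees, function(t)
    structure(list_to_node(t), class = "cart_tree",
              features = unlist(obj$features)))
  structure(list(trees = trees,
                 rmse = unlist(obj$rmse),
                 training_size = as.integer(obj$training_size),
                 features = unlist(obj$features),
                 feature_hash = obj$feature_hash,
                 cfg = do.call(tree_config, obj$cfg)),
            class = "radon_forest")
}
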