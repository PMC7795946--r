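# Recommendation assembly and reporting: the frozen 12-feature predictor
# vector, the six-valued recommendation vector from the trained forest, and
# the spider-web report (chart + machine-readable JSON).

FEATURE_ORDER <- c("day_serial", "hour", "radon", "t_in", "t_out", "t_diff",
                   "pressure", "wind", "rainfall", "humidity", "fc", "rr")

feature_hash <- function(features) config_hash(as.list(features))

#' Assemble the 12-feature predictor vector
#'
#' Fixed order: day serial, hour, radon, indoor/outdoor temperature and
#' their difference, pressure, wind, rainfall, humidity, then the two
#' inferred variables fc and rr. The order is frozen and hashed; a
#' serialized forest refuses to predict against a different order, which
#' guards against silent feature misalignment.
#'
#' @param rec A \code{\link{measurement_record}} (or 1-row data frame).
#' @param out Inference outputs from \code{\link{compute_outputs}} (list
#'   with \code{fc} in [0,10] and \code{rr} in [0,100]).
#' @return Named numeric vector of length 12, class
#'   \code{"feature_vector"}.
#' @export
assemble_features <- function(rec, out) {
  stopifnot(is.list(out), !is.null(out$fc), !is.null(out$rr))
  if (out$fc < 0 || out$fc > 10) stop("fc outside [0, 10]")
  if (out$rr < 0 || out$rr > 100) stop("rr outside [0, 100]")
  base <- setdiff(FEATURE_ORDER, c("fc", "rr"))
  miss <- setdiff(base, names(rec))
  if (length(miss))
    stop("record lacks fields: ", paste(miss, collapse = ", "))
  fv <- c(vapply(base, function(f) as.numeric(rec[[f]][1]), 0),
          fc = out$fc, rr = out$rr)
  if (anyNA(fv)) stop("missing component in feature vector")
  structure(fv[FEATURE_ORDER], class = "feature_vector")
}

#' Predict the six recommendation levels
#'
#' One prediction per tree; each lies in [0, 5] by construction because
#' leaf means are convex combinations of labels set on that scale. The
#' first three outputs are the preventive actions (activate forced
#' evacuation, de-activate forced evacuation, natural ventilation), the
#' last three the checking actions (check sensors, check inference, check
#' exposure time).
#'
#' @param forest A trained \code{radon_forest}.
#' @param fv A \code{\link{assemble_features}} vector, or a data frame of
#'   rows in the frozen feature order.
#' @return Named numeric vector (or matrix for multiple rows) of the six
#'   recommendation levels.
#' @export
recommend <- function(forest, fv) {
  if (!inherits(forest, "radon_forest") || is.null(forest$trees))
    stop("forest not trained")
  if (is.data.frame(fv) || is.matrix(fv)) {
    nm <- colnames(fv)
    if (is.null(nm) || !identical(feature_hash(as.list(nm)),
                                  forest$feature_hash))
      stop("feature order mismatch: refusing to predict", call. = FALSE)
    X <- as.matrix(fv)
    return(vapply(forest$trees, function(t) predict(t, X),
                  numeric(nrow(X))))
  }
  if (!identical(feature_hash(as.list(names(fv))), forest$feature_hash))
    stop("feature order mismatch: refusing to predict", call. = FALSE)
  vapply(forest$trees, function(t) descend(t, as.numeric(fv)), 0)
}

#' Render the spider-web recommendation report
#'
#' Writes (i) a radar chart with six labelled axes on the 0--5 scale, as
#' SVG and PNG, and (ii) a machine-readable JSON report carrying the six
#' recommendation levels, fc, rr, per-tree RMSEs, the configuration hash
#' and the timestamp of the underlying measurement.
#'
#' @param rv Named six-vector of recommendation levels in [0, 5].
#' @param meta List of provenance fields merged into the report (e.g.
#'   \code{fc}, \code{rr}, \code{rmse}, \code{config_hash},
#'   \code{day_serial}, \code{hour}).
#' @param dir Output directory (created if needed).
#' @param stem File stem, default \code{"recommendation"}.
#' @param formats Chart formats to write, subset of \code{c("svg","png")}.
#' @return Named list of written paths, invisibly.
#' @export
render_report <- function(rv, meta = list(), dir = ".",
                          stem = "recommendation",
                          formats = c("svg", "png")) {
  stopifnot(length(rv) == 6, all(rv >= 0), all(rv <= 5))
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir)
  paths <- list()
  for (fmt in formats) {
    p <- file.path(dir, paste0(stem, ".", fmt))
    dev <- switch(fmt, svg = grDevices::svg, png = grDevices::png,
                  stop("unknown chart format ", fmt))
    if (fmt == "png") dev(p, width = 640, height = 640) else dev(p)
    tryCatch(spider_chart(rv), finally = grDevices::dev.off())
    paths[[fmt]] <- p
  }
  report <- c(list(recommendations = as.list(rv)), meta)
  jp <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(report, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths$json <- jp
  invisible(paths)
}

#' Read back a machine-readable recommendation report
#'
#' @param path JSON path written by \code{\link{render_report}}.
#' @return List with \code{recommendations} as a named numeric vector plus
#'   all provenance fields.
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path)
  obj$recommendations <- unlist(obj$recommendations)
  obj
}

#' Draw a spider-web (radar) chart of the six recommendations
#'
#' Six axes on the fixed 0--5 strength scale; the filled polygon shows how
#' strongly each action is recommended.
#'
#' @param rv Named six-vector in [0, 5].
#' @param main Title.
#' @export
spider_chart <- function(rv, main = "Recommendation levels (0-5)") {
  stopifnot(length(rv) == 6)
  labels <- if (!is.null(names(rv))) names(rv) else REC_NAMES
  k <- length(rv)
  ang <- pi / 2 - 2 * pi * (seq_len(k) - 1) / k
  op <- graphics::par(mar = c(1, 1, 3, 1), xpd = NA)
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(-6.5, 6.5), ylim = c(-6.5, 6.5), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  for (ring in 1:5)
    graphics::polygon(ring * cos(ang), ring * sin(ang), border = "grey80")
  graphics::segments(0, 0, 5 * cos(ang), 5 * sin(ang), col = "grey60")
  graphics::text(5.9 * cos(ang), 5.9 * sin(ang), labels, cex = 0.8)
  graphics::polygon(rv * cos(ang), rv * sin(ang),
                    col = grDevices::adjustcolor("steelblue", 0.4),
                    border = "steelblue", lwd = 2)
  graphics::points(rv * cos(ang), rv * sin(ang), pch = 19,
                   col = "steelblue")
  invisible(NULL)
}
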