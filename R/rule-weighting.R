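# Adaptive rule weighting: Pearson correlation of each atmospheric variable
# with radon concentration, pushed through a user-tunable sigmoid, gates the
# direct/inverse rule families of the correction-factor system.

ATMOSPHERIC_VARS <- c("t_in", "t_out", "t_diff", "pressure", "wind",
                      "rainfall", "humidity")

#' Sigmoid configuration for rule reweighting
#'
#' The transform is \code{1 / (1 + exp(-b * (x - c)))} applied to the
#' absolute Pearson correlation (amplitude fixed at 1). \code{b} sets how
#' steep the transition from the low- to the high-weight zone is; \code{c}
#' places the midpoint (weight 0.5) on the \code{[0, 1]} correlation axis,
#' so moving it left makes the system more sensitive to weak correlations.
#'
#' @param b Growth rate, > 0 (default 10, a smooth mid-centred transition).
#' @param c Centre in \code{[0, 1]} (default 0.5).
#' @return Object of class \code{"sigmoid_config"}.
#' @export
sigmoid_config <- function(b = 10, c = 0.5) {
  stopifnot(is.numeric(b), b > 0, is.numeric(c), c >= 0, c <= 1)
  structure(list(b = b, c = c), class = "sigmoid_config")
}

#' Pearson correlation with degenerate-variance handling
#'
#' Covariance over the product of standard deviations, clipped to
#' \code{[-1, 1]} against rounding. A constant sequence has no defined
#' correlation; it is reported as 0 with the \code{"degenerate"} attribute
#' set, so an uninformative variable neither dominates nor crashes the
#' weighting.
#'
#' @param x,y Equal-length numeric vectors, length >= 2.
#' @return Correlation in \code{[-1, 1]} with attribute \code{degenerate}.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(0, degenerate = TRUE))
  structure(min(1, max(-1, stats::cor(x, y, method = "pearson"))),
            degenerate = FALSE)
}

#' Sigmoid weight transform
#'
#' Maps an absolute correlation through the configured sigmoid; strictly
#' increasing, bounded in (0, 1), exactly 0.5 at \code{rho_abs == c}.
#'
#' @param rho_abs Absolute correlation(s) in \code{[0, 1]}.
#' @param cfg A \code{\link{sigmoid_config}}.
#' @return Weight(s) in (0, 1).
#' @export
sigmoid_weight <- function(rho_abs, cfg = sigmoid_config()) {
  stopifnot(all(rho_abs >= 0), all(rho_abs <= 1))
  1 / (1 + exp(-cfg$b * (rho_abs - cfg$c)))
}

#' Correlation table over the knowledge base
#'
#' Pearson correlation of each atmospheric variable against radon
#' concentration over the stored history (optionally a trailing window),
#' plus the sigmoid-transformed weight of each. Mirrors the per-variable
#' correlation report of the methodology's dashboard.
#'
#' @param history Data frame carrying \code{radon} and the atmospheric
#'   columns, or a knowledge base object.
#' @param cfg Sigmoid configuration.
#' @param window Optional integer: use only the most recent \code{window}
#'   records.
#' @param vars Atmospheric variables to correlate (default all seven).
#' @return Data frame with columns \code{variable}, \code{rho},
#'   \code{weight}, \code{degenerate}; class \code{"correlation_table"}.
#' @export
correlation_table <- function(history, cfg = sigmoid_config(),
                              window = NULL, vars = ATMOSPHERIC_VARS) {
  df <- if (inherits(history, "radon_kb")) history$data else history
  stopifnot(is.data.frame(df), "radon" %in% names(df))
  miss <- setdiff(vars, names(df))
  if (length(miss))
    stop("history lacks atmospheric columns: ", paste(miss, collapse = ", "))
  if (!is.null(window) && nrow(df) > window)
    df <- df[seq.int(nrow(df) - window + 1L, nrow(df)), ]
  if (nrow(df) < 2) stop("need at least two records to correlate")
  rows <- lapply(vars, function(v) {
    r <- pearson(df[[v]], df$radon)
    data.frame(variable = v, rho = as.numeric(r),
               weight = sigmoid_weight(abs(as.numeric(r)), cfg),
               degenerate = attr(r, "degenerate"),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("correlation_table",
                                            "data.frame"))
}

#' Reset a rulebase to the standard initial weight
#'
#' Every rule receives the standard initialisation weight of 0.25,
#' regardless of prior weights.
#'
#' @param rules Rulebase data frame.
#' @return The rulebase with all weights at 0.25.
#' @export
initialize_rulebase <- function(rules) {
  if (nrow(rules)) rules$weight <- 0.25
  rules
}

#' Reweight a rulebase from a correlation table
#'
#' For each rule keyed on atmospheric variable v: when \code{rho_v > 0} the
#' direct-polarity family gets \code{sigmoid_weight(|rho_v|)} and the
#' inverse family weight 0; when \code{rho_v < 0} the assignment is
#' mirrored; when \code{rho_v == 0} (including degenerate variance) both
#' families get \code{sigmoid_weight(0)}, so an uninformative variable
#' neither dominates nor vanishes.
#'
#' @param rules Rulebase data frame with \code{polarity} and \code{key_var}.
#' @param table A \code{\link{correlation_table}}.
#' @param cfg Sigmoid configuration (must match the one behind
#'   \code{table} for consistent weights).
#' @return The reweighted rulebase.
#' @export
reweight <- function(rules, table, cfg = sigmoid_config()) {
  if (!nrow(rules)) return(rules)
  miss <- setdiff(unique(rules$key_var), table$variable)
  if (length(miss))
    stop("correlation table lacks variables: ", paste(miss, collapse = ", "))
  rho <- stats::setNames(table$rho, table$variable)
  for (i in seq_len(nrow(rules))) {
    r <- rho[[rules$key_var[i]]]
    w_on <- sigmoid_weight(abs(r), cfg)
    rules$weight[i] <-
      if (r > 0) { if (rules$polarity[i] == "direct") w_on else 0 }
      else if (r < 0) { if (rules$polarity[i] == "inverse") w_on else 0 }
      else sigmoid_weight(0, cfg)
  }
  rules
}

#' Write a correlation report
#'
#' One delimited-text row per atmospheric variable: Pearson rho and the
#' transformed rule weight.
#'
#' @param table A \code{\link{correlation_table}}.
#' @param path Output file path.
#' @param sep Field delimiter (default comma).
#' @return \code{path}, invisibly.
#' @export
write_correlation_report <- function(table, path, sep = ",") {
  utils::write.table(as.data.frame(table), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
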