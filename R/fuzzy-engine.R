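# Weighted-rule Mamdani inference core: trapezoidal membership, min-AND
# firing, truncation implication, max aggregation, centroid defuzzification.

#' Trapezoidal membership function
#'
#' Constructs a trapezoidal membership function with breakpoints
#' \code{a <= b <= c <= d} on the variable's own scale. Membership is 0
#' outside \code{[a, d]}, 1 on the plateau \code{[b, c]}, and linear on the
#' two ramps. Degenerate ramps (\code{a == b} or \code{c == d}) give a
#' crisp shoulder.
#'
#' @param a,b,c,d Numeric breakpoints, non-decreasing.
#' @return An object of class \code{"trapmf"}.
#' @examples
#' mf <- trapmf(0, 1, 2, 3)
#' membership(mf, c(-1, 0.5, 1.5, 3.5))
#' @export
trapmf <- function(a, b, c, d) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), is.numeric(d))
  if (!(a <= b && b <= c && c <= d))
    stop("trapezoid breakpoints must satisfy a <= b <= c <= d")
  structure(c(a = a, b = b, c = c, d = d), class = "trapmf")
}

#' Evaluate a trapezoidal membership function
#'
#' @param mf A \code{trapmf}.
#' @param x Numeric vector of crisp values (values outside the support are
#'   allowed and get membership 0).
#' @return Membership degrees in \code{[0, 1]}, same length as \code{x}.
#' @export
membership <- function(mf, x) {
  stopifnot(inherits(mf, "trapmf"))
  a <- mf[["a"]]; b <- mf[["b"]]; c <- mf[["c"]]; d <- mf[["d"]]
  y <- numeric(length(x))
  y[x >= b & x <= c] <- 1
  up <- x > a & x < b
  if (any(up)) y[up] <- (x[up] - a) / (b - a)
  dn <- x > c & x < d
  if (any(dn)) y[dn] <- (d - x[dn]) / (d - c)
  pmin(pmax(y, 0), 1)
}

#' Linguistic variable
#'
#' A named variable over a closed domain, partitioned into qualifier levels
#' (at least \code{low}, \code{medium}, \code{high}), each a trapezoid whose
#' support lies inside the domain.
#'
#' @param name Identifier string.
#' @param domain Length-2 numeric \code{c(lo, hi)}, \code{lo < hi}.
#' @param levels Named list of \code{trapmf} objects.
#' @return Object of class \code{"lingvar"}.
#' @export
lingvar <- function(name, domain, levels) {
  stopifnot(is.character(name), length(domain) == 2, domain[1] < domain[2])
  if (!all(c("low", "medium", "high") %in% names(levels)))
    stop("linguistic variable '", name,
         "' needs at least the qualifiers low, medium, high")
  for (lv in names(levels)) {
    mf <- levels[[lv]]
    if (!inherits(mf, "trapmf"))
      stop("level '", lv, "' of '", name, "' is not a trapmf")
    if (mf[["a"]] < domain[1] - 1e-9 || mf[["d"]] > domain[2] + 1e-9)
      stop("level '", lv, "' of '", name, "' escapes the domain")
  }
  structure(list(name = name, domain = as.numeric(domain), levels = levels),
            class = "lingvar")
}

# Standard three-way partition of a range: low/medium/high with ramps of
# width 20% of the range centred on the 1/3 and 2/3 boundaries, so adjacent
# memberships sum to one across each crossover.
partition3 <- function(lo, hi) {
  w <- hi - lo
  b1 <- lo + w / 3; b2 <- lo + 2 * w / 3; h <- 0.1 * w
  list(low    = trapmf(lo, lo, b1 - h, b1 + h),
       medium = trapmf(b1 - h, b1 + h, b2 - h, b2 + h),
       high   = trapmf(b2 - h, b2 + h, hi, hi))
}

# Five-way partition (very_low .. very_high) with ramps of width 10% of the
# range centred on the 1/5 .. 4/5 boundaries; used where a finer output
# graduation keeps a rule ladder strictly increasing.
partition5 <- function(lo, hi) {
  w <- hi - lo
  bs <- lo + w * (1:4) / 5
  h <- 0.05 * w
  list(very_low  = trapmf(lo, lo, bs[1] - h, bs[1] + h),
       low       = trapmf(bs[1] - h, bs[1] + h, bs[2] - h, bs[2] + h),
       medium    = trapmf(bs[2] - h, bs[2] + h, bs[3] - h, bs[3] + h),
       high      = trapmf(bs[3] - h, bs[3] + h, bs[4] - h, bs[4] + h),
       very_high = trapmf(bs[4] - h, bs[4] + h, hi, hi))
}

#' Fuzzy rule with at most two antecedents
#'
#' @param antecedents Named character vector mapping variable name to
#'   qualifier, length 1 or 2 (AND-combined).
#' @param consequent Output qualifier label.
#' @param weight Rule weight in \code{[0, 1]}, a multiplier on the firing
#'   strength.
#' @param polarity \code{"direct"} or \code{"inverse"}; consumed by the
#'   correlation-driven reweighting, which keeps at most one polarity family
#'   per variable active.
#' @param key_var Variable the rule is keyed on for reweighting; defaults to
#'   the first antecedent's variable.
#' @return One-row data frame (rulebases are data frames, one rule per row).
#' @export
fuzzy_rule <- function(antecedents, consequent, weight = 0.25,
                       polarity = c("direct", "inverse"), key_var = NULL) {
  polarity <- match.arg(polarity)
  if (length(antecedents) < 1 || length(antecedents) > 2)
    stop("a rule takes one or two antecedents")
  if (is.null(names(antecedents)) || any(!nzchar(names(antecedents))))
    stop("antecedents must be a named character vector (variable = qualifier)")
  if (weight < 0 || weight > 1) stop("rule weight must lie in [0, 1]")
  v <- names(antecedents)
  data.frame(var1 = v[1], lev1 = unname(antecedents[1]),
             var2 = if (length(v) == 2) v[2] else NA_character_,
             lev2 = if (length(v) == 2) unname(antecedents[2]) else NA_character_,
             consequent = consequent, weight = weight, polarity = polarity,
             key_var = if (is.null(key_var)) v[1] else key_var,
             stringsAsFactors = FALSE)
}

#' Assemble a Mamdani inference system
#'
#' @param inputs Named list of \code{lingvar} input variables.
#' @param output A \code{lingvar} describing the output variable.
#' @param rules Rulebase data frame (rows from \code{\link{fuzzy_rule}}).
#' @param grid_n Number of uniform sample points on the output domain used
#'   for implication/aggregation/centroid (default 1001).
#' @return Object of class \code{"fis"}.
#' @export
fis <- function(inputs, output, rules, grid_n = 1001) {
  stopifnot(is.list(inputs), inherits(output, "lingvar"), grid_n >= 2)
  names(inputs) <- vapply(inputs, function(v) v$name, "")
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    for (vn in c(r$var1, r$var2)) {
      if (is.na(vn)) next
      if (!vn %in% names(inputs))
        stop("rule ", i, " references unknown variable '", vn, "'")
    }
    levs <- c(r$lev1, if (!is.na(r$var2)) r$lev2)
    vars <- c(r$var1, if (!is.na(r$var2)) r$var2)
    for (k in seq_along(vars))
      if (!levs[k] %in% names(inputs[[vars[k]]]$levels))
        stop("rule ", i, ": variable '", vars[k],
             "' has no qualifier '", levs[k], "'")
    if (!r$consequent %in% names(output$levels))
      stop("rule ", i, ": output has no qualifier '", r$consequent, "'")
  }
  structure(list(inputs = inputs, output = output, rules = rules,
                 grid_n = as.integer(grid_n)),
            class = "fis")
}

output_grid <- function(system) {
  seq(system$output$domain[1], system$output$domain[2],
      length.out = system$grid_n)
}

#' Firing strength of a single rule
#'
#' The activation is \code{weight * min} over the antecedent membership
#' degrees (AND by minimum, then weighting).
#'
#' @param rule One rulebase row.
#' @param inputs Named numeric vector of crisp input values.
#' @param system The \code{fis} the rule belongs to.
#' @return Activation in \code{[0, 1]}.
#' @export
rule_activation <- function(rule, inputs, system) {
  vars <- c(rule$var1, if (!is.na(rule$var2)) rule$var2)
  levs <- c(rule$lev1, if (!is.na(rule$var2)) rule$lev2)
  deg <- vapply(seq_along(vars), function(k) {
    v <- system$inputs[[vars[k]]]
    if (is.null(v)) stop("unknown variable '", vars[k], "'")
    if (!vars[k] %in% names(inputs))
      stop("no crisp value supplied for '", vars[k], "'")
    membership(v$levels[[levs[k]]], inputs[[vars[k]]])
  }, 0)
  rule$weight * min(deg)
}

#' Implication by truncation
#'
#' Clips a consequent membership function at the rule activation level,
#' sampled on the output grid.
#'
#' @param mf Consequent \code{trapmf}.
#' @param activation Firing strength in \code{[0, 1]}.
#' @param grid Numeric grid over the output domain.
#' @return Numeric vector of clipped degrees on the grid.
#' @export
implicate <- function(mf, activation, grid) {
  stopifnot(activation >= 0, activation <= 1)
  pmin(membership(mf, grid), activation)
}

#' Disjunctive aggregation of clipped consequents
#'
#' Pointwise maximum across clipped sets sharing one grid; an empty list
#' aggregates to the all-zero set.
#'
#' @param sets List of equal-length degree vectors.
#' @param grid_n Grid length, required when \code{sets} is empty.
#' @return Aggregated degree vector.
#' @export
fuzzy_aggregate <- function(sets, grid_n = NULL) {
  if (length(sets) == 0) {
    if (is.null(grid_n)) stop("grid length needed to aggregate nothing")
    return(numeric(grid_n))
  }
  n <- unique(lengths(sets))
  if (length(n) != 1) stop("clipped sets sampled on mismatched grids")
  Reduce(pmax, sets)
}

#' Centroid defuzzification
#'
#' Centre of gravity \code{sum(x * mu) / sum(mu)} of the aggregated set on
#' its grid.
#'
#' @param grid Sample points over the output domain.
#' @param degrees Aggregated membership degrees at the grid points.
#' @return Crisp value inside the output domain.
#' @export
defuzzify_centroid <- function(grid, degrees) {
  stopifnot(length(grid) == length(degrees))
  s <- sum(degrees)
  if (s <= 0) stop("no rule fired: aggregate set is empty",
                   call. = FALSE)
  sum(grid * degrees) / s
}

# Batch evaluation over a data frame of crisp inputs (one row per case).
# Returns list(value, no_rule_fired, clamped). Out-of-domain inputs are
# clamped to the nearest bound; rows where nothing fires fall back to the
# output-domain midpoint and are flagged.
fis_infer_batch <- function(system, X, chunk = 5000L) {
  stopifnot(inherits(system, "fis"), is.data.frame(X) || is.matrix(X))
  X <- as.data.frame(X)
  need <- names(system$inputs)
  miss <- setdiff(need, names(X))
  if (length(miss))
    stop("missing crisp inputs: ", paste(miss, collapse = ", "))
  n <- nrow(X)
  clamped <- logical(n)
  mu <- list()   # mu[[var]][[level]] = n-vector
  for (vn in need) {
    v <- system$inputs[[vn]]
    x <- as.numeric(X[[vn]])
    out <- x < v$domain[1] | x > v$domain[2]
    clamped <- clamped | (out & !is.na(out))
    x <- pmin(pmax(x, v$domain[1]), v$domain[2])
    mu[[vn]] <- lapply(v$levels, membership, x = x)
  }
  # activation per output level = max over rules with that consequent
  out_levels <- names(system$output$levels)
  act <- matrix(0, n, length(out_levels),
                dimnames = list(NULL, out_levels))
  R <- system$rules
  for (i in seq_len(nrow(R))) {
    w <- R$weight[i]
    if (w <= 0) next
    a <- mu[[R$var1[i]]][[R$lev1[i]]]
    if (!is.na(R$var2[i])) a <- pmin(a, mu[[R$var2[i]]][[R$lev2[i]]])
    a <- w * a
    j <- R$consequent[i]
    act[, j] <- pmax(act[, j], a)
  }
  grid <- output_grid(system)
  M <- vapply(out_levels,
              function(l) membership(system$output$levels[[l]], grid),
              numeric(length(grid)))           # grid_n x L
  value <- numeric(n)
  none <- logical(n)
  mid <- mean(system$output$domain)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    idx <- s:e; m <- length(idx)
    agg <- matrix(0, m, length(grid))
    for (l in seq_along(out_levels)) {
      cl <- pmin(matrix(act[idx, l], m, length(grid)),
                 matrix(M[, l], m, length(grid), byrow = TRUE))
      agg <- pmax(agg, cl)
    }
    den <- rowSums(agg)
    num <- as.numeric(agg %*% grid)
    z <- den <= 0
    value[idx] <- ifelse(z, mid, num / pmax(den, .Machine$double.eps))
    none[idx] <- z
  }
  list(value = value, no_rule_fired = none, clamped = clamped)
}

#' Run a full Mamdani inference pass
#'
#' Fuzzify, fire every rule (weighted min-AND), truncate consequents,
#' aggregate by maximum, defuzzify by centroid. Inputs outside a variable's
#' domain are clamped to the nearest bound. If no rule fires, the
#' output-domain midpoint is returned and flagged so callers can escalate.
#'
#' @param system A \code{fis}.
#' @param inputs Named numeric vector (or 1-row data frame) of crisp values.
#' @param details If \code{TRUE} return a list with \code{value},
#'   \code{no_rule_fired} and \code{clamped}; otherwise the crisp value with
#'   those two flags attached as attributes.
#' @return Crisp output (see \code{details}).
#' @export
fis_infer <- function(system, inputs, details = FALSE) {
  if (!is.data.frame(inputs)) inputs <- as.data.frame(as.list(inputs))
  res <- fis_infer_batch(system, inputs)
  if (details)
    return(list(value = res$value[1], no_rule_fired = res$no_rule_fired[1],
                clamped = res$clamped[1]))
  structure(res$value[1], no_rule_fired = res$no_rule_fired[1],
            clamped = res$clamped[1])
}
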