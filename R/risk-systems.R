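# Concrete configurations of the two concurrent inference systems:
# FIS-1 maps the sensor snapshot to a correction factor on [0, 10] (how
# favourable conditions are to a radon rise); FIS-2 maps radon
# concentration plus that factor to a radon risk percentage on [0, 100].

# Default technical measurement ranges, all config-overridable.
TECH_RANGES <- list(
  radon    = c(0, 1000),   # Bq/m^3
  t_in     = c(-10, 45),   # degC
  t_out    = c(-10, 45),   # degC
  t_diff   = c(-20, 40),   # degC
  pressure = c(950, 1060), # mbar
  wind     = c(0, 120),    # km/h
  rainfall = c(0, 60),     # mm
  humidity = c(0, 100)     # %
)

mirror_level <- function(level) {
  c(low = "high", medium = "medium", high = "low")[[level]]
}

#' Default correction-factor inference system (FIS-1)
#'
#' Inputs are the radon concentration and the seven atmospheric variables,
#' each partitioned low/medium/high over its technical range. The rulebase
#' pairs every atmospheric variable v with radon concentration as second
#' antecedent: for each qualifier combination, a direct-polarity rule
#' "IF v is L AND radon is L_r THEN fc is L" and its inverse-polarity
#' mirror "... THEN fc is mirror(L)" (low and high swapped). That yields
#' 7 variables x 9 combinations x 2 polarities = 126 rules, all starting at
#' the standard weight 0.25; the correlation-driven reweighting later keeps
#' at most one polarity family per variable alive. Output: correction
#' factor on [0, 10].
#'
#' @param ranges Named list of technical ranges to override the defaults.
#' @param grid_n Output grid resolution.
#' @return A \code{\link{fis}} for the correction factor.
#' @export
default_fc_config <- function(ranges = list(), grid_n = 1001) {
  rng <- utils::modifyList(TECH_RANGES, ranges)
  inputs <- lapply(names(rng), function(v)
    lingvar(v, rng[[v]], partition3(rng[[v]][1], rng[[v]][2])))
  names(inputs) <- names(rng)
  out <- lingvar("fc", c(0, 10), partition3(0, 10))
  qualifiers <- c("low", "medium", "high")
  rules <- list()
  for (v in ATMOSPHERIC_VARS)
    for (lv in qualifiers)
      for (lr in qualifiers) {
        ante <- stats::setNames(c(lv, lr), c(v, "radon"))
        rules[[length(rules) + 1L]] <-
          fuzzy_rule(ante, lv, weight = 0.25, polarity = "direct",
                     key_var = v)
        rules[[length(rules) + 1L]] <-
          fuzzy_rule(ante, mirror_level(lv), weight = 0.25,
                     polarity = "inverse", key_var = v)
      }
  fis(inputs, out, do.call(rbind, rules), grid_n = grid_n)
}

#' Default radon-risk inference system (FIS-2)
#'
#' Inputs are the radon concentration, with qualifiers anchored at the
#' regulatory reference levels (low plateau ending at the 100 Bq/m^3 WHO
#' reference, medium reaching full membership at the 148 Bq/m^3 EPA action
#' level, high plateau from the 300 Bq/m^3 EU workplace reference), and the
#' correction factor on [0, 10]. Nine monotone rules ladder each
#' (radon level, fc level) pair onto a five-way risk graduation
#' (very_low .. very_high), strictly increasing in both antecedents, so
#' higher antecedents never map to a lower consequent and the defuzzified
#' risk surface is non-decreasing in both inputs. Output: radon risk on
#' [0, 100].
#'
#' @param radon_range Technical radon range (Bq/m^3).
#' @param grid_n Output grid resolution.
#' @return A \code{\link{fis}} for the radon risk.
#' @export
default_rr_config <- function(radon_range = c(0, 1000), grid_n = 1001) {
  radon <- lingvar("radon", radon_range, list(
    low    = trapmf(radon_range[1], radon_range[1], 100, 148),
    medium = trapmf(100, 148, 200, 300),
    high   = trapmf(200, 300, radon_range[2], radon_range[2])))
  fc <- lingvar("fc", c(0, 10), partition3(0, 10))
  out <- lingvar("rr", c(0, 100), partition5(0, 100))
  qualifiers <- c("low", "medium", "high")
  risk_levels <- names(out$levels)
  rules <- list()
  for (i in 1:3)
    for (j in 1:3)
      rules[[length(rules) + 1L]] <- fuzzy_rule(
        stats::setNames(c(qualifiers[i], qualifiers[j]), c("radon", "fc")),
        risk_levels[i + j - 1], weight = 1, polarity = "direct",
        key_var = "radon")
  fis(list(radon, fc), out, do.call(rbind, rules), grid_n = grid_n)
}

#' Run both inference systems on one measurement record
#'
#' FIS-1 consumes the full sensor snapshot to give the correction factor
#' fc; FIS-2 then combines the radon reading with fc to give the radon
#' risk rr. Any clamp or no-rule-fired event is collected into
#' \code{flags} (callers may escalate those to the check-inference
#' pathway).
#'
#' @param rec A \code{\link{measurement_record}} (or 1-row data frame).
#' @param fc_cfg FIS-1 configuration (default \code{default_fc_config()}).
#' @param rr_cfg FIS-2 configuration (default \code{default_rr_config()}).
#' @return List with \code{fc} in [0,10], \code{rr} in [0,100], and
#'   character vector \code{flags}.
#' @export
compute_outputs <- function(rec, fc_cfg = default_fc_config(),
                            rr_cfg = default_rr_config()) {
  r1 <- fis_infer(fc_cfg, rec[names(fc_cfg$inputs)], details = TRUE)
  r2 <- fis_infer(rr_cfg,
                  data.frame(radon = rec$radon, fc = r1$value),
                  details = TRUE)
  flags <- character(0)
  if (r1$clamped) flags <- c(flags, "fc_input_clamped")
  if (r1$no_rule_fired) flags <- c(flags, "fc_no_rule_fired")
  if (r2$clamped) flags <- c(flags, "rr_input_clamped")
  if (r2$no_rule_fired) flags <- c(flags, "rr_no_rule_fired")
  list(fc = r1$value, rr = r2$value, flags = flags)
}

#' Run both inference systems over every record of a history
#'
#' Vectorised pass filling the \code{fc} and \code{rr} columns.
#'
#' @param kb A \code{radon_kb} (or plain data frame of records).
#' @param fc_cfg,rr_cfg System configurations.
#' @return The knowledge base (or data frame) with fc/rr filled in.
#' @export
infer_history <- function(kb, fc_cfg = default_fc_config(),
                          rr_cfg = default_rr_config()) {
  df <- if (inherits(kb, "radon_kb")) kb$data else kb
  if (!nrow(df)) return(kb)
  r1 <- fis_infer_batch(fc_cfg, df[names(fc_cfg$inputs)])
  r2 <- fis_infer_batch(rr_cfg, data.frame(radon = df$radon,
                                           fc = r1$value))
  df$fc <- r1$value
  df$rr <- r2$value
  if (inherits(kb, "radon_kb")) { kb$data <- df; kb } else df
}

# ---- configuration serialization -------------------------------------

fis_to_list <- function(system) {
  list(
    grid_n = system$grid_n,
    inputs = lapply(system$inputs, function(v)
      list(domain = v$domain,
           levels = lapply(v$levels, function(m) as.numeric(m)))),
    output = list(name = system$output$name, domain = system$output$domain,
                  levels = lapply(system$output$levels, as.numeric)),
    rules = lapply(seq_len(nrow(system$rules)), function(i)
      as.list(system$rules[i, ]))
  )
}

list_to_fis <- function(x) {
  mk <- function(name, spec)
    lingvar(name, as.numeric(spec$domain),
            lapply(spec$levels, function(p) do.call(trapmf, as.list(as.numeric(p)))))
  inputs <- lapply(names(x$inputs), function(n) mk(n, x$inputs[[n]]))
  names(inputs) <- names(x$inputs)
  rules <- do.call(rbind, lapply(x$rules, function(r)
    data.frame(var1 = r$var1, lev1 = r$lev1,
               var2 = if (is.null(r$var2) || is.na(r$var2)) NA_character_ else r$var2,
               lev2 = if (is.null(r$lev2) || is.na(r$lev2)) NA_character_ else r$lev2,
               consequent = r$consequent, weight = as.numeric(r$weight),
               polarity = r$polarity, key_var = r$key_var,
               stringsAsFactors = FALSE)))
  fis(inputs, mk(x$output$name, x$output), rules, grid_n = x$grid_n)
}

#' Write an inference-system configuration to YAML
#'
#' Serialises variable domains, trapezoid breakpoints and the full
#' weighted rulebase so runs are bit-reproducible from the file.
#'
#' @param system A \code{\link{fis}}.
#' @param path Output path (.yaml).
#' @return \code{path}, invisibly.
#' @export
write_fis_config <- function(system, path) {
  yaml::write_yaml(fis_to_list(system), path, precision = 15)
  invisible(path)
}

#' Read an inference-system configuration from YAML
#'
#' @param path Path written by \code{\link{write_fis_config}}.
#' @return A \code{\link{fis}}.
#' @export
read_fis_config <- function(path) {
  list_to_fis(yaml::read_yaml(path))
}

#' Provenance fingerprint of a configuration
#'
#' 32-bit FNV-1a hash of the canonical JSON form of an inference-system
#' (or any jsonlite-serialisable) configuration, printed into every report
#' so results can be traced to the exact configuration that produced them.
#'
#' @param x A \code{fis} or plain list.
#' @return 8-character hex string.
#' @export
config_hash <- function(x) {
  if (inherits(x, "fis")) x <- fis_to_list(x)
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # multiply by the FNV prime 16777619 modulo 2^32, split into 16-bit
    # halves so every intermediate stays inside double precision
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}
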