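# Seeded generator of twice-daily indoor radon + weather series with the
# qualitative structure of the domain phenomenology -- radon higher at night
# than by day, higher in winter than in summer, suppressed by rainfall
# (soil-pore saturation) and drawn up by the indoor-outdoor temperature
# difference (stack effect) -- plus a deterministic ground-truth labelling
# policy so every downstream stage is testable without field data.

#' Simulation parameters
#'
#' Defaults describe a temperate dwelling with a moderate radon baseline:
#' 120 Bq/m^3 baseline, a 30 Bq/m^3 night-positive diurnal swing, a
#' 40 Bq/m^3 winter-positive seasonal swing (365-day sinusoid peaking in
#' mid-January), a -5 (Bq/m^3)/mm rainfall coupling, a +2 (Bq/m^3)/degC
#' stack-effect coupling on the indoor-outdoor temperature difference, and
#' 15 Bq/m^3 measurement noise. Weather channels are mean-reverting AR(1)
#' processes; rainfall is intermittent (30% wet readings, exponential
#' depth). All coefficients are configuration, not claims about any
#' specific site.
#'
#' @param n_days Number of simulated days, >= 1.
#' @param seed RNG seed.
#' @param start_date First calendar day of the series.
#' @param radon_baseline Baseline concentration, Bq/m^3.
#' @param diurnal_amp Night-positive diurnal amplitude, Bq/m^3 (the 24.00 h
#'   reading sits at +amp, the 12.00 h reading at -amp).
#' @param seasonal_amp Winter-positive seasonal amplitude, Bq/m^3.
#' @param rain_coupling Radon response per mm of rainfall (expected < 0).
#' @param tdiff_coupling Radon response per degC of indoor-outdoor
#'   difference (expected > 0).
#' @param radon_noise_sd Measurement noise SD, Bq/m^3.
#' @param t_in_mean,t_in_sd Indoor temperature process, degC.
#' @param t_out_mean,t_out_seasonal_amp,t_out_sd Outdoor temperature
#'   process, degC (seasonal sinusoid peaking in mid-July).
#' @param pressure_mean,pressure_sd Pressure process, mbar.
#' @param wind_mean,wind_sd Wind process, km/h (reflected at 0).
#' @param humidity_mean,humidity_sd Humidity process, percent.
#' @param rain_prob,rain_mean_mm Wet-reading probability and mean depth.
#' @param ar AR(1) coefficient shared by the weather channels, in [0, 1).
#' @param hours Sampling hours within each day.
#' @return Object of class \code{"sim_params"}.
#' @export
sim_params <- function(n_days = 30L, seed = 1L,
                       start_date = as.Date("2020-09-01"),
                       radon_baseline = 120, diurnal_amp = 30,
                       seasonal_amp = 40, rain_coupling = -5,
                       tdiff_coupling = 2, radon_noise_sd = 15,
                       t_in_mean = 21, t_in_sd = 1.5,
                       t_out_mean = 12, t_out_seasonal_amp = 8,
                       t_out_sd = 3,
                       pressure_mean = 1013, pressure_sd = 5,
                       wind_mean = 10, wind_sd = 6,
                       humidity_mean = 70, humidity_sd = 10,
                       rain_prob = 0.3, rain_mean_mm = 4,
                       ar = 0.8, hours = c(12, 24)) {
  stopifnot(n_days >= 1, diurnal_amp >= 0, seasonal_amp >= 0,
            radon_noise_sd >= 0, ar >= 0, ar < 1,
            all(hours > 0), all(hours <= 24))
  structure(as.list(environment()), class = "sim_params")
}

# mean-reverting AR(1) around 0 with stationary SD sd
ar1 <- function(n, ar, sd) {
  if (n == 0) return(numeric(0))
  innov_sd <- sd * sqrt(1 - ar^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  for (i in seq_len(n)[-1]) x[i] <- ar * x[i - 1] + stats::rnorm(1, 0, innov_sd)
  x
}

#' Simulate a twice-daily measurement series
#'
#' Generates \code{length(hours) * n_days} validated records at the
#' configured sampling hours. Identical seeds give identical series. The
#' radon channel is baseline + seasonal sinusoid + diurnal alternation +
#' linear rainfall and temperature-difference couplings + Gaussian noise,
#' clipped at zero.
#'
#' @param params A \code{\link{sim_params}}.
#' @return Data frame of measurement records (internal column names),
#'   strictly ordered in time.
#' @export
simulate_series <- function(params = sim_params()) {
  p <- params
  set.seed(p$seed)
  n <- p$n_days * length(p$hours)
  day <- rep(encode_date(p$start_date) + seq_len(p$n_days) - 1L,
             each = length(p$hours))
  hour <- rep(sort(p$hours), times = p$n_days)
  doy <- as.integer(format(decode_date(day), "%j"))
  # winter-positive seasonal term: peak around 15 January (doy 15)
  season <- cos(2 * pi * (doy - 15) / 365)
  t_out <- p$t_out_mean - p$t_out_seasonal_amp * season +
    ar1(n, p$ar, p$t_out_sd)
  t_in <- p$t_in_mean + ar1(n, p$ar, p$t_in_sd)
  t_diff <- t_in - t_out
  pressure <- p$pressure_mean + ar1(n, p$ar, p$pressure_sd)
  wind <- abs(p$wind_mean + ar1(n, p$ar, p$wind_sd))
  humidity <- pmin(100, pmax(0, p$humidity_mean + ar1(n, p$ar, p$humidity_sd)))
  rainfall <- stats::rbinom(n, 1, p$rain_prob) *
    stats::rexp(n, 1 / p$rain_mean_mm)
  night <- ifelse(hour >= 21 | hour <= 6, 1, -1)
  radon <- p$radon_baseline +
    p$seasonal_amp * season +
    p$diurnal_amp * night +
    p$rain_coupling * rainfall +
    p$tdiff_coupling * t_diff +
    stats::rnorm(n, 0, p$radon_noise_sd)
  radon <- pmax(0, radon)
  data.frame(day_serial = day, hour = hour, radon = radon, t_in = t_in,
             t_out = t_out, t_diff = t_diff, pressure = pressure,
             wind = wind, rainfall = rainfall, humidity = humidity)
}

#' Simulate straight into a knowledge-base file
#'
#' Writes the series in the datastore format and the parameters alongside
#' as YAML for provenance.
#'
#' @param params A \code{\link{sim_params}}.
#' @param path Knowledge-base file to write.
#' @return The \code{\link{knowledge_base}}, invisibly.
#' @export
simulate_to_file <- function(params = sim_params(), path) {
  kb <- knowledge_base(simulate_series(params))
  write_history(kb, path)
  pl <- unclass(params)
  pl$start_date <- as.character(pl$start_date)
  yaml::write_yaml(pl, paste0(path, ".params.yaml"))
  invisible(kb)
}

#' Default ground-truth labelling policy
#'
#' A deterministic stand-in for the bootstrap labels a user sets before
#' autonomous operation (synthetic: it encodes no field expertise beyond
#' the regulatory anchors). Thresholds, all configurable:
#' \itemize{
#'   \item activate_forced: 5 above 300 Bq/m^3, 3 above 148, 1 above 100,
#'     else 0;
#'   \item deactivate_forced: 4 when radon is below 100 and risk below 35,
#'     else 0;
#'   \item natural_vent: 4 between 100 and 300 Bq/m^3, else 0;
#'   \item check_sensors: 5 when humidity exceeds 95% (saturation-suspect
#'     reading), else 0;
#'   \item check_inference: 5 when the risk score disagrees with the raw
#'     reading (rr above 66 with radon below 100), else 0;
#'   \item check_exposure: 2 when rr is at least 66, else 0.
#' }
#'
#' @param radon_levels Regulatory anchors \code{c(low, action, high)}.
#' @param rr_high Risk threshold for the exposure check.
#' @return Object of class \code{"label_policy"} (callable via
#'   \code{\link{label_records}}).
#' @export
default_label_policy <- function(radon_levels = c(100, 148, 300),
                                 rr_high = 66) {
  force(radon_levels); force(rr_high)
  fn <- function(radon, rr, fc, humidity, ...) {
    clamp5 <- function(x) pmin(5, pmax(0, x))
    data.frame(
      activate_forced = clamp5(ifelse(radon > radon_levels[3], 5,
                               ifelse(radon > radon_levels[2], 3,
                               ifelse(radon > radon_levels[1], 1, 0)))),
      deactivate_forced = clamp5(ifelse(radon < radon_levels[1] & rr < 35,
                                        4, 0)),
      natural_vent = clamp5(ifelse(radon > radon_levels[1] &
                                     radon <= radon_levels[3], 4, 0)),
      check_sensors = clamp5(ifelse(humidity > 95, 5, 0)),
      check_inference = clamp5(ifelse(rr > rr_high &
                                        radon < radon_levels[1], 5, 0)),
      check_exposure = clamp5(ifelse(rr >= rr_high, 2, 0)))
  }
  structure(fn, class = c("label_policy", "function"),
            needs = c("radon", "rr", "fc", "humidity"))
}

#' Apply a labelling policy to records
#'
#' Deterministically fills the six recommendation labels, each in [0, 5].
#'
#' @param records Data frame (or \code{radon_kb}) carrying every field the
#'   policy needs (the default policy needs radon, rr, fc, humidity, so
#'   run \code{\link{infer_history}} first).
#' @param policy A \code{\link{default_label_policy}}-style function.
#' @return The records (or kb) with the six label columns filled.
#' @export
label_records <- function(records, policy = default_label_policy()) {
  df <- if (inherits(records, "radon_kb")) records$data else records
  need <- attr(policy, "needs")
  if (!is.null(need)) {
    miss <- setdiff(need, names(df))
    ok <- vapply(intersect(need, names(df)),
                 function(cc) !anyNA(df[[cc]]), TRUE)
    if (length(miss) || !all(ok))
      stop("policy needs fields unavailable or incomplete: ",
           paste(c(miss, names(ok)[!ok]), collapse = ", "), call. = FALSE)
  }
  labs <- do.call(policy, c(unname(as.list(df[need]))))
  stopifnot(identical(names(labs), REC_NAMES), nrow(labs) == nrow(df))
  if (any(as.matrix(labs) < 0 | as.matrix(labs) > 5))
    stop("policy produced labels outside [0, 5]")
  for (cc in REC_NAMES) df[[cc]] <- labs[[cc]]
  if (inherits(records, "radon_kb")) { records$data <- df; records }
  else df
}
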