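# Knowledge-base store: validated sensor readings plus inferred columns
# (fc, rr) and the six user-set recommendation labels, persisted as
# delimited text.

KB_SENSOR_COLS <- c("day", "hour", "radon_bq_m3", "t_in_c", "t_out_c",
                    "t_diff_c", "pressure_mbar", "wind_kmh", "rainfall_mm",
                    "humidity_pct")
KB_INFERRED_COLS <- c("fc", "rr")
REC_NAMES <- c("activate_forced", "deactivate_forced", "natural_vent",
               "check_sensors", "check_inference", "check_exposure")
KB_LABEL_COLS <- paste0("rec_", REC_NAMES)

# internal (in-memory) column names, aligned with KB_SENSOR_COLS
KB_FIELDS <- c("day_serial", "hour", "radon", "t_in", "t_out", "t_diff",
               "pressure", "wind", "rainfall", "humidity")

#' Encode a calendar date as an integer day serial
#'
#' Days elapsed since the 1899-12-30 epoch, the spreadsheet-style
#' convention under which 2020-09-01 encodes as 44075. Consecutive dates
#' differ by exactly 1. Dates before 1900-03-01 are rejected: the historic
#' epoch convention diverges there and is deliberately not emulated.
#'
#' @param date A \code{Date}, or anything \code{as.Date} accepts.
#' @return Integer day serial(s).
#' @examples
#' encode_date("2020-09-01")  # 44075
#' @export
encode_date <- function(date) {
  d <- tryCatch(as.Date(date), error = function(e) NA)
  if (anyNA(d)) stop("unparseable date")
  if (any(d < as.Date("1900-03-01")))
    stop("unsupported date before 1900-03-01")
  as.integer(d - as.Date("1899-12-30"))
}

#' Decode a day serial back to a calendar date
#'
#' Inverse of \code{\link{encode_date}}.
#'
#' @param serial Integer day serial(s).
#' @return \code{Date} vector.
#' @export
decode_date <- function(serial) {
  as.Date("1899-12-30") + as.numeric(serial)
}

#' A validated measurement record
#'
#' One timestamped sensor reading. The hour is a decimal in \code{(0, 24]}
#' with 24.00 meaning the end of the named day (a midnight reading belongs
#' to the day it closes, not to hour 0 of the next). Validation enforces
#' the physical invariants: non-negative radon, wind and rainfall, humidity
#' in \code{[0, 100]}, positive pressure, and \code{t_diff == t_in - t_out}
#' within 1e-6.
#'
#' @param day_serial Integer day code (see \code{\link{encode_date}}).
#' @param hour Decimal hour in \code{(0, 24]}.
#' @param radon Radon concentration, Bq/m^3, >= 0.
#' @param t_in,t_out Indoor / outdoor temperature, degrees C.
#' @param t_diff Indoor-outdoor difference, degrees C; defaults to
#'   \code{t_in - t_out}.
#' @param pressure Atmospheric pressure, mbar, > 0.
#' @param wind Wind speed, km/h, >= 0.
#' @param rainfall Rainfall, mm, >= 0.
#' @param humidity Relative humidity, percent, in \code{[0, 100]}.
#' @return One-row data frame of class \code{"measurement_record"}.
#' @export
measurement_record <- function(day_serial, hour, radon, t_in, t_out,
                               t_diff = t_in - t_out, pressure, wind,
                               rainfall, humidity) {
  rec <- data.frame(day_serial = as.integer(day_serial), hour = hour,
                    radon = radon, t_in = t_in, t_out = t_out,
                    t_diff = t_diff, pressure = pressure, wind = wind,
                    rainfall = rainfall, humidity = humidity)
  err <- validate_records(rec)
  if (length(err)) stop(paste(err, collapse = "; "), call. = FALSE)
  class(rec) <- c("measurement_record", "data.frame")
  rec
}

# returns character vector of problems, "" prefix = row label
validate_records <- function(df, rows = seq_len(nrow(df))) {
  problems <- character(0)
  chk <- function(bad, field, what) {
    bad <- which(bad | is.na(bad))
    if (length(bad))
      problems <<- c(problems, sprintf("row %d: %s %s", rows[bad], field, what))
  }
  chk(!is.finite(df$day_serial), "day_serial", "is not numeric")
  chk(!is.finite(df$hour) | df$hour <= 0 | df$hour > 24, "hour",
      "must lie in (0, 24]")
  chk(!is.finite(df$radon) | df$radon < 0, "radon", "must be >= 0")
  chk(!is.finite(df$t_in), "t_in", "is not numeric")
  chk(!is.finite(df$t_out), "t_out", "is not numeric")
  chk(!is.finite(df$t_diff) |
        abs(df$t_diff - (df$t_in - df$t_out)) > 1e-6, "t_diff",
      "must equal t_in - t_out")
  chk(!is.finite(df$pressure) | df$pressure <= 0, "pressure", "must be > 0")
  chk(!is.finite(df$wind) | df$wind < 0, "wind", "must be >= 0")
  chk(!is.finite(df$rainfall) | df$rainfall < 0, "rainfall", "must be >= 0")
  chk(!is.finite(df$humidity) | df$humidity < 0 | df$humidity > 100,
      "humidity", "must lie in [0, 100]")
  problems
}

#' Construct a knowledge base
#'
#' Orders records strictly by (day_serial, hour); duplicate timestamps are
#' rejected. Inferred columns (\code{fc}, \code{rr}) and the six
#' recommendation labels are carried as NA until computed or set.
#'
#' @param records Data frame with the measurement columns (internal names
#'   \code{day_serial, hour, radon, t_in, t_out, t_diff, pressure, wind,
#'   rainfall, humidity}); may already carry fc/rr/label columns.
#' @param last_training_index Index of the last record included in tree
#'   training (0 = never trained).
#' @return Object of class \code{"radon_kb"}.
#' @export
knowledge_base <- function(records = NULL, last_training_index = 0L) {
  label_cols <- REC_NAMES
  if (is.null(records) || nrow(records) == 0) {
    df <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(c(KB_FIELDS, KB_INFERRED_COLS, label_cols))),
      c(KB_FIELDS, KB_INFERRED_COLS, label_cols)))
  } else {
    miss <- setdiff(KB_FIELDS, names(records))
    if (length(miss))
      stop("records lack columns: ", paste(miss, collapse = ", "))
    err <- validate_records(records)
    if (length(err)) stop(paste(err, collapse = "; "), call. = FALSE)
    df <- records
    for (cc in c(KB_INFERRED_COLS, label_cols))
      if (!cc %in% names(df)) df[[cc]] <- NA_real_
    df <- df[c(KB_FIELDS, KB_INFERRED_COLS, label_cols)]
    key <- df$day_serial * 24 + df$hour
    if (anyDuplicated(key)) stop("duplicate timestamps in records")
    if (is.unsorted(key, strictly = TRUE)) df <- df[order(key), ]
    bad <- which(!is.na(df[label_cols]) & (df[label_cols] < 0 | df[label_cols] > 5),
                 arr.ind = TRUE)
    if (nrow(bad)) stop("recommendation labels must lie in [0, 5]")
    rownames(df) <- NULL
  }
  structure(list(data = df,
                 last_training_index = as.integer(last_training_index)),
            class = "radon_kb")
}

#' @export
print.radon_kb <- function(x, ...) {
  cat("Radon knowledge base:", nrow(x$data), "records;",
      sum(!is.na(x$data$fc)), "with inferred fc/rr;",
      sum(stats::complete.cases(x$data[REC_NAMES])), "labelled;",
      new_since_training(x), "since last training\n")
  invisible(x)
}

#' Records accumulated since the last tree training
#' @param kb A knowledge base.
#' @return Integer count.
#' @export
new_since_training <- function(kb) {
  nrow(kb$data) - kb$last_training_index
}

#' Append one record to the knowledge base
#'
#' The record's timestamp must be strictly later than the last stored one.
#'
#' @param kb A \code{radon_kb}.
#' @param rec A \code{\link{measurement_record}} (or 1-row data frame with
#'   the measurement columns).
#' @return The grown knowledge base.
#' @export
append_record <- function(kb, rec) {
  stopifnot(inherits(kb, "radon_kb"))
  err <- validate_records(rec)
  if (length(err)) stop(paste(err, collapse = "; "), call. = FALSE)
  if (nrow(kb$data)) {
    last <- kb$data[nrow(kb$data), ]
    if (rec$day_serial * 24 + rec$hour <= last$day_serial * 24 + last$hour)
      stop("out-of-order or duplicate timestamp", call. = FALSE)
  }
  row <- rec[intersect(names(kb$data), names(rec))]
  for (cc in setdiff(names(kb$data), names(row))) row[[cc]] <- NA_real_
  kb$data <- rbind(kb$data, row[names(kb$data)])
  rownames(kb$data) <- NULL
  kb
}

#' Read a knowledge-base file
#'
#' Parses a delimited-text file with the ten sensor columns
#' (\code{day,hour,radon_bq_m3,t_in_c,t_out_c,t_diff_c,pressure_mbar,
#' wind_kmh,rainfall_mm,humidity_pct}) plus optional inferred/label
#' columns. Every row is validated; malformed rows are reported with their
#' line numbers. Missing sensor values reject the row rather than being
#' imputed: the methodology assumes complete readings, and a rejected row
#' is itself a signal for the check-sensors pathway.
#'
#' @param path File path.
#' @param sep Field delimiter (default comma). The decimal separator is
#'   always ".".
#' @return A \code{\link{knowledge_base}}.
#' @export
read_history <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = NA)
  miss <- setdiff(KB_SENSOR_COLS, names(df))
  if (length(miss))
    stop("schema error: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- stats::setNames(df[KB_SENSOR_COLS], KB_FIELDS)
  for (k in seq_along(KB_FIELDS)) {
    v <- out[[k]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop("validation error: non-numeric value in column '",
             KB_SENSOR_COLS[k], "' at data row ", bad[1], call. = FALSE)
      v <- vn
    }
    out[[KB_FIELDS[k]]] <- v
  }
  err <- validate_records(out)
  if (length(err))
    stop("validation error: ", paste(err, collapse = "; "), call. = FALSE)
  for (k in seq_along(KB_LABEL_COLS)) {
    src <- KB_LABEL_COLS[k]
    if (src %in% names(df)) out[[REC_NAMES[k]]] <- as.numeric(df[[src]])
  }
  for (cc in KB_INFERRED_COLS)
    if (cc %in% names(df)) out[[cc]] <- as.numeric(df[[cc]])
  knowledge_base(out)
}

#' Write a knowledge base to delimited text
#'
#' Inverse of \code{\link{read_history}}: the header uses the external
#' column names and all present inferred/label columns are appended.
#'
#' @param kb A \code{radon_kb}.
#' @param path Output file path.
#' @param sep Field delimiter.
#' @return \code{path}, invisibly.
#' @export
write_history <- function(kb, path, sep = ",") {
  stopifnot(inherits(kb, "radon_kb"))
  df <- kb$data
  out <- stats::setNames(df[KB_FIELDS], KB_SENSOR_COLS)
  for (cc in KB_INFERRED_COLS)
    if (any(!is.na(df[[cc]]))) out[[cc]] <- df[[cc]]
  for (k in seq_along(REC_NAMES))
    if (any(!is.na(df[[REC_NAMES[k]]])))
      out[[KB_LABEL_COLS[k]]] <- df[[REC_NAMES[k]]]
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
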