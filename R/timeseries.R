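# Monitoring time-series data model: record container, time arithmetic,
# CSV input/output and annual aggregation.

# Strict ISO-8601 date parsing; returns Date or NA per element.
parse_iso_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

#' Days elapsed since the Chernobyl accident
#'
#' Converts calendar dates to the whole-day count used as the model time
#' coordinate, with day 0 on 1986-04-26 (Gregorian calendar, leap years
#' included).
#'
#' @param date A `Date` vector, or character in `YYYY-MM-DD` form.
#' @return Numeric vector of day counts (0 on the accident day).
#' @examples
#' days_since_accident("1986-04-26")  # 0
#' days_since_accident("1990-01-01")  # 1346
#' @export
days_since_accident <- function(date) {
  d <- parse_iso_date(date)
  if (anyNA(d)) {
    stop("unparseable date(s): ", paste(utils::head(date[is.na(d)], 3), collapse = ", "),
         " (expected YYYY-MM-DD)")
  }
  if (any(d < accident_date)) {
    stop("date(s) before the accident (1986-04-26) are outside the model domain: ",
         paste(format(utils::head(d[d < accident_date], 3)), collapse = ", "))
  }
  as.numeric(d - accident_date)
}

#' Construct a monitoring record set
#'
#' Builds the record container used throughout the package: one row per
#' stream sample with its date, days since the accident, discharge `Q`
#' (mm/day), dissolved concentration `C` (Bq/m3) and, optionally, the
#' relative measurement error in percent. Rows are sorted by date. All
#' admitted records must have strictly positive `Q` and `C` (log-space
#' computations downstream require it).
#'
#' @param date Sample dates (`Date` or `YYYY-MM-DD` character).
#' @param Q Discharge, mm/day, strictly positive.
#' @param C Dissolved concentration, Bq/m3, strictly positive.
#' @param err_pct Optional relative measurement error, percent, nonnegative.
#' @return A data frame of class `sr_records` with columns `date`, `t_days`,
#'   `Q`, `C` and (if supplied) `err_pct`.
#' @export
sr_records <- function(date, Q, C, err_pct = NULL) {
  d <- parse_iso_date(date)
  if (anyNA(d)) stop("unparseable date(s) in record set")
  n <- length(d)
  Q <- as.numeric(Q); C <- as.numeric(C)
  if (length(Q) != n || length(C) != n) stop("date, Q and C must have equal length")
  if (anyNA(Q) || any(Q <= 0)) stop("all records must have Q > 0")
  if (anyNA(C) || any(C <= 0)) stop("all records must have C > 0")
  out <- data.frame(date = d, t_days = days_since_accident(d), Q = Q, C = C)
  if (!is.null(err_pct)) {
    err_pct <- as.numeric(err_pct)
    if (length(err_pct) != n) stop("err_pct must match the number of records")
    if (any(err_pct < 0, na.rm = TRUE)) stop("err_pct must be nonnegative")
    out$err_pct <- err_pct
  }
  out <- out[order(out$date), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sr_records", "data.frame")
  out
}

#' Read a monitoring series from CSV
#'
#' Expects columns `date` (ISO 8601), `discharge_mm_day`, `sr90_bq_m3` and
#' optionally `err_pct`. Rows with missing or nonpositive discharge or
#' concentration are excluded (they cannot enter any log-space computation);
#' the number excluded is reported via [message()] and attached as the
#' `n_excluded` attribute.
#'
#' @param path Path to the CSV file.
#' @param quiet Suppress the load report message.
#' @return An [sr_records] data frame, sorted by date, with attribute
#'   `n_excluded`.
#' @export
read_timeseries <- function(path, quiet = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                         check.names = FALSE)
  required <- c("date", "discharge_mm_day", "sr90_bq_m3")
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    stop("missing required column(s): ", paste(sQuote(miss), collapse = ", "))
  }
  d <- parse_iso_date(raw$date)
  bad <- which(is.na(d) & nzchar(trimws(raw$date)))
  if (length(bad)) {
    stop("malformed date in row ", bad[1], ", column 'date': ", sQuote(raw$date[bad[1]]))
  }
  if (anyNA(d)) stop("empty date in row ", which(is.na(d))[1], ", column 'date'")
  num_col <- function(col) {
    x <- trimws(raw[[col]])
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & nzchar(x))
    if (length(bad)) {
      stop("non-numeric value in row ", bad[1], ", column ", sQuote(col), ": ",
           sQuote(raw[[col]][bad[1]]))
    }
    v
  }
  Q <- num_col("discharge_mm_day")
  C <- num_col("sr90_bq_m3")
  err <- if ("err_pct" %in% names(raw)) num_col("err_pct") else NULL
  if (!is.null(err) && any(err < 0, na.rm = TRUE)) {
    stop("negative value in column 'err_pct' (row ", which(err < 0)[1], ")")
  }
  keep <- !is.na(Q) & Q > 0 & !is.na(C) & C > 0
  n_excluded <- sum(!keep)
  if (n_excluded && !quiet) {
    message(n_excluded, " row(s) with missing or nonpositive discharge/concentration excluded")
  }
  out <- sr_records(d[keep], Q[keep], C[keep],
                    err_pct = if (!is.null(err)) err[keep])
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Write a monitoring series to CSV
#'
#' Inverse of [read_timeseries()]; numeric fields are written with 17
#' significant digits so that a write/read round trip reproduces the values
#' exactly.
#'
#' @param records An [sr_records] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- data.frame(
    date = format(records$date, "%Y-%m-%d"),
    discharge_mm_day = sprintf("%.17g", records$Q),
    sr90_bq_m3 = sprintf("%.17g", records$C),
    stringsAsFactors = FALSE
  )
  if (!is.null(records$err_pct)) out$err_pct <- sprintf("%.17g", records$err_pct)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Annual mean concentrations
#'
#' Aggregates a monitoring series into calendar-year arithmetic means, the
#' level at which the long-term trend model is fitted (annual averaging
#' suppresses the within-year concentration-discharge fluctuation). The
#' representative time of each year, `t_repr`, is the arithmetic mean of the
#' sampling times of that year's records. Years with a single sample are
#' retained: the early part of typical monitoring records is sparse.
#'
#' @param records An [sr_records] data frame (at least one record).
#' @return Data frame with columns `year`, `mean_C` (Bq/m3), `t_repr`
#'   (days since the accident) and `n` (sample count), ordered by year.
#' @export
annual_means <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("at least one record is required")
  }
  year <- as.integer(format(records$date, "%Y"))
  mc <- tapply(records$C, year, mean)
  tr <- tapply(records$t_days, year, mean)
  nn <- tapply(records$C, year, length)
  out <- data.frame(
    year = as.integer(names(mc)),
    mean_C = as.numeric(mc),
    t_repr = as.numeric(tr),
    n = as.integer(nn)
  )
  out[order(out$year), , drop = FALSE]
}
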