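# Empirical power-law concentration-discharge analysis: decay correction,
# period splitting, log-log OLS fits, discharge binning and the
# declining-exponent report.

#' Decay-correct a monitoring series
#'
#' Divides every observed concentration by the long-term baseline
#' `C_ref(t)` at the sample time, replacing `C` by the dimensionless ratio
#' `C / C_ref`. This removes the decadal attenuation (physical decay plus
#' environmental rates) before examining the concentration-discharge
#' relationship. Applying the correction twice would divide by the
#' baseline again, so corrected record sets are flagged and refuse a
#' second pass.
#'
#' @param records An [sr_records] data frame.
#' @param trend A [trend_params] object with `alpha + beta > 0`.
#' @return The records with `C` replaced by the ratio and attribute
#'   `decay_corrected = TRUE`.
#' @export
decay_correct <- function(records, trend) {
  if (isTRUE(attr(records, "decay_corrected"))) {
    stop("records are already decay-corrected; refusing to correct twice")
  }
  if (trend$alpha + trend$beta <= 0) {
    stop("degenerate trend (alpha + beta = 0): baseline is identically zero")
  }
  ref <- c_ref(records$t_days, trend)
  if (any(ref <= 0)) stop("baseline C_ref is zero at one or more record times")
  records$C <- records$C / ref
  attr(records, "decay_corrected") <- TRUE
  records
}

parse_period <- function(p) {
  if (is.character(p)) p <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
  if (length(p) != 2 || anyNA(p) || p[1] > p[2]) {
    stop("each period must be a start-end year pair, e.g. '1991-2000'")
  }
  as.integer(p)
}

#' Split records into analysis periods
#'
#' Assigns each record to at most one period by the calendar year of its
#' sampling date, inclusive of both endpoint years (a record dated
#' 2000-12-31 belongs to a 1991-2000 period). Records outside every period
#' are returned in the `unassigned` element, never silently dropped.
#'
#' @param records An [sr_records] data frame.
#' @param periods List (or character vector) of year ranges, e.g.
#'   `c("1991-2000", "2001-2010", "2011-2016")`; must be ordered and
#'   non-overlapping.
#' @return Named list of record subsets, one per period (names
#'   `"start-end"`), plus an `unassigned` element.
#' @export
split_periods <- function(records, periods) {
  pp <- lapply(periods, parse_period)
  if (length(pp) > 1) {
    for (i in seq_len(length(pp) - 1)) {
      if (pp[[i + 1]][1] <= pp[[i]][2]) {
        stop("periods must be ordered and non-overlapping")
      }
    }
  }
  year <- as.integer(format(records$date, "%Y"))
  assigned <- rep(0L, nrow(records))
  for (i in seq_along(pp)) {
    assigned[year >= pp[[i]][1] & year <= pp[[i]][2]] <- i
  }
  out <- lapply(seq_along(pp), function(i) records[assigned == i, , drop = FALSE])
  names(out) <- vapply(pp, function(p) paste0(p[1], "-", p[2]), character(1))
  out$unassigned <- records[assigned == 0L, , drop = FALSE]
  out
}

#' Fit a power law to concentration-discharge pairs
#'
#' Ordinary least squares of `log y` on `log Q`: the fitted relation is
#' `y = p Q^q` with `q` the log-log slope and `p = exp(intercept)` (the
#' value of `y` at `Q = 1`). Fitting uses the raw (unbinned) points.
#'
#' @param pairs Data frame with columns `Q` and `C` (the response:
#'   concentration, or the decay-corrected ratio), all strictly positive;
#'   at least 3 rows with non-degenerate `Q`. A `t_days` column, when
#'   present, yields `t_harm`, the harmonic-mean sample time (the natural
#'   time at which to compare the fitted exponent with the model slope
#'   `d/(b t)`, which is proportional to `1/t`).
#' @param period Optional year range label attached to the fit.
#' @return An object of class `power_law_fit`: list with `p`, `q`,
#'   `r_squared_loglog`, `n`, `period`, `t_harm` (or `NA`).
#' @export
fit_power_law <- function(pairs, period = NULL) {
  if (!is.data.frame(pairs) || !all(c("Q", "C") %in% names(pairs))) {
    stop("pairs must be a data frame with columns Q and C")
  }
  if (nrow(pairs) < 3) stop("at least 3 pairs are required")
  if (any(pairs$Q <= 0) || any(pairs$C <= 0)) {
    stop("all Q and C values must be strictly positive")
  }
  lx <- log(pairs$Q); ly <- log(pairs$C)
  if (stats::var(lx) == 0) stop("zero variance in log Q: the slope is undefined")
  fit <- stats::lm(ly ~ lx)
  cf <- stats::coef(fit)
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((ly - mean(ly))^2)
  t_harm <- if ("t_days" %in% names(pairs)) 1 / mean(1 / pairs$t_days) else NA_real_
  structure(list(p = exp(unname(cf[1])), q = unname(cf[2]),
                 r_squared_loglog = r2, n = nrow(pairs),
                 period = if (is.null(period)) NULL else parse_period(period),
                 t_harm = t_harm),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  lab <- if (is.null(x$period)) "" else paste0(" [", x$period[1], "-", x$period[2], "]")
  cat(sprintf("Power law%s: y = %.4g * Q^%.4g  (n = %d, log-log R^2 = %.3f)\n",
              lab, x$p, x$q, x$n, x$r_squared_loglog))
  invisible(x)
}

#' Bin concentration-discharge pairs into discharge classes
#'
#' Splits the pairs into `n_bins` equal-count classes by log-discharge
#' rank (equal-count binning keeps the sparse high-discharge tail
#' populated) and summarises each class: mean discharge, mean response and
#' the 25%/75% response quantiles. Intended for display alongside the raw
#' points, mirroring the usual binned C-Q plot.
#'
#' @param pairs Data frame with positive columns `Q` and `C`.
#' @param n_bins Number of classes; bin counts differ by at most one.
#' @return Data frame with one row per bin: `bin`, `n`, `mean_Q`,
#'   `mean_C`, `q25`, `q75`.
#' @export
bin_by_discharge <- function(pairs, n_bins = 10L) {
  if (!is.data.frame(pairs) || !all(c("Q", "C") %in% names(pairs))) {
    stop("pairs must be a data frame with columns Q and C")
  }
  n <- nrow(pairs)
  if (n < n_bins) stop("fewer pairs (", n, ") than bins (", n_bins, ")")
  if (any(pairs$Q <= 0) || any(pairs$C <= 0)) stop("all values must be positive")
  ord <- order(log(pairs$Q))
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  idx <- rep(seq_len(n_bins), sizes)
  out <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    rows <- pairs[ord[idx == b], , drop = FALSE]
    data.frame(bin = b, n = nrow(rows), mean_Q = mean(rows$Q),
               mean_C = mean(rows$C),
               q25 = unname(stats::quantile(rows$C, 0.25, type = 7)),
               q75 = unname(stats::quantile(rows$C, 0.75, type = 7)))
  }))
  rownames(out) <- NULL
  out
}

#' Exponent trend across periods
#'
#' Collects period-wise power-law fits into an ordered report of the
#' fitted exponents, flags whether the exponent declines strictly with
#' time, and — when the generating model parameters are supplied —
#' compares each exponent with the model slope `d/(b t)` evaluated at the
#' period's harmonic-mean sample time.
#'
#' @param fits List of [fit_power_law()] results, each carrying a
#'   `period`; periods must be ordered and disjoint.
#' @param cq Optional [cq_params]; adds the model-implied exponent and the
#'   relative deviation per period.
#' @return Data frame with one row per period (`period`, `mid_year`, `p`,
#'   `q`, `n`, and when `cq` is given `q_model`, `rel_dev`), with
#'   attribute `strictly_decreasing`.
#' @export
slope_trend <- function(fits, cq = NULL) {
  if (length(fits) < 2) stop("at least 2 period fits are required")
  per <- lapply(fits, function(f) {
    if (is.null(f$period)) stop("every fit must carry a period")
    f$period
  })
  for (i in seq_len(length(per) - 1)) {
    if (per[[i + 1]][1] <= per[[i]][2]) {
      stop("period fits must be ordered and disjoint")
    }
  }
  out <- data.frame(
    period = vapply(per, function(p) paste0(p[1], "-", p[2]), character(1)),
    mid_year = vapply(per, function(p) mean(p) + 0.5, numeric(1)),
    p = vapply(fits, `[[`, numeric(1), "p"),
    q = vapply(fits, `[[`, numeric(1), "q"),
    n = vapply(fits, `[[`, numeric(1), "n"),
    stringsAsFactors = FALSE
  )
  if (!is.null(cq)) {
    th <- vapply(fits, `[[`, numeric(1), "t_harm")
    if (anyNA(th)) stop("fits lack t_harm; fit with a t_days column to compare with the model")
    out$q_model <- model_exponent(th, cq)
    out$rel_dev <- out$q / out$q_model - 1
  }
  attr(out, "strictly_decreasing") <- all(diff(out$q) < 0)
  out
}
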