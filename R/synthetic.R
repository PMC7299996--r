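# Synthetic monitoring-series generator: a seeded stand-in for a
# biweekly-sampled small-catchment record with a snowmelt-driven
# hydrograph and concentrations drawn from the C-Q formation model.

#' Configuration of the synthetic catchment generator
#'
#' Defaults emulate a biweekly 1990-2016 monitoring record of a small,
#' flat, snowmelt-dominated catchment: discharge is a phenomenological
#' seasonal shape (baseflow, a Gaussian snowmelt bump peaking in
#' mid-April, a late-summer trough) under multiplicative lognormal
#' variability, clipped to the envelope 0.004-4.2 mm/day; concentrations
#' follow the closed-form C-Q model with the double-exponential baseline
#' and 10.9% multiplicative measurement noise. The default trend and C-Q
#' parameters are the package's reference parameter set for a heavily
#' contaminated catchment (see [trend_params] and [cq_params]).
#'
#' @param start,end First and last sampling dates.
#' @param interval_days Sampling interval, days.
#' @param baseflow Baseflow discharge, mm/day.
#' @param peak_amplitude Additive snowmelt peak amplitude, mm/day.
#' @param peak_doy,peak_width Day-of-year centre and Gaussian width of the
#'   snowmelt bump, days.
#' @param summer_trough Multiplicative factor the baseflow drops to at the
#'   centre of the summer trough (1 = no trough).
#' @param trough_doy,trough_width Day-of-year centre and width of the
#'   trough, days.
#' @param q_noise_cv Lognormal coefficient of variation of the discharge
#'   noise (mean-one).
#' @param q_floor,q_cap Clipping envelope for the generated discharge,
#'   mm/day.
#' @param trend A [trend_params] object (the generating baseline).
#' @param cq A [cq_params] object (the generating C-Q model).
#' @param noise_cv Multiplicative measurement-noise coefficient of
#'   variation on concentrations.
#' @param seed Integer seed; discharge uses `seed`, concentration noise
#'   `seed + 1`.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(start = "1990-01-01", end = "2016-12-31",
                             interval_days = 14L,
                             baseflow = 0.08, peak_amplitude = 1.0,
                             peak_doy = 105, peak_width = 30,
                             summer_trough = 0.25, trough_doy = 220,
                             trough_width = 50,
                             q_noise_cv = 0.6, q_floor = 0.004, q_cap = 4.2,
                             trend = trend_params(9357, 2500, 0.254, 0.002),
                             cq = cq_params(0.28, 1.37, 2117),
                             noise_cv = 0.109, seed = 1L) {
  cfg <- list(start = as.character(start), end = as.character(end),
              interval_days = as.integer(interval_days),
              baseflow = baseflow, peak_amplitude = peak_amplitude,
              peak_doy = peak_doy, peak_width = peak_width,
              summer_trough = summer_trough, trough_doy = trough_doy,
              trough_width = trough_width,
              q_noise_cv = q_noise_cv, q_floor = q_floor, q_cap = q_cap,
              trend = trend, cq = cq, noise_cv = noise_cv,
              seed = as.integer(seed))
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(parse_iso_date(cfg$start) <= parse_iso_date(cfg$end), "start must not follow end")
  chk(cfg$interval_days >= 1, "interval_days must be >= 1")
  chk(cfg$q_floor > 0, "q_floor must be positive")
  chk(cfg$q_cap > cfg$q_floor, "q_cap must exceed q_floor")
  chk(cfg$baseflow >= 0 && cfg$peak_amplitude >= 0, "flows must be nonnegative")
  chk(cfg$summer_trough > 0 && cfg$summer_trough <= 1,
      "summer_trough must lie in (0, 1]")
  chk(cfg$q_noise_cv >= 0 && cfg$noise_cv >= 0, "noise CVs must be nonnegative")
  if (length(problems)) stop("invalid synthetic configuration: ",
                             paste(problems, collapse = "; "))
  structure(cfg, class = "synthetic_config")
}

# lognormal multiplicative noise with unit mean
lognorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sig <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, 0, sig) - sig^2 / 2)
}

#' Generate a dated synthetic discharge series
#'
#' Deterministic seasonal shape (snowmelt bump + summer trough) times
#' mean-one lognormal noise, clipped to the configured envelope:
#' `Q = clip(baseflow * s(doy) + A * bump(doy), floor, cap) * noise`,
#' where `s` carries the trough and `bump` the snowmelt peak (clipping is
#' applied after the noise).
#'
#' @param cfg A [synthetic_config()].
#' @return Data frame with columns `date`, `t_days`, `Q`.
#' @export
generate_discharge <- function(cfg) {
  if (!inherits(cfg, "synthetic_config")) stop("cfg must come from synthetic_config()")
  dates <- seq(parse_iso_date(cfg$start), parse_iso_date(cfg$end),
               by = cfg$interval_days)
  doy <- as.numeric(format(dates, "%j"))
  trough <- 1 - (1 - cfg$summer_trough) *
    exp(-0.5 * ((doy - cfg$trough_doy) / cfg$trough_width)^2)
  bump <- exp(-0.5 * ((doy - cfg$peak_doy) / cfg$peak_width)^2)
  q_det <- cfg$baseflow * trough + cfg$peak_amplitude * bump
  set.seed(cfg$seed)
  Q <- pmin(pmax(q_det * lognorm_noise(length(dates), cfg$q_noise_cv),
                 cfg$q_floor), cfg$q_cap)
  data.frame(date = dates, t_days = days_since_accident(dates), Q = Q)
}

#' Generate synthetic concentrations for a discharge series
#'
#' Applies the closed-form C-Q model at each sample and multiplies by
#' mean-one lognormal measurement noise, so the expected concentration at
#' each `(Q, t)` equals the model value; `noise_cv = 0` reproduces the
#' model curve exactly.
#'
#' @param qser Data frame with columns `t_days` and `Q` (all positive),
#'   e.g. from [generate_discharge()].
#' @param trend A [trend_params] object.
#' @param cq A [cq_params] object.
#' @param noise_cv Measurement-noise coefficient of variation.
#' @param seed Integer seed.
#' @return `qser` with a `C` column added (Bq/m3).
#' @export
generate_concentrations <- function(qser, trend, cq, noise_cv = 0.109, seed = 1L) {
  if (any(qser$Q <= 0)) stop("all discharges must be positive")
  mu <- concentration_closed_form(qser$Q, qser$t_days, cq, trend)
  set.seed(seed)
  qser$C <- mu * lognorm_noise(nrow(qser), noise_cv)
  qser
}

#' Generate a complete synthetic monitoring dataset
#'
#' Runs the discharge and concentration generators and returns an
#' [sr_records] set together with a ground-truth sidecar (attribute
#' `truth`): the full generating configuration as a plain list, from
#' which [regenerate_dataset()] reproduces the identical dataset.
#'
#' @param cfg A [synthetic_config()].
#' @return An [sr_records] data frame (with `err_pct` set to
#'   `100 * noise_cv`) carrying attribute `truth`.
#' @export
generate_dataset <- function(cfg) {
  qser <- generate_discharge(cfg)
  qser <- generate_concentrations(qser, cfg$trend, cfg$cq,
                                  noise_cv = cfg$noise_cv, seed = cfg$seed + 1L)
  rec <- sr_records(qser$date, qser$Q, qser$C,
                    err_pct = rep(100 * cfg$noise_cv, nrow(qser)))
  truth <- unclass(cfg)
  truth$trend <- unclass(cfg$trend)
  truth$cq <- unclass(cfg$cq)
  attr(rec, "truth") <- truth
  rec
}

#' Rebuild a synthetic dataset from its ground-truth sidecar
#'
#' @param truth The `truth` attribute of a generated dataset (or the same
#'   structure read back from JSON): the generating parameters and seed.
#' @return The identical [sr_records] dataset.
#' @export
regenerate_dataset <- function(truth) {
  cfg <- truth
  cfg$trend <- do.call(trend_params, truth$trend[c("alpha", "beta", "k1", "k2", "lam")])
  cfg$cq <- do.call(cq_params, truth$cq[c("a", "b", "d")])
  generate_dataset(do.call(synthetic_config, cfg))
}
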