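# Concentration-formation model: vertical soil activity profile,
# exponential lateral-flow profile, water-table position, the closed-form
# C(Q, t) and its flux-weighted quadrature oracle.

#' Parameters of the concentration-discharge formation model
#'
#' Three coefficients govern the model: `a` (mm/day) and `b` (1/m) set the
#' exponential lateral-flow profile with depth, `q(z) = a exp(b z)`, whose
#' cumulative integral up to the water table equals the stream discharge;
#' `d` (m day) sets the steepness of the vertical soil activity profile
#' `c(z, t) = C_ref(t) exp(d z / t)`, which flattens as time passes.
#'
#' Note the model output is invariant under the joint rescaling
#' `(a, b, d) -> (c a, c b, c d)`: only the ratios (e.g. `a/b`, `d/b`) are
#' constrained by concentration-discharge data. See the package vignette.
#'
#' @param a Flow-profile scale, mm/day, positive.
#' @param b Flow-profile depth rate, 1/m, positive.
#' @param d Soil-profile steepness coefficient, m day, positive.
#' @return An object of class `cq_params`.
#' @examples
#' cq_params(0.28, 1.37, 2117)
#' @export
cq_params <- function(a, b, d) {
  v <- c(a = a, b = b, d = d)
  if (anyNA(v) || any(!is.finite(v)) || any(v <= 0)) {
    stop("a, b and d must be finite and positive")
  }
  structure(list(a = a, b = b, d = d), class = "cq_params")
}

#' @export
print.cq_params <- function(x, ...) {
  cat(sprintf("C-Q model parameters: a = %.4g mm/day, b = %.4g 1/m, d = %.5g m day\n",
              x$a, x$b, x$d))
  cat(sprintf("  surface-saturation discharge a/b = %.4g mm/day\n", x$a / x$b))
  invisible(x)
}

check_cq <- function(cq) {
  if (is.null(cq$a) || is.null(cq$b) || is.null(cq$d)) stop("cq must supply a, b, d")
  if (cq$a <= 0 || cq$b <= 0) stop("a and b must be positive")
  if (cq$d < 0) stop("d must be nonnegative")
  cq
}

#' Vertical soil activity concentration profile
#'
#' Concentration of the mobile radionuclide in soil water at depth `z`
#' (metres; negative below the ground surface, 0 at the surface) and time
#' `t_days` after deposition: `cref_value * exp(d z / t)`. The profile
#' equals the surface value at `z = 0`, decreases with depth, and flattens
#' as `t` grows (downward migration of the initially surface-deposited
#' activity).
#'
#' @param z Depth coordinate, m (vectorised).
#' @param t_days Time since deposition, days, strictly positive (the
#'   profile is undefined at the deposition instant).
#' @param cref_value Surface (baseline) concentration, Bq/m3.
#' @param d Profile-steepness coefficient, m day.
#' @return Concentration, Bq/m3.
#' @export
soil_concentration <- function(z, t_days, cref_value, d) {
  if (any(t_days <= 0)) stop("t_days must be strictly positive")
  cref_value * exp(d * z / t_days)
}

#' Lateral flow density profile
#'
#' Flux density of lateral subsurface flow per unit depth,
#' `q(z) = a exp(b z)`: positive everywhere and strictly increasing toward
#' the ground surface. Its integral over `(-Inf, 0]` is `a / b`.
#'
#' @param z Depth coordinate, m (vectorised).
#' @param a Flow-profile scale, mm/day.
#' @param b Flow-profile depth rate, 1/m.
#' @return Flux density, mm/day per metre of depth.
#' @export
lateral_flow <- function(z, a, b) {
  a * exp(b * z)
}

#' Water-table depth for a given discharge
#'
#' The depth `z_w` above which the lateral-flow profile integrates to the
#' observed discharge: `z_w = log(b Q / a) / b`. Zero exactly at the
#' surface-saturation discharge `Q = a/b`; positive values (saturation
#' excess) are permitted for larger discharges.
#'
#' @param Q Discharge, mm/day, strictly positive (vectorised).
#' @param a,b Flow-profile parameters (see [cq_params]).
#' @return Depth, m.
#' @export
water_table_depth <- function(Q, a, b) {
  if (any(Q <= 0)) stop("Q must be strictly positive")
  log(b * Q / a) / b
}

#' Stream concentration: closed form
#'
#' The flux-weighted mean soil-water concentration delivered to the stream
#' at discharge `Q` and time `t`:
#' \deqn{C(Q, t) = C_{ref}(t) \frac{b t}{b t + d}
#'                \left(\frac{b Q}{a}\right)^{d / (b t)},}
#' with `t` in days. Strictly increasing in `Q`, tending to 0 as `Q -> 0`
#' (deep groundwater carries no fuel-particle-derived activity) and to the
#' baseline `C_ref` as `t -> Inf` (the soil profile flattens completely).
#' The expression is applied unchanged above the surface-saturation
#' discharge `a/b` (saturation excess).
#'
#' @param Q Discharge, mm/day, strictly positive (vectorised).
#' @param t_days Time since the accident, days, strictly positive
#'   (vectorised, recycled against `Q`).
#' @param cq A [cq_params] object (or list with `a`, `b`, `d >= 0`).
#' @param trend A [trend_params] object.
#' @return Concentration, Bq/m3.
#' @examples
#' cq <- cq_params(0.28, 1.37, 2117)
#' tr <- trend_params(9357, 2500, 0.254, 0.002)
#' concentration_closed_form(0.2, 7305, cq, tr)
#' @export
concentration_closed_form <- function(Q, t_days, cq, trend) {
  cq <- check_cq(cq)
  if (any(Q <= 0)) stop("Q must be strictly positive")
  if (any(t_days <= 0)) stop("t_days must be strictly positive")
  bt <- cq$b * t_days
  c_ref(t_days, trend) * bt / (bt + cq$d) * (cq$b * Q / cq$a)^(cq$d / bt)
}

#' Stream concentration: flux-weighted depth integral (numerical oracle)
#'
#' Evaluates the same quantity as [concentration_closed_form()] directly
#' from its definition, the flux-weighted mean of the soil profile over the
#' saturated depth range,
#' `C = \int q(z) c(z, t) dz / \int q(z) dz` over `(-Inf, z_w]`,
#' by adaptive quadrature. The lower limit is truncated where the integrand
#' falls below `exp(-40)` of its maximum. Serves as the independent check
#' of the analytic solution.
#'
#' @param Q Discharge, mm/day, strictly positive (scalar).
#' @param t_days Time since the accident, days, strictly positive (scalar).
#' @param cq A [cq_params] object (or list with `a`, `b`, `d >= 0`).
#' @param trend A [trend_params] object.
#' @param tol Relative quadrature tolerance.
#' @return Concentration, Bq/m3, with attribute `abs_error` (the quadrature
#'   error estimate propagated to the ratio).
#' @export
concentration_numeric <- function(Q, t_days, cq, trend, tol = 1e-9) {
  cq <- check_cq(cq)
  stopifnot(length(Q) == 1, length(t_days) == 1)
  if (Q <= 0) stop("Q must be strictly positive")
  if (t_days <= 0) stop("t_days must be strictly positive")
  if (tol <= 0) stop("tol must be positive")
  a <- cq$a; b <- cq$b; d <- cq$d
  zw <- water_table_depth(Q, a, b)
  # integrand decay rates with depth: b for the flow alone, b + d/t for the
  # flux-weighted product; truncate 40 e-foldings below the water table
  zlo_num <- zw - 40 / (b + d / t_days)
  zlo_den <- zw - 40 / b
  cref <- c_ref(t_days, trend)
  num <- tryCatch(
    stats::integrate(function(z) lateral_flow(z, a, b) *
                       soil_concentration(z, t_days, cref, d),
                     lower = zlo_num, upper = zw, rel.tol = tol,
                     subdivisions = 500L),
    error = function(e) stop("quadrature failed for the flux-weighted numerator: ",
                             conditionMessage(e)))
  den <- tryCatch(
    stats::integrate(function(z) lateral_flow(z, a, b),
                     lower = zlo_den, upper = zw, rel.tol = tol,
                     subdivisions = 500L),
    error = function(e) stop("quadrature failed for the discharge denominator: ",
                             conditionMessage(e)))
  val <- num$value / den$value
  structure(val, abs_error = abs(val) *
              (num$abs.error / num$value + den$abs.error / den$value))
}

#' Instantaneous power-law exponent implied by the model
#'
#' The closed form predicts a log(C)-log(Q) slope of `d / (b t)` at time
#' `t`: the concentration-discharge relationship steepens toward the
#' accident and flattens as the soil profile relaxes, so the exponent
#' decays inversely with time.
#'
#' @param t_days Time since the accident, days, strictly positive
#'   (vectorised).
#' @param cq A [cq_params] object.
#' @return Dimensionless slope `d / (b t)`.
#' @export
model_exponent <- function(t_days, cq) {
  cq <- check_cq(cq)
  if (any(t_days <= 0)) stop("t_days must be strictly positive")
  cq$d / (cq$b * t_days)
}
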