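# Bayesian calibration of the concentration-discharge model: log-space
# Gaussian likelihood, adaptive random-walk Metropolis in log-parameter
# space, posterior summaries, model agreement and posterior-predictive
# bands.

#' MCMC configuration
#'
#' Settings for [run_mcmc()]. Priors are log-uniform (uniform in the
#' sampled log-parameter space) over per-parameter bounds chosen wide
#' enough to contain any plausible catchment by a comfortable margin.
#' The observation-noise standard deviation `sigma` (log space) is either
#' estimated as a free parameter under the same log-uniform treatment
#' (`sigma_mode = "estimated"`, the default) or held fixed
#' (`sigma_mode = "fixed"`): at `sigma` if given, else at the mean
#' per-sample relative measurement error of the data, else at 0.109.
#'
#' @param n_chains Number of independent chains (>= 2 recommended for the
#'   split-chain convergence diagnostic).
#' @param n_draws Post-burn-in draws retained per chain.
#' @param n_burn Burn-in iterations per chain (adaptation happens here).
#' @param seed Integer seed; the full run is deterministic given it.
#' @param bounds Named list of length-2 prior bounds for `a`, `b`, `d` and
#'   `sigma` (natural scale; the prior is uniform in the log).
#' @param sigma_mode `"estimated"` or `"fixed"`.
#' @param sigma Fixed value of sigma when `sigma_mode = "fixed"`.
#' @param prior_only If `TRUE`, sample the prior alone (likelihood
#'   disabled) — a sampler sanity check.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4L, n_draws = 2000L, n_burn = 2000L,
                        seed = 1L,
                        bounds = list(a = c(1e-3, 1e2), b = c(1e-2, 1e2),
                                      d = c(1, 1e5), sigma = c(1e-3, 1e1)),
                        sigma_mode = c("estimated", "fixed"),
                        sigma = NULL, prior_only = FALSE) {
  sigma_mode <- match.arg(sigma_mode)
  if (n_chains < 2) stop("at least 2 chains are required")
  if (n_draws < 1 || n_burn < 0) stop("n_draws must be positive and n_burn nonnegative")
  for (nm in c("a", "b", "d", "sigma")) {
    bb <- bounds[[nm]]
    if (is.null(bb) || length(bb) != 2 || any(!is.finite(bb)) ||
        any(bb <= 0) || bb[1] >= bb[2]) {
      stop("bounds for ", sQuote(nm), " must be two finite positive increasing values")
    }
  }
  structure(list(n_chains = as.integer(n_chains), n_draws = as.integer(n_draws),
                 n_burn = as.integer(n_burn), seed = as.integer(seed),
                 bounds = bounds, sigma_mode = sigma_mode, sigma = sigma,
                 prior_only = isTRUE(prior_only)),
            class = "mcmc_config")
}

#' Log-likelihood of a monitoring series under the C-Q model
#'
#' Gaussian likelihood on log-concentration residuals: the per-sample
#' measurement error is quoted as a relative percentage, so multiplicative
#' (lognormal) errors are the natural observation model. For each record,
#' `log C_obs ~ Normal(log C_model(Q, t), sigma)` with `C_model` the
#' closed-form model prediction.
#'
#' @param cq A [cq_params] object or plain list with `a`, `b`, `d`. Any
#'   nonpositive parameter yields `-Inf` (an impossible state for the
#'   sampler), not an error.
#' @param sigma Log-space residual standard deviation, positive.
#' @param records An [sr_records] data frame (all `Q > 0`, `C > 0`).
#' @param trend A [trend_params] object (held fixed during calibration).
#' @return The summed log-likelihood (scalar).
#' @export
log_likelihood <- function(cq, sigma, records, trend) {
  if (is.null(cq$a) || is.null(cq$b) || is.null(cq$d)) stop("cq must supply a, b, d")
  v <- c(cq$a, cq$b, cq$d, sigma)
  if (any(!is.finite(v)) || any(v <= 0)) return(-Inf)
  mu <- log(concentration_closed_form(records$Q, records$t_days, cq, trend))
  sum(stats::dnorm(log(records$C) - mu, mean = 0, sd = sigma, log = TRUE))
}

# split-chain convergence statistic (each chain halved; rank-free R-hat)
split_rhat <- function(x) {  # draws x chains
  n <- floor(nrow(x) / 2)
  if (n < 2) return(NA_real_)
  halves <- cbind(x[seq_len(n), , drop = FALSE],
                  x[seq.int(nrow(x) - n + 1, nrow(x)), , drop = FALSE])
  w <- mean(apply(halves, 2, stats::var))
  b <- n * stats::var(colMeans(halves))
  if (w <= 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Calibrate the C-Q model by Markov chain Monte Carlo
#'
#' Adaptive random-walk Metropolis in log-parameter space over
#' `(a, b, d[, sigma])` with log-uniform priors (see [mcmc_config()]).
#' During burn-in the proposal is first scale-tuned toward ~30%
#' acceptance, then switched to a multivariate Gaussian whose covariance
#' is adapted from the chain history (scaled by `2.38^2 / n_par`); after
#' burn-in the proposal is frozen so the retained draws form a valid
#' Markov chain. Chains start from independent prior draws. A warning is
#' issued when any split-chain convergence statistic exceeds 1.05 — with
#' the model's `(a, b, d)` scale invariance (see [cq_params]) the
#' posterior has an almost flat ridge and slow mixing along it is
#' expected; ratios such as `d/b` converge much faster than the raw
#' parameters.
#'
#' @param records An [sr_records] data frame with at least 20 records.
#' @param trend A [trend_params] object, held fixed.
#' @param config An [mcmc_config()].
#' @return An object of class `sr_mcmc`: list with `draws` (array
#'   `n_draws x n_par x n_chains`), `params` (names), `accept` (mean
#'   post-burn acceptance rate), `rhat` (named split-chain statistics),
#'   `map` (highest-posterior draw seen, list of parameters + log
#'   posterior), `sigma_mode`, `sigma_fixed`, `trend`, `config`.
#' @export
run_mcmc <- function(records, trend, config = mcmc_config()) {
  if (!is.data.frame(records) || nrow(records) < 20) {
    stop("at least 20 records are required for calibration")
  }
  if (!inherits(config, "mcmc_config")) stop("config must come from mcmc_config()")
  est_sigma <- config$sigma_mode == "estimated"
  sigma_fixed <- NULL
  if (!est_sigma) {
    sigma_fixed <- config$sigma
    if (is.null(sigma_fixed)) {
      sigma_fixed <- if (!is.null(records$err_pct) && any(is.finite(records$err_pct))) {
        mean(records$err_pct, na.rm = TRUE) / 100
      } else 0.109
    }
    if (sigma_fixed <= 0) stop("fixed sigma must be positive")
  }
  pn <- c("a", "b", "d", if (est_sigma) "sigma")
  npar <- length(pn)
  lb <- log(vapply(config$bounds[pn], `[`, numeric(1), 1))
  ub <- log(vapply(config$bounds[pn], `[`, numeric(1), 2))

  # data precomputed once; likelihood vectorised over records
  lq <- log(records$Q)
  tt <- records$t_days
  lcref <- log(c_ref(tt, trend))
  lobs <- log(records$C)
  nrec <- length(lobs)
  logpost <- function(u) {
    if (any(u < lb | u > ub)) return(-Inf)
    if (config$prior_only) return(0)
    a <- exp(u[1]); b <- exp(u[2]); d <- exp(u[3])
    sig <- if (est_sigma) exp(u[4]) else sigma_fixed
    bt <- b * tt
    mu <- lcref + log(bt / (bt + d)) + (d / bt) * (u[2] + lq - u[1])
    r <- lobs - mu
    -0.5 * sum(r * r) / sig^2 - nrec * log(sig) - 0.5 * nrec * log(2 * pi)
  }

  set.seed(config$seed)
  n_iter <- config$n_burn + config$n_draws
  draws <- array(NA_real_, dim = c(config$n_draws, npar, config$n_chains),
                 dimnames = list(NULL, pn, NULL))
  acc_post <- numeric(config$n_chains)
  map <- list(logpost = -Inf)
  phase1 <- min(max(200L, config$n_burn %/% 4L), config$n_burn)

  for (ch in seq_len(config$n_chains)) {
    u <- NULL
    for (try in seq_len(200)) {
      cand <- lb + stats::runif(npar) * (ub - lb)
      lp <- logpost(cand)
      if (is.finite(lp)) { u <- cand; break }
    }
    if (is.null(u)) {
      stop("no finite posterior density found in 200 prior draws; ",
           "check records and prior bounds")
    }
    hist_u <- matrix(NA_real_, n_iter, npar)
    scale <- 0.1 * (ub - lb)
    chol_prop <- NULL
    n_acc_post <- 0L
    for (i in seq_len(n_iter)) {
      prop <- if (is.null(chol_prop)) {
        u + stats::rnorm(npar) * scale
      } else {
        u + drop(crossprod(chol_prop, stats::rnorm(npar)))
      }
      lp_prop <- logpost(prop)
      acc <- is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp
      if (acc) { u <- prop; lp <- lp_prop }
      hist_u[i, ] <- u
      if (lp > map$logpost) map <- list(logpost = lp, u = u)
      if (i <= config$n_burn) {
        if (i <= phase1) {
          # Robbins-Monro tuning of the diagonal scale toward ~30% acceptance
          scale <- scale * exp(((if (acc) 1 else 0) - 0.3) / sqrt(i))
        } else if (i %% 100L == 0L) {
          sub <- hist_u[seq.int(max(1L, i %/% 2L), i), , drop = FALSE]
          S <- stats::cov(sub) * 2.38^2 / npar + diag(1e-10, npar)
          chol_prop <- tryCatch(chol(S), error = function(e) NULL)
        }
      } else if (acc) {
        n_acc_post <- n_acc_post + 1L
      }
    }
    if (n_acc_post == 0L) {
      stop("chain ", ch, " accepted no proposals after burn-in; ",
           "the proposal scale failed to adapt")
    }
    draws[, , ch] <- hist_u[seq.int(config$n_burn + 1L, n_iter), , drop = FALSE]
    acc_post[ch] <- n_acc_post / config$n_draws
  }
  draws <- exp(draws)  # back to natural scale

  rhat <- vapply(seq_len(npar), function(j) split_rhat(log(draws[, j, ])),
                 numeric(1))
  names(rhat) <- pn
  if (any(rhat > 1.05, na.rm = TRUE)) {
    warning("split-chain convergence statistic above 1.05 for: ",
            paste(pn[which(rhat > 1.05)], collapse = ", "),
            " (slow mixing along the (a, b, d) scale ridge is expected; ",
            "consider more draws)")
  }
  map_par <- setNames(as.list(exp(map$u)), pn)
  structure(list(draws = draws, params = pn, accept = mean(acc_post),
                 rhat = rhat,
                 map = c(map_par, list(log_posterior = map$logpost)),
                 sigma_mode = config$sigma_mode, sigma_fixed = sigma_fixed,
                 trend = trend, config = config),
            class = "sr_mcmc")
}

#' @export
print.sr_mcmc <- function(x, ...) {
  cat(sprintf("MCMC calibration: %d chains x %d draws (%s sigma)\n",
              dim(x$draws)[3], dim(x$draws)[1], x$sigma_mode))
  cat(sprintf("  mean acceptance %.2f; split-chain statistic: %s\n", x$accept,
              paste(sprintf("%s %.3f", x$params, x$rhat), collapse = ", ")))
  print(posterior_summary(x))
  invisible(x)
}

# pooled draws matrix (rows = draws across all chains)
pool_draws <- function(fit) {
  d <- fit$draws
  m <- do.call(rbind, lapply(seq_len(dim(d)[3]), function(ch) d[, , ch, drop = TRUE]))
  colnames(m) <- fit$params
  m
}

#' Posterior summary table
#'
#' Per-parameter posterior median ("best fit") with 2.5% and 97.5%
#' percentile bounds. Percentiles use linear interpolation between order
#' statistics (the default sample-quantile definition, type 7).
#'
#' @param fit An `sr_mcmc` object from [run_mcmc()], or a numeric
#'   vector/matrix of draws (columns = parameters).
#' @param probs Lower and upper interval probabilities.
#' @return Data frame with columns `param`, `best_fit`, `lo_2p5`,
#'   `hi_97p5` (column names follow `probs`); for `sr_mcmc` input the
#'   acceptance rate and convergence statistics are attached as
#'   attribute `diagnostics`.
#' @export
posterior_summary <- function(fit, probs = c(0.025, 0.975)) {
  if (inherits(fit, "sr_mcmc")) {
    m <- pool_draws(fit)
    diag <- list(accept = fit$accept, rhat = fit$rhat)
  } else if (is.numeric(fit)) {
    m <- if (is.matrix(fit)) fit else matrix(fit, ncol = 1, dimnames = list(NULL, "x"))
    diag <- NULL
  } else stop("fit must be an sr_mcmc object or numeric draws")
  if (nrow(m) == 0) stop("empty chains")
  qs <- t(apply(m, 2, stats::quantile, probs = c(probs[1], 0.5, probs[2]),
                names = FALSE, type = 7))
  out <- data.frame(param = colnames(m), best_fit = qs[, 2],
                    lo_2p5 = qs[, 1], hi_97p5 = qs[, 3],
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(diag)) attr(out, "diagnostics") <- diag
  out
}

#' Model agreement (coefficient of determination)
#'
#' `1 - SS_res / SS_tot` of the model predictions against the
#' observations, computed by default on log concentrations (consistent
#' with the multiplicative observation model); `space = "linear"` is
#' available for comparison.
#'
#' @param records An [sr_records] data frame, at least 3 records.
#' @param cq A [cq_params] object (or list with `a`, `b`, `d`).
#' @param trend A [trend_params] object.
#' @param space `"log"` (default) or `"linear"`.
#' @return Scalar, at most 1; 1 for perfect predictions.
#' @export
r_squared <- function(records, cq, trend, space = c("log", "linear")) {
  space <- match.arg(space)
  if (!is.data.frame(records) || nrow(records) < 3) {
    stop("at least 3 records are required")
  }
  pred <- concentration_closed_form(records$Q, records$t_days, cq, trend)
  obs <- records$C
  if (space == "log") { pred <- log(pred); obs <- log(obs) }
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) stop("observations have zero variance; R^2 undefined")
  1 - sum((obs - pred)^2) / ss_tot
}

#' Posterior-predictive quantile bands
#'
#' For each point of a `(Q, t)` grid, quantiles of the predicted
#' observation: a posterior draw of `(a, b, d, sigma)` is sampled for each
#' replicate, the closed-form concentration computed, and multiplicative
#' observation noise `exp(Normal(0, sigma))` applied, so both parameter
#' and measurement uncertainty enter the band.
#'
#' @param fit An `sr_mcmc` object, or a numeric matrix of draws with
#'   columns `a`, `b`, `d` (and optionally `sigma`).
#' @param grid Data frame with columns `Q` and `t_days`.
#' @param trend A [trend_params] object; defaults to the one stored in
#'   `fit` when available.
#' @param probs Quantile levels, all strictly inside (0, 1).
#' @param n_rep Number of posterior draws resampled for the band.
#' @param seed Integer seed for the draw resampling and noise.
#' @param sigma Observation-noise s.d. used when the draws carry no
#'   `sigma` column (e.g. a fixed-sigma fit); may be 0 for a pure
#'   parameter-uncertainty band.
#' @return `grid` with one extra column per requested quantile, named
#'   `q<level>`.
#' @export
posterior_predictive <- function(fit, grid, trend = NULL,
                                 probs = c(0.025, 0.25, 0.5, 0.75, 0.975),
                                 n_rep = 1000L, seed = 1L, sigma = NULL) {
  if (any(probs <= 0 | probs >= 1)) stop("quantile levels must lie strictly in (0, 1)")
  if (inherits(fit, "sr_mcmc")) {
    m <- pool_draws(fit)
    if (is.null(trend)) trend <- fit$trend
    if (is.null(sigma)) sigma <- fit$sigma_fixed
  } else if (is.matrix(fit)) {
    m <- fit
  } else stop("fit must be an sr_mcmc object or a draws matrix")
  if (is.null(trend)) stop("a trend_params object is required")
  if (!all(c("Q", "t_days") %in% names(grid))) stop("grid needs columns Q and t_days")
  set.seed(seed)
  idx <- sample.int(nrow(m), n_rep, replace = TRUE)
  ng <- nrow(grid)
  sim <- matrix(NA_real_, n_rep, ng)
  has_sigma <- "sigma" %in% colnames(m)
  if (!has_sigma && is.null(sigma)) stop("draws carry no sigma; supply one (possibly 0)")
  for (r in seq_len(n_rep)) {
    th <- m[idx[r], ]
    mu <- concentration_closed_form(grid$Q, grid$t_days,
                                    list(a = th[["a"]], b = th[["b"]], d = th[["d"]]),
                                    trend)
    s <- if (has_sigma) th[["sigma"]] else sigma
    noise <- if (s > 0) exp(stats::rnorm(ng, 0, s)) else 1
    sim[r, ] <- mu * noise
  }
  qs <- apply(sim, 2, stats::quantile, probs = probs, names = FALSE, type = 7)
  qs <- if (length(probs) == 1) matrix(qs, nrow = 1) else qs
  out <- grid
  for (j in seq_along(probs)) {
    out[[paste0("q", format(100 * probs[j], trim = TRUE))]] <- qs[j, ]
  }
  out
}
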