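test_that("log-likelihood matches a direct Gaussian computation on log residuals", {
  cq <- ref_cq(); tr <- ref_trend()
  dates <- c("2000-05-01", "2000-08-01")
  t <- days_since_accident(dates)
  mu <- concentration_closed_form(c(0.5, 0.05), t, cq, tr)

  # perfect fit, sigma = 1, n = 2: only the normalising constant remains
  rec <- sr_records(dates, c(0.5, 0.05), mu)
  expect_equal(log_likelihood(cq, 1, rec, tr), -log(2 * pi))

  # hand-made residuals {0.1, -0.2, 0.05}, sigma = 0.109: term-by-term sum
  dates3 <- c("1995-04-01", "2000-05-01", "2005-06-01")
  t3 <- days_since_accident(dates3)
  Q3 <- c(1.2, 0.5, 0.08)
  mu3 <- concentration_closed_form(Q3, t3, cq, tr)
  resid <- c(0.1, -0.2, 0.05)
  rec3 <- sr_records(dates3, Q3, mu3 * exp(resid))
  by_hand <- sum(-0.5 * (resid / 0.109)^2 - log(0.109) - 0.5 * log(2 * pi))
  expect_equal(log_likelihood(cq, 0.109, rec3, tr), by_hand)

  # doubling every observation shifts each residual by log 2: strictly worse
  rec3b <- rec3; rec3b$C <- 2 * rec3$C
  expect_lt(log_likelihood(cq, 0.109, rec3b, tr),
            log_likelihood(cq, 0.109, rec3, tr))

  # invalid parameter states are rejected with -Inf, not an exception
  expect_identical(log_likelihood(list(a = -1, b = 1.37, d = 2117), 0.109, rec3, tr), -Inf)
  expect_identical(log_likelihood(list(a = 0.28, b = 1.37, d = 0), 0.109, rec3, tr), -Inf)
  expect_identical(log_likelihood(cq, 0, rec3, tr), -Inf)

  # invariant to record ordering
  expect_equal(log_likelihood(cq, 0.109, rec3[c(3, 1, 2), ], tr),
               log_likelihood(cq, 0.109, rec3, tr))
})

test_that("posterior summaries use linear interpolation between order statistics", {
  # constant chain collapses all three summaries
  s <- posterior_summary(rep(4.2, 50))
  expect_equal(unlist(s[c("best_fit", "lo_2p5", "hi_97p5")], use.names = FALSE),
               c(4.2, 4.2, 4.2))

  # order-statistics oracle for 1..100: q_p = 1 + p * 99 under linear
  # interpolation
  s2 <- posterior_summary(as.numeric(1:100))
  expect_equal(s2$lo_2p5, 1 + 0.025 * 99)
  expect_equal(s2$best_fit, 1 + 0.5 * 99)
  expect_equal(s2$hi_97p5, 1 + 0.975 * 99)

  # permutation invariance
  set.seed(3)
  x <- rnorm(501)
  expect_equal(posterior_summary(sample(x)), posterior_summary(x))

  expect_error(posterior_summary(matrix(numeric(0), ncol = 2)), "empty")
})

test_that("model agreement R^2 matches hand computation and its edge cases", {
  cq <- ref_cq(); tr <- ref_trend()
  dates <- c("1995-04-01", "1999-05-01", "2004-06-01", "2010-07-01")
  t <- days_since_accident(dates)
  Q <- c(1.5, 0.4, 0.09, 0.02)
  mu <- concentration_closed_form(Q, t, cq, tr)

  # noise-free data at the generating parameters
  expect_equal(r_squared(sr_records(dates, Q, mu), cq, tr), 1.0)

  # hand computation on a perturbed 4-point set
  obs <- mu * exp(c(0.2, -0.1, 0.15, -0.05))
  rec <- sr_records(dates, Q, obs)
  lo <- log(obs); lp <- log(mu)
  expect_equal(r_squared(rec, cq, tr),
               1 - sum((lo - lp)^2) / sum((lo - mean(lo))^2))

  # predictions equal to the observed mean give exactly zero
  lo2 <- c(7.1, 7.4, 6.9, 7.0)
  rec2 <- sr_records(dates, Q, exp(lo2))
  pred_flat <- rep(mean(lo2), 4)
  expect_equal(1 - sum((lo2 - pred_flat)^2) / sum((lo2 - mean(lo2))^2), 0)

  expect_error(r_squared(sr_records(dates, Q, rep(100, 4)), cq, tr), "zero variance")
  expect_error(r_squared(rec[1:2, ], cq, tr), "at least 3")
})

test_that("the sampler is deterministic and reproduces the prior when asked to", {
  ds <- generate_dataset(synthetic_config(seed = 21))
  tr <- ref_trend()
  cfg <- mcmc_config(n_chains = 2, n_draws = 200, n_burn = 200, seed = 5)
  f1 <- suppressWarnings(run_mcmc(ds, tr, cfg))
  f2 <- suppressWarnings(run_mcmc(ds, tr, cfg))
  expect_identical(f1$draws, f2$draws)

  # prior-only sampling: each log-parameter is uniform over its bounds
  cfgp <- mcmc_config(n_chains = 4, n_draws = 4000, n_burn = 2000, seed = 8,
                      prior_only = TRUE)
  fp <- suppressWarnings(run_mcmc(ds, tr, cfgp))
  m <- log(do.call(rbind, lapply(1:4, function(ch) fp$draws[, , ch])))
  colnames(m) <- fp$params
  b <- fp$config$bounds
  for (nm in fp$params) {
    u <- (m[, nm] - log(b[[nm]][1])) / (log(b[[nm]][2]) - log(b[[nm]][1]))
    expect_true(all(u >= 0 & u <= 1))
    expect_equal(mean(u), 0.5, tolerance = 0.1)
    expect_equal(unname(quantile(u, 0.25)), 0.25, tolerance = 0.1)
    expect_equal(unname(quantile(u, 0.75)), 0.75, tolerance = 0.1)
  }
})

test_that("calibration recovers the identifiable parameter combinations", {
  # the closed form is invariant under (a, b, d) -> (ca, cb, cd): data pin
  # down the ratios a/b and d/b, while the raw parameters carry a flat
  # prior-bounded ridge. The ratios are the recovery target here.
  cfg <- synthetic_config(seed = 31)
  ds <- generate_dataset(cfg)
  fit <- suppressWarnings(run_mcmc(ds, cfg$trend,
    mcmc_config(n_chains = 3, n_draws = 2500, n_burn = 2500, seed = 41)))
  m <- do.call(rbind, lapply(1:3, function(ch) fit$draws[, , ch]))
  colnames(m) <- fit$params
  expect_lt(abs(median(m[, "d"] / m[, "b"]) / (2117 / 1.37) - 1), 0.15)
  expect_lt(abs(median(m[, "a"] / m[, "b"]) / (0.28 / 1.37) - 1), 0.15)
  # estimated observation noise near the generating 10.9%
  expect_lt(abs(median(m[, "sigma"]) / sqrt(log(1 + 0.109^2)) - 1), 0.15)
  # posterior ordering invariant
  s <- posterior_summary(fit)
  expect_true(all(s$lo_2p5 <= s$best_fit & s$best_fit <= s$hi_97p5))
})

test_that("the flat-prior MAP coincides with log-space least squares in prediction", {
  cfg <- synthetic_config(seed = 55)
  ds <- generate_dataset(cfg)
  tr <- cfg$trend
  fit <- suppressWarnings(run_mcmc(ds, tr,
    mcmc_config(n_chains = 3, n_draws = 2000, n_burn = 2000, seed = 9,
                sigma_mode = "fixed", sigma = 0.109)))
  # polish the best posterior draw (with fixed sigma and flat log-priors the
  # posterior mode is the log-space least-squares optimum)
  lobs <- log(ds$C)
  sse <- function(u) {
    p <- list(a = exp(u[1]), b = exp(u[2]), d = exp(u[3]))
    sum((lobs - log(concentration_closed_form(ds$Q, ds$t_days, p, tr)))^2)
  }
  map_u <- log(c(fit$map$a, fit$map$b, fit$map$d))
  map_pol <- optim(map_u, sse, method = "BFGS", control = list(reltol = 1e-14))

  # independent route: direct nonlinear least squares from a neutral start
  nls_fit <- optim(log(c(0.1, 1, 1000)), sse, method = "Nelder-Mead",
                   control = list(maxit = 10000, reltol = 1e-14))
  nls_fit <- optim(nls_fit$par, sse, method = "BFGS", control = list(reltol = 1e-14))

  # the scale ridge means the parameter vectors may differ; the fitted
  # curves (and the attained objective) must agree
  p1 <- list(a = exp(map_pol$par[1]), b = exp(map_pol$par[2]), d = exp(map_pol$par[3]))
  p2 <- list(a = exp(nls_fit$par[1]), b = exp(nls_fit$par[2]), d = exp(nls_fit$par[3]))
  pred1 <- log(concentration_closed_form(ds$Q, ds$t_days, p1, tr))
  pred2 <- log(concentration_closed_form(ds$Q, ds$t_days, p2, tr))
  expect_lt(max(abs(pred1 - pred2)), 1e-3)
  expect_equal(map_pol$value, nls_fit$value, tolerance = 1e-6)
  # and both ridge points share the identifiable ratios
  expect_equal(p1$d / p1$b, p2$d / p2$b, tolerance = 1e-3)
})

test_that("posterior-predictive bands collapse, nest and calibrate correctly", {
  tr <- ref_trend()
  grid <- data.frame(Q = c(0.02, 0.2, 2), t_days = c(3000, 6000, 9000))

  # degenerate chain + sigma = 0: band collapses onto the point prediction
  one <- matrix(rep(c(0.28, 1.37, 2117), each = 2), nrow = 2,
                dimnames = list(NULL, c("a", "b", "d")))
  pp0 <- posterior_predictive(one, grid, tr, probs = c(0.025, 0.975),
                              n_rep = 100, sigma = 0)
  mu <- concentration_closed_form(grid$Q, grid$t_days, ref_cq(), tr)
  expect_equal(pp0$q2.5, mu)
  expect_equal(pp0$q97.5, mu)

  # nesting: 50% band inside the 95% band at every grid point
  set.seed(12)
  dr <- cbind(a = 0.28 * exp(rnorm(400, 0, 0.05)),
              b = 1.37 * exp(rnorm(400, 0, 0.05)),
              d = 2117 * exp(rnorm(400, 0, 0.05)),
              sigma = rep(0.109, 400))
  pp <- posterior_predictive(dr, grid, tr, probs = c(0.025, 0.25, 0.75, 0.975),
                             n_rep = 2000, seed = 2)
  expect_true(all(pp$q2.5 <= pp$q25 & pp$q25 <= pp$q75 & pp$q75 <= pp$q97.5))

  # empirical coverage of the 95% band over 1000 synthetic observations
  set.seed(77)
  big <- data.frame(Q = exp(runif(1000, log(0.004), log(4.2))),
                    t_days = runif(1000, 1500, 11000))
  truth_draws <- matrix(rep(c(0.28, 1.37, 2117), each = 2), nrow = 2,
                        dimnames = list(NULL, c("a", "b", "d")))
  band <- posterior_predictive(truth_draws, big, tr, probs = c(0.025, 0.975),
                               n_rep = 4000, seed = 3, sigma = 0.109)
  obs <- concentration_closed_form(big$Q, big$t_days, ref_cq(), tr) *
    exp(rnorm(1000, 0, 0.109))
  cover <- mean(obs >= band$q2.5 & obs <= band$q97.5)
  expect_gt(cover, 0.90)
  expect_lt(cover, 1.0)

  expect_error(posterior_predictive(truth_draws, big, tr, probs = c(0, 0.5)),
               "strictly")
})
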