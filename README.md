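# srstream

Analysis of long-term dissolved strontium-90 monitoring in small
contaminated catchment streams — the kind of biweekly discharge/activity
record collected for decades downstream of the 1986 Chernobyl release.
It is written for environmental radioecologists and catchment
hydrochemists who need to (i) describe the decadal decline of dissolved
⁹⁰Sr, (ii) model and calibrate its coupling to stream discharge, and
(iii) account for the cumulative activity washed off the catchment.

## The model

Two parametric pieces, linked:

**Decadal baseline.** The reference concentration follows a double
exponential in time since deposition ($t$ in days),

$$C_\mathrm{ref}(t) = \alpha\,e^{-(\lambda+k_1)t/365.25} + \beta\,e^{-(\lambda+k_2)t/365.25},$$

with $\lambda = \ln 2/28.79\,\mathrm{yr} \approx 0.024$ 1/yr the fixed
physical decay rate and $(\alpha,\beta,k_1,k_2)$ fitted by least-RMSE to
annual mean concentrations (`fit_trend()`).

**Concentration-discharge formation.** Lateral subsurface flow
$q(z)=a e^{bz}$ sweeps a soil activity profile
$c(z,t)=C_\mathrm{ref}(t)e^{dz/t}$ that flattens with time; flux-weighting
over the saturated depth gives the closed form

$$C(Q,t) = C_\mathrm{ref}(t)\,\frac{bt}{bt+d}\left(\frac{bQ}{a}\right)^{d/(bt)},$$

an instantaneous power law in $Q$ whose exponent $d/(bt)$ decays as $1/t$ —
the mechanism behind the observed long-term flattening of the
log(⁹⁰Sr)–log(Q) slope, which persists after decay correction. The closed
form is verified in the test suite against an independent flux-weighted
quadrature (`concentration_numeric()`), and its parameters are calibrated
by adaptive Metropolis MCMC with a lognormal observation model
(`run_mcmc()`). Note the model is exactly invariant under
$(a,b,d)\to(ca,cb,cd)$: data constrain the ratios $a/b$ and $d/b$, not the
scale — see the vignette (`vignettes/sr90-catchment-model.Rmd`).

Since real series of this kind are generally not deposited, the package
includes a seeded synthetic generator (`generate_dataset()`) reproducing
the study conditions: biweekly 1990–2016 sampling, a snowmelt-peaked
hydrograph inside the 0.004–4.2 mm/day envelope, and 10.9% multiplicative
measurement noise.

## Worked example

```r
library(srstream)

cfg <- synthetic_config(seed = 42)   # study conditions; truth: a=0.28, b=1.37, d=2117
ds  <- generate_dataset(cfg)         # 705 biweekly records, 1990-2016

fit_trend(annual_means(ds))
#> Trend fit to 27 annual means (RMSE 98.04 Bq/m3, 6 starts)
#> Double-exponential trend parameters
#>   alpha = 623403 Bq/m3, k1 = 1.23581 1/yr (fast)
#>   beta  = 2199.95 Bq/m3, k2 = 0.00731967 1/yr (slow)
#>   lambda = 0.024 1/yr (physical decay, fixed)
```

The slow component ($\beta$, $k_2$) is what a record starting in 1990
constrains; the fast pair is sloppy because that component has largely
decayed before the first sample — expect it to vary wildly between
refits while the fitted curve barely moves.

```r
cal <- run_mcmc(ds, cfg$trend,
                mcmc_config(n_chains = 3, n_draws = 3000, n_burn = 3000, seed = 1))
posterior_summary(cal)
#>   param     best_fit       lo_2p5      hi_97p5
#> 1     a    0.1632841  0.002375758 1.042983e+01
#> 2     b    0.7932895  0.011642082 5.076399e+01
#> 3     d 1233.6534441 18.151139243 7.835808e+04
#> 4 sigma    0.1063441  0.101149568 1.120803e-01
```

Raw `(a, b, d)` intervals are wide — the scale ridge — while the
identifiable ratios recover the truth: here the posterior medians give
`d/b = 1547` (generating value 1545) and `a/b = 0.205` (0.204), and the
noise level `sigma` comes back at the generating 10.9%.

```r
periods <- c("1991-2000", "2001-2010", "2011-2016")
g <- split_periods(ds, periods)
slope_trend(lapply(periods, function(p) fit_power_law(g[[p]], period = p)),
            cq = cfg$cq)
#>      period mid_year        p         q   n   q_model      rel_dev
#> 1 1991-2000     1996 4034.059 0.4874329 260 0.4830295  0.009116185
#> 2 2001-2010     2006 1801.867 0.2244540 261 0.2199227  0.020604479
#> 3 2011-2016     2014 1368.115 0.1516280 157 0.1534506 -0.011877061

washoff_integral(ds, period = "1993-2016", inventory = 470.7)
#> Wash-off 1993-01-11 to 2016-12-26: 4.441 kBq/m2 (trapezoid over 626 samples)
#>   = 0.944% of the initial inventory (470.7 kBq/m2)
```

The fitted power-law exponent `q` declines 0.49 → 0.15 across the decades,
each within ~2% of the model slope $d/(b\,t)$ at the period's
harmonic-mean time, and about 24 years of discharge exports ≈ 4.4 kBq/m²,
i.e. roughly 1% of a 470.7 kBq/m² initial inventory.

A command-line front end over the same functions is installed at
`inst/scripts/srstream` (subcommands `simulate`, `fit-trend`, `calibrate`,
`cq-fit`, `washoff`; JSON outputs with a schema-version field).

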