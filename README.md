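# spingarch

Spatially correlated self-exciting count models on lattices: simulation,
Bayesian inference, convergence diagnostics and predictive evaluation for
the **SPINGARCH(1,1)** model, aimed at panels of event counts per spatial
unit per period — the motivating case is monthly crime counts over the
administrative zones of a city.

## The model

Counts are conditionally Poisson with an intensity that follows a
stochastic difference equation:

    Y(s_i, t) | lambda(s_i, t)  ~  Pois(lambda(s_i, t))
    lambda_t = exp(X_t + eps_t) + eta * Y_{t-1} + kappa * lambda_{t-1}
    X_t   ~ Gau(alpha_t, (I - zeta * N)^(-1) sigma^2)     (CAR field)
    eps_t ~ Gau(0, I * sigma_eps^2)

`eta` is self-excitation (repeat victimization: observed events raise
tomorrow's risk), `kappa` is intensity persistence (`1 - kappa` the natural
decay), and `eta + kappa < 1` guarantees a finite long-run mean. The CAR
field `X_t` carries residual spatial dependence on a lattice with scaled
adjacency `N` and dependence coefficient `zeta`; `eps_t` is unstructured
overdispersion. The baseline `alpha_t` is driven by covariates (e.g.
per-zone distances to police units, cameras, markets, parks, hospitals, and
population density) through a penalized cubic B-spline additive model with
GCV-selected smoothing.

Inference is two-stage: the baseline is fit first (`fit_alpha_gam()`), then
`theta = (eta, kappa, sigma, sigma_eps)` is sampled by an adaptive
Metropolis-within-Gibbs sampler with data augmentation of the latent field
(`run_mcmc()`, core in C++ via Rcpp), with `zeta` fixed at 0.99 by default.
`posterior_summary()` reports means, quantiles, split-Rhat, effective
sample size and the Shannon entropy of the draws (square-root-of-n bins).
`compare_models()` scores INGARCH (no spatial field), linear-covariate
SPINGARCH and B-spline SPINGARCH by mean square prediction error. The
`synthetic_scenario()` / `generate_scenario()` generators build city-like
lattices and landmark-distance covariates so everything is testable without
any external data. See `vignettes/spingarch-methods.Rmd` for the full
methods account.

## Worked example

Simulate a 6 x 6 city (36 zones, 36 months) with a camera-distance effect
`0.6 * exp(-d)` on the log baseline and truth `eta = 0.3, kappa = 0.05,
sigma = 0.3, sigma_eps = 0.8, zeta = 0.99`, then run the full two-stage
pipeline:

```r
library(spingarch)
sc <- synthetic_scenario(grid_rows = 6, grid_cols = 6, T_len = 36,
                         landmark_counts = c(cam = 8),
                         eta = 0.3, kappa = 0.05, sigma = 0.3,
                         sigma_eps = 0.8, zeta = 0.99, beta0 = 0,
                         effect_functions = list(cam = function(d) 0.6 * exp(-d)),
                         seed = 7)
dat <- generate_scenario(sc)
fit <- fit_spingarch(dat$Y, dat$covariates["cam"], dat$lattice,
                     baseline = "bsplines",
                     config = chain_config(n_chains = 3, n_iter = 4000,
                                           burn_in = 1500, thin = 10, seed = 7))
posterior_summary(fit$draws)
pred <- one_step_predict(dat$Y, fit$theta, fit$alpha, dat$lattice)
mspe(pred, dat$Y, "temporal", 2:36)
```

Output (about 80 s on one CPU):

```
      param   Mean     Sd   2.5% 25.0%  50.0%  75.0%  97.5% n_eff Rhat    H
1       eta  0.209 0.0427 0.1244 0.181  0.209  0.237  0.295 164.4 1.02 2.99
2     kappa  0.175 0.0517 0.0731 0.142  0.175  0.210  0.285  93.1 1.04 3.02
3     sigma  0.302 0.0464 0.2180 0.270  0.298  0.332  0.401  56.8 1.06 3.08
4       tau 11.745 3.7031 6.2300 9.081 11.251 13.717 21.050  55.1 1.07 2.95
5 sigma_eps  0.774 0.0435 0.6911 0.745  0.774  0.804  0.861 159.1 1.03 2.94

temporal MSPE: 1874.57
```

Reading it: the scale parameters recover sharply (`sigma` 0.30 vs truth
0.3, `sigma_eps` 0.77 vs 0.8; `tau = 1/sigma^2`), split-Rhat near 1 says
the three chains agree, and `H` is the entropy of each marginal in nats
(ceiling `ln 32 ≈ 3.47` here). `eta` and `kappa` show the expected
attenuation when the baseline must be *estimated* rather than known —
baseline misfit is partly absorbed by the recursion weights; with the true
baseline supplied, their 95% intervals cover the truth (that experiment is
`test-acceptance.R`, criterion 4). The temporal MSPE is the mean squared
error of predicted city-wide monthly totals (~112 events/month here, so
RMSE ≈ 43).

A command-line front end covering simulate / synth / fit / diagnose /
compare lives at `inst/cli/spingarch.R`.

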