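Package: spingarch
Title: Spatially Correlated Self-Exciting Count Models on Lattices
Version: 0.1.0
Authors@R:
    person("SPINGARCH", "Developers", email = "spingarch@example.org",
           role = c("aut", "cre"))
Description: Simulation and Bayesian inference for the SPINGARCH(1,1) model:
    lattice count panels whose conditional-Poisson intensity follows a
    stochastic difference equation driven by a conditionally autoregressive
    (CAR) latent Gaussian field, independent log-normal noise, self-excitation
    on lagged counts and persistence on lagged intensity. Covariate effects
    enter the baseline log-intensity through penalized B-spline generalized
    additive models with GCV smoothing selection. Includes an adaptive
    Metropolis-within-Gibbs sampler with data augmentation of the latent
    field, posterior convergence diagnostics (split-Rhat, effective sample
    size, Shannon entropy of posterior draws), one-step-ahead prediction,
    mean square prediction error evaluation, and generators for synthetic
    city-like lattices with landmark-distance covariates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    splines,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
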