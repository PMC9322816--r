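#' MCMC chain configuration
#'
#' Defaults follow the reference analysis setup: three chains of 70,000
#' iterations, a 10,000-iteration burn-in, thinning every 100 iterations
#' (600 retained draws per chain), and the CAR dependence zeta held fixed at
#' 0.99, near the edge of its valid interval.
#'
#' @param n_chains number of independent chains.
#' @param n_iter iterations per chain.
#' @param burn_in discarded initial iterations (< n_iter).
#' @param thin retain every `thin`-th post-burn-in iteration.
#' @param seed integer base seed; chain c uses `seed + 1000 * (c - 1)`.
#' @param zeta_fixed value at which zeta is held (set `sample_zeta = TRUE`
#'   in [run_mcmc()] to sample it instead).
#' @return object of class `chain_config`.
#' @export
chain_config <- function(n_chains = 3L, n_iter = 70000L, burn_in = 10000L,
                         thin = 100L, seed = 1L, zeta_fixed = 0.99) {
  stopifnot(n_chains >= 1, burn_in < n_iter, thin >= 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), zeta_fixed = zeta_fixed),
            class = "chain_config")
}

#' Retained draws per chain under a configuration
#' @param config a [chain_config()].
#' @return integer `floor((n_iter - burn_in) / thin)`.
#' @export
retained_per_chain <- function(config) {
  (config$n_iter - config$burn_in) %/% config$thin
}

#' Run the data-augmented MCMC sampler
#'
#' Samples theta = (eta, kappa, sigma, sigma_eps) and the latent field
#' U = X + eps given counts Y and a precomputed baseline panel alpha (the
#' two-stage pipeline: alpha from the covariate GAM first, theta second).
#' Adaptive random-walk Metropolis-within-Gibbs; see the package vignette
#' for the update scheme. zeta stays fixed at `config$zeta_fixed`.
#'
#' Individual parameters can be held fixed via `fixed`, e.g.
#' `fixed = list(sigma = 0)` collapses the CAR field (the INGARCH special
#' case), `fixed = list(eta = 0, kappa = 0)` removes self-excitation.
#'
#' @param Y n x T matrix of counts.
#' @param alpha n x T baseline log-intensity panel (scalar/vector recycled).
#' @param lattice a [build_lattice()] lattice.
#' @param priors a [prior_spec()].
#' @param config a [chain_config()].
#' @param fixed optional named list fixing a subset of `eta`, `kappa`
#'   (only jointly), `sigma`, `sigma_eps`.
#' @param init optional named list of initial values.
#' @param theta_reps number of theta proposals per latent sweep (the theta
#'   block is cheap relative to the latent sweep; repeating it improves
#'   mixing of eta and kappa).
#' @return object of class `spingarch_draws`: `draws` (matrix with columns
#'   eta, kappa, sigma, tau = 1/sigma^2, sigma_eps, logpost), `chain_id`,
#'   `config`, `acceptance` rates per chain.
#' @export
run_mcmc <- function(Y, alpha, lattice, priors = prior_spec(),
                     config = chain_config(), fixed = list(), init = list(),
                     theta_reps = 5L) {
  stopifnot(inherits(lattice, "spingarch_lattice"),
            inherits(priors, "prior_spec"), inherits(config, "chain_config"))
  Y <- as.matrix(Y)
  if (any(Y < 0) || any(Y != round(Y))) stop("Y must be non-negative integers")
  n <- lattice$n; T_len <- ncol(Y)
  if (nrow(Y) != n) stop("Y rows must match the lattice size")
  alpha <- expand_alpha(alpha, n, T_len)

  fix_ek <- !is.null(fixed$eta) || !is.null(fixed$kappa)
  if (fix_ek && (is.null(fixed$eta) || is.null(fixed$kappa)))
    stop("eta and kappa can only be fixed jointly")
  fix_sigma <- !is.null(fixed$sigma)
  fix_se <- !is.null(fixed$sigma_eps)

  zeta <- config$zeta_fixed
  if (!fix_sigma || fixed$sigma > 0) {
    if (any(1 - zeta * lattice$eigvals <= 0))
      stop("zeta_fixed invalid for this lattice (CAR precision not positive definite)")
  }

  init_eta <- if (fix_ek) fixed$eta else if (!is.null(init$eta)) init$eta else 0.2
  init_kap <- if (fix_ek) fixed$kappa else if (!is.null(init$kappa)) init$kappa else 0.2
  init_sig <- if (fix_sigma) fixed$sigma else if (!is.null(init$sigma)) init$sigma else 0.5
  init_se <- if (fix_se) fixed$sigma_eps else if (!is.null(init$sigma_eps)) init$sigma_eps else 1
  if (!fix_ek && init_eta + init_kap >= 1) stop("initial eta + kappa >= 1")
  if (fix_se && init_se <= 0) stop("sigma_eps cannot be fixed at zero in the augmented sampler")

  pr <- list(eta_a = priors$eta_shape[1], eta_b = priors$eta_shape[2],
             kappa_a = priors$kappa_shape[1], kappa_b = priors$kappa_shape[2],
             sigma_scale = priors$sigma_scale,
             sigma_eps_scale = priors$sigma_eps_scale)
  U_init <- log(pmax(Y, 0.5))

  n_keep <- retained_per_chain(config)
  all_draws <- vector("list", config$n_chains)
  acc <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + 1000L * (ch - 1L))
    res <- run_chain_cpp(Y = matrix(as.integer(Y), n, T_len), alpha = alpha,
                         W = lattice$N_scaled, eigvals = lattice$eigvals,
                         zeta = zeta, prior = pr,
                         n_iter = config$n_iter, burn_in = config$burn_in,
                         thin = config$thin,
                         init = c(init_eta, init_kap, init_sig, init_se),
                         fix_ek = fix_ek, fix_sigma = fix_sigma,
                         fix_se = fix_se, U_init = U_init,
                         theta_reps = as.integer(theta_reps))
    all_draws[[ch]] <- res$samples
    acc[[ch]] <- res[c("acc_u", "acc_ek", "acc_sigma", "acc_sigma_eps")]
  }
  draws <- do.call(rbind, all_draws)
  sigma_col <- draws[, 3]
  tau <- ifelse(sigma_col > 0, 1 / sigma_col^2, NA_real_)
  draws <- cbind(eta = draws[, 1], kappa = draws[, 2], sigma = sigma_col,
                 tau = tau, sigma_eps = draws[, 4], logpost = draws[, 5])
  structure(list(draws = draws,
                 chain_id = rep(seq_len(config$n_chains), each = n_keep),
                 param_names = c("eta", "kappa", "sigma", "tau", "sigma_eps"),
                 fixed = fixed, config = config, acceptance = acc,
                 alpha = alpha, lattice_n = n),
            class = "spingarch_draws")
}

#' @export
print.spingarch_draws <- function(x, ...) {
  cat(sprintf("spingarch posterior draws: %d chains x %d retained (%d total)\n",
              x$config$n_chains, retained_per_chain(x$config), nrow(x$draws)))
  pm <- colMeans(x$draws[, c("eta", "kappa", "sigma_eps"), drop = FALSE])
  cat(sprintf("posterior means: eta=%.3f kappa=%.3f sigma_eps=%.3f\n",
              pm[1], pm[2], pm[3]))
  invisible(x)
}

#' @export
as.data.frame.spingarch_draws <- function(x, ...) {
  data.frame(chain = x$chain_id,
             iter = rep(seq_len(retained_per_chain(x$config)),
                        times = x$config$n_chains),
             x$draws)
}

#' Posterior means as a parameter object
#'
#' Plug-in point estimates for prediction: posterior means of theta combined
#' with the supplied (or stored) baseline panel.
#'
#' @param draws a [run_mcmc()] result.
#' @param alpha optional baseline panel overriding the one stored in `draws`.
#' @return a [spingarch_params()] object.
#' @export
posterior_mean_params <- function(draws, alpha = NULL) {
  d <- draws$draws
  if (is.null(alpha)) alpha <- draws$alpha
  spingarch_params(eta = mean(d[, "eta"]), kappa = mean(d[, "kappa"]),
                   sigma = mean(d[, "sigma"]), sigma_eps = mean(d[, "sigma_eps"]),
                   zeta = draws$config$zeta_fixed, alpha = alpha)
}
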