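#' Log-density of the latent field
#'
#' Sum over time slices of the CAR log-density of X_t around alpha_t —
#' using the eigenvalue log-determinant and the sparse quadratic form over
#' neighbour pairs — plus the i.i.d. Normal(0, sigma_eps^2) log-density of
#' eps_t. Time slices are independent given alpha (the block-diagonal
#' structure of the full space-time covariance).
#'
#' @param X,eps n x T matrices of CAR field and noise (U = X + eps).
#' @param alpha n x T baseline panel.
#' @param theta a [spingarch_params()] (uses sigma, sigma_eps, zeta).
#' @param lattice a [build_lattice()] lattice.
#' @return scalar log-density (possibly -Inf for degenerate scales).
#' @export
log_latent_density <- function(X, eps, alpha, theta, lattice) {
  n <- lattice$n; T_len <- ncol(X)
  stopifnot(nrow(X) == n, all(dim(eps) == dim(X)), all(dim(alpha) == dim(X)))
  # CAR part
  if (theta$sigma == 0) {
    ll_car <- if (all(X == alpha)) 0 else -Inf
  } else {
    car <- car_spec(theta$zeta, theta$sigma^2)
    validate_car(car, lattice)
    D <- X - alpha
    # quadratic form (X-a)'(I - zeta*Ns)(X-a)/sigma^2, neighbour pairs only
    qf <- sum(D * D) - theta$zeta * sum(D * (lattice$N_scaled %*% D))
    ll_car <- -n * T_len / 2 * log(2 * pi) +
      log_det_car_precision(lattice, car, T_len) / 2 -
      qf / (2 * theta$sigma^2)
  }
  # noise part
  if (theta$sigma_eps == 0) {
    ll_eps <- if (all(eps == 0)) 0 else -Inf
  } else {
    ll_eps <- sum(stats::dnorm(eps, 0, theta$sigma_eps, log = TRUE))
  }
  ll_car + ll_eps
}

#' Poisson log-likelihood of a count panel
#'
#' Sum over all space-time cells of the Poisson log-pmf of Y given the
#' intensity panel lambda (inside the sampler, lambda is reconstructed
#' deterministically from U, Y, theta and lambda_0 by the recursion).
#'
#' @param Y n x T non-negative integer matrix.
#' @param lam n x T strictly positive matrix.
#' @return scalar log-likelihood.
#' @export
log_likelihood_counts <- function(Y, lam) {
  stopifnot(all(dim(Y) == dim(lam)))
  if (any(lam <= 0)) stop("intensity must be strictly positive")
  sum(stats::dpois(Y, lam, log = TRUE))
}

#' Joint log-posterior (assembly identity)
#'
#' log_prior + log_latent_density + log_likelihood_counts, with lambda
#' reconstructed from the latents under the stationary lambda_0 policy.
#'
#' @inheritParams log_latent_density
#' @param Y n x T count panel.
#' @param priors a [prior_spec()].
#' @return scalar log-posterior density (up to the constant count factorials
#'   included via `dpois`).
#' @export
log_posterior <- function(Y, X, eps, alpha, theta, lattice, priors) {
  lp <- log_prior(theta, priors)
  if (!is.finite(lp)) return(-Inf)
  lam0 <- exp(alpha[, 1] + theta$sigma_eps^2 / 2) / (1 - theta$eta - theta$kappa)
  lam <- reconstruct_intensity(X + eps, Y, theta$eta, theta$kappa, lam0)
  lp + log_latent_density(X, eps, alpha, theta, lattice) +
    log_likelihood_counts(Y, lam)
}
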