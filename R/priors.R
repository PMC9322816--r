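#' Prior specification for theta
#'
#' Informative Beta priors on the recursion weights eta and kappa, jointly
#' truncated to the stationarity triangle {eta + kappa < 1}, and half-Cauchy
#' priors on the scales sigma and sigma_eps. All hyperparameters are
#' configurable; the defaults are weakly informative.
#'
#' @param eta_shape,kappa_shape length-2 positive Beta (a, b) hyperparameters.
#' @param sigma_scale,sigma_eps_scale half-Cauchy scales (> 0).
#' @return object of class `prior_spec`; the normalizing constant of the
#'   triangle truncation is computed by quadrature and cached.
#' @export
prior_spec <- function(eta_shape = c(2, 2), kappa_shape = c(2, 2),
                       sigma_scale = 2.5, sigma_eps_scale = 2.5) {
  stopifnot(length(eta_shape) == 2L, length(kappa_shape) == 2L,
            all(eta_shape > 0), all(kappa_shape > 0),
            sigma_scale > 0, sigma_eps_scale > 0)
  # P(eta + kappa < 1) under independent Betas, by 1-D quadrature
  z <- stats::integrate(function(k)
    stats::dbeta(k, kappa_shape[1], kappa_shape[2]) *
      stats::pbeta(1 - k, eta_shape[1], eta_shape[2]),
    0, 1, rel.tol = 1e-10)$value
  structure(list(eta_shape = eta_shape, kappa_shape = kappa_shape,
                 sigma_scale = sigma_scale, sigma_eps_scale = sigma_eps_scale,
                 log_triangle_norm = log(z)),
            class = "prior_spec")
}

# half-Cauchy log-density on [0, Inf)
log_half_cauchy <- function(x, scale) {
  ifelse(x < 0, -Inf, log(2) + stats::dcauchy(x, 0, scale, log = TRUE))
}

#' Log prior density of theta
#'
#' Sum of the truncated-Beta joint log-density of (eta, kappa) — normalized
#' over the triangle, hence symmetric in (eta, kappa) at equal
#' hyperparameters — and half-Cauchy log-densities for sigma and sigma_eps.
#' Returns -Inf outside {eta + kappa < 1} or the positivity constraints.
#'
#' @param theta a [spingarch_params()] object (alpha and zeta carry no prior
#'   mass here; zeta is fixed by default and alpha is estimated upstream).
#' @param priors a [prior_spec()].
#' @return scalar log-density (possibly -Inf).
#' @export
log_prior <- function(theta, priors) {
  if (theta$eta < 0 || theta$kappa < 0 || theta$eta + theta$kappa >= 1)
    return(-Inf)
  if (theta$sigma < 0 || theta$sigma_eps < 0) return(-Inf)
  stats::dbeta(theta$eta, priors$eta_shape[1], priors$eta_shape[2], log = TRUE) +
    stats::dbeta(theta$kappa, priors$kappa_shape[1], priors$kappa_shape[2], log = TRUE) -
    priors$log_triangle_norm +
    log_half_cauchy(theta$sigma, priors$sigma_scale) +
    log_half_cauchy(theta$sigma_eps, priors$sigma_eps_scale)
}
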