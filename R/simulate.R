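#' One step of the intensity recursion
#'
#' lambda_t = exp(U_t) + eta * Y_{t-1} + kappa * lambda_{t-1}, elementwise
#' over sites, where U_t = X_t + eps_t is the latent log-Gaussian term.
#'
#' @param lam_prev positive intensity vector at t-1.
#' @param Y_prev non-negative count vector at t-1.
#' @param U_t latent field (CAR draw plus noise) at t.
#' @param eta,kappa recursion weights.
#' @return intensity vector at t (strictly positive).
#' @export
step_intensity <- function(lam_prev, Y_prev, U_t, eta, kappa) {
  if (!all(is.finite(U_t))) stop("U_t must be finite")
  stopifnot(all(lam_prev > 0), all(Y_prev >= 0))
  exp(U_t) + eta * Y_prev + kappa * lam_prev
}

#' Simulate a SPINGARCH(1,1) count panel
#'
#' For each time slice t: draws the CAR field X_t around alpha_t
#' (independently across t), i.i.d. noise eps_t, advances the intensity
#' recursion, and draws Poisson counts sitewise.
#'
#' The initial intensity is set by `lam0_policy`: `"stationary"` (default)
#' uses the homogeneous stationary mean per site,
#' lambda_0 = exp(alpha_1 + sigma_eps^2/2) / (1 - eta - kappa), with the
#' lagged count Y_0 set to its expectation lambda_0; `"constant"` uses
#' `lam0_value` everywhere (and Y_0 = lam0_value).
#'
#' @param params a [spingarch_params()] object (its `alpha` is recycled to
#'   n x T).
#' @param lattice a [build_lattice()] lattice.
#' @param T_len number of time periods.
#' @param seed optional integer seed.
#' @param lam0_policy `"stationary"` or `"constant"`.
#' @param lam0_value positive scalar used when `lam0_policy = "constant"`.
#' @return a list of class `spingarch_sim` with elements `Y` (n x T integer
#'   counts), `lam` (n x T intensities), `lam0`, `X`, `eps`, `U = X + eps`,
#'   `alpha` (expanded panel), `site_ids`, and `params`.
#' @export
spingarch_simulate <- function(params, lattice, T_len, seed = NULL,
                               lam0_policy = c("stationary", "constant"),
                               lam0_value = 1) {
  lam0_policy <- match.arg(lam0_policy)
  stopifnot(inherits(params, "spingarch_params"), T_len >= 1)
  if (params$eta + params$kappa >= 1)
    stop("stationarity requires eta + kappa < 1")
  n <- lattice$n
  alpha <- expand_alpha(params$alpha, n, T_len)
  car <- NULL
  if (params$sigma > 0) {
    car <- car_spec(params$zeta, params$sigma^2)
    validate_car(car, lattice)
  }
  if (!is.null(seed)) set.seed(seed)

  X <- matrix(0, n, T_len); eps <- matrix(0, n, T_len)
  lam <- matrix(0, n, T_len)
  Y <- matrix(0L, n, T_len)

  if (!is.null(car)) R <- chol(car_precision(lattice, car))
  lam0 <- switch(lam0_policy,
    stationary = exp(alpha[, 1] + params$sigma_eps^2 / 2) /
      (1 - params$eta - params$kappa),
    constant = rep(lam0_value, n))
  Y_prev <- lam0
  lam_prev <- lam0
  for (t in seq_len(T_len)) {
    X[, t] <- if (is.null(car)) alpha[, t] else
      alpha[, t] + backsolve(R, stats::rnorm(n))
    eps[, t] <- if (params$sigma_eps > 0) stats::rnorm(n, 0, params$sigma_eps) else 0
    U_t <- X[, t] + eps[, t]
    lam[, t] <- step_intensity(lam_prev, Y_prev, U_t, params$eta, params$kappa)
    Y[, t] <- stats::rpois(n, lam[, t])
    lam_prev <- lam[, t]
    Y_prev <- Y[, t]
  }
  if (!all(is.finite(lam))) stop("non-finite intensity during simulation")
  dimnames(Y) <- dimnames(lam) <- dimnames(X) <- list(lattice$site_ids, NULL)
  structure(list(Y = Y, lam = lam, lam0 = lam0, X = X, eps = eps,
                 U = X + eps, alpha = alpha, site_ids = lattice$site_ids,
                 params = params),
            class = "spingarch_sim")
}

#' Reconstruct the intensity path from latents and parameters
#'
#' Deterministic replay of the recursion given U, the observed counts and
#' theta; used inside the sampler and by the prediction rule.
#'
#' @param U n x T latent panel (X + eps).
#' @param Y n x T count panel.
#' @param eta,kappa recursion weights.
#' @param lam0 length-n initial intensity (Y_0 is taken as lam0).
#' @return n x T intensity matrix.
#' @export
reconstruct_intensity <- function(U, Y, eta, kappa, lam0) {
  n <- nrow(U); T_len <- ncol(U)
  stopifnot(nrow(Y) == n, ncol(Y) == T_len, length(lam0) == n)
  lam <- matrix(0, n, T_len)
  lam_prev <- lam0; Y_prev <- lam0
  for (t in seq_len(T_len)) {
    lam[, t] <- exp(U[, t]) + eta * Y_prev + kappa * lam_prev
    lam_prev <- lam[, t]
    Y_prev <- Y[, t]
  }
  lam
}
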