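#' SPINGARCH(1,1) model parameters
#'
#' Bundles theta = (eta, kappa, sigma, sigma_eps, zeta) and the baseline
#' log-intensity panel alpha. `eta` weights yesterday's observed counts
#' (repeated victimization / self-excitation), `kappa = 1 - chi` weights
#' yesterday's intensity (persistence in the absence of new events, with chi
#' the natural deterioration), `sigma` is the CAR conditional standard
#' deviation, `sigma_eps` the i.i.d. noise standard deviation, and `zeta` the
#' spatial dependence of the CAR field. Stationarity of the mean requires
#' `eta + kappa < 1`.
#'
#' @param eta,kappa non-negative recursion weights with `eta + kappa < 1`.
#' @param sigma,sigma_eps non-negative scale parameters (log-intensity scale).
#' @param zeta CAR spatial-dependence coefficient.
#' @param alpha baseline log-intensity: an n x T matrix, or a scalar/vector
#'   recycled when the lattice and horizon are known downstream.
#' @return object of class `spingarch_params`.
#' @export
spingarch_params <- function(eta, kappa, sigma, sigma_eps, zeta = 0.99, alpha = 0) {
  stopifnot(is.finite(eta), is.finite(kappa), is.finite(sigma),
            is.finite(sigma_eps), is.finite(zeta), all(is.finite(alpha)))
  if (eta < 0 || kappa < 0) stop("eta and kappa must be non-negative")
  if (eta + kappa >= 1) stop("stationarity requires eta + kappa < 1")
  if (sigma < 0 || sigma_eps < 0) stop("scale parameters must be non-negative")
  structure(list(eta = eta, kappa = kappa, sigma = sigma,
                 sigma_eps = sigma_eps, zeta = zeta, alpha = alpha),
            class = "spingarch_params")
}

#' @export
print.spingarch_params <- function(x, ...) {
  cat(sprintf(
    "SPINGARCH(1,1) parameters: eta=%.3f kappa=%.3f (margin %.3f) sigma=%.3f sigma_eps=%.3f zeta=%.3f\n",
    x$eta, x$kappa, 1 - x$eta - x$kappa, x$sigma, x$sigma_eps, x$zeta))
  invisible(x)
}

#' Stationarity margin 1 - eta - kappa
#'
#' Positive iff the count process admits a finite long-run mean.
#'
#' @param eta,kappa non-negative recursion weights.
#' @return `1 - eta - kappa` (may be negative, signalling an invalid region).
#' @export
stationarity_margin <- function(eta, kappa) {
  stopifnot(eta >= 0, kappa >= 0)
  1 - eta - kappa
}

#' Long-run mean under a spatially homogeneous model
#'
#' Closed form for the stationary mean of the intensity (and of the counts)
#' when the CAR field is degenerate (sigma = 0) and the baseline is a
#' constant: E(lambda) = exp(alpha + sigma_eps^2 / 2) / (1 - eta - kappa),
#' the lognormal mean of exp(alpha + eps) amplified by the ARMA-like
#' feedback.
#'
#' @param alpha_const constant baseline log-intensity.
#' @param sigma_eps i.i.d. noise standard deviation.
#' @param eta,kappa recursion weights, `eta + kappa < 1`.
#' @return the stationary mean (scalar).
#' @export
stationary_mean_homogeneous <- function(alpha_const, sigma_eps, eta, kappa) {
  if (eta + kappa >= 1) stop("stationarity requires eta + kappa < 1")
  stopifnot(eta >= 0, kappa >= 0, sigma_eps >= 0)
  exp(alpha_const + sigma_eps^2 / 2) / (1 - eta - kappa)
}

# recycle a scalar/vector/matrix alpha to an n x T panel
expand_alpha <- function(alpha, n, T_len) {
  if (is.matrix(alpha)) {
    if (nrow(alpha) == n && ncol(alpha) == T_len) return(alpha)
    if (nrow(alpha) == n && ncol(alpha) == 1L) return(matrix(alpha, n, T_len))
    if (nrow(alpha) == 1L && ncol(alpha) == T_len)
      return(matrix(alpha, n, T_len, byrow = TRUE))
    stop("alpha has incompatible dimensions")
  }
  if (length(alpha) == 1L) return(matrix(alpha, n, T_len))
  if (length(alpha) == n) return(matrix(alpha, n, T_len))
  stop("alpha has incompatible length")
}
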