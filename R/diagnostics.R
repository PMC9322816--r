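# Posterior summaries and convergence diagnostics: split-Rhat, ESS,
# Shannon entropy of draws under the sqrt(n)-bins rule, and the
# summary table with columns Mean Sd 2.5% 25% 50% 75% 97.5% n_eff Rhat H.

# coerce list-of-chains / matrix (iterations x chains) to a matrix
as_chain_matrix <- function(chains) {
  if (is.list(chains)) {
    len <- unique(lengths(chains))
    if (length(len) != 1L) stop("chains must have equal length")
    chains <- do.call(cbind, chains)
  }
  as.matrix(chains)
}

#' Split-chain potential scale reduction factor (Rhat)
#'
#' Each chain is split in half; Rhat is sqrt(var_plus / W) with
#' W the mean within-half variance and var_plus the usual weighted
#' combination of within and between variance. Values near 1 indicate
#' convergence.
#'
#' @param chains list of equal-length numeric vectors (>= 2 chains of
#'   length >= 4), or an iterations x chains matrix.
#' @return scalar Rhat; 1 by convention when every half is constant.
#' @export
split_rhat <- function(chains) {
  m <- as_chain_matrix(chains)
  if (ncol(m) < 2L || nrow(m) < 4L) stop("need >= 2 chains of length >= 4")
  half <- nrow(m) %/% 2L
  halves <- cbind(m[seq_len(half), , drop = FALSE],
                  m[(nrow(m) - half + 1L):nrow(m), , drop = FALSE])
  W <- mean(apply(halves, 2L, stats::var))
  if (W == 0) return(1)
  B_over_n <- stats::var(colMeans(halves))
  var_plus <- (half - 1) / half * W + B_over_n
  sqrt(var_plus / W)
}

#' Effective sample size of MCMC draws
#'
#' Autocorrelation-based ESS with initial-positive-sequence truncation:
#' per-lag correlations are combined across chains through the pooled
#' variance (split-chain var_plus), summed over lags while consecutive
#' pairs remain positive, and ESS = m*n / (1 + 2 * sum rho). Capped at the
#' total number of draws (negative autocorrelation would push the raw
#' estimate above the total); a capped or degenerate result carries the
#' attribute `flag`.
#'
#' @inheritParams split_rhat
#' @return scalar ESS, possibly with attribute `flag` in
#'   `c("capped", "constant")`.
#' @export
effective_sample_size <- function(chains) {
  m <- as_chain_matrix(chains)
  n <- nrow(m); n_chain <- ncol(m)
  if (n < 4L) stop("chains too short")
  total <- n * n_chain
  ch_var <- apply(m, 2L, stats::var)
  if (all(ch_var == 0))
    return(structure(total, flag = "constant"))
  W <- mean(ch_var)
  var_plus <- (n - 1) / n * W +
    if (n_chain > 1L) stats::var(colMeans(m)) else 0
  # chain-averaged autocovariances
  acov <- sapply(seq_len(n_chain), function(j) {
    a <- stats::acf(m[, j], lag.max = n - 2L, plot = FALSE,
                    type = "covariance", demean = TRUE)$acf[, 1, 1]
    a
  })
  mean_acov <- rowMeans(as.matrix(acov))
  rho <- 1 - (W - mean_acov) / var_plus   # rho[1] is lag 0
  # Geyer initial positive sequence on pairs Gamma_k = rho_{2k} + rho_{2k+1}
  tau <- -1
  t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (!is.finite(pair) || pair < 0) break
    tau <- tau + 2 * pair
    t <- t + 2L
  }
  tau <- max(tau, 1e-8)
  ess <- total / tau
  if (ess > total) structure(total, flag = "capped") else ess
}

#' Shannon entropy of a sample under the sqrt(n)-bins rule
#'
#' Discretizes the sample range into `round(sqrt(length(sample)))`
#' equal-width bins and returns H = -sum p_hat * ln(p_hat) over non-empty
#' bins (natural log, so the maximum is ln(bins)). A small H signals low
#' posterior uncertainty. Constant samples return 0 by convention.
#'
#' @param sample numeric vector, length >= 4.
#' @return scalar entropy in nats.
#' @export
shannon_entropy_sqrt_bins <- function(sample) {
  sample <- sample[is.finite(sample)]
  n <- length(sample)
  if (n < 4L) stop("sample size must be >= 4")
  rng <- range(sample)
  if (rng[1] == rng[2]) return(0)
  bins <- max(1L, as.integer(round(sqrt(n))))
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  cnt <- tabulate(findInterval(sample, edges, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = bins)
  p <- cnt[cnt > 0] / n
  -sum(p * log(p))
}

#' Normalized autocorrelation function of a draw sequence
#'
#' @param sample numeric vector.
#' @param max_lag largest lag (< length(sample)).
#' @return numeric vector of autocorrelations at lags 0..max_lag (lag 0 is
#'   1); for a constant sample, zeros beyond lag 0 with attribute
#'   `flag = "constant"`.
#' @export
posterior_acf <- function(sample, max_lag = 20L) {
  stopifnot(length(sample) > max_lag)
  if (stats::var(sample) == 0)
    return(structure(c(1, rep(0, max_lag)), flag = "constant"))
  drop(stats::acf(sample, lag.max = max_lag, plot = FALSE,
                  demean = TRUE)$acf)
}

#' Posterior summary table
#'
#' One row per parameter with the columns Mean, Sd, 2.5%, 25.0%, 50.0%,
#' 75.0%, 97.5%, n_eff, Rhat and the Shannon entropy H of the pooled draws
#' (sqrt(n)-bins rule). Quantiles are empirical with linear interpolation.
#' Parameters with non-finite draws (e.g. tau when sigma is fixed at zero)
#' are dropped.
#'
#' @param draws a [run_mcmc()] result, or a plain matrix of draws with a
#'   parallel `chain_id` vector.
#' @param chain_id chain labels when `draws` is a matrix.
#' @return data.frame of class `spingarch_summary`.
#' @export
posterior_summary <- function(draws, chain_id = NULL) {
  if (inherits(draws, "spingarch_draws")) {
    m <- draws$draws[, draws$param_names, drop = FALSE]
    chain_id <- draws$chain_id
  } else {
    m <- as.matrix(draws)
    if (is.null(chain_id)) chain_id <- rep(1L, nrow(m))
  }
  keep <- apply(m, 2L, function(v) all(is.finite(v)))
  m <- m[, keep, drop = FALSE]
  chains <- sort(unique(chain_id))
  rows <- lapply(colnames(m), function(p) {
    v <- m[, p]
    per_chain <- lapply(chains, function(ch) v[chain_id == ch])
    q <- stats::quantile(v, c(0.025, 0.25, 0.5, 0.75, 0.975),
                         names = FALSE, type = 7)
    rh <- if (length(chains) >= 2L && length(per_chain[[1]]) >= 4L)
      split_rhat(per_chain) else NA_real_
    ne <- if (length(per_chain[[1]]) >= 4L)
      as.numeric(effective_sample_size(per_chain)) else NA_real_
    data.frame(param = p, Mean = mean(v), Sd = stats::sd(v),
               `2.5%` = q[1], `25.0%` = q[2], `50.0%` = q[3],
               `75.0%` = q[4], `97.5%` = q[5],
               n_eff = ne, Rhat = rh,
               H = shannon_entropy_sqrt_bins(v),
               check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("spingarch_summary", "data.frame")
  out
}
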