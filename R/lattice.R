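#' Build a lattice from an edge list
#'
#' Constructs the neighbourhood structure used throughout the package: a
#' binary symmetric adjacency matrix with zero diagonal, its spectral-radius
#' scaled version, and the cached eigenvalues of the scaled matrix that feed
#' the eigenvalue form of the CAR log-determinant.
#'
#' The adjacency is always rescaled by its largest eigenvalue so that the
#' scaled matrix has spectral radius 1. This makes the spatial-dependence
#' coefficient `zeta` interpretable on a fixed interval with upper limit 1 on
#' any lattice, so a value such as 0.99 ("near the edge of the parameter
#' space") is admissible regardless of the graph.
#'
#' @param edges two-column object (matrix or data.frame) of site-id pairs, or
#'   `NULL` for an edgeless lattice.
#' @param site_ids character or integer vector of unit identifiers; every edge
#'   endpoint must appear here.
#' @return an object of class `spingarch_lattice`: a list with `site_ids`,
#'   `n`, `N_raw` (binary adjacency), `N_scaled` (adjacency over its spectral
#'   radius), and `eigvals` (sorted eigenvalues of `N_scaled`).
#' @examples
#' lat <- build_lattice(cbind(c("a", "b"), c("b", "c")), c("a", "b", "c"))
#' lat$eigvals  # path graph: -1, 0, 1 after scaling
#' @export
build_lattice <- function(edges, site_ids) {
  site_ids <- as.character(site_ids)
  if (anyDuplicated(site_ids)) stop("duplicate site ids")
  n <- length(site_ids)
  if (n < 1L) stop("need at least one site")
  A <- matrix(0, n, n, dimnames = list(site_ids, site_ids))
  if (!is.null(edges) && NROW(edges) > 0L) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("edges must have two columns")
    a <- as.character(edges[, 1L]); b <- as.character(edges[, 2L])
    bad <- !(a %in% site_ids) | !(b %in% site_ids)
    if (any(bad)) stop("edge endpoint not in site_ids: ",
                       paste(unique(c(a[bad], b[bad])), collapse = ", "))
    if (any(a == b)) stop("self-loops are not allowed")
    ia <- match(a, site_ids); ib <- match(b, site_ids)
    A[cbind(ia, ib)] <- 1     # duplicates are idempotent
    A[cbind(ib, ia)] <- 1
  }
  new_lattice(A, site_ids)
}

# shared constructor from a validated 0/1 symmetric matrix
new_lattice <- function(A, site_ids) {
  n <- length(site_ids)
  if (any(A > 0)) {
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    chi_max <- max(ev)
    Ns <- A / chi_max
    eigvals <- sort(ev / chi_max)
  } else {
    Ns <- A
    eigvals <- rep(0, n)
  }
  structure(list(site_ids = site_ids, n = n, N_raw = A,
                 N_scaled = Ns, eigvals = eigvals),
            class = "spingarch_lattice")
}

#' Build a lattice from a dense adjacency matrix
#'
#' @param A square 0/1 matrix; symmetrized (`(A + t(A)) > 0`) with a warning
#'   if asymmetric; diagonal must be zero.
#' @param site_ids optional ids; defaults to the matrix dimnames or `1:n`.
#' @return a [build_lattice()] object.
#' @export
as_lattice <- function(A, site_ids = NULL) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (any(diag(A) != 0)) stop("adjacency diagonal must be zero (no self-loops)")
  if (!all(A %in% c(0, 1))) stop("adjacency entries must be 0/1")
  if (!isTRUE(all.equal(A, t(A)))) {
    warning("adjacency not symmetric; symmetrizing with (A + t(A)) > 0")
    A <- 1 * ((A + t(A)) > 0)
  }
  if (is.null(site_ids)) {
    site_ids <- if (!is.null(rownames(A))) rownames(A) else as.character(seq_len(nrow(A)))
  }
  dimnames(A) <- list(site_ids, site_ids)
  new_lattice(A, as.character(site_ids))
}

#' @export
print.spingarch_lattice <- function(x, ...) {
  cat(sprintf("spingarch lattice: %d sites, %d edges, eigenvalue range [%.3f, %.3f]\n",
              x$n, sum(x$N_raw) / 2, min(x$eigvals), max(x$eigvals)))
  invisible(x)
}

#' CAR specification
#'
#' Pairs the spatial-dependence coefficient `zeta` with the conditional
#' variance `sigma2` of the conditionally autoregressive Gaussian field whose
#' joint precision is (I - zeta * N_scaled) / sigma2.
#'
#' @param zeta spatial dependence; must satisfy `1 - zeta * chi_j > 0` for all
#'   eigenvalues of the lattice it is used with.
#' @param sigma2 conditional variance, > 0.
#' @return object of class `car_spec`.
#' @export
car_spec <- function(zeta, sigma2) {
  stopifnot(is.finite(zeta), is.finite(sigma2))
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  structure(list(zeta = zeta, sigma2 = sigma2), class = "car_spec")
}

# positive-definiteness of the CAR precision for this lattice
validate_car <- function(car, lattice) {
  if (any(1 - car$zeta * lattice$eigvals <= 0))
    stop("CAR precision not positive definite: 1 - zeta*chi_j <= 0 for some eigenvalue")
  invisible(TRUE)
}

# dense precision (I - zeta * N_scaled) / sigma2; internal
car_precision <- function(lattice, car) {
  (diag(lattice$n) - car$zeta * lattice$N_scaled) / car$sigma2
}

#' CAR full-conditional mean at one site
#'
#' The conditional mean of the latent field at site i given all other sites:
#' mu_i = alpha_i + zeta * sum_j w_ij (X_j - alpha_j), where the weights w_ij
#' are the entries of the spectral-radius-scaled adjacency.
#'
#' @param X,alpha numeric vectors of length n (field and baseline).
#' @param car a [car_spec()].
#' @param lattice a [build_lattice()] object.
#' @param site_index integer in 1..n.
#' @return scalar conditional mean.
#' @export
car_conditional_mean <- function(X, alpha, car, lattice, site_index) {
  n <- lattice$n
  stopifnot(length(X) == n, length(alpha) == n)
  validate_car(car, lattice)
  if (length(site_index) != 1L || site_index < 1L || site_index > n)
    stop("site_index out of range")
  alpha[site_index] +
    car$zeta * sum(lattice$N_scaled[site_index, ] * (X - alpha))
}

#' Log-determinant of the T-block CAR precision
#'
#' Uses the cached eigenvalues chi_j of the scaled neighbourhood matrix:
#' `T * ( -n log(sigma2) + sum_j log(1 - zeta * chi_j) )`, the log-determinant
#' of the precision of T independent CAR time slices. Avoids any dense
#' determinant at run time; the eigenvalues depend only on the lattice.
#'
#' @inheritParams car_conditional_mean
#' @param T_blocks number of independent time blocks (>= 1).
#' @return scalar log-determinant.
#' @export
log_det_car_precision <- function(lattice, car, T_blocks = 1L) {
  stopifnot(T_blocks >= 1)
  v <- 1 - car$zeta * lattice$eigvals
  if (any(v <= 0)) stop("CAR precision not positive definite")
  T_blocks * (-lattice$n * log(car$sigma2) + sum(log(v)))
}

#' Sample a CAR Gaussian field
#'
#' Draws from N(alpha, sigma2 * (I - zeta N_scaled)^(-1)) via the Cholesky
#' factor of the precision.
#'
#' @inheritParams car_conditional_mean
#' @param n_draws number of independent fields to draw.
#' @param seed optional integer; if given, `set.seed(seed)` is called so the
#'   draw is reproducible.
#' @return numeric vector of length n (or an n x n_draws matrix).
#' @export
sample_car_field <- function(lattice, alpha, car, n_draws = 1L, seed = NULL) {
  validate_car(car, lattice)
  n <- lattice$n
  stopifnot(length(alpha) == n)
  if (!is.null(seed)) set.seed(seed)
  R <- chol(car_precision(lattice, car))   # upper triangular, P = R'R
  Z <- matrix(stats::rnorm(n * n_draws), n, n_draws)
  X <- alpha + backsolve(R, Z)             # cov = P^{-1}
  if (n_draws == 1L) drop(X) else X
}
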