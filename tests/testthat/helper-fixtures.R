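# Shared fixtures: tiny lattices and a random-lattice generator used by
# property-style tests. Everything is built in code; no data files.

lattice_pair <- function() build_lattice(cbind("a", "b"), c("a", "b"))

lattice_path3 <- function()
  build_lattice(cbind(c("a", "b"), c("b", "c")), c("a", "b", "c"))

# random connected-ish lattice with n sites (n >= 2), at least one edge
random_lattice <- function(n) {
  ids <- letters[seq_len(n)]
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < 0.5
  if (!any(keep)) keep[sample(nrow(pairs), 1)] <- TRUE
  build_lattice(cbind(ids[pairs[keep, 1]], ids[pairs[keep, 2]]), ids)
}

broadcast_cov_for_test <- function(cv, n, T_len)
  spingarch:::broadcast_covariate(cv, n, T_len)

# random CAR spec valid for a given lattice
random_car <- function(lattice) {
  lo <- 1 / min(lattice$eigvals)   # eigvals include -something <= 0
  zeta <- stats::runif(1, max(lo * 0.8, -5), 0.95)
  car_spec(zeta, stats::runif(1, 0.2, 3))
}
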