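# Synthetic city-like data: rook-grid lattices standing in for the ~141
# administrative zones of a mid-sized city, landmark-distance covariates
# (police units, cameras, markets, parks, hospitals) averaged per zone per
# month, a static population-density covariate, and count panels generated
# by the SPINGARCH(1,1) model itself.

#' Rook-adjacency grid lattice with centroids
#'
#' The default 12 x 12 grid has 144 zones, close to the 141 administrative
#' zones the model is designed for; centroids are unit-spaced.
#'
#' @param rows,cols grid dimensions, `rows * cols >= 2`.
#' @return a [build_lattice()] lattice with an extra `centroids` element
#'   (n x 2 matrix of x, y coordinates).
#' @export
generate_city_lattice <- function(rows = 12L, cols = 12L) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows * cols < 2L) stop("need at least two zones")
  ids <- sprintf("z%03d", seq_len(rows * cols))
  idx <- function(r, c) (r - 1L) * cols + c
  edges <- NULL
  for (r in seq_len(rows)) for (cc in seq_len(cols)) {
    if (cc < cols) edges <- rbind(edges, c(ids[idx(r, cc)], ids[idx(r, cc + 1L)]))
    if (r < rows) edges <- rbind(edges, c(ids[idx(r, cc)], ids[idx(r + 1L, cc)]))
  }
  lat <- build_lattice(edges, ids)
  cent <- cbind(x = rep(seq_len(cols), times = rows),
                y = rep(seq_len(rows), each = cols))
  rownames(cent) <- ids
  lat$centroids <- cent
  lat
}

#' Landmark-distance and density covariates
#'
#' Places each landmark type uniformly in the grid's bounding box and, for
#' every zone and month, records the distance from the zone centroid to the
#' nearest landmark plus a small monthly jitter (emulating the within-zone
#' averaging of event-to-landmark distances, which varies by month). Also
#' emits a static lognormal population-density covariate `pob`.
#'
#' @param lattice a [generate_city_lattice()] lattice (needs `centroids`).
#' @param landmark_counts named integer vector, e.g.
#'   `c(upc = 6, cam = 12, cc = 5, par = 8, hos = 3)`.
#' @param T_len number of months.
#' @param jitter_sd standard deviation of the monthly jitter (distance
#'   units; grid cells are unit-spaced).
#' @param seed optional integer seed.
#' @return named list of [covariate_panel()] objects (distances are n x T,
#'   `pob` is n x 1).
#' @export
generate_landmark_covariates <- function(lattice, landmark_counts =
                                           c(upc = 6, cam = 12, cc = 5,
                                             par = 8, hos = 3),
                                         T_len = 60L, jitter_sd = 0.25,
                                         seed = NULL) {
  if (is.null(lattice$centroids)) stop("lattice has no centroids")
  stopifnot(all(landmark_counts >= 1))
  if (!is.null(seed)) set.seed(seed)
  cent <- lattice$centroids
  n <- lattice$n
  diag_len <- sqrt(diff(range(cent[, 1]))^2 + diff(range(cent[, 2]))^2) + 1
  out <- list()
  for (nm in names(landmark_counts)) {
    k <- landmark_counts[[nm]]
    lx <- stats::runif(k, min(cent[, 1]), max(cent[, 1]))
    ly <- stats::runif(k, min(cent[, 2]), max(cent[, 2]))
    d <- apply(cent, 1L, function(p) min(sqrt((p[1] - lx)^2 + (p[2] - ly)^2)))
    panel <- matrix(d, n, T_len) +
      matrix(stats::rnorm(n * T_len, 0, jitter_sd), n, T_len)
    panel <- pmin(pmax(panel, 0), diag_len)
    out[[nm]] <- covariate_panel(nm, panel, "spatiotemporal")
  }
  out$pob <- covariate_panel("pob",
    matrix(stats::rlnorm(n, meanlog = 0, sdlog = 0.5), n, 1L), "spatial")
  out
}

#' Synthetic scenario description
#'
#' A fully stated world for end-to-end tests: grid size, horizon, landmark
#' layout, true model parameters, and per-covariate effect functions on the
#' baseline log-intensity. Defaults emulate the reference setting: a
#' 12 x 12 grid (144 zones, close to the 141 modeled), 60 monthly periods,
#' self-excitation eta = 0.35, persistence kappa = 0.01 and noise
#' sigma_eps = 1.37 (posterior-mean scale of the reference fit), CAR
#' dependence zeta = 0.99 with a moderate conditional scale sigma = 0.3.
#'
#' @param grid_rows,grid_cols lattice dimensions.
#' @param T_len months.
#' @param landmark_counts named integer vector of landmarks per type.
#' @param eta,kappa,sigma,sigma_eps,zeta true parameter values.
#' @param beta0 baseline intercept (log scale).
#' @param effect_functions named list of functions of the covariate value,
#'   added to the baseline log-intensity (names must match covariates).
#' @param jitter_sd monthly jitter of the distance covariates.
#' @param seed integer seed driving every random element.
#' @return object of class `spingarch_scenario`.
#' @export
synthetic_scenario <- function(grid_rows = 12L, grid_cols = 12L, T_len = 60L,
                               landmark_counts = c(upc = 6, cam = 12, cc = 5,
                                                   par = 8, hos = 3),
                               eta = 0.35, kappa = 0.01, sigma = 0.3,
                               sigma_eps = 1.37, zeta = 0.99, beta0 = -0.5,
                               effect_functions = list(),
                               jitter_sd = 0.25, seed = 1L) {
  if (eta + kappa >= 1) stop("true parameters violate eta + kappa < 1")
  structure(list(grid_rows = grid_rows, grid_cols = grid_cols, T_len = T_len,
                 landmark_counts = landmark_counts, eta = eta, kappa = kappa,
                 sigma = sigma, sigma_eps = sigma_eps, zeta = zeta,
                 beta0 = beta0, effect_functions = effect_functions,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "spingarch_scenario")
}

#' Generate a full synthetic dataset from a scenario
#'
#' Builds the lattice and covariates, assembles the true baseline
#' alpha_t = beta0 + sum effect_functions(covariates), simulates the count
#' panel from the SPINGARCH(1,1) model, and returns everything needed for
#' recovery and comparison experiments, ground truth included.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with `Y` (n x T counts), `covariates`, `lattice`, `alpha`
#'   (true baseline), `sim` (full [spingarch_simulate()] output) and
#'   `truth` (the scenario, with the realized parameter object).
#' @export
generate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "spingarch_scenario"))
  set.seed(scenario$seed)
  lat <- generate_city_lattice(scenario$grid_rows, scenario$grid_cols)
  covs <- generate_landmark_covariates(lat, scenario$landmark_counts,
                                       scenario$T_len,
                                       jitter_sd = scenario$jitter_sd)
  n <- lat$n
  alpha <- matrix(scenario$beta0, n, scenario$T_len)
  for (nm in names(scenario$effect_functions)) {
    if (!nm %in% names(covs)) stop("effect function for unknown covariate: ", nm)
    v <- broadcast_covariate(covs[[nm]], n, scenario$T_len)
    alpha <- alpha + scenario$effect_functions[[nm]](v)
  }
  params <- spingarch_params(scenario$eta, scenario$kappa, scenario$sigma,
                             scenario$sigma_eps, scenario$zeta, alpha)
  sim <- spingarch_simulate(params, lat, scenario$T_len)
  list(Y = sim$Y, covariates = covs, lattice = lat, alpha = alpha,
       sim = sim, truth = list(scenario = scenario, params = params))
}
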