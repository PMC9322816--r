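test_that("generate_city_lattice builds rook grids", {
  g22 <- generate_city_lattice(2, 2)
  expect_equal(g22$n, 4L)
  expect_equal(sum(g22$N_raw) / 2, 4)          # the 4-cycle
  g <- generate_city_lattice(12, 12)
  expect_equal(g$n, 144L)
  expect_equal(sum(g$N_raw) / 2, 12 * 11 * 2)  # 264 edges
  # interior site has 4 neighbours
  deg <- rowSums(g$N_raw)
  interior <- g$centroids[, 1] > 1 & g$centroids[, 1] < 12 &
    g$centroids[, 2] > 1 & g$centroids[, 2] < 12
  expect_true(all(deg[interior] == 4))
  expect_error(generate_city_lattice(1, 1), "two zones")
})

test_that("landmark covariates are deterministic distances with jitter", {
  g <- generate_city_lattice(6, 6)
  set.seed(100)
  covs <- generate_landmark_covariates(g, c(par = 3), T_len = 12,
                                       jitter_sd = 0.1, seed = 101)
  covs2 <- generate_landmark_covariates(g, c(par = 3), T_len = 12,
                                        jitter_sd = 0.1, seed = 101)
  expect_equal(covs$par$values, covs2$par$values)
  d <- covs$par$values
  expect_true(all(d >= 0))
  expect_true(all(d <= sqrt(2) * 5 + 1))       # grid diagonal bound
  expect_equal(dim(d), c(36L, 12L))
  expect_equal(covs$pob$kind, "spatial")
  # zero jitter: landmark at a centroid gives (near) zero distance somewhere
  cz <- generate_landmark_covariates(g, c(hos = 40), T_len = 2,
                                     jitter_sd = 0, seed = 102)
  expect_lt(min(cz$hos$values), 0.5)
})

test_that("generate_scenario composes covariate effects into the truth", {
  sc <- synthetic_scenario(grid_rows = 3, grid_cols = 3, T_len = 10,
                           landmark_counts = c(cc = 2), eta = 0, kappa = 0,
                           sigma = 0, sigma_eps = 0, zeta = 0, beta0 = 0,
                           effect_functions = list(), seed = 103)
  dat <- generate_scenario(sc)
  # all-zero scenario: iid Poisson(1)
  expect_true(all(dat$sim$lam == 1))
  expect_equal(mean(dat$Y), 1, tolerance = 3 * sqrt(1 / 90) + 0.2)

  sc2 <- synthetic_scenario(grid_rows = 3, grid_cols = 3, T_len = 10,
                            landmark_counts = c(cc = 2), eta = 0.2,
                            kappa = 0.1, sigma = 0.2, sigma_eps = 0.4,
                            zeta = 0.8, beta0 = -0.2,
                            effect_functions = list(cc = function(d) 0.3 * d),
                            seed = 104)
  dat2 <- generate_scenario(sc2)
  dat2b <- generate_scenario(sc2)
  expect_identical(dat2$Y, dat2b$Y)            # end-to-end determinism
  d <- broadcast_cov_for_test(dat2$covariates$cc, 9, 10)
  expect_equal(dat2$alpha, -0.2 + 0.3 * d)
  expect_error(generate_scenario(synthetic_scenario(
    effect_functions = list(nope = identity), seed = 1)), "unknown covariate")
})

test_that("a sinusoidal distance effect is recovered as a non-monotone smooth", {
  sc <- synthetic_scenario(grid_rows = 6, grid_cols = 6, T_len = 30,
                           landmark_counts = c(cc = 3), eta = 0, kappa = 0,
                           sigma = 0, sigma_eps = 0.2, zeta = 0, beta0 = 0.3,
                           effect_functions = list(cc = function(d) sin(1.5 * d)),
                           jitter_sd = 0.3, seed = 105)
  dat <- generate_scenario(sc)
  truth <- dat$alpha
  cv <- dat$covariates["cc"]
  fs <- fit_alpha_gam(dat$Y, cv, smooth = TRUE)
  fl <- fit_alpha_gam(dat$Y, cv, smooth = FALSE)
  expect_lt(sqrt(mean((fs$fitted_alpha - truth)^2)),
            sqrt(mean((fl$fitted_alpha - truth)^2)))
})

test_that("synthetic datasets round-trip through the I/O layer", {
  sc <- synthetic_scenario(grid_rows = 3, grid_cols = 3, T_len = 6,
                           landmark_counts = c(upc = 2), eta = 0.1,
                           kappa = 0.1, sigma = 0.2, sigma_eps = 0.3,
                           zeta = 0.7, seed = 106)
  dat <- generate_scenario(sc)
  td <- tempdir()
  fc <- file.path(td, "counts.csv"); fa <- file.path(td, "adj.csv")
  fv <- file.path(td, "cov.csv")
  write_counts_csv(dat$Y, fc)
  write_adjacency_csv(dat$lattice, fa)
  write_covariates_csv(dat$covariates, dat$lattice$site_ids, fv)
  Y2 <- read_counts_csv(fc, site_ids = dat$lattice$site_ids)
  expect_equal(unname(Y2), unname(dat$Y))
  lat2 <- read_adjacency_csv(fa, site_ids = dat$lattice$site_ids)
  expect_equal(lat2$N_raw, dat$lattice$N_raw)
  cov2 <- read_covariates_csv(fv, dat$lattice$site_ids, 6)
  expect_equal(cov2$upc$values, unname(dat$covariates$upc$values),
               tolerance = 1e-12)
  expect_equal(cov2$pob$values, unname(dat$covariates$pob$values),
               tolerance = 1e-12)
  unlink(c(fc, fa, fv))
})
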