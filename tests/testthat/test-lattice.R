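test_that("build_lattice validates input and caches scaled spectrum", {
  lat <- lattice_pair()
  expect_equal(lat$N_raw, matrix(c(0, 1, 1, 0), 2, 2,
                                 dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(lat$eigvals, c(-1, 1))

  expect_equal(lattice_path3()$eigvals, c(-1, 0, 1), tolerance = 1e-12)

  # 4-cycle (2x2 rook grid)
  cyc <- build_lattice(cbind(c("a", "b", "c", "d"), c("b", "c", "d", "a")),
                       letters[1:4])
  expect_equal(cyc$eigvals, c(-1, 0, 0, 1), tolerance = 1e-12)

  expect_error(build_lattice(cbind("a", "a"), c("a", "b")), "self-loop")
  expect_error(build_lattice(cbind("a", "z"), c("a", "b")), "not in site_ids")
  # duplicate edges are idempotent
  dup <- build_lattice(rbind(c("a", "b"), c("b", "a"), c("a", "b")), c("a", "b"))
  expect_equal(dup$N_raw, lattice_pair()$N_raw)
})

test_that("scaled eigenvalues sum to zero with max one on random lattices", {
  set.seed(11)
  for (i in 1:20) {
    lat <- random_lattice(sample(2:6, 1))
    expect_equal(sum(lat$eigvals), 0, tolerance = 1e-9)
    expect_equal(max(lat$eigvals), 1, tolerance = 1e-9)
  }
})

test_that("as_lattice symmetrizes with a warning and rejects bad matrices", {
  A <- matrix(0, 3, 3); A[1, 2] <- 1           # asymmetric
  expect_warning(lat <- as_lattice(A), "symmetriz")
  expect_equal(lat$N_raw[2, 1], 1)
  expect_error(as_lattice(diag(2)), "diagonal")
  expect_error(as_lattice(matrix(c(0, 2, 2, 0), 2, 2)), "0/1")
})

test_that("car_conditional_mean matches its closed form and edge cases", {
  lat <- lattice_pair()
  cs0 <- car_spec(0, 1)
  X <- c(3, -2)
  expect_equal(car_conditional_mean(X, c(1, 5), cs0, lat, 1), 1)
  cs <- car_spec(0.5, 1)
  expect_equal(car_conditional_mean(c(0.7, 0.7), c(0.7, 0.7), cs, lat, 2), 0.7)
  expect_equal(car_conditional_mean(c(1, 0), c(0, 0), cs, lat, 2), 0.5)
  expect_error(car_conditional_mean(X, c(0, 0), cs, lat, 3), "out of range")
})

test_that("car_conditional_mean is the stationary point of the joint density", {
  # gradient of the log joint CAR density w.r.t. X_i vanishes at the
  # conditional mean, holding the other sites fixed
  set.seed(21)
  for (rep in 1:5) {
    lat <- random_lattice(4)
    car <- random_car(lat)
    alpha <- rnorm(4); X <- rnorm(4)
    P <- (diag(4) - car$zeta * lat$N_scaled) / car$sigma2
    logd <- function(x, i) {
      Xi <- X; Xi[i] <- x
      -0.5 * drop(t(Xi - alpha) %*% P %*% (Xi - alpha))
    }
    for (i in 1:4) {
      mu <- car_conditional_mean(X, alpha, car, lat, i)
      g <- (logd(mu + 1e-6, i) - logd(mu - 1e-6, i)) / 2e-6
      expect_lt(abs(g), 1e-6)
    }
  }
})

test_that("log_det_car_precision matches dense determinants", {
  lat <- lattice_pair()
  expect_equal(log_det_car_precision(lat, car_spec(0.5, 1), 1), log(0.75))
  expect_equal(log_det_car_precision(lat, car_spec(0, 1), 1), 0)
  expect_equal(log_det_car_precision(lat, car_spec(0.5, 2), 3),
               3 * (-2 * log(2) + log(0.75)))
  expect_error(log_det_car_precision(lat, car_spec(1.5, 1), 1),
               "positive definite")
})

test_that("sample_car_field is seed-deterministic and honours the CAR", {
  lat <- lattice_path3()
  cs <- car_spec(0.5, 1.3)
  x1 <- sample_car_field(lat, c(0, 1, 2), cs, seed = 5)
  x2 <- sample_car_field(lat, c(0, 1, 2), cs, seed = 5)
  expect_identical(x1, x2)

  # zeta = 0: independent N(alpha, sigma2)
  cs0 <- car_spec(0, 1)
  X <- sample_car_field(lat, rep(0, 3), cs0, n_draws = 50000, seed = 6)
  v <- apply(X, 1, var)
  mc_se <- sqrt(2 / 50000)  # sd of a sample variance of N(0,1)
  expect_true(all(abs(v - 1) < 3 * mc_se))

  # positive neighbour correlation at strong dependence
  g <- generate_city_lattice(5, 5)
  cs9 <- car_spec(0.9, 1)
  Xg <- sample_car_field(g, rep(0, 25), cs9, n_draws = 20000, seed = 7)
  expect_gt(cor(Xg[1, ], Xg[2, ]), 0)   # adjacent in the grid
})

test_that("isolated sites behave as independent Gaussians", {
  lat <- build_lattice(cbind("a", "b"), c("a", "b", "c"))   # c isolated
  cs <- car_spec(0.8, 2)
  X <- sample_car_field(lat, rep(0, 3), cs, n_draws = 30000, seed = 8)
  expect_equal(var(X[3, ]), 2, tolerance = 0.1)
  expect_lt(abs(cor(X[3, ], X[1, ])), 0.05)
})
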