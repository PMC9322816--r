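test_that("bspline_basis is a non-negative partition of unity", {
  set.seed(30)
  for (k in c(4, 7, 10)) {
    x <- runif(200, -2, 5)
    b <- bspline_basis(x, num_basis = k, degree = 3)
    expect_equal(ncol(b$B), k)
    expect_true(all(b$B >= 0))
    expect_equal(rowSums(b$B), rep(1, 200), tolerance = 1e-12)
  }
  # degree 0, one interval: indicator of the whole range
  b0 <- bspline_basis(runif(50), num_basis = 1, degree = 0)
  expect_equal(as.vector(b0$B), rep(1, 50))
  expect_error(bspline_basis(runif(10), num_basis = 2, degree = 3), "num_basis")
  expect_error(bspline_basis(rep(1, 10), num_basis = 5), "constant")
})

test_that("cubic bases reproduce linear functions exactly", {
  set.seed(31)
  x <- runif(100)
  b <- bspline_basis(x, num_basis = 8, degree = 3)
  y <- 2 * x + 1
  beta <- qr.solve(b$B, y)
  expect_lt(max(abs(b$B %*% beta - y)), 1e-8)
})

test_that("tensor_row_kronecker flattens per-row outer products", {
  expect_equal(tensor_row_kronecker(matrix(1, 3, 1), matrix(1, 3, 1)),
               matrix(1, 3, 1))
  expect_equal(as.vector(tensor_row_kronecker(matrix(c(1, 2), 1),
                                              matrix(c(3, 4, 5), 1))),
               c(3, 4, 5, 6, 8, 10))
  set.seed(32)
  B1 <- matrix(rnorm(12), 4, 3); B2 <- matrix(rnorm(20), 4, 5)
  out <- tensor_row_kronecker(B1, B2)
  expect_equal(dim(out), c(4L, 15L))
  for (i in 1:4)
    expect_equal(out[i, ], as.vector(t(outer(B1[i, ], B2[i, ]))))
  expect_error(tensor_row_kronecker(B1, matrix(0, 5, 2)), "mismatch")
})

test_that("gcv_score implements n*rss/(n-edf)^2", {
  expect_equal(gcv_score(0, 50, 3), 0)
  expect_equal(gcv_score(50, 100, 0), 0.5)
  expect_gt(gcv_score(60, 100, 5), gcv_score(50, 100, 5))
  expect_error(gcv_score(1, 10, 10), "edf")
})

test_that("fit_alpha_gam recovers a noise-free log-linear signal", {
  set.seed(33)
  x <- matrix(runif(150, 0, 2), 15, 10)
  resp <- exp(0.5 + 0.7 * x)
  fit <- fit_alpha_gam(resp, list(covariate_panel("d", x)))
  expect_lt(max(abs(fit$fitted_alpha - (0.5 + 0.7 * x))), 1e-3)
  # prediction on training covariates reproduces the fit
  expect_equal(predict_alpha(fit, list(covariate_panel("d", x))),
               fit$fitted_alpha, tolerance = 1e-10)
})

test_that("spline smooths beat straight lines on a sinusoidal effect", {
  set.seed(34)
  x <- matrix(runif(400, 0, 6), 20, 20)
  truth <- 0.3 + sin(x)
  y <- matrix(rpois(400, exp(truth)), 20, 20)
  cv <- list(covariate_panel("d", x))
  fs <- fit_alpha_gam(y, cv, smooth = TRUE)
  fl <- fit_alpha_gam(y, cv, smooth = FALSE)
  expect_lt(sqrt(mean((fs$fitted_alpha - truth)^2)),
            sqrt(mean((fl$fitted_alpha - truth)^2)))
})

test_that("a pure-noise covariate is shrunk by GCV", {
  set.seed(35)
  y <- matrix(rpois(150, 3), 15, 10)
  fit <- fit_alpha_gam(y, list(covariate_panel("noise",
                                               matrix(runif(150), 15, 10))))
  expect_lte(fit$terms$noise$edf, 2)
})

test_that("GCV selection never exceeds the best grid candidate", {
  set.seed(36)
  x <- matrix(runif(200, 0, 4), 10, 20)
  y <- matrix(rpois(200, exp(0.2 + 0.3 * sin(x))), 10, 20)
  grid <- 10^seq(-2, 4, length.out = 7)
  fit <- fit_alpha_gam(y, list(covariate_panel("d", x)), lambda_grid = grid)
  # refit at each grid value with a single fixed lambda and compare
  single <- vapply(grid, function(lv)
    fit_alpha_gam(y, list(covariate_panel("d", x)), lambda_grid = lv)$gcv,
    numeric(1))
  expect_lte(fit$gcv, min(single) + 1e-8)
})

test_that("fitting is invariant to affine covariate rescaling", {
  set.seed(37)
  x <- matrix(runif(200, 0, 4), 10, 20)
  y <- matrix(rpois(200, exp(0.4 + 0.5 * cos(x))), 10, 20)
  f1 <- fit_alpha_gam(y, list(covariate_panel("d", x)))
  f2 <- fit_alpha_gam(y, list(covariate_panel("d", 10 * x + 3)))
  expect_lt(max(abs(f1$fitted_alpha - f2$fitted_alpha)), 1e-6)
})

test_that("predict_alpha clamps out-of-range covariates with a warning", {
  set.seed(38)
  x <- matrix(runif(100, 0, 1), 10, 10)
  fit <- fit_alpha_gam(exp(0.5 + x), list(covariate_panel("d", x)))
  expect_warning(pa <- predict_alpha(fit, list(covariate_panel("d",
                   matrix(2, 10, 10)))), "clamp")
  expect_true(all(is.finite(pa)))
  expect_error(predict_alpha(fit, list(covariate_panel("other", x))),
               "missing covariate")
})

test_that("term selection drops a pure-noise covariate", {
  set.seed(39)
  x <- matrix(runif(600, 0, 3), 20, 30)
  y <- matrix(rpois(600, exp(0.3 + 0.8 * x)), 20, 30)
  covs <- list(covariate_panel("sig", x),
               covariate_panel("jnk", matrix(runif(600), 20, 30)))
  fit <- fit_alpha_gam(y, covs, select = TRUE, select_threshold = 0.05)
  expect_true("sig" %in% names(fit$terms))
  expect_false("jnk" %in% names(fit$terms))
})

test_that("spatial and temporal covariates broadcast", {
  set.seed(40)
  sp <- covariate_panel("pob", matrix(runif(6), 6, 1))
  tm <- covariate_panel("month", matrix(runif(8), 1, 8))
  expect_equal(sp$kind, "spatial")
  expect_equal(tm$kind, "temporal")
  y <- matrix(rpois(48, 2), 6, 8)
  fit <- fit_alpha_gam(y, list(sp, tm), num_basis = 4)
  expect_equal(dim(fit$fitted_alpha), c(6L, 8L))
})
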