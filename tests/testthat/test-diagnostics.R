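test_that("split_rhat distinguishes mixed from separated chains", {
  set.seed(80)
  x <- rnorm(4000)
  same <- list(x[1:1000], x[1001:2000], x[2001:3000], x[3001:4000])
  expect_lt(abs(split_rhat(same) - 1), 0.01)
  apart <- list(rnorm(500, 0), rnorm(500, 10))
  expect_gt(split_rhat(apart), 1.5)
  # monotone in mean separation
  rh <- vapply(c(0, 1, 3), function(d)
    split_rhat(list(rnorm(500, 0), rnorm(500, d))), numeric(1))
  expect_true(all(diff(rh) > 0))
  expect_error(split_rhat(list(rnorm(10))), "2 chains")
})

test_that("split_rhat matches a hand computation on 2 chains of 4", {
  ch <- list(c(1, 2, 3, 4), c(2, 4, 6, 8))
  # halves: (1,2) (3,4) (2,4) (6,8); within var = (0.5+0.5+2+2)/4 = 1.25
  # half means: 1.5 3.5 3 7 -> var = 5.729166...
  W <- 1.25
  Bn <- var(c(1.5, 3.5, 3, 7))
  vp <- (2 - 1) / 2 * W + Bn
  expect_equal(split_rhat(ch), sqrt(vp / W), tolerance = 1e-10)
})

test_that("effective_sample_size behaves on iid, AR(1), antithetic inputs", {
  set.seed(81)
  iid <- lapply(1:4, function(i) rnorm(1000))
  expect_lt(abs(as.numeric(effective_sample_size(iid)) - 4000) / 4000, 0.2)
  ar <- lapply(1:4, function(i) as.numeric(arima.sim(list(ar = 0.9), 5000)))
  tgt <- 20000 * (1 - 0.9) / (1 + 0.9)
  expect_lt(abs(as.numeric(effective_sample_size(ar)) - tgt) / tgt, 0.25)
  alt <- matrix(rep(c(1, -1), 500), ncol = 2)
  ea <- effective_sample_size(alt)
  expect_equal(as.numeric(ea), 1000)
  expect_equal(attr(ea, "flag"), "capped")
  cst <- matrix(1, 100, 2)
  ec <- effective_sample_size(cst)
  expect_equal(attr(ec, "flag"), "constant")
})

test_that("shannon_entropy_sqrt_bins follows the sqrt-bins rule", {
  # 1024 points, 32 bins, 32 per bin -> ln 32
  x <- as.vector(vapply(1:32, function(b) b + (0:31) / 33, numeric(32)))
  expect_equal(shannon_entropy_sqrt_bins(x), log(32), tolerance = 1e-10)
  expect_equal(shannon_entropy_sqrt_bins(rep(3, 100)), 0)
  # two far point masses, n = 4 -> 2 bins equally occupied -> ln 2
  expect_equal(shannon_entropy_sqrt_bins(c(0, 0, 10, 10)), log(2))
  # affine invariance and the ln(bins) bound
  set.seed(82)
  y <- rnorm(900)
  expect_equal(shannon_entropy_sqrt_bins(y),
               shannon_entropy_sqrt_bins(5 * y - 2), tolerance = 1e-12)
  expect_lte(shannon_entropy_sqrt_bins(y), log(30))
})

test_that("posterior_acf normalizes and flags degenerate input", {
  set.seed(83)
  a <- posterior_acf(rnorm(10000), 20)
  expect_equal(a[1], 1)
  expect_gt(mean(abs(a[-1]) < 3 / sqrt(10000)), 0.95)
  ar <- posterior_acf(as.numeric(arima.sim(list(ar = 0.8), 10000)), 5)
  expect_equal(ar[2], 0.8, tolerance = 0.05)
  cst <- posterior_acf(rep(2, 100), 5)
  expect_equal(as.numeric(cst), c(1, rep(0, 5)))
  expect_equal(attr(cst, "flag"), "constant")
})

test_that("posterior_summary has the reference table layout", {
  set.seed(84)
  m <- cbind(eta = rnorm(800, 0.3, 0.02), kappa = rnorm(800, 0.1, 0.01))
  sm <- posterior_summary(m, chain_id = rep(1:2, each = 400))
  expect_equal(names(sm), c("param", "Mean", "Sd", "2.5%", "25.0%", "50.0%",
                            "75.0%", "97.5%", "n_eff", "Rhat", "H"))
  expect_true(all(sm$`2.5%` <= sm$`25.0%` & sm$`25.0%` <= sm$`50.0%` &
                  sm$`50.0%` <= sm$`75.0%` & sm$`75.0%` <= sm$`97.5%`))
  expect_true(all(sm$n_eff <= 800))
  # linear-interpolation quantiles: median of 1..100 is 50.5
  sq <- posterior_summary(cbind(x = 1:100), chain_id = rep(1, 100))
  expect_equal(sq$`50.0%`, 50.5)
  # constant draws
  sc <- posterior_summary(cbind(c = rep(2, 100)), chain_id = rep(1, 100))
  expect_equal(sc$Sd, 0)
  expect_equal(sc$H, 0)
  expect_equal(sc$`2.5%`, 2)
})

test_that("summary matches a conjugate-normal toy posterior", {
  # y ~ N(mu, 1), mu ~ N(0, 10^2): posterior is available in closed form;
  # iid draws from it summarize correctly
  set.seed(85)
  y <- rnorm(50, 2, 1)
  post_prec <- 50 + 1 / 100
  post_mean <- sum(y) / post_prec
  draws <- rnorm(20000, post_mean, sqrt(1 / post_prec))
  sm <- posterior_summary(cbind(mu = draws), chain_id = rep(1:4, each = 5000))
  expect_equal(sm$Mean, post_mean, tolerance = 0.01)
  expect_equal(sm$Sd, sqrt(1 / post_prec), tolerance = 0.01)
})
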