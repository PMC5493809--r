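test_that("acceptance probability follows the symmetric-kernel ratio", {
  expect_equal(mh_accept_prob(-3, -1, -3, -1), 1)
  expect_equal(mh_accept_prob(-3 - log(2), -1, -3, -1), 0.5)
  expect_equal(mh_accept_prob(5, 0, -10, 0), 1)
  expect_equal(mh_accept_prob(-1e10, -Inf, -1e10, -Inf), 0)
})

test_that("sampler configuration validates its invariants", {
  expect_error(bden_control(n_samples = 10, n_burnin = 20), "n_samples")
  expect_error(bden_control(thin = 0), "thin")
  expect_error(bden_control(kernel_sd = -1), "kernel_sd")
  ctrl <- bden_control(n_samples = 100, n_burnin = 40, thin = 3)
  expect_s3_class(ctrl, "bden_control")
})

test_that("a degenerate kernel leaves the state untouched with full acceptance", {
  m <- toy_chain2()
  d <- simulate_dataset(m, noise_level = 0.025, seed = 2)
  w <- matrix(0.1, 2, length(d$grid))
  h <- en_hyper(2, length(d$grid))
  out <- bden_sweep(m, d, w, h, bden_control(n_samples = 10, n_burnin = 1,
                                             kernel_sd = 0, seed = 4,
                                             sample_hyper = FALSE))
  expect_equal(out$w, w)
  expect_true(all(out$acceptance == out$proposals))
})

test_that("fits are deterministic under a fixed seed and have the right shape", {
  m <- toy_decay(grid = seq(0, 4, by = 1))
  d <- simulate_dataset(m, noise_level = 0.05, seed = 3)
  ctrl <- bden_control(n_samples = 120, n_burnin = 40, thin = 4, seed = 11)
  f1 <- bden(m, d, ctrl)
  f2 <- bden(m, d, ctrl)
  expect_identical(f1$w_draws, f2$w_draws)
  expect_identical(f1$lambda2_draws, f2$lambda2_draws)
  expect_equal(dim(f1$w_draws), c((120 - 40) / 4, 1, 5))
  expect_true(all(f1$acceptance_rate >= 0 & f1$acceptance_rate <= 1))
  expect_length(f1$log_posterior_trace, 120)
})

test_that("posterior summaries are pointwise means and equal-tailed intervals", {
  g <- c(0, 1, 2)
  f <- fake_fit(matrix(c(1, 2, 3), 1, 3), g, spread = 0)
  sm <- summarize_posterior(f)
  expect_equal(sm$w_mean[1, ], c(1, 2, 3))
  expect_equal(sm$w_lower, sm$w_upper)

  set.seed(10)
  S <- 10000
  fz <- fake_fit(matrix(0, 1, 3), g, spread = 0, S = S)
  fz$w_draws[, 1, ] <- rnorm(S * 3)
  smz <- summarize_posterior(fz, credible_level = 0.95)
  expect_equal(unname(smz$w_lower[1]), -1.96, tolerance = 0.05)
  expect_equal(unname(smz$w_upper[1]), 1.96, tolerance = 0.05)

  f1 <- fake_fit(matrix(0, 1, 3), g, S = 1L)
  expect_error(summarize_posterior(f1), "at least 2")
})

test_that("the fitted object exposes the standard modelling methods", {
  m <- toy_chain2()
  d <- simulate_dataset(m, noise_level = 0.05, seed = 6)
  fit <- bden(m, d, bden_control(n_samples = 150, n_burnin = 50, thin = 5,
                                 seed = 2))
  expect_s3_class(fit, "bden")
  expect_equal(dim(coef(fit)), c(2L, 7L))
  expect_equal(dim(fitted(fit)), c(2L, 7L))
  expect_equal(dim(residuals(fit)), dim(d$values))
  ph <- predict(fit, type = "hidden", level = 0.9)
  expect_equal(dim(ph), c(2L, 7L))
  expect_true(all(attr(ph, "lower") <= attr(ph, "upper")))
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "bden_data")
  expect_output(print(fit), "elastic-net fit")
  expect_output(print(summary(fit)), "Influence scores")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("hidden influences are recruited only when the data demand them", {
  ## same nominal model fitted to (a) its own data and (b) data carrying a
  ## genuine exogenous input: the input node's recovered influence dominates
  m <- toy_decay(k = 0.8, eta = 1, grid = seq(0, 6, by = 0.75))
  g <- m$default_grid
  ctrl <- bden_control(n_samples = 500, n_burnin = 200, thin = 3, seed = 14)
  d0 <- simulate_dataset(m, noise_level = 0.025, seed = 21)
  a0 <- influence_score(coef(bden(m, d0, ctrl))[1, ], g)
  w_in <- function(t) 1.5 * t * exp(-t)
  d1 <- simulate_dataset(m, w_true = function(t) w_in(t),
                         noise_level = 0.025, seed = 22)
  a1 <- influence_score(coef(bden(m, d1, ctrl))[1, ], g)
  expect_lt(a0, 0.1 * a1)
})

test_that("single sweeps from bden_sweep are reproducible and consistent", {
  m <- toy_chain2()
  d <- simulate_dataset(m, noise_level = 0.05, seed = 2)
  w <- matrix(0, 2, 7)
  h <- en_hyper(2, 7, sigma2 = 0.01)
  ctrl <- bden_control(n_samples = 10, n_burnin = 1, kernel_sd = 0.05, seed = 8)
  s1 <- bden_sweep(m, d, w, h, ctrl)
  s2 <- bden_sweep(m, d, w, h, ctrl)
  expect_identical(s1$w, s2$w)
  expect_identical(s1$hyper, s2$hyper)
  expect_equal(dim(s1$acceptance), c(2L, 7L))
  expect_true(all(colSums(s1$proposals) == 2))
})
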