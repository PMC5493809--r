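test_that("noise-marginalized point likelihood matches quadrature and known values", {
  # t2 density at 0 with unit inverse-gamma prior: 1/(2 sqrt(2))
  expect_equal(marginal_loglik_point(0, noise_prior(1, 1)),
               log(1 / (2 * sqrt(2))), tolerance = 1e-12)
  expect_equal(marginal_loglik_point(0, noise_prior(1, 1)),
               quad_marginal_loglik(0, 1, 1), tolerance = 1e-9)

  for (r in c(0.3, 1.7, 4)) {
    pr <- noise_prior(2.5, 0.7)
    expect_equal(marginal_loglik_point(r, pr), marginal_loglik_point(-r, pr))
    expect_equal(marginal_loglik_point(r, pr), quad_marginal_loglik(r, 2.5, 0.7),
                 tolerance = 1e-8)
  }
})

test_that("a concentrated inverse-gamma prior recovers the plain Gaussian", {
  ## as the shape grows with scale = shape * v, the prior concentrates at
  ## variance v and the marginal converges to N(0, v); the worst probe point
  ## (r = 1, two prior-sd out) still has a ~0.017 gap at shape 50, so the
  ## convergence is asserted at two shapes
  v <- 0.25
  gap <- function(a) max(abs(marginal_loglik_point(c(0, 0.5, 1), noise_prior(a, a * v)) -
                               dnorm(c(0, 0.5, 1), 0, sqrt(v), log = TRUE)))
  expect_lt(gap(50), 2e-2)
  expect_lt(gap(200), 5e-3)
  expect_lt(gap(200), gap(50))
})

test_that("point likelihood is a proper density, unimodal at zero", {
  pr <- noise_prior(1.5, 0.4)
  total <- integrate(function(r) exp(marginal_loglik_point(r, pr)),
                     -Inf, Inf, rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-6)
  rs <- seq(0, 6, by = 0.25)
  ll <- marginal_loglik_point(rs, pr)
  expect_true(all(diff(ll) < 0))
  expect_error(noise_prior(-1, 1), "shape")
  expect_error(noise_prior(1, 0), "scale")
})

test_that("data log-likelihood factorizes and decreases when data are perturbed", {
  m <- toy_chain2()
  g <- m$default_grid
  y <- observe(m, integrate_model(m, g))
  pr <- noise_prior(2, 0.1)
  d <- measurement_set(y, g, prior = pr)
  w0 <- hidden_influence(matrix(0, 2, length(g)), g)
  ll0 <- data_loglik(m, w0, d)
  expect_equal(ll0, length(y) * marginal_loglik_point(0, pr), tolerance = 1e-8)

  y2 <- y; y2[1, 3] <- y2[1, 3] + 0.5
  expect_lt(data_loglik(m, w0, measurement_set(y2, g, prior = pr)), ll0)

  # permuting observable rows leaves the total unchanged (pure factorization)
  d_perm <- measurement_set(y[c(2, 1), ], g, prior = pr)
  m_perm <- ode_model(m$vector_field,
                      measurement_map = function(x, u, t, p) x[c(2, 1)],
                      initial_state = unname(m$initial_state),
                      kinetic_params = m$kinetic_params, default_grid = g)
  expect_equal(data_loglik(m_perm, w0, d_perm), ll0)
})

test_that("data log-likelihood matches an independent brute-force oracle", {
  m <- toy_chain2(a = 0.8, b = 0.4)
  g <- m$default_grid
  set.seed(12)
  w <- matrix(rnorm(2 * length(g), 0, 0.2), 2)
  y <- observe(m, integrate_model(m, g)) +
    matrix(rnorm(2 * length(g), 0, 0.1), 2)
  d <- measurement_set(y, g, prior = noise_prior(1, 1))
  got <- data_loglik(m, hidden_influence(w, g), d)

  # oracle: independent solver + spline + quadrature point likelihoods
  sfs <- lapply(1:2, function(i) splinefun(g, w[i, ], method = "natural"))
  ref <- deSolve::lsoda(y = c(1, 0), times = g, func = function(t, x, parms)
    list(c(-0.8 * x[1] + sfs[[1]](t), 0.8 * x[1] - 0.4 * x[2] + sfs[[2]](t))),
    rtol = 1e-10, atol = 1e-12)
  res <- y - t(unname(ref[, -1]))
  want <- sum(vapply(as.vector(res), quad_marginal_loglik, numeric(1), a = 1, b = 1))
  expect_equal(got, want, tolerance = 1e-4)
})

test_that("failed integration hits the likelihood floor instead of crashing", {
  m <- ode_model(function(x, u, t, p) x^2, initial_state = 2,
                 default_grid = c(0, 1, 2), name = "blowup")
  d <- measurement_set(matrix(1, 1, 3), c(0, 1, 2), prior = noise_prior(1, 1))
  expect_equal(suppressWarnings(data_loglik(m, NULL, d)), -1e10)
})

test_that("noise-prior estimation moment-matches replicates and falls back sanely", {
  set.seed(5)
  K <- 2; Tn <- 50; R <- 50
  truth <- array(rep(1, R * K * Tn), c(R, K, Tn))
  reps <- truth + array(rnorm(R * K * Tn, 0, 0.2), c(R, K, Tn))
  pr <- estimate_noise_prior(reps)
  prior_mean_var <- pr$scale / (pr$shape - 1)
  expect_true(all(abs(prior_mean_var - 0.04) / 0.04 < 0.15))

  # single replicate and degenerate replicates: default scale-aware prior
  one <- reps[1, , , drop = FALSE]
  p1 <- estimate_noise_prior(one)
  expect_equal(p1$shape, rep(5, K))
  same <- array(rep(as.vector(reps[1, , ]), each = 4), c(4, K, Tn))
  for (r in 1:4) same[r, , ] <- reps[1, , ]
  p2 <- estimate_noise_prior(same)
  expect_equal(p2$shape, rep(5, K))
})

test_that("measurement sets validate their inputs", {
  g <- c(0, 1, 2, 3)
  expect_error(measurement_set(matrix(1, 1, 3), g), "mismatch")
  expect_error(measurement_set(matrix(c(1, NA, 1, 1), 1, 4), g), "finite")
  d <- measurement_set(data.frame(time = g, a = 1:4, b = 4:1))
  expect_equal(nrow(d$values), 2)
  expect_equal(d$grid, g)
})
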