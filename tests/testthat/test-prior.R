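test_that("conditional increment prior is Gaussian with the stated variance", {
  set.seed(1)
  h <- en_hyper(3, 4, lambda1 = c(1, 2, 3), lambda2 = 2, sigma2 = 0.5,
                latent_scales = matrix(runif(12, 1.2, 5), 3, 4))
  wp <- c(0.1, -0.2, 0.05)
  # mode at the predecessor
  expect_gt(log_prior_increment(wp, wp, h, l = 2),
            log_prior_increment(wp + 0.1, wp, h, l = 2))
  # doubling lambda2 halves every conditional variance: + (N/2) log 2 at mode
  h2 <- h; h2$lambda2 <- 2 * h$lambda2
  expect_equal(log_prior_increment(wp, wp, h2, l = 2) -
                 log_prior_increment(wp, wp, h, l = 2),
               3 / 2 * log(2), tolerance = 1e-12)
  # N = 1: matches a direct Gaussian computation at probe points
  h1 <- en_hyper(1, 2, lambda1 = 1.5, lambda2 = 1.2, sigma2 = 0.8,
                 latent_scales = matrix(c(3, 2), 1, 2))
  v <- 0.8 * (2 - 1) / (1.2 * 2)
  for (x in c(-1, -0.2, 0, 0.4, 2))
    expect_equal(log_prior_increment(x, 0.1, h1, l = 2),
                 dnorm(x, 0.1, sqrt(v), log = TRUE), tolerance = 1e-12)
  # proper density
  total <- integrate(function(x) vapply(x, function(xi)
    exp(log_prior_increment(xi, 0.1, h1, l = 2)), numeric(1)),
    -Inf, Inf, rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-6)
  expect_error(en_hyper(2, 3, lambda2 = -1), "invalid")
})

test_that("marginalizing the latent scale yields the elastic-net density", {
  l1 <- 1.3; l2 <- 0.8; s2 <- 0.6
  cc <- l1^2 / (8 * s2 * l2)
  # quadrature of N(d; 0, s2 (tau-1)/(l2 tau)) against the truncated-gamma
  # prior on tau, compared with the closed-form marginal
  znorm <- integrate(function(s) s^(-0.5) * exp(-cc * s), 1, Inf,
                     rel.tol = 1e-12)$value
  marg <- function(d) integrate(function(s) {
    v <- s2 * (s - 1) / (l2 * s)
    dnorm(d, 0, sqrt(v)) * s^(-0.5) * exp(-cc * s) / znorm
  }, 1, Inf, rel.tol = 1e-11)$value
  for (d in c(0.05, 0.3, 1, 2.5))
    expect_equal(log(marg(d)),
                 en_marginal_logprior(d, l1, l2, s2, normalized = TRUE),
                 tolerance = 1e-6)
  # normalized marginal integrates to one
  total <- integrate(function(d) exp(en_marginal_logprior(d, l1, l2, s2,
                                                          normalized = TRUE)),
                     -Inf, Inf, rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-6)
})

test_that("latent-scale conditional sampler matches its density by quadrature", {
  dw <- 0.6; l1 <- 1.1; l2 <- 0.9; s2 <- 0.5
  cc <- l1^2 / (8 * s2 * l2)
  a <- dw^2 * l2 / (2 * s2)
  set.seed(42)
  draws <- bden:::draw_scale_conditional(rep(dw, 5000), rep(cc, 5000), l2, s2)
  # density of s = tau - 1 is GIG(1/2): s^{-1/2} exp(-a/s - c s)
  dens <- function(s) s^(-0.5) * exp(-a / s - cc * s)
  zz <- integrate(dens, 0, Inf, rel.tol = 1e-11)$value
  cdf <- Vectorize(function(q) integrate(dens, 0, q, rel.tol = 1e-9)$value / zz)
  ks <- ks.test(draws - 1, cdf)
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("a Gibbs sweep leaves the joint prior invariant (1 node, 2 times)", {
  set.seed(2024)
  n <- 5000
  gam <- 0.7; a2 <- 2; b2 <- 2; as_ <- 3; bs_ <- 2
  l2_before <- numeric(n); l2_after <- numeric(n)
  l1_before <- numeric(n); l1_after <- numeric(n)
  for (k in seq_len(n)) {
    l1 <- rexp(1, gam); l2 <- rgamma(1, a2, b2); s2 <- 1 / rgamma(1, as_, bs_)
    cc <- l1^2 / (8 * s2 * l2)
    tau <- bden:::rtrunc_gamma_tau(2, cc)
    v <- s2 * (tau - 1) / (l2 * tau)
    w1 <- rnorm(1, 0, sqrt(v[1])); w2 <- rnorm(1, w1, sqrt(v[2]))
    h <- en_hyper(1, 2, lambda1 = l1, lambda2 = l2, sigma2 = s2,
                  latent_scales = matrix(tau, 1, 2), hyper_rates = gam,
                  a2 = a2, b2 = b2, a_sigma = as_, b_sigma = bs_)
    h2 <- gibbs_update(h, matrix(c(w1, w2), 1, 2), update_sigma2 = TRUE)
    l2_before[k] <- l2; l2_after[k] <- h2$lambda2
    l1_before[k] <- l1; l1_after[k] <- h2$lambda1
  }
  expect_lt(unname(ks.test(l2_before, l2_after)$statistic), 0.05)
  expect_lt(unname(ks.test(l1_before, l1_after)$statistic), 0.05)
})

test_that("sparsity parameters grow when the signal vanishes", {
  set.seed(31)
  Tn <- 8
  w_zero <- matrix(0, 1, Tn)
  w_big <- matrix(cumsum(rnorm(Tn, 0, 0.8)), 1, Tn)
  mean_l1 <- function(w, seed) {
    set.seed(seed)
    h <- en_hyper(1, Tn, hyper_rates = 0.5)
    acc <- 0
    for (s in 1:2000) { h <- gibbs_update(h, w); acc <- acc + h$lambda1 }
    acc / 2000
  }
  expect_gt(mean_l1(w_zero, 7), mean_l1(w_big, 7))
})

test_that("gibbs updates are deterministic under a fixed seed", {
  h <- en_hyper(2, 3)
  w <- matrix(c(0.1, -0.2, 0.3, 0, 0.05, 0.2), 2, 3)
  set.seed(5); h1 <- gibbs_update(h, w)
  set.seed(5); h2 <- gibbs_update(h, w)
  expect_identical(h1, h2)
})

test_that("prior-predictive paths behave like a shrunken random walk", {
  set.seed(8)
  # enormous smoothness penalty: paths pinned near zero
  h <- en_hyper(1, 10, lambda1 = 1, lambda2 = 1e6, sigma2 = 1)
  mx <- replicate(100, max(abs(sample_prior_path(h, 10))))
  expect_gte(mean(mx < 1e-2), 0.99)

  # T = 1: a single Gaussian draw centred at zero
  h1 <- en_hyper(1, 1, lambda1 = 1, lambda2 = 1, sigma2 = 1)
  d1 <- replicate(2000, sample_prior_path(h1, 1)[1, 1])
  expect_lt(abs(mean(d1)), 0.05)

  # positive lag-1 autocorrelation (random-walk-like)
  h50 <- en_hyper(1, 50, lambda1 = 1, lambda2 = 1, sigma2 = 1)
  ac1 <- replicate(200, {
    p <- sample_prior_path(h50, 50)[1, ]
    cor(p[-1], p[-50])
  })
  expect_gt(median(ac1), 0.5)
})

test_that("larger sparsity rates stochastically shrink prior paths", {
  set.seed(9)
  maxw <- function(rate) replicate(200, {
    l1 <- rexp(1, rate)
    h <- en_hyper(1, 12, lambda1 = l1, lambda2 = 1, sigma2 = 1,
                  hyper_rates = rate)
    max(abs(sample_prior_path(h, 12)))
  })
  big_l1 <- maxw(0.1)   # rate 0.1: lambda1 around 10, strong shrinkage
  small_l1 <- maxw(10)  # rate 10: lambda1 around 0.1, weak shrinkage
  wt <- wilcox.test(big_l1, small_l1, alternative = "less")
  expect_lt(wt$p.value, 0.01)
})

test_that("hyper-parameter state survives a JSON round trip", {
  set.seed(3)
  h <- en_hyper(2, 4, lambda1 = c(0.5, 2), lambda2 = 1.7, sigma2 = 0.3,
                latent_scales = matrix(runif(8, 1.5, 4), 2, 4),
                hyper_rates = c(0.2, 0.4))
  h2 <- hyper_from_json(hyper_to_json(h))
  expect_equal(h2$lambda1, h$lambda1)
  expect_equal(h2$latent_scales, h$latent_scales, tolerance = 1e-12)
  expect_equal(h2$sigma2, h$sigma2)
})
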