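test_that("cubic spline interpolation honours its contracts", {
  g <- seq(0, 4, by = 0.5)

  f0 <- fit_spline(rep(0, length(g)), g)
  expect_equal(f0(seq(0, 4, length.out = 37)), rep(0, 37))

  fid <- fit_spline(g, g)  # linear data reproduced exactly
  tt <- seq(0, 4, length.out = 23)
  expect_equal(fid(tt), tt, tolerance = 1e-12)

  gk <- seq(0, pi, length.out = 11)
  fs <- fit_spline(sin(gk), gk)
  toff <- seq(0.01, pi - 0.01, length.out = 50)
  expect_lt(max(abs(fs(toff) - sin(toff))), 1e-3)

  expect_error(fit_spline(c(1, 2, 3), c(0, 2, 1)), "increasing")
  expect_error(fit_spline(c(1, NaN, 3), c(0, 1, 2)), "finite|NaN")
  expect_error(fit_spline(c(1, 2), c(0, 1)), "3 points")
})

test_that("spline is held constant left of the first knot", {
  g <- c(1, 2, 3, 4)
  f <- fit_spline(c(5, 1, 2, 0), g)
  expect_equal(f(c(-1, 0, 0.99)), rep(5, 3))
})

test_that("integration matches closed forms on linear toys", {
  m <- toy_decay(k = 1, eta = 1, grid = c(0, 0.5, 1))
  tr <- integrate_model(m, c(0, 1))
  expect_equal(tr$states[1, 2], exp(-1), tolerance = 1e-5)  # solver rtol 1e-6

  # forced system dx = -x + 1 from 0: x(t) = 1 - exp(-t)
  m0 <- toy_decay(k = 1, eta = 0, grid = c(0, 0.5, 1, 2))
  w1 <- hidden_influence(matrix(1, 1, 4), c(0, 0.5, 1, 2))
  tr1 <- integrate_model(m0, c(0, 0.5, 1, 2), w = w1)
  expect_equal(tr1$states[1, ], 1 - exp(-c(0, 0.5, 1, 2)), tolerance = 1e-6)
})

test_that("packaged model integration matches an independent high-accuracy solve", {
  m <- build_model("jak-stat")
  g <- m$default_grid
  tr <- integrate_model(m, g)
  f <- m$vector_field; uf <- m$known_input; p <- m$kinetic_params
  ref <- deSolve::lsoda(y = unname(m$initial_state), times = g,
                        func = function(t, x, parms) list(f(x, uf(t), t, p)),
                        rtol = 1e-10, atol = 1e-12)
  ref <- t(unname(ref[, -1]))
  expect_lt(max(abs(tr$states - ref)) / max(abs(ref)), 1e-6)
})

test_that("zero hidden influence reproduces the nominal trajectory exactly", {
  m <- toy_chain2()
  g <- m$default_grid
  w0 <- hidden_influence(matrix(0, 2, length(g)), g)
  expect_identical(integrate_model(m, g, w = w0)$states,
                   integrate_model(m, g)$states)
})

test_that("superposition holds for a linear system", {
  A <- matrix(c(-1, 0.5, 0, -0.3), 2, 2)
  g <- seq(0, 5, by = 0.5)
  m <- toy_linear(A, c(1, 0), g)
  set.seed(4)
  w1 <- matrix(rnorm(2 * length(g), 0, 0.3), 2)
  w2 <- matrix(rnorm(2 * length(g), 0, 0.3), 2)
  hi <- function(w) integrate_model(m, g, w = hidden_influence(w, g),
                                    rtol = 1e-10, atol = 1e-12)$states
  x0 <- integrate_model(m, g, rtol = 1e-10, atol = 1e-12)$states
  xab <- hi(w1 + w2)
  expect_equal(xab, hi(w1) + hi(w2) - x0, tolerance = 1e-6)
})

test_that("chained segment integration reproduces the whole interval", {
  m <- build_model("motif-cascade")
  g <- m$default_grid
  set.seed(7)
  w <- hidden_influence(matrix(rnorm(3 * length(g), 0, 0.1), 3), g)
  whole <- integrate_model(m, g, w = w)$states
  x <- unname(m$initial_state)
  seg <- matrix(NA_real_, 3, length(g)); seg[, 1] <- x
  for (l in 2:length(g)) {
    x <- integrate_model(m, g[(l - 1):l], w = w, init = x)$states[, 2]
    seg[, l] <- x
  }
  expect_lt(max(abs(seg - whole)) / max(abs(whole)), 1e-5)
})

test_that("observe applies the measurement map columnwise", {
  m <- toy_chain2()
  g <- m$default_grid
  tr <- integrate_model(m, g)
  expect_equal(unname(observe(m, tr)), tr$states)  # identity default

  msum <- ode_model(function(x, u, t, p) c(-x[1], x[1] - x[2]),
                    measurement_map = function(x, u, t, p) x[1] + x[2],
                    initial_state = c(1, 0), default_grid = g)
  y <- observe(msum, tr)
  expect_equal(dim(y), c(1L, length(g)))
  expect_equal(unname(y[1, ]), colSums(tr$states))
})

test_that("integration failure raises a typed error carrying the interval", {
  m <- ode_model(function(x, u, t, p) x^2, initial_state = 2,
                 default_grid = c(0, 1, 2), name = "blowup")
  err <- tryCatch(suppressWarnings(integrate_model(m, c(0, 1, 2))),
                  error = identity)
  expect_s3_class(err, "bden_integration_error")
  expect_length(err$interval, 2)
})

test_that("trajectory/data-frame round trip keeps names and values", {
  m <- toy_chain2()
  tr <- integrate_model(m, m$default_grid)
  df <- as.data.frame(tr)
  expect_equal(names(df)[1], "time")
  expect_equal(nrow(df), length(m$default_grid))
})
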