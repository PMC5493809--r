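# Small models built in code for unit tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

# 1-state linear decay with identity observation: dx/dt = -k x + w
toy_decay <- function(k = 1, eta = 1, grid = seq(0, 5, by = 1), t0 = grid[1]) {
  ode_model(vector_field = function(x, u, t, p) -p[["k"]] * x,
            initial_state = eta, kinetic_params = c(k = k),
            t0 = t0, default_grid = grid, name = "toy-decay")
}

# 2-state linear chain: dx1 = -a x1 + w1; dx2 = a x1 - b x2 + w2
toy_chain2 <- function(a = 1, b = 0.5, eta = c(1, 0),
                       grid = seq(0, 6, by = 1)) {
  ode_model(vector_field = function(x, u, t, p)
              c(-p[["a"]] * x[1], p[["a"]] * x[1] - p[["b"]] * x[2]),
            initial_state = eta, kinetic_params = c(a = a, b = b),
            default_grid = grid, name = "toy-chain2")
}

# linear system dx/dt = A x + w (for superposition checks)
toy_linear <- function(A, eta, grid) {
  ode_model(vector_field = function(x, u, t, p) as.vector(A %*% x),
            initial_state = eta, default_grid = grid, name = "toy-linear")
}

# independent quadrature of the noise-marginalized point likelihood:
# log int N(r; 0, s) InvGamma(s; a, b) ds, integrated over the variance s
quad_marginal_loglik <- function(r, a, b) {
  f <- function(s) exp(stats::dnorm(r, 0, sqrt(s), log = TRUE) +
                         a * log(b) - lgamma(a) - (a + 1) * log(s) - b / s)
  log(stats::integrate(f, 0, Inf, rel.tol = 1e-12, abs.tol = 0)$value)
}

# deterministic fake ensemble for summary/diagnosis plumbing tests
fake_fit <- function(w_mean, grid, spread = 0, S = 50L, model = NULL) {
  N <- nrow(w_mean); Tn <- ncol(w_mean)
  if (is.null(model))
    model <- ode_model(function(x, u, t, p) rep(0, N), initial_state = rep(0, N),
                       default_grid = grid, name = "fake")
  w_draws <- array(rep(w_mean, each = S), c(S, N, Tn))
  if (spread > 0) {
    set.seed(99)
    w_draws <- w_draws + array(rnorm(S * N * Tn, 0, spread), c(S, N, Tn))
  }
  data <- measurement_set(matrix(1, model$n_obs, Tn), grid)
  structure(list(w_draws = w_draws, state_draws = w_draws,
                 lambda1_draws = matrix(1, S, N), lambda2_draws = rep(1, S),
                 sigma2_draws = rep(1, S),
                 acceptance_rate = matrix(0.3, N, Tn),
                 log_posterior_trace = numeric(S), kernel_sd = rep(0.1, N),
                 model = model, data = data,
                 control = bden_control(n_samples = 200, n_burnin = 100,
                                        thin = 2),
                 diagnostics = character(0)),
            class = "bden")
}
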