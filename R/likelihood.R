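#' Inverse-gamma prior on the measurement-noise variance
#'
#' Replicate measurements per time point are typically too few for a reliable
#' empirical variance, so each observable's noise variance carries an
#' inverse-gamma prior InvGamma(shape, scale) that is integrated out of the
#' likelihood analytically. \code{shape} and \code{scale} may be scalars or
#' length-\code{K} vectors (one pair per observable, constant over time; the
#' noise is assumed uncorrelated across observables and time points).
#'
#' @param shape alpha > 0.
#' @param scale beta > 0.
#' @return Object of class \code{bden_noise_prior}.
#' @export
noise_prior <- function(shape = 1, scale = 0.01) {
  if (any(!is.finite(shape)) || any(shape <= 0) ||
      any(!is.finite(scale)) || any(scale <= 0))
    stop("noise prior requires shape > 0 and scale > 0", call. = FALSE)
  structure(list(shape = shape, scale = scale), class = "bden_noise_prior")
}

## Default scale-aware noise prior per observable: the prior mode of the
## noise variance is (5% of the series mean)^2 with shape 5, i.e. the
## marginal likelihood is a Student-t with 10 degrees of freedom around a
## few-percent noise scale. A flatter prior (shape near 1) makes the
## marginal likelihood so heavy-tailed that systematic model error costs
## almost nothing and hidden influences are never recruited.
default_noise_prior <- function(values, rel_sd = 0.05, shape = 5) {
  m <- rowMeans(abs(values))
  noise_prior(shape = rep(shape, nrow(values)),
              scale = pmax((shape + 1) * (rel_sd * m)^2, 1e-10))
}

#' Marginal log-likelihood of a single residual
#'
#' The Gaussian measurement density with its variance integrated out under
#' InvGamma(alpha, beta) is a scaled Student-t with 2 alpha degrees of freedom:
#' \deqn{\log\left[\frac{\Gamma(\alpha + 1/2)}{\Gamma(\alpha)} (2\pi)^{-1/2}
#'   \beta^{\alpha} (\beta + r^2/2)^{-(\alpha + 1/2)}\right].}
#' Strictly decreasing in |r| and properly normalized over r.
#'
#' @param residual numeric vector of residuals \code{y - h(x)}.
#' @param prior a \code{bden_noise_prior} (scalar shape/scale here).
#' @return log-density values, vectorized over \code{residual}.
#' @export
marginal_loglik_point <- function(residual, prior) {
  if (!inherits(prior, "bden_noise_prior")) stop("prior must be a bden_noise_prior")
  a <- prior$shape; b <- prior$scale
  lgamma(a + 0.5) - lgamma(a) - 0.5 * log(2 * pi) + a * log(b) -
    (a + 0.5) * log(b + residual^2 / 2)
}

## Vectorized over a K x T residual matrix with per-observable (a, b).
marginal_loglik_matrix <- function(res, a, b) {
  K <- nrow(res)
  a <- rep_len(a, K); b <- rep_len(b, K)
  const <- lgamma(a + 0.5) - lgamma(a) - 0.5 * log(2 * pi) + a * log(b)
  sum(const) * ncol(res) - sum((a + 0.5) * rowSums(log(b + res^2 / 2)))
}

#' Measurement set
#'
#' A \code{K x T} matrix of observed values on a time grid, together with the
#' noise-variance prior. Optionally carries a replicate stack
#' (\code{R x K x T} array) from which the prior can be moment-matched.
#'
#' @param values \code{K x T} numeric matrix (rows = observables), or a
#'   data.frame whose first column is time (rows = time points).
#' @param grid time grid (ignored when \code{values} is a data.frame).
#' @param prior a \code{bden_noise_prior}, or \code{NULL} for the default
#'   scale-aware weakly informative prior.
#' @param replicates optional \code{R x K x T} array.
#' @param obs_names observable names.
#' @return Object of class \code{bden_data}.
#' @export
measurement_set <- function(values, grid = NULL, prior = NULL,
                            replicates = NULL, obs_names = NULL) {
  if (is.data.frame(values)) {
    grid <- values[[1L]]
    obs_names <- obs_names %||% names(values)[-1L]
    values <- t(as.matrix(values[, -1L, drop = FALSE]))
  }
  if (is.vector(values)) values <- matrix(values, nrow = 1L)
  check_grid(grid)
  if (ncol(values) != length(grid)) stop("values/grid dimension mismatch")
  if (anyNA(values) || any(!is.finite(values)))
    stop("measurements must be finite; missing values are not supported")
  if (!is.null(replicates)) {
    stopifnot(length(dim(replicates)) == 3L,
              dim(replicates)[2L] == nrow(values),
              dim(replicates)[3L] == length(grid))
    if (is.null(prior)) prior <- estimate_noise_prior(replicates)
  }
  if (is.null(prior)) prior <- default_noise_prior(values)
  rownames(values) <- obs_names %||% rownames(values) %||%
    paste0("y", seq_len(nrow(values)))
  structure(list(values = values, grid = grid, noise_prior = prior,
                 replicates = replicates),
            class = "bden_data")
}

#' @export
print.bden_data <- function(x, ...) {
  cat("Measurement set:", nrow(x$values), "observables at", length(x$grid),
      "time points\n")
  cat("  noise prior: InvGamma(shape = ",
      paste(signif(rep_len(x$noise_prior$shape, nrow(x$values)), 3), collapse = ", "),
      "; scale = ",
      paste(signif(rep_len(x$noise_prior$scale, nrow(x$values)), 3), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Moment-match a noise prior from replicate measurements
#'
#' With at least three replicates, the within-time-point variances are pooled
#' per observable and an inverse-gamma prior is fitted by moment matching
#' (matching the mean and variance of the empirical variances). With fewer
#' replicates, or degenerate (zero-variance) replicates, the default weakly
#' informative prior is returned.
#'
#' @param replicates \code{R x K x T} numeric array.
#' @return A \code{bden_noise_prior} with per-observable shape/scale.
#' @export
estimate_noise_prior <- function(replicates) {
  stopifnot(length(dim(replicates)) == 3L)
  R <- dim(replicates)[1L]; K <- dim(replicates)[2L]
  mean_series <- apply(replicates, 2L, function(m) mean(abs(m)))
  fallback <- noise_prior(shape = rep(5, K),
                          scale = pmax(6 * (0.05 * mean_series)^2, 1e-10))
  if (R < 3L) return(fallback)
  shape <- numeric(K); scale <- numeric(K)
  for (k in seq_len(K)) {
    v <- apply(replicates[, k, , drop = FALSE], 3L, stats::var)  # per time point
    m <- mean(v); s2 <- stats::var(v)
    if (!is.finite(m) || m <= 0 || !is.finite(s2) || s2 <= 0) return(fallback)
    shape[k] <- m^2 / s2 + 2
    scale[k] <- m * (shape[k] - 1)
  }
  noise_prior(shape = shape, scale = scale)
}

#' Marginal log-likelihood of the data under a hidden influence
#'
#' Integrates the model under \code{w}, applies the measurement map and sums
#' the per-point marginal log-likelihoods; the likelihood factorizes over
#' observables and time points because the measurement noise is independent.
#' A failed or diverging integration returns the finite log-density floor
#' (-1e10) so that a sampler rejects rather than crashes.
#'
#' @param model a \code{bden_model}.
#' @param w \code{NULL} or a \code{bden_influence} on \code{data$grid}.
#' @param data a \code{bden_data}.
#' @return Scalar log-likelihood.
#' @export
data_loglik <- function(model, w, data) {
  stopifnot(inherits(model, "bden_model"), inherits(data, "bden_data"))
  grid <- data$grid
  times <- if (model$t0 < grid[1L]) c(model$t0, grid) else grid
  traj <- try(integrate_model(model, times, w = w), silent = TRUE)
  if (inherits(traj, "try-error")) return(LOGLIK_FLOOR)
  states <- traj$states
  if (model$t0 < grid[1L]) states <- states[, -1L, drop = FALSE]
  y_hat <- observe(model, states, grid)
  res <- data$values - y_hat
  marginal_loglik_matrix(res, data$noise_prior$shape, data$noise_prior$scale)
}

LOGLIK_FLOOR <- -1e10
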