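#' Hierarchical Bayesian elastic-net hyper-parameters
#'
#' The prior on the hidden influences combines L1-like sparsity across nodes
#' with L2-like smoothness across time through a Gaussian scale mixture on the
#' increments dw[i,l] = w[i,l] - w[i,l-1] (with w[i,0] = 0):
#' \deqn{dw \mid \tau \sim N\!\big(0,\; \sigma^2 (\tau - 1) / (\lambda_2 \tau)\big),
#'   \qquad \tau \sim \mathrm{Gamma}(1/2,\; \lambda_{1,i}^2 / (8 \sigma^2 \lambda_2))
#'   \ \text{truncated to } (1, \infty).}
#' Each per-node sparsity parameter lambda1[i] carries an Exponential(gamma[i])
#' hyper-prior; the smoothness parameter lambda2 a Gamma(a2, b2) prior and the
#' global scale sigma2 an InvGamma(as, bs) prior. Marginally over tau the
#' increments follow an elastic-net-type density: large lambda1 concentrates
#' tau near 1 and shrinks increments towards zero (sparsity), large lambda2
#' uniformly shrinks all conditional variances (smoothness).
#'
#' @param n_states number of nodes N.
#' @param n_times number of time points T.
#' @param lambda1 non-negative numeric vector of length N.
#' @param lambda2 positive scalar.
#' @param sigma2 positive scalar.
#' @param latent_scales \code{N x T} matrix of scale variables, all > 1.
#' @param hyper_rates exponential hyper-prior rates gamma (length N).
#' @param a2,b2 Gamma prior on lambda2.
#' @param a_sigma,b_sigma InvGamma prior on sigma2.
#' @return Object of class \code{bden_hyper}.
#' @export
en_hyper <- function(n_states, n_times, lambda1 = NULL, lambda2 = 1,
                     sigma2 = 1, latent_scales = NULL, hyper_rates = 0.1,
                     a2 = 1, b2 = 1, a_sigma = 1, b_sigma = 1) {
  hyper_rates <- rep_len(hyper_rates, n_states)
  if (is.null(lambda1)) lambda1 <- 1 / hyper_rates  # prior means
  lambda1 <- rep_len(lambda1, n_states)
  if (is.null(latent_scales))
    latent_scales <- matrix(2, n_states, n_times)
  h <- structure(list(lambda1 = lambda1, lambda2 = lambda2, sigma2 = sigma2,
                      latent_scales = latent_scales, hyper_rates = hyper_rates,
                      a2 = a2, b2 = b2, a_sigma = a_sigma, b_sigma = b_sigma),
                 class = "bden_hyper")
  validate_hyper(h)
  h
}

validate_hyper <- function(h) {
  ok <- all(is.finite(h$lambda1)) && all(h$lambda1 >= 0) &&
    is.finite(h$lambda2) && h$lambda2 > 0 &&
    is.finite(h$sigma2) && h$sigma2 > 0 &&
    all(is.finite(h$latent_scales)) && all(h$latent_scales > 1) &&
    all(is.finite(h$hyper_rates)) && all(h$hyper_rates > 0)
  if (!ok) stop("invalid elastic-net hyper-parameters", call. = FALSE)
  invisible(h)
}

#' @export
print.bden_hyper <- function(x, ...) {
  cat("Elastic-net hyper-parameters:\n")
  cat("  lambda1:", paste(signif(x$lambda1, 3), collapse = ", "), "\n")
  cat("  lambda2:", signif(x$lambda2, 4), " sigma2:", signif(x$sigma2, 4), "\n")
  cat("  latent scales:", nrow(x$latent_scales), "x", ncol(x$latent_scales),
      "(range", paste(signif(range(x$latent_scales), 3), collapse = " - "), ")\n")
  invisible(x)
}

## Conditional increment variances v[i,l] = sigma2 * (tau - 1) / (lambda2 * tau)
increment_variances <- function(hyper) {
  tau <- hyper$latent_scales
  hyper$sigma2 * (tau - 1) / (hyper$lambda2 * tau)
}

#' Conditional log-prior of one time slice of hidden influences
#'
#' The elastic-net construction yields a conditional Gaussian prior for each
#' \code{w[i,l]} given its predecessor \code{w[i,l-1]} (the zero vector at
#' l = 1), with variance \code{sigma2 (tau[i,l] - 1) / (lambda2 tau[i,l])}.
#'
#' @param w_l numeric vector of length N (values at time l).
#' @param w_prev predecessor values (zeros at l = 1).
#' @param hyper a \code{bden_hyper}.
#' @param l time index selecting the latent-scale column.
#' @return Scalar log-density.
#' @export
log_prior_increment <- function(w_l, w_prev, hyper, l = 1L) {
  validate_hyper(hyper)
  if (length(w_l) != nrow(hyper$latent_scales) || length(w_prev) != length(w_l))
    stop("dimension mismatch between w and hyper-parameters")
  v <- increment_variances(hyper)[, l]
  sum(stats::dnorm(w_l, mean = w_prev, sd = sqrt(v), log = TRUE))
}

#' Marginal elastic-net log-density of increments
#'
#' Integrating the latent scale out of the Gaussian scale mixture gives the
#' elastic-net density on an increment d = w[l] - w[l-1] exactly:
#' log p(d) = -(lambda2 d^2 + lambda1 |d|) / (2 sigma2) + const. The sampler
#' evaluates proposals under this marginal (a partially collapsed scheme):
#' under the conditional Gaussian, elements whose latent scale has closed
#' around a zero increment could never open again.
#'
#' @param d numeric increments.
#' @param lambda1,lambda2,sigma2 elastic-net parameters (lambda1 may be a
#'   vector recycled along \code{d}).
#' @param normalized include the log normalizing constant (needed when
#'   comparing across hyper-parameter settings; it cancels in w-moves).
#' @return Log-density values.
#' @export
en_marginal_logprior <- function(d, lambda1, lambda2, sigma2,
                                 normalized = FALSE) {
  out <- -(lambda2 * d^2 + lambda1 * abs(d)) / (2 * sigma2)
  if (normalized) {
    ## int exp(-(l2 d^2 + l1 |d|)/(2 s2)) dd via the Gaussian cdf
    mu <- lambda1 / (2 * lambda2)
    lz <- 0.5 * log(2 * pi * sigma2 / lambda2) +
      lambda1^2 / (8 * lambda2 * sigma2) +
      stats::pnorm(-mu / sqrt(sigma2 / lambda2), log.p = TRUE) + log(2)
    out <- out - lz
  }
  out
}

## ---- samplers for the augmentation ----------------------------------------

## Inverse-Gaussian draws (mean mu, shape lam), Michael-Schucany-Haas.
rinvgauss <- function(n, mu, lam) {
  nu <- stats::rnorm(n)
  y <- nu^2
  x <- mu + mu^2 * y / (2 * lam) - mu / (2 * lam) * sqrt(4 * mu * lam * y + mu^2 * y^2)
  x <- pmax(x, .Machine$double.xmin)
  z <- stats::runif(n)
  ifelse(z <= mu / (mu + x), x, mu^2 / x)
}

## Draw tau from its prior: density propto tau^{-1/2} exp(-c tau) on (1, Inf),
## exact inverse-CDF via the Gamma(1/2, c) quantile function.
rtrunc_gamma_tau <- function(n, c) {
  c <- rep_len(pmax(c, 1e-300), n)
  lo <- stats::pgamma(1, shape = 0.5, rate = c)
  u <- lo + stats::runif(n) * (1 - lo)
  tau <- stats::qgamma(pmin(u, 1 - 1e-16), shape = 0.5, rate = c)
  pmin(pmax(tau, 1 + 1e-12), 1e12)
}

## log of the truncation normalizer Z(c) = int_1^Inf tau^{-1/2} e^{-c tau} dtau
##                                      = c^{-1/2} * Gamma(1/2) * P(Gamma(1/2,c) > 1)
log_znorm_tau <- function(c) {
  c <- pmax(c, 1e-300)
  -0.5 * log(c) + lgamma(0.5) +
    stats::pgamma(1, shape = 0.5, rate = c, lower.tail = FALSE, log.p = TRUE)
}

## Full conditional of tau[i,l] given dw: with s = tau - 1,
## p(s) propto s^{-1/2} exp(-a/s - c s), a = dw^2 lambda2 / (2 sigma2),
## i.e. GIG(1/2, 2a, 2c); sampled as s = 1/g with g ~ InvGauss(sqrt(c/a), 2c).
draw_scale_conditional <- function(dw, c, lambda2, sigma2) {
  a <- dw^2 * lambda2 / (2 * sigma2)
  n <- length(dw)
  out <- numeric(n)
  small <- a < 1e-14
  if (any(small)) {
    s <- stats::rgamma(sum(small), shape = 0.5, rate = pmax(c[small], 1e-300))
    out[small] <- 1 + pmax(s, 1e-12)
  }
  if (any(!small)) {
    mu <- sqrt(pmax(c[!small], 1e-300) / a[!small])
    g <- rinvgauss(sum(!small), mu = mu, lam = 2 * pmax(c[!small], 1e-300))
    out[!small] <- 1 + pmax(1 / g, 1e-12)
  }
  pmin(out, 1e12)  # numerically degenerate draws are clipped to the domain
}

## Neal (2003) univariate slice sampler with stepping out, on an unbounded
## transformed scale. logf must be finite at x0.
slice_sample1 <- function(x0, logf, w = 1, max_steps = 50L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) return(x0)
  z <- f0 + log(stats::runif(1))
  lo <- x0 - w * stats::runif(1)
  hi <- lo + w
  k <- max_steps
  while (k > 0L && logf(lo) > z) { lo <- lo - w; k <- k - 1L }
  k <- max_steps
  while (k > 0L && logf(hi) > z) { hi <- hi + w; k <- k - 1L }
  repeat {
    x1 <- stats::runif(1, lo, hi)
    if (logf(x1) > z) return(x1)
    if (x1 < x0) lo <- x1 else hi <- x1
    if (hi - lo < 1e-12) return(x0)
  }
}

## ---- Gibbs sweep over hyper-parameters ------------------------------------

#' One Gibbs refresh of the elastic-net hyper-parameters
#'
#' Draws, in order, the latent scales from their exact conditionals (derived
#' generalized-inverse-Gaussian form), then lambda1 per node, lambda2 and
#' sigma2 by univariate slice sampling of their full conditionals (the
#' truncated-gamma normalizer makes the lambda updates non-conjugate).
#' Deterministic under a fixed RNG state.
#'
#' @param hyper a \code{bden_hyper}.
#' @param w \code{N x T} hidden-influence matrix (or \code{bden_influence}).
#' @param update_sigma2 also draw sigma2 from its conditional; [bden()] keeps
#'   sigma2 fixed at the system's squared derivative scale by default (the
#'   global scale is not identified against lambda1/lambda2 and its
#'   conditional collapses while the influences are still near zero).
#' @return Updated \code{bden_hyper}.
#' @export
gibbs_update <- function(hyper, w, update_sigma2 = TRUE) {
  validate_hyper(hyper)
  if (inherits(w, "bden_influence")) w <- w$values
  if (is.vector(w)) w <- matrix(w, nrow = 1L)
  N <- nrow(w); Tn <- ncol(w)
  stopifnot(N == nrow(hyper$latent_scales), Tn == ncol(hyper$latent_scales))
  dw <- w - cbind(0, w[, -Tn, drop = FALSE])

  ## latent scales | dw, lambda1, lambda2, sigma2
  cmat <- matrix(hyper$lambda1^2 / (8 * hyper$sigma2 * hyper$lambda2), N, Tn)
  tau <- matrix(draw_scale_conditional(as.vector(dw), as.vector(cmat),
                                       hyper$lambda2, hyper$sigma2), N, Tn)
  hyper$latent_scales <- tau

  ## lambda1[i] | tau[i,], gamma[i]  (slice on log lambda1)
  stau <- rowSums(tau)
  for (i in seq_len(N)) {
    gi <- hyper$hyper_rates[i]; sti <- stau[i]
    denom <- 8 * hyper$sigma2 * hyper$lambda2
    logf <- function(th) {
      l1 <- exp(th)
      cc <- l1^2 / denom
      -gi * l1 - cc * sti - Tn * log_znorm_tau(cc) + th  # + log-Jacobian
    }
    hyper$lambda1[i] <- exp(slice_sample1(log(max(hyper$lambda1[i], 1e-8)), logf))
  }

  ## shared pieces for lambda2 / sigma2 conditionals
  s <- tau - 1
  q <- sum(dw^2 * tau / s)          # dw^2 * tau/(tau-1), finite since tau > 1
  l1sq_tau <- sum(hyper$lambda1^2 * stau)
  znorm_sum <- function(denom) {
    cc <- hyper$lambda1^2 / denom
    Tn * sum(log_znorm_tau(cc))
  }

  ## lambda2 | rest (Gamma(a2, b2) prior), slice on log lambda2
  logf2 <- function(th) {
    l2 <- exp(th)
    denom <- 8 * hyper$sigma2 * l2
    (hyper$a2 - 1) * th - hyper$b2 * l2 +
      0.5 * N * Tn * th - l2 * q / (2 * hyper$sigma2) -
      l1sq_tau / denom - znorm_sum(denom) + th
  }
  hyper$lambda2 <- exp(slice_sample1(log(hyper$lambda2), logf2))

  ## sigma2 | rest (InvGamma(a_sigma, b_sigma) prior), slice on log sigma2
  if (update_sigma2) {
    logfs <- function(th) {
      s2 <- exp(th)
      denom <- 8 * s2 * hyper$lambda2
      (-hyper$a_sigma - 1) * th - hyper$b_sigma / s2 -
        0.5 * N * Tn * th - hyper$lambda2 * q / (2 * s2) -
        l1sq_tau / denom - znorm_sum(denom) + th
    }
    hyper$sigma2 <- exp(slice_sample1(log(hyper$sigma2), logfs))
  }

  ## refresh scales once more under the new lambda/sigma (keeps the sweep
  ## a valid composition of conditional updates and speeds mixing)
  cmat <- matrix(hyper$lambda1^2 / (8 * hyper$sigma2 * hyper$lambda2), N, Tn)
  hyper$latent_scales <- matrix(draw_scale_conditional(as.vector(dw),
                                                       as.vector(cmat),
                                                       hyper$lambda2, hyper$sigma2),
                                N, Tn)
  hyper
}

#' Ancestral draw of a hidden-influence path from the prior
#'
#' Samples the first-order Markov chain w[, 1], ..., w[, T] from w0 = 0 under
#' fixed lambda1/lambda2/sigma2, drawing fresh latent scales per element from
#' their (truncated-gamma) prior. Used for prior-predictive checks.
#'
#' @param hyper a \code{bden_hyper}.
#' @param n_times number of time points T >= 1.
#' @return \code{N x T} matrix.
#' @export
sample_prior_path <- function(hyper, n_times) {
  validate_hyper(hyper)
  N <- length(hyper$lambda1)
  cvec <- hyper$lambda1^2 / (8 * hyper$sigma2 * hyper$lambda2)
  w <- matrix(0, N, n_times)
  prev <- numeric(N)
  for (l in seq_len(n_times)) {
    tau <- rtrunc_gamma_tau(N, cvec)
    v <- hyper$sigma2 * (tau - 1) / (hyper$lambda2 * tau)
    w[, l] <- prev + stats::rnorm(N, 0, sqrt(v))
    prev <- w[, l]
  }
  w
}

#' Serialize / restore hyper-parameters as JSON
#'
#' Flat JSON document for checkpointing chains.
#' @param hyper a \code{bden_hyper}.
#' @param path optional file; when NULL the JSON string is returned.
#' @export
hyper_to_json <- function(hyper, path = NULL) {
  validate_hyper(hyper)
  doc <- list(lambda1 = hyper$lambda1, lambda2 = hyper$lambda2,
              sigma2 = hyper$sigma2, hyper_rates = hyper$hyper_rates,
              latent_scales = as.vector(hyper$latent_scales),
              n_states = nrow(hyper$latent_scales),
              n_times = ncol(hyper$latent_scales),
              a2 = hyper$a2, b2 = hyper$b2,
              a_sigma = hyper$a_sigma, b_sigma = hyper$b_sigma)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname hyper_to_json
#' @param json JSON string or file path produced by [hyper_to_json()].
#' @export
hyper_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json)
  en_hyper(n_states = doc$n_states, n_times = doc$n_times,
           lambda1 = doc$lambda1, lambda2 = doc$lambda2, sigma2 = doc$sigma2,
           latent_scales = matrix(doc$latent_scales, doc$n_states, doc$n_times),
           hyper_rates = doc$hyper_rates, a2 = doc$a2, b2 = doc$b2,
           a_sigma = doc$a_sigma, b_sigma = doc$b_sigma)
}
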