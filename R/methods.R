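#' @export
print.bden <- function(x, ...) {
  S <- dim(x$w_draws)[1L]
  cat("Bayesian dynamic elastic-net fit\n")
  cat("  model:", x$model$name, "-", x$model$n_states, "states,",
      x$model$n_obs, "observables,", length(x$data$grid), "time points\n")
  cat("  chain:", x$control$n_samples, "sweeps (", x$control$n_burnin,
      "burn-in, thin", x$control$thin, ") ->", S, "retained draws\n")
  cat("  mean acceptance rate:", signif(mean(x$acceptance_rate), 3), "\n")
  sc <- influence_scores(x)
  cat("  influence scores (area under |posterior mean w|):\n")
  print(signif(sc, 3))
  invisible(x)
}

#' @export
summary.bden <- function(object, credible_level = object$control$credible_level, ...) {
  sm <- summarize_posterior(object, credible_level)
  sm$influence_score <- influence_scores(object)
  sm$model <- object$model$name
  sm$n_draws <- dim(object$w_draws)[1L]
  sm$acceptance <- mean(object$acceptance_rate)
  class(sm) <- "summary.bden"
  sm
}

#' @export
print.summary.bden <- function(x, ...) {
  cat("Posterior summary (", x$n_draws, " draws, ",
      round(100 * x$credible_level), "% intervals)\n", sep = "")
  cat("Influence scores:\n"); print(signif(x$influence_score, 3))
  cat("Posterior mean hidden influences (nodes x time):\n")
  print(signif(x$w_mean, 3))
  invisible(x)
}

#' Posterior-mean hidden influences
#'
#' @param object a \code{bden} fit.
#' @param ... unused.
#' @return \code{N x T} matrix of posterior means of w.
#' @export
coef.bden <- function(object, ...) {
  w <- apply(object$w_draws, c(2L, 3L), mean)
  rownames(w) <- object$model$species_names
  colnames(w) <- signif(object$data$grid, 6)
  w
}

#' @export
fitted.bden <- function(object, ...) {
  xm <- apply(object$state_draws, c(2L, 3L), mean)
  observe(object$model, xm, object$data$grid)
}

#' @export
residuals.bden <- function(object, ...) {
  object$data$values - fitted(object)
}

#' Posterior predictions from a fit
#'
#' @param object a \code{bden} fit.
#' @param type \code{"observables"} (posterior-mean states through the
#'   measurement map), \code{"states"}, or \code{"hidden"} (posterior-mean
#'   hidden influences).
#' @param level credible level; when not \code{NULL}, lower/upper matrices are
#'   attached.
#' @param ... unused.
#' @return A matrix (series x time), optionally with \code{lower}/\code{upper}
#'   attributes.
#' @export
predict.bden <- function(object, type = c("observables", "states", "hidden"),
                         level = NULL, ...) {
  type <- match.arg(type)
  if (type == "observables") return(fitted(object))
  sm <- summarize_posterior(object, level %||% object$control$credible_level)
  out <- if (type == "states") sm$x_mean else sm$w_mean
  rownames(out) <- object$model$species_names
  if (!is.null(level)) {
    attr(out, "lower") <- if (type == "states") sm$x_lower else sm$w_lower
    attr(out, "upper") <- if (type == "states") sm$x_upper else sm$w_upper
  }
  out
}

#' Simulate datasets from the fitted system
#'
#' Integrates the model under the posterior-mean hidden influence and adds
#' Gaussian noise at the posterior-centre noise scale of each observable
#' (the mode beta/(alpha + 1) of its inverse-gamma prior).
#'
#' @param object a \code{bden} fit.
#' @param nsim number of datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return List of \code{bden_data} objects.
#' @export
simulate.bden <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  model <- object$model; grid <- object$data$grid
  w <- hidden_influence(coef(object), grid)
  times <- if (model$t0 < grid[1L]) c(model$t0, grid) else grid
  traj <- integrate_model(model, times, w = w)
  states <- traj$states
  if (model$t0 < grid[1L]) states <- states[, -1L, drop = FALSE]
  y <- observe(object$model, states, grid)
  K <- nrow(y)
  sd_k <- sqrt(rep_len(object$data$noise_prior$scale, K) /
                 (rep_len(object$data$noise_prior$shape, K) + 1))
  lapply(seq_len(nsim), function(s) {
    yy <- y + matrix(stats::rnorm(length(y), 0, sd_k), K, ncol(y))
    measurement_set(yy, grid, prior = object$data$noise_prior,
                    obs_names = object$model$obs_names)
  })
}

#' Plot a fit: data vs posterior predictions and hidden influences
#'
#' Top row: each observable's measurements with the posterior-mean prediction.
#' Bottom row: posterior-mean hidden influence per node with the credible
#' band.
#'
#' @param x a \code{bden} fit.
#' @param which \code{"both"}, \code{"fit"} or \code{"hidden"}.
#' @param ... passed to \code{matplot}.
#' @export
plot.bden <- function(x, which = c("both", "fit", "hidden"), ...) {
  which <- match.arg(which)
  sm <- summarize_posterior(x)
  grid <- x$data$grid
  op <- graphics::par(no.readonly = TRUE); on.exit(graphics::par(op))
  nr <- if (which == "both") 2L else 1L
  graphics::par(mfrow = c(nr, 1L), mar = c(4, 4, 2, 1))
  if (which %in% c("both", "fit")) {
    yfit <- observe(x$model, sm$x_mean, grid)
    graphics::matplot(grid, t(x$data$values), pch = 16, col = seq_len(nrow(yfit)),
                      xlab = "time", ylab = "observables", main = x$model$name, ...)
    graphics::matlines(grid, t(yfit), lty = 1, col = seq_len(nrow(yfit)))
  }
  if (which %in% c("both", "hidden")) {
    ylim <- range(sm$w_lower, sm$w_upper)
    graphics::matplot(grid, t(sm$w_mean), type = "l", lty = 1, ylim = ylim,
                      col = seq_len(nrow(sm$w_mean)),
                      xlab = "time", ylab = "hidden influence w(t)",
                      main = "posterior mean and credible band")
    for (i in seq_len(nrow(sm$w_mean))) {
      graphics::polygon(c(grid, rev(grid)), c(sm$w_lower[i, ], rev(sm$w_upper[i, ])),
                        border = NA,
                        col = grDevices::adjustcolor(i, alpha.f = 0.15))
    }
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}
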