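## Packaged nominal-model fixtures. Each model ships as a declarative
## model-spec file under inst/extdata/models/ and is parsed on demand; the
## file documents its literature source and any reconstruction choice.

fixture_dir <- function() system.file("extdata", "models", package = "bden")

MOTIF_NAMES <- c("motif-cascade", "motif-negative-feedback", "motif-coherent-ffl",
                 "motif-incoherent-ffl", "motif-fanout")

#' List the packaged models
#'
#' @return Character vector of registry names accepted by [build_model()].
#' @export
list_models <- function() {
  sort(sub("\\.yaml$", "", list.files(fixture_dir(), pattern = "\\.yaml$")))
}

#' Build a packaged nominal model by name
#'
#' The registry covers the literature test systems (JAK-STAT signalling,
#' yeast G protein cycle, plant UV-B signalling, EpoR information processing,
#' alpha-pinene isomerization, a DREAM6-style gene-regulatory network) and the
#' five network motifs (see [list_motifs()]).
#'
#' @param name registry name, e.g. \code{"jak-stat"}; see [list_models()].
#' @return A \code{bden_model}.
#' @examples
#' m <- build_model("jak-stat")
#' m$n_states  # 4
#' @export
build_model <- function(name) {
  path <- file.path(fixture_dir(), paste0(name, ".yaml"))
  if (!file.exists(path))
    stop("unknown model '", name, "'; available: ",
         paste(list_models(), collapse = ", "))
  read_model_spec(path)
}

#' The packaged network-motif models
#'
#' Five canonical small topologies with mass-action kinetics and identity
#' observation: a three-step linear cascade, a negative feedback loop, a
#' coherent and an incoherent feed-forward loop, and a single-input fan-out.
#'
#' @return Named list of \code{bden_model} objects.
#' @export
list_motifs <- function() {
  stats::setNames(lapply(MOTIF_NAMES, build_model), MOTIF_NAMES)
}

#' Simulate a noisy dataset from a model
#'
#' Integrates the (true) system, optionally under a hidden influence, applies
#' the measurement map and adds independent Gaussian noise per observable with
#' standard deviation \code{noise_level} times the mean of that observable's
#' noise-free series (relative noise, e.g. 0.025 for 2.5\%).
#'
#' @param model a \code{bden_model}.
#' @param grid measurement grid; defaults to the model's.
#' @param w_true \code{NULL}, a \code{bden_influence} or a function of t.
#' @param noise_level relative noise fraction (>= 0).
#' @param seed optional seed for the noise draws.
#' @param prior optional \code{bden_noise_prior} to attach; defaults to the
#'   package default.
#' @return A \code{bden_data} with attributes \code{truth} (the noise-free
#'   observable matrix) and \code{states} (the true state trajectory).
#' @export
simulate_dataset <- function(model, grid = NULL, w_true = NULL,
                             noise_level = 0.025, seed = NULL, prior = NULL) {
  stopifnot(inherits(model, "bden_model"))
  grid <- grid %||% model$default_grid
  if (is.null(grid)) stop("no grid given and the model has no default grid")
  check_grid(grid)
  times <- if (model$t0 < grid[1L]) c(model$t0, grid) else grid
  traj <- integrate_model(model, times, w = w_true)
  states <- traj$states
  if (model$t0 < grid[1L]) states <- states[, -1L, drop = FALSE]
  y <- observe(model, states, grid)
  if (!is.null(seed)) set.seed(seed)
  sd_k <- noise_level * pmax(abs(rowMeans(y)), 1e-12)
  yy <- y + matrix(stats::rnorm(length(y), 0, sd_k), nrow(y), ncol(y))
  out <- measurement_set(yy, grid, prior = prior, obs_names = model$obs_names)
  attr(out, "truth") <- y
  attr(out, "states") <- states
  out
}
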