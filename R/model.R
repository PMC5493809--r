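#' Construct a nominal ODE model
#'
#' A nominal model is the assumed (possibly incomplete or partially wrong)
#' description of a molecular network: a vector field \code{f(x, u, t)} with
#' fixed kinetic parameters, a known input function \code{u(t)}, a measurement
#' map \code{h(x, u, t)} onto \code{K} observables (\code{K} need not equal the
#' state dimension \code{N}) and an initial state \code{eta} at time \code{t0}.
#' Hidden influences enter additively on the right-hand side,
#' \code{dx/dt = f(x, u, t) + w(t)}.
#'
#' @param vector_field function \code{(x, u, t, p)} returning the \code{N}
#'   state derivatives; \code{p} is the named kinetic parameter vector.
#' @param measurement_map function \code{(x, u, t, p)} returning the \code{K}
#'   observables. Defaults to the identity map.
#' @param known_input function of \code{t} returning the (possibly empty)
#'   input vector.
#' @param initial_state numeric state vector \code{eta} at \code{t0}.
#' @param kinetic_params named numeric vector of rate constants.
#' @param t0 initial time; defaults to the first point of \code{default_grid}
#'   (or 0 when no grid is given).
#' @param species_names,obs_names character vectors naming states and
#'   observables.
#' @param default_grid optional strictly increasing measurement time grid.
#' @param name optional model name.
#' @param variants optional list of structural variants (used by the
#'   benchmark to emulate missing/wrong interactions), see
#'   \code{\link{model_variants}}.
#' @param rk_steps integer, fixed RK4 sub-steps per grid segment used by the
#'   sampler's local integrator.
#' @return An object of class \code{bden_model}.
#' @seealso [integrate_model()], [observe()], [build_model()]
#' @export
ode_model <- function(vector_field, measurement_map = NULL, known_input = NULL,
                      initial_state, kinetic_params = numeric(0), t0 = NULL,
                      species_names = NULL, obs_names = NULL,
                      default_grid = NULL, name = "model", variants = list(),
                      rk_steps = 8L) {
  stopifnot(is.function(vector_field), is.numeric(initial_state),
            length(initial_state) >= 1L, all(is.finite(initial_state)))
  n <- length(initial_state)
  if (is.null(known_input)) known_input <- function(t) numeric(0)
  if (is.null(measurement_map))
    measurement_map <- function(x, u, t, p) x
  if (is.null(species_names)) species_names <- paste0("x", seq_len(n))
  if (!is.null(default_grid)) check_grid(default_grid)
  if (is.null(t0)) t0 <- if (!is.null(default_grid)) default_grid[1L] else 0
  u0 <- known_input(t0)
  y0 <- measurement_map(initial_state, u0, t0, kinetic_params)
  k <- length(y0)
  if (k < 1L) stop("measurement map must return at least one observable")
  if (is.null(obs_names)) obs_names <- paste0("y", seq_len(k))
  structure(list(
    name = name, n_states = n, n_obs = k,
    vector_field = vector_field, measurement_map = measurement_map,
    known_input = known_input, initial_state = stats::setNames(initial_state, species_names),
    kinetic_params = kinetic_params, t0 = t0,
    species_names = species_names, obs_names = obs_names,
    default_grid = default_grid, variants = variants,
    rk_steps = as.integer(rk_steps)
  ), class = "bden_model")
}

#' @export
print.bden_model <- function(x, ...) {
  cat("Nominal ODE model '", x$name, "'\n", sep = "")
  cat("  states     :", x$n_states, paste0("(", paste(x$species_names, collapse = ", "), ")"), "\n")
  cat("  observables:", x$n_obs, paste0("(", paste(x$obs_names, collapse = ", "), ")"), "\n")
  cat("  parameters :", length(x$kinetic_params), "\n")
  if (!is.null(x$default_grid))
    cat("  default grid: ", length(x$default_grid), " points on [",
        x$default_grid[1L], ", ", x$default_grid[length(x$default_grid)], "]\n", sep = "")
  if (length(x$variants))
    cat("  variants   :", paste(vapply(x$variants, `[[`, "", "name"), collapse = ", "), "\n")
  invisible(x)
}

check_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 3L)
    stop("time grid must be numeric with at least 3 points", call. = FALSE)
  if (anyNA(grid) || any(!is.finite(grid)))
    stop("time grid contains non-finite values", call. = FALSE)
  if (any(diff(grid) <= 0))
    stop("time grid must be strictly increasing", call. = FALSE)
  invisible(grid)
}

#' Fit a cubic (smoothing) spline through one time series
#'
#' Used to turn the discrete hidden-influence values at the measurement grid
#' into a continuous-time signal entering the ODE right-hand side. With
#' \code{smoothing = 0} (the default) the natural interpolating cubic spline
#' is returned, which passes through every knot; the between-knot smoothness
#' of the hidden influence is already controlled by the prior. A positive
#' \code{smoothing} is handed to \code{\link[stats]{smooth.spline}} as
#' \code{spar}. Left of the first knot the function is held constant at its
#' first value; this covers integration from an initial time earlier than the
#' first measurement.
#'
#' @param values numeric vector of length \code{T}.
#' @param grid strictly increasing time grid of the same length (\code{T >= 3}).
#' @param smoothing smoothing parameter; 0 interpolates.
#' @return A function of time, vectorized, C1 on the grid span.
#' @export
fit_spline <- function(values, grid, smoothing = 0) {
  check_grid(grid)
  if (length(values) != length(grid))
    stop("values and grid lengths differ")
  if (anyNA(values) || any(!is.finite(values)))
    stop("spline values must be finite (no NaN/NA)")
  t1 <- grid[1L]
  if (smoothing > 0 && length(grid) >= 4L) {
    sm <- stats::smooth.spline(grid, values, spar = smoothing)
    f <- function(t) stats::predict(sm, pmax(t, t1))$y
  } else {
    sf <- stats::splinefun(grid, values, method = "natural")
    f <- function(t) sf(pmax(t, t1))
  }
  f
}

#' Hidden influence trajectory
#'
#' Bundles the discrete \code{N x T} hidden-influence matrix with its grid and
#' the per-node spline interpolants.
#'
#' @param values numeric \code{N x T} matrix (or a vector for \code{N = 1}).
#' @param grid strictly increasing time grid of length \code{T}.
#' @param smoothing passed to [fit_spline()].
#' @return Object of class \code{bden_influence}: list with \code{values},
#'   \code{grid} and \code{interpolant(t)} returning an \code{N}-vector.
#' @export
hidden_influence <- function(values, grid, smoothing = 0) {
  if (is.vector(values)) values <- matrix(values, nrow = 1L)
  check_grid(grid)
  stopifnot(ncol(values) == length(grid))
  funs <- lapply(seq_len(nrow(values)), function(i)
    fit_spline(values[i, ], grid, smoothing))
  interp <- function(t) vapply(funs, function(f) f(t), numeric(length(t)))
  structure(list(values = values, grid = grid, funs = funs,
                 interpolant = interp),
            class = "bden_influence")
}

#' Integrate a nominal model, optionally under a hidden influence
#'
#' Solves \code{dx/dt = f(x, u, t) + w(t)} with \code{\link[deSolve]{lsoda}}
#' (adaptive, stiff-capable; rtol 1e-6, atol 1e-8). With \code{w = NULL} the
#' nominal trajectory is returned. Segment-mode integration (from an arbitrary
#' state over a sub-interval) is obtained via \code{init} and a two-point
#' \code{times} vector; this equivalence between chained segments and
#' whole-interval integration underpins the sampler's sequential scheme.
#'
#' @param model a \code{bden_model}.
#' @param times strictly increasing times; first element is the initial time.
#' @param w \code{NULL}, a \code{bden_influence}, or a function of \code{t}
#'   returning the \code{N}-vector of influences.
#' @param init initial state; defaults to \code{model$initial_state} (valid
#'   when \code{times[1] == model$t0}).
#' @param rtol,atol solver tolerances.
#' @return Object of class \code{bden_trajectory}: list with \code{states}
#'   (\code{N x length(times)} matrix) and \code{grid}.
#' @export
integrate_model <- function(model, times, w = NULL, init = NULL,
                            rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(model, "bden_model"))
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("times must be strictly increasing with at least 2 points")
  if (is.null(init)) init <- unname(model$initial_state)
  wfun <- influence_fun(w, model$n_states)
  f <- model$vector_field; uf <- model$known_input; p <- model$kinetic_params
  deriv <- function(t, x, parms) list(f(x, uf(t), t, p) + wfun(t))
  out <- try(deSolve::lsoda(y = init, times = times, func = deriv, parms = NULL,
                            rtol = rtol, atol = atol), silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(times) ||
      anyNA(out) || any(!is.finite(out))) {
    bad <- if (inherits(out, "try-error")) times[c(1L, length(times))] else {
      i <- if (inherits(out, "try-error")) 1L else max(1L, nrow(out))
      c(times[min(i, length(times))], times[length(times)])
    }
    stop(structure(class = c("bden_integration_error", "error", "condition"),
                   list(message = sprintf("ODE integration failed on [%g, %g] for model '%s'",
                                          bad[1L], bad[2L], model$name),
                        call = sys.call(-1L), interval = bad)))
  }
  structure(list(states = t(unname(out[, -1L, drop = FALSE])), grid = times,
                 model = model$name),
            class = "bden_trajectory")
}

influence_fun <- function(w, n) {
  if (is.null(w)) return(function(t) numeric(n))
  if (inherits(w, "bden_influence")) {
    funs <- w$funs
    return(function(t) vapply(funs, function(f) f(t), numeric(1L)))
  }
  if (is.function(w)) return(w)
  stop("w must be NULL, a bden_influence, or a function of t")
}

#' Apply the measurement map to a state trajectory
#'
#' Maps states to the \code{K} observables columnwise; no noise is added.
#'
#' @param model a \code{bden_model}.
#' @param traj a \code{bden_trajectory} (or plain \code{N x T} matrix plus
#'   \code{grid}).
#' @param grid time grid, required when \code{traj} is a bare matrix.
#' @return \code{K x T} numeric matrix with observable names as rownames.
#' @export
observe <- function(model, traj, grid = NULL) {
  stopifnot(inherits(model, "bden_model"))
  if (inherits(traj, "bden_trajectory")) {
    states <- traj$states; grid <- traj$grid
  } else {
    states <- traj
    if (is.null(grid)) stop("grid required for a bare state matrix")
  }
  if (nrow(states) != model$n_states)
    stop("trajectory state dimension does not match the model")
  h <- model$measurement_map; uf <- model$known_input; p <- model$kinetic_params
  y <- vapply(seq_along(grid), function(j)
    h(states[, j], uf(grid[j]), grid[j], p), numeric(model$n_obs))
  y <- matrix(y, nrow = model$n_obs)
  rownames(y) <- model$obs_names
  y
}

#' @export
print.bden_trajectory <- function(x, ...) {
  cat("State trajectory:", nrow(x$states), "states at", length(x$grid),
      "time points on [", x$grid[1L], ",", x$grid[length(x$grid)], "]\n")
  invisible(x)
}

#' Convert a trajectory or observable matrix to a data frame
#'
#' First column \code{time}, one column per series; the delimited-table
#' round-trip format used throughout the package.
#' @param x a \code{bden_trajectory} or a series-by-time matrix.
#' @param grid time grid when \code{x} is a bare matrix.
#' @param ... unused.
#' @export
as.data.frame.bden_trajectory <- function(x, grid = NULL, ...) {
  df <- data.frame(time = x$grid, t(x$states))
  names(df)[-1L] <- if (!is.null(rownames(x$states))) rownames(x$states)
                    else paste0("x", seq_len(nrow(x$states)))
  df
}
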