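#' Read a delimited time-series table
#'
#' Expects a header row, the first column holding time and one column per
#' observable. The separator is auto-detected among tab, comma and
#' semicolon. Time must be strictly increasing and all cells finite.
#'
#' @param path file path.
#' @param prior optional \code{bden_noise_prior} to attach.
#' @return A \code{bden_data}.
#' @export
read_timeseries <- function(path, prior = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  l1 <- readLines(path, n = 1L)
  sep <- if (grepl("\t", l1)) "\t" else if (grepl(",", l1)) "," else
    if (grepl(";", l1)) ";" else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected a time column plus at least one series: ", path)
  tm <- df[[1L]]
  if (!is.numeric(tm) || anyNA(tm))
    stop("non-numeric or missing time values in ", path)
  bad <- which(diff(tm) <= 0)
  if (length(bad))
    stop("time is not strictly increasing at data row ", bad[1L] + 1L,
         " of ", path)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (anyNA(vals) || any(!is.finite(vals))) {
    ij <- which(!is.finite(vals), arr.ind = TRUE)[1L, ]
    stop("non-finite measurement at data row ", ij[1L], ", column '",
         colnames(vals)[ij[2L]], "' of ", path)
  }
  measurement_set(t(vals), tm, prior = prior, obs_names = colnames(vals))
}

#' Write a time series as a delimited table
#'
#' Full-precision tab-separated text: first column time, one column per
#' series, header row. Lossless round-trip with [read_timeseries()].
#'
#' @param x a \code{bden_data}, \code{bden_trajectory}, or series-by-time
#'   matrix.
#' @param path output file.
#' @param grid time grid for a bare matrix.
#' @export
write_timeseries <- function(x, path, grid = NULL) {
  if (inherits(x, "bden_data")) { vals <- x$values; grid <- x$grid }
  else if (inherits(x, "bden_trajectory")) { vals <- x$states; grid <- x$grid }
  else { vals <- x; if (is.null(grid)) stop("grid required for a bare matrix") }
  df <- data.frame(time = grid, t(vals), check.names = FALSE)
  if (!is.null(rownames(vals))) names(df)[-1L] <- rownames(vals)
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Save / load a posterior ensemble
#'
#' A fit persists as a single JSON document (arrays flattened with their
#' dimensions plus the resolved control block and seed, so a run can be
#' reproduced from its output alone). The model itself is referenced by name.
#'
#' @param fit a \code{bden} fit.
#' @param path output file.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "bden"))
  doc <- list(
    package_version = as.character(utils::packageVersion("bden")),
    model = fit$model$name, species = fit$model$species_names,
    grid = fit$data$grid, values = fit$data$values,
    noise_prior = list(shape = fit$data$noise_prior$shape,
                       scale = fit$data$noise_prior$scale),
    control = unclass(fit$control),
    dims = dim(fit$w_draws),
    w_draws = as.vector(fit$w_draws),
    state_draws = as.vector(fit$state_draws),
    lambda1_draws = as.vector(fit$lambda1_draws),
    lambda2_draws = fit$lambda2_draws, sigma2_draws = fit$sigma2_draws,
    acceptance_rate = fit$acceptance_rate,
    log_posterior_trace = fit$log_posterior_trace,
    kernel_sd = fit$kernel_sd)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_fit
#' @param model the \code{bden_model} the fit was produced with (fits store
#'   only the model name).
#' @export
read_fit <- function(path, model) {
  stopifnot(inherits(model, "bden_model"))
  doc <- jsonlite::fromJSON(path)
  if (!identical(doc$model, model$name))
    warning("fit was produced with model '", doc$model, "', got '",
            model$name, "'")
  ctrl_args <- doc$control
  ctrl_args <- ctrl_args[!vapply(ctrl_args, is.null, logical(1L))]
  ctrl <- do.call(bden_control, ctrl_args)
  vals <- doc$values
  if (!is.matrix(vals)) vals <- matrix(unlist(vals), ncol = length(doc$grid))
  data <- measurement_set(vals, doc$grid,
                          prior = noise_prior(doc$noise_prior$shape,
                                              doc$noise_prior$scale),
                          obs_names = model$obs_names)
  d <- doc$dims
  structure(list(
    w_draws = array(doc$w_draws, d),
    state_draws = array(doc$state_draws, d),
    lambda1_draws = matrix(doc$lambda1_draws, d[1L], d[2L]),
    lambda2_draws = doc$lambda2_draws, sigma2_draws = doc$sigma2_draws,
    acceptance_rate = matrix(unlist(doc$acceptance_rate), d[2L], d[3L]),
    log_posterior_trace = doc$log_posterior_trace,
    kernel_sd = doc$kernel_sd, model = model, data = data, control = ctrl,
    diagnostics = character(0)
  ), class = "bden")
}
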