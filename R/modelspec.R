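## Declarative model-spec files: YAML documents listing species, parameters,
## rate expressions (strings), observables, initial values and input
## expressions. Fixtures under inst/extdata/models/ use this format; users can
## supply their own files. Expressions are parsed once and compiled into a
## single vectorised R function per map.

#' Read a declarative model-spec file
#'
#' The format is YAML with fields \code{name}, \code{species} (list),
#' \code{initial} (map), \code{parameters} (map), \code{inputs} (map of input
#' name to an expression in \code{t}), \code{rates} (map species -> derivative
#' expression in species, parameters, inputs and \code{t}), \code{observables}
#' (map observable name -> expression), \code{time} (\code{t0} and
#' \code{grid}), and optionally \code{variants} (structural variants, each
#' with \code{name}, \code{mode} = \code{"remove"}/\code{"add"}, \code{source},
#' \code{target}, \code{sign} = \code{"stim"}/\code{"inh"} and the \code{rates}
#' entries that differ from the base model).
#'
#' @param path path to a YAML model-spec file.
#' @return A \code{bden_model}.
#' @export
read_model_spec <- function(path) {
  if (!file.exists(path)) stop("model-spec file not found: ", path)
  spec <- yaml::read_yaml(path)
  model_from_spec(spec)
}

model_from_spec <- function(spec) {
  need <- c("species", "initial", "rates", "observables")
  miss <- setdiff(need, names(spec))
  if (length(miss)) stop("model spec missing fields: ", paste(miss, collapse = ", "))
  species <- as.character(unlist(spec$species))
  pars <- unlist(spec$parameters %||% list())
  pars <- stats::setNames(as.numeric(pars), names(pars))
  inputs <- spec$inputs %||% list()
  eta <- as.numeric(unlist(spec$initial[species]))
  if (anyNA(eta)) stop("initial values missing for some species")
  grid <- as.numeric(unlist(spec$time$grid %||% list()))
  t0 <- spec$time$t0 %||% (if (length(grid)) grid[1L] else 0)

  input_fun <- compile_inputs(inputs)
  f <- compile_map(spec$rates[species], species, pars, names(inputs))
  h <- compile_map(spec$observables, species, pars, names(inputs))

  variants <- lapply(spec$variants %||% list(), function(v) {
    rates <- spec$rates
    for (nm in names(v$rates)) rates[[nm]] <- v$rates[[nm]]
    list(name = v$name, mode = v$mode %||% "remove",
         source = v$source, target = v$target, sign = v$sign %||% "stim",
         rate_strings = rates[species],
         vector_field = compile_map(rates[species], species, pars, names(inputs)))
  })

  m <- ode_model(vector_field = f, measurement_map = h, known_input = input_fun,
                 initial_state = eta, kinetic_params = pars, t0 = t0,
                 species_names = species, obs_names = names(spec$observables),
                 default_grid = if (length(grid)) grid else NULL,
                 name = spec$name %||% "model", variants = variants,
                 rk_steps = spec$rk_steps %||% 8L)
  ## keep the expression strings so the maps can be recompiled when the
  ## kinetic parameters change (see set_kinetic_params)
  m$rate_strings <- spec$rates[species]
  m$obs_strings <- spec$observables
  m$input_names <- names(inputs)
  ## packaged fixtures also ship generated C derivative functions keyed by
  ## model (and variant) name; the sampler's segment integrator uses them
  m$c_key <- spec$name
  m
}

#' Replace a model's kinetic parameters
#'
#' For spec-file models the vector field and measurement map are recompiled
#' with the new values (parameters are baked into the compiled expressions
#' for speed); for models built directly from R functions the parameter
#' vector is simply swapped.
#'
#' @param model a \code{bden_model}.
#' @param params named numeric vector (same names as the current ones).
#' @return The updated model.
#' @export
set_kinetic_params <- function(model, params) {
  stopifnot(inherits(model, "bden_model"),
            identical(sort(names(params)), sort(names(model$kinetic_params))))
  model$kinetic_params <- params[names(model$kinetic_params)]
  if (!is.null(model$rate_strings)) {
    model$vector_field <- compile_map(model$rate_strings, model$species_names,
                                      model$kinetic_params, model$input_names)
    model$measurement_map <- compile_map(model$obs_strings, model$species_names,
                                         model$kinetic_params, model$input_names)
  }
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

compile_inputs <- function(inputs) {
  if (!length(inputs)) return(function(t) numeric(0))
  txt <- paste0("function(t) c(", paste(unlist(inputs), collapse = ", "), ")")
  compiler::cmpfun(eval(parse(text = txt), envir = baseenv()))
}

## Build function(x, u, t, p) from expression strings by generating a flat
## function body (species/inputs bound by position, parameter VALUES baked in
## as numeric constants), then byte-compiling it. One plain function call per
## RHS evaluation keeps the sampler's inner loop cheap.
compile_map <- function(exprs, species, params, input_names) {
  stopifnot(!is.null(exprs))
  bind <- c(
    sprintf("%s <- x[%d]", species, seq_along(species)),
    if (length(params)) sprintf("%s <- %.17g", names(params), unname(params)),
    if (length(input_names)) sprintf("%s <- u[%d]", input_names, seq_along(input_names))
  )
  txt <- paste0("function(x, u, t, p) {\n",
                paste(bind, collapse = "\n"), "\n",
                "c(", paste(unlist(exprs), collapse = ",\n  "), ")\n}")
  compiler::cmpfun(eval(parse(text = txt), envir = baseenv()))
}

#' List structural variants of a model
#'
#' Variants encode a single missing or wrongly included molecular interaction:
#' \code{mode = "remove"} means the variant lacks an interaction the true
#' system has (handing the variant to [bden()] emulates a missing
#' interaction); \code{mode = "add"} means the variant contains a spurious
#' interaction (a wrong interaction). \code{source}/\code{target} name the
#' interacting species and \code{sign} its stimulatory/inhibitory nature.
#'
#' @param model a \code{bden_model}.
#' @return data.frame with one row per variant.
#' @export
model_variants <- function(model) {
  stopifnot(inherits(model, "bden_model"))
  if (!length(model$variants))
    return(data.frame(name = character(0), mode = character(0),
                      source = character(0), target = character(0),
                      sign = character(0)))
  do.call(rbind, lapply(model$variants, function(v)
    data.frame(name = v$name, mode = v$mode, source = v$source,
               target = v$target, sign = v$sign)))
}

#' Extract the nominal model corresponding to a named variant
#'
#' Returns a copy of \code{model} whose vector field is the variant's
#' (structurally altered) one; grid, parameters, measurement map and initial
#' state are shared with the base model.
#'
#' @param model a \code{bden_model} with variants.
#' @param name variant name.
#' @return A \code{bden_model}.
#' @export
variant_model <- function(model, name) {
  stopifnot(inherits(model, "bden_model"))
  idx <- match(name, vapply(model$variants, `[[`, "", "name"))
  if (is.na(idx)) stop("unknown variant '", name, "' for model '", model$name, "'")
  v <- model$variants[[idx]]
  out <- model
  out$vector_field <- v$vector_field
  if (!is.null(v$rate_strings)) out$rate_strings <- v$rate_strings
  if (!is.null(model$c_key)) out$c_key <- paste0(model$c_key, ":", v$name)
  out$name <- paste0(model$name, ":", v$name)
  out$variants <- list()
  out
}
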