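#!/usr/bin/env Rscript
# Developer tool: translate the packaged model-spec files into C derivative
# functions (src/model_derivs.c). Run from the repository root after editing
# any fixture under inst/extdata/models/; the generated file is committed.
# Each fixture and each of its structural variants gets one C function; the
# sampler's segment integrator calls them directly, avoiding an R evaluation
# per right-hand side.

suppressMessages(library(yaml))

expr_to_c <- function(e, species, pars, inputs) {
  rec <- function(x) {
    if (is.numeric(x)) {
      if (x == round(x) && abs(x) < 1e15) return(sprintf("%.1f", x))
      return(sprintf("%.17g", x))
    }
    if (is.symbol(x)) {
      nm <- as.character(x)
      if (nm == "t") return("t")
      i <- match(nm, species); if (!is.na(i)) return(sprintf("x[%d]", i - 1L))
      i <- match(nm, pars); if (!is.na(i)) return(sprintf("p[%d]", i - 1L))
      i <- match(nm, inputs); if (!is.na(i)) return(sprintf("u[%d]", i - 1L))
      stop("unknown symbol in rate expression: ", nm)
    }
    if (is.call(x)) {
      op <- as.character(x[[1L]])
      a <- lapply(as.list(x)[-1L], rec)
      return(switch(op,
        "+" = if (length(a) == 1L) sprintf("(+%s)", a[[1L]]) else
          sprintf("(%s + %s)", a[[1L]], a[[2L]]),
        "-" = if (length(a) == 1L) sprintf("(-%s)", a[[1L]]) else
          sprintf("(%s - %s)", a[[1L]], a[[2L]]),
        "*" = sprintf("(%s * %s)", a[[1L]], a[[2L]]),
        "/" = sprintf("(%s / %s)", a[[1L]], a[[2L]]),
        "^" = sprintf("pow(%s, %s)", a[[1L]], a[[2L]]),
        "(" = sprintf("(%s)", a[[1L]]),
        "exp" = sprintf("exp(%s)", a[[1L]]),
        "log" = sprintf("log(%s)", a[[1L]]),
        "sqrt" = sprintf("sqrt(%s)", a[[1L]]),
        "sin" = sprintf("sin(%s)", a[[1L]]),
        "cos" = sprintf("cos(%s)", a[[1L]]),
        stop("unsupported function in rate expression: ", op)))
    }
    stop("cannot translate: ", deparse(x))
  }
  rec(e)
}

gen_fun <- function(key, id, rates, species, pars, inputs) {
  body <- vapply(seq_along(species), function(i) {
    ex <- parse(text = rates[[species[i]]])[[1L]]
    sprintf("  dx[%d] = %s;", i - 1L, expr_to_c(ex, species, pars, inputs))
  }, character(1L))
  c(sprintf("/* %s */", key),
    sprintf("static void deriv_%d(double t, const double *x, const double *u, const double *p, double *dx)", id),
    "{", "  (void) t; (void) u; (void) p;", body, "}", "")
}

dir_models <- file.path("inst", "extdata", "models")
files <- sort(list.files(dir_models, pattern = "\\.yaml$", full.names = TRUE))
funs <- character(0)
table_entries <- character(0)
id <- 0L
for (fp in files) {
  spec <- yaml::read_yaml(fp)
  species <- as.character(unlist(spec$species))
  pars <- names(spec$parameters)
  inputs <- names(spec$inputs)
  funs <- c(funs, gen_fun(spec$name, id, spec$rates, species, pars, inputs))
  table_entries <- c(table_entries,
                     sprintf('  {"%s", %d, deriv_%d},', spec$name, length(species), id))
  id <- id + 1L
  for (v in spec$variants) {
    rates <- spec$rates
    for (nm in names(v$rates)) rates[[nm]] <- v$rates[[nm]]
    key <- paste0(spec$name, ":", v$name)
    funs <- c(funs, gen_fun(key, id, rates, species, pars, inputs))
    table_entries <- c(table_entries,
                       sprintf('  {"%s", %d, deriv_%d},', key, length(species), id))
    id <- id + 1L
  }
}

out <- c(
  "/* Generated by scripts/gen_model_c.R from inst/extdata/models/ - do not edit. */",
  "#include <math.h>",
  "#include \"model_derivs.h\"",
  "",
  funs,
  "const bden_deriv_entry bden_deriv_table[] = {",
  table_entries,
  "  {0, 0, 0}",
  "};")
writeLines(out, file.path("src", "model_derivs.c"))
cat("wrote src/model_derivs.c with", id, "derivative functions\n")
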