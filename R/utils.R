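## internal helpers

.assertScalarNumber <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  if (x < min)
    stop(sprintf("'%s' must be >= %g (got %g)", name, min, x), call. = FALSE)
  invisible(x)
}

## Booleanize a feature record the way the class catalog sees it.
## For SP+ records GPI anchoring dominates the membrane state (the TM slot
## booleanizes to FALSE), matching the catalog's SP+ factorization into
## GPI-anchored / membrane-spanning / soluble states. SP- records keep their
## TM slot: their signal anchor is the ER-entry signal.
.booleanize <- function(rec) {
  gpi <- isTRUE(rec$gpi_anchor)
  sp <- isTRUE(rec$signal_peptide)
  list(
    signal_peptide = sp,
    n_glyc   = rec$n_glyc_sites > 0,
    o_glyc   = rec$o_glyc_sites > 0,
    disulfide = rec$disulfide_bonds > 0,
    gpi      = gpi,
    tm       = (rec$tm_domains > 0) && !(gpi && sp),
    localization = as.character(rec$localization)
  )
}

## Evaluate a model-document arithmetic expression (applicability or scale)
## against a feature environment. Expressions are trusted (they come from the
## packaged model document) but evaluation is confined to a minimal env.
.evalModelExpr <- function(expr, env) {
  if (is.null(expr) || identical(expr, "")) return(TRUE)
  if (is.logical(expr) || is.numeric(expr)) return(expr)
  eval(parse(text = expr)[[1]], envir = env,
       enclos = baseenv())
}

.featureEnv <- function(bool, rec, options) {
  list2env(list(
    sp  = bool$signal_peptide,
    n   = as.numeric(rec$n_glyc_sites),
    o   = as.numeric(rec$o_glyc_sites),
    ds  = as.numeric(rec$disulfide_bonds),
    tm  = as.numeric(rec$tm_domains),
    g   = as.numeric(isTRUE(rec$gpi_anchor)),
    gpi = isTRUE(rec$gpi_anchor),
    loc = bool$localization,
    route = options$route %||% "CPY",
    f   = options$f_misfold %||% 0,
    erad_branch = options$erad_branch %||% ""
  ), parent = baseenv())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
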