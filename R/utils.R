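#' Round half away from zero
#'
#' Presentation rounding used for report columns: ties go up (25.85 -> 25.9
#' at 1 decimal), unlike [round()], which rounds half to even. Full-precision
#' values are always retained alongside rounded ones; this is only for the
#' printed columns.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# condition constructors: validation failures carry a class so callers can
# map them (schema/reference/value) without parsing messages
stop_schema <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("cpnquant_schema_error", "error", "condition"),
                 list(message = msg, call = call)))
}

stop_reference <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("cpnquant_reference_error", "error", "condition"),
                 list(message = msg, call = call)))
}

stop_value <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("cpnquant_value_error", "error", "condition"),
                 list(message = msg, call = call)))
}

# evaluate expr with a private RNG stream seeded by `seed`, restoring the
# caller's .Random.seed afterwards
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
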