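#' @keywords internal
"_PACKAGE"

# internal validation helpers ------------------------------------------------

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop_config(field, "probabilities must lie in [0, 1]")
  invisible(x)
}

check_pos <- function(x, field, strict = TRUE) {
  ok <- is.numeric(x) && !anyNA(x) && all(if (strict) x > 0 else x >= 0)
  if (!ok) stop_config(field, if (strict) "must be > 0" else "must be >= 0")
  invisible(x)
}

as_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x, format = "%Y-%m-%d")
}

# local RNG scope: run `expr` under `seed` without disturbing the caller's
# random-number stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# round half away from zero, the convention used when printing percentages
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
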