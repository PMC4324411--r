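# internal helpers

# evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

# trapezoidal quadrature mean of y over x
trapz_mean <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  dx <- diff(x)
  sum(dx * (head(y, -1) + tail(y, -1)) / 2) / (x[length(x)] - x[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_arg <- function(...) stop(..., call. = FALSE)
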