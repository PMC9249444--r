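#' @keywords internal
#' @importFrom stats rnorm runif median setNames
#' @importFrom utils read.table write.table relist
#' @importFrom signal resample
"_PACKAGE"

# Run `expr` under `set.seed(seed)` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

stop_mb <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_mb(sprintf("`%s` must be a single finite number", name))
  }
  if (strict_lower) {
    if (x <= lower) stop_mb(sprintf("`%s` must be > %g", name, lower))
  } else if (x < lower) {
    stop_mb(sprintf("`%s` must be >= %g", name, lower))
  }
  if (x > upper) stop_mb(sprintf("`%s` must be <= %g", name, upper))
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  check_number(x, name, lower = lower)
  if (x != round(x)) stop_mb(sprintf("`%s` must be an integer", name))
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
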