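# Internal helpers shared across modules.

#' Evaluate an expression with a temporary, fully specified RNG state
#'
#' All randomized operations in the package take an explicit `seed` and route
#' through this helper, so nothing perturbs (or depends on) the caller's
#' global RNG stream and identical seeds give bit-identical results.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_invalid("seed must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

# classed conditions so callers/tests can distinguish error families
stop_with <- function(class, msg, call. = FALSE) {
  cnd <- structure(
    class = c(class, "sraguide_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cnd)
}

stop_invalid  <- function(msg) stop_with("sraguide_invalid_input", msg)
stop_geometry <- function(msg) stop_with("sraguide_geometry_error", msg)

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v, what = "vector") {
  n <- vnorm(v)
  if (n < 1e-12) stop_invalid(sprintf("zero-length %s cannot be normalized", what))
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# rows of matrix M crossed with a single vector v
cross3_rows <- function(M, v) {
  cbind(M[, 2] * v[3] - M[, 3] * v[2],
        M[, 3] * v[1] - M[, 1] * v[3],
        M[, 1] * v[2] - M[, 2] * v[1])
}
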