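# Small numeric helpers shared across modules.

# Cross product of two 3-vectors.
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vec_norm <- function(v) sqrt(sum(v^2))

# Normalize to unit length; errors on (near-)zero input.
unit_vector <- function(v, what = "vector") {
  n <- vec_norm(v)
  if (!is.finite(n) || n < 1e-300) {
    stop(sprintf("cannot normalize zero-length %s", what), call. = FALSE)
  }
  v / n
}

as_point3 <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 3L || any(!is.finite(p))) {
    stop(sprintf("%s must be a finite numeric 3-vector", what), call. = FALSE)
  }
  p
}

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero (so 4.95 at one
#' decimal becomes 5.0), matching how engineering reports typically print
#' ratios. Base R's [round()] rounds ties to even instead.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' round_half_up(3.086, 1)
#' round_half_up(4.95, 1)
#' @export
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

# Run expr with a fixed, restorable RNG state so generators are reproducible
# without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}
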