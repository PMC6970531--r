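## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run expr with a temporarily seeded RNG; global RNG state is untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## unit-normalize a 3-vector
unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stopf("cannot normalize a zero-length vector")
  v / n
}

## rotation matrix from axis (unit) and angle in degrees (Rodrigues)
rotation_about_axis <- function(axis, angle_deg) {
  a <- unit3(as.numeric(axis))
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

check_rotation <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || any(dim(R) != c(3L, 3L)))
    stopf("rotation must be a 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stopf("matrix is not orthonormal (tolerance %g)", tol)
  if (abs(det(R) - 1) > tol)
    stopf("matrix determinant is %.6f, not +1: improper rotation", det(R))
  invisible(TRUE)
}
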