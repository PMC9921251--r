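# Small shared utilities: seeded evaluation that restores RNG state, random
# rotations, and rotation of parameter vectors.

# evaluate expr under a temporary RNG state; NULL seed = use current stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Uniformly random rotation matrices
#'
#' Samples rotations uniformly over SO(3) from unit quaternions.
#'
#' @param n number of rotations.
#' @param seed optional integer seed.
#' @return list of n orthogonal 3x3 matrices with determinant 1.
#' @export
random_rotations <- function(n, seed = NULL) {
  .with_seed(seed, {
    lapply(seq_len(n), function(i) {
      q <- stats::rnorm(4L)
      q <- q / sqrt(sum(q^2))
      w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
      matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
               2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
               2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
             3L, 3L, byrow = TRUE)
    })
  })
}

# 6x6 Voigt-space representation of conjugation by R: voigt6(R T R') = L voigt6(T)
.rotation_voigt6 <- function(R) {
  L <- matrix(0, 6L, 6L)
  for (i in seq_len(6L)) {
    e <- numeric(6L); e[i] <- 1
    L[, i] <- voigt6(R %*% unvoigt6(e) %*% t(R))
  }
  L
}

#' Rotate a parameter vector
#'
#' Applies the rotation `R` to both the mean tensor and the covariance
#' tensor of `theta = (log S0, d, c)`; all scalar metrics are invariant
#' under this operation.
#'
#' @param theta 28-parameter vector.
#' @param R orthogonal 3x3 rotation matrix.
#' @return rotated 28-parameter vector.
#' @export
rotate_theta <- function(theta, R) {
  stopifnot(length(theta) == 28L)
  L <- .rotation_voigt6(R)
  d <- drop(L %*% theta[.THETA_D])
  C6 <- unvoigt21_mat(theta[.THETA_C])
  c(theta[.THETA_LOGS0], d, voigt21_mat(L %*% C6 %*% t(L)))
}
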