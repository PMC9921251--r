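# Voigt-notation algebra for symmetric second- and fourth-order tensors.
#
# Conventions used throughout the package:
#  * A symmetric 3x3 tensor T is stored as the 6-vector
#      (Txx, Tyy, Tzz, sqrt(2) Tyz, sqrt(2) Txz, sqrt(2) Txy),
#    so that the Euclidean dot product of two 6-vectors equals the full
#    double contraction T:U = sum_ij Tij Uij.
#  * A fourth-order tensor with major and minor symmetry is carried as a
#    symmetric 6x6 matrix in the same basis; its 21-vector form lists the six
#    diagonal entries followed by the fifteen upper-triangle entries (column
#    major) scaled by sqrt(2), so that 21-vector dot products equal the full
#    four-index contraction.  Only inner products are contract-relevant; the
#    ordering is fixed here once and documented.

.SQRT2 <- sqrt(2)

# upper-triangle index pairs of a 6x6 matrix, column-major (15 pairs)
.UT6 <- which(upper.tri(diag(6)), arr.ind = TRUE)

#' Voigt 6-vector of a symmetric 3x3 tensor
#'
#' Components are ordered (xx, yy, zz, yz, xz, xy) with the three cross terms
#' scaled by \eqn{\sqrt{2}} so that `sum(voigt6(T) * voigt6(U))` equals the
#' double contraction \eqn{T:U}.
#'
#' @param T symmetric 3x3 numeric matrix.
#' @param tol symmetry tolerance.
#' @return numeric vector of length 6.
#' @seealso [unvoigt6()], [voigt21_outer()]
#' @export
#' @examples
#' voigt6(diag(3))
voigt6 <- function(T, tol = 1e-10) {
  stopifnot(is.matrix(T), all(dim(T) == c(3L, 3L)))
  if (max(abs(T - t(T))) > tol * max(1, max(abs(T))))
    stop("voigt6(): input tensor is not symmetric")
  c(T[1L, 1L], T[2L, 2L], T[3L, 3L],
    .SQRT2 * T[2L, 3L], .SQRT2 * T[1L, 3L], .SQRT2 * T[1L, 2L])
}

#' Rebuild a symmetric 3x3 tensor from its Voigt 6-vector
#'
#' Inverse of [voigt6()]; the round trip is lossless.
#'
#' @param v numeric vector of length 6.
#' @return symmetric 3x3 matrix.
#' @export
unvoigt6 <- function(v) {
  stopifnot(length(v) == 6L)
  yz <- v[4L] / .SQRT2; xz <- v[5L] / .SQRT2; xy <- v[6L] / .SQRT2
  matrix(c(v[1L], xy, xz,
           xy, v[2L], yz,
           xz, yz, v[3L]), 3L, 3L)
}

# 21-vector of a symmetric 6x6 (Voigt-basis) matrix, and its inverse.
# Internal: fourth-order objects cross the API as 21-vectors only.
voigt21_mat <- function(M) {
  c(diag(M), .SQRT2 * M[.UT6])
}

unvoigt21_mat <- function(v) {
  stopifnot(length(v) == 21L)
  M <- diag(v[1L:6L])
  M[.UT6] <- v[7L:21L] / .SQRT2
  M[.UT6[, c(2L, 1L)]] <- v[7L:21L] / .SQRT2
  M
}

#' Voigt 21-vector of the outer square of a symmetric tensor
#'
#' Returns the fourth-order tensor \eqn{T \otimes T} as a 21-vector whose
#' normalization is fixed by the contraction-fidelity requirement
#' \deqn{\langle v_{21}(P \otimes P),\ v_{21}(Q \otimes Q)\rangle = (P:Q)^2,}
#' i.e. vector inner products equal full four-index tensor contractions.
#'
#' @param T symmetric 3x3 matrix.
#' @return numeric vector of length 21.
#' @export
voigt21_outer <- function(T) {
  v <- voigt6(T)
  voigt21_mat(tcrossprod(v))
}

#' Isotropic fourth-order basis tensors
#'
#' `e_bulk()` and `e_shear()` return the two constant fourth-order tensors
#' (as 21-vectors) that project a second-moment tensor onto its bulk
#' (squared-mean-diffusivity) and shear (eigenvalue-spread) parts.  For a
#' single tensor D with eigenvalues \eqn{\lambda_i},
#' \eqn{\langle E_{bulk}, D^{\otimes 2}\rangle = (\mathrm{tr} D / 3)^2} and
#' \eqn{\langle E_{shear}, D^{\otimes 2}\rangle = \frac{1}{9}\sum_{i<j}
#' (\lambda_i - \lambda_j)^2}.
#'
#' @return numeric vector of length 21.
#' @export
e_bulk <- function() {
  M <- matrix(0, 6L, 6L)
  M[1L:3L, 1L:3L] <- 1 / 9
  voigt21_mat(M)
}

#' @rdname e_bulk
#' @export
e_shear <- function() {
  M <- matrix(0, 6L, 6L)
  M[1L:3L, 1L:3L] <- -1 / 9
  diag(M) <- c(2, 2, 2, 3, 3, 3) / 9
  voigt21_mat(M)
}

# 6x6 matrix forms, precomputed for quadratic forms d' E d
.E_BULK_M <- local({ M <- matrix(0, 6L, 6L); M[1L:3L, 1L:3L] <- 1 / 9; M })
.E_SHEAR_M <- local({
  M <- matrix(0, 6L, 6L); M[1L:3L, 1L:3L] <- -1 / 9
  diag(M) <- c(2, 2, 2, 3, 3, 3) / 9; M
})

#' Construct an axisymmetric b-tensor
#'
#' Builds the symmetric 3x3 b-tensor with principal axis `g`, total
#' diffusion weighting (trace) `b` and shape parameter `bdelta`:
#' \deqn{B = b\left(\frac{1 - b_\Delta}{3} I + b_\Delta\, g g^T\right),}
#' so its eigenvalues are the radial value \eqn{b_\perp = b(1-b_\Delta)/3}
#' (twice) and the axial value \eqn{b_\parallel = b(1+2b_\Delta)/3}.
#' `bdelta = 1` is linear (LTE), `0` spherical (STE), `-0.5` planar (PTE)
#' encoding.
#'
#' @param g unit 3-vector (principal axis).
#' @param b b-value, ms/um^2, non-negative.
#' @param bdelta b-tensor anisotropy, in \[-0.5, 1\].
#' @return symmetric 3x3 matrix with trace `b`.
#' @export
#' @examples
#' btensor_from_shape(c(0, 0, 1), 1, 1)     # linear encoding: diag(0, 0, 1)
#' btensor_from_shape(c(1, 0, 0), 1, 0)     # spherical encoding: I/3
btensor_from_shape <- function(g, b, bdelta) {
  stopifnot(length(g) == 3L, length(b) == 1L, length(bdelta) == 1L)
  if (abs(sum(g^2) - 1) > 1e-8)
    stop("btensor_from_shape(): direction g must be unit norm")
  if (b < 0) stop("btensor_from_shape(): b must be non-negative")
  if (bdelta < -0.5 - 1e-12 || bdelta > 1 + 1e-12)
    stop("btensor_from_shape(): bdelta must lie in [-0.5, 1]")
  b * ((1 - bdelta) / 3 * diag(3) + bdelta * tcrossprod(g))
}

#' Recover (b, bdelta) from an axisymmetric b-tensor
#'
#' Inverts [btensor_from_shape()] via the eigenvalues: `b` is the trace and
#' `bdelta = (bpar - bperp) / b` where the axial eigenvalue is the one of
#' multiplicity one.  At the spherical point the shape is reported as 0.
#'
#' @param B symmetric 3x3 matrix.
#' @param tol eigenvalue-degeneracy tolerance (relative to `b`).
#' @return list with elements `b`, `bdelta`, and `axis` (unit 3-vector; the
#'   stored principal axis is meaningless when `bdelta` is 0).
#' @export
btensor_shape <- function(B, tol = 1e-8) {
  ev <- eigen(B, symmetric = TRUE)
  lam <- ev$values                      # decreasing
  b <- sum(lam)
  s <- max(abs(lam), 1e-300)
  if (abs(lam[1L] - lam[3L]) <= tol * s) {
    return(list(b = b, bdelta = 0, axis = c(0, 0, 1)))
  }
  # axial eigenvalue: the isolated one
  if (abs(lam[1L] - lam[2L]) > abs(lam[2L] - lam[3L])) {
    bpar <- lam[1L]; bperp <- (lam[2L] + lam[3L]) / 2; ax <- ev$vectors[, 1L]
  } else {
    bpar <- lam[3L]; bperp <- (lam[1L] + lam[2L]) / 2; ax <- ev$vectors[, 3L]
  }
  list(b = b, bdelta = (bpar - bperp) / (bpar + 2 * bperp), axis = ax)
}
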