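# The two-term cumulant model of the diffusion tensor distribution (DTD):
#   S(B) = S0 exp(-B:<D> + 1/2 B⊗2 : C)
# parametrized by theta = (log S0, d, c) with d the Voigt 6-vector of the
# mean tensor <D> (um^2/ms) and c the Voigt 21-vector of the fourth-order
# covariance tensor C ((um^2/ms)^2); 28 parameters in total.

.THETA_LOGS0 <- 1L
.THETA_D <- 2L:7L
.THETA_C <- 8L:28L

# exponent clip for forward_signal; far outside any physical regime
.EXP_CLIP <- 700

#' Acquisition scheme constructor
#'
#' An acquisition scheme is the N x 5 experimental description of a
#' tensor-valued diffusion acquisition: per sample a unit principal-axis
#' direction, a b-value (ms/um^2) and a b-tensor anisotropy in \[-0.5, 1\].
#'
#' @param directions N x 3 matrix of unit row vectors.
#' @param b numeric N-vector of b-values, ms/um^2, non-negative.
#' @param bdelta numeric N-vector of b-tensor anisotropies in \[-0.5, 1\].
#' @return object of class `"acquisition_scheme"`: a list with elements
#'   `directions`, `b`, `bdelta`.
#' @export
#' @examples
#' acquisition_scheme(diag(3), b = c(1, 1, 2), bdelta = c(1, 0, -0.5))
acquisition_scheme <- function(directions, b, bdelta) {
  directions <- as.matrix(directions)
  b <- as.numeric(b); bdelta <- as.numeric(bdelta)
  n <- nrow(directions)
  stopifnot(ncol(directions) == 3L, length(b) == n, length(bdelta) == n, n >= 1L)
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-8)) {
    if (any(abs(nrm - 1) > 1e-3))
      stop("acquisition_scheme(): direction rows must be unit norm")
    directions <- directions / nrm
  }
  if (any(b < 0)) stop("acquisition_scheme(): b-values must be non-negative")
  if (any(bdelta < -0.5 - 1e-12 | bdelta > 1 + 1e-12))
    stop("acquisition_scheme(): bdelta must lie in [-0.5, 1]")
  structure(list(directions = directions, b = b, bdelta = bdelta),
            class = "acquisition_scheme")
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  n <- length(x$b)
  cat(sprintf("Acquisition scheme: %d samples\n", n))
  key <- paste(signif(x$b, 3), signif(x$bdelta, 3))
  tab <- table(key)
  cat("  shells (b bdelta : count):\n")
  for (k in names(tab)) cat(sprintf("    %s : %d\n", k, tab[[k]]))
  invisible(x)
}

#' Number of samples in a scheme
#' @param scheme an [acquisition_scheme()].
#' @return integer sample count.
#' @export
n_samples <- function(scheme) length(scheme$b)

#' Assemble a 28-parameter vector
#'
#' @param S0 unweighted signal (positive scalar).
#' @param d Voigt 6-vector of the mean diffusion tensor, um^2/ms.
#' @param c21 Voigt 21-vector of the covariance tensor, (um^2/ms)^2.
#' @return numeric vector of length 28 `(log S0, d, c)`.
#' @export
qti_theta <- function(S0 = 1, d = numeric(6), c21 = numeric(21)) {
  stopifnot(length(d) == 6L, length(c21) == 21L, S0 > 0)
  c(log(S0), as.numeric(d), as.numeric(c21))
}

#' Model-matrix row for one b-tensor
#'
#' Returns the 28-vector `a(B) = (1, -voigt6(B), 1/2 voigt21_outer(B))`,
#' so that `sum(a(B) * theta) = log S0 - B:<D> + 1/2 B⊗2:C`.
#'
#' @param B symmetric 3x3 b-tensor.
#' @return numeric vector of length 28.
#' @export
design_row <- function(B) {
  c(1, -voigt6(B), 0.5 * voigt21_outer(B))
}

#' Model (design) matrix of an acquisition scheme
#'
#' Stacks [design_row()] over all samples of the scheme; row i corresponds to
#' the b-tensor `btensor_from_shape(g_i, b_i, bdelta_i)`.
#'
#' @param scheme an [acquisition_scheme()].
#' @return N x 28 numeric matrix.
#' @export
design_matrix <- function(scheme) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  g <- scheme$directions; b <- scheme$b; bd <- scheme$bdelta
  iso <- b * (1 - bd) / 3
  # voigt6 components of each row's b-tensor, vectorized over samples
  v6 <- cbind(iso + b * bd * g[, 1L]^2,
              iso + b * bd * g[, 2L]^2,
              iso + b * bd * g[, 3L]^2,
              .SQRT2 * b * bd * g[, 2L] * g[, 3L],
              .SQRT2 * b * bd * g[, 1L] * g[, 3L],
              .SQRT2 * b * bd * g[, 1L] * g[, 2L])
  v21 <- cbind(v6^2, .SQRT2 * v6[, .UT6[, 1L], drop = FALSE] *
                 v6[, .UT6[, 2L], drop = FALSE])
  cbind(1, -v6, 0.5 * v21, deparse.level = 0)
}

#' Cumulant-model signal prediction
#'
#' Evaluates `exp(A theta)` for the scheme's model matrix A.  Exponents are
#' clipped at +/-700 to avoid overflow (the number of clipped entries is
#' attached as attribute `"clipped"` when non-zero).
#'
#' @param theta 28-parameter vector.
#' @param scheme an [acquisition_scheme()], or a precomputed N x 28 model
#'   matrix.
#' @return strictly positive N-vector of signal values.
#' @export
forward_signal <- function(theta, scheme) {
  stopifnot(length(theta) == 28L, all(is.finite(theta)))
  A <- if (is.matrix(scheme)) scheme else design_matrix(scheme)
  eta <- drop(A %*% theta)
  nclip <- sum(eta > .EXP_CLIP | eta < -.EXP_CLIP)
  if (nclip > 0L) {
    eta <- pmin(pmax(eta, -.EXP_CLIP), .EXP_CLIP)
    s <- exp(eta)
    attr(s, "clipped") <- nclip
    return(s)
  }
  exp(eta)
}

#' Discrete diffusion tensor distribution
#'
#' A weighted finite mixture of microscopic Gaussian diffusion tensors,
#' used as ground truth generator and exact signal oracle.
#'
#' @param weights K-vector of non-negative weights summing to 1.
#' @param tensors list of K symmetric positive semidefinite 3x3 matrices
#'   (um^2/ms).
#' @return object of class `"discrete_dtd"`.
#' @export
discrete_dtd <- function(weights, tensors) {
  weights <- as.numeric(weights)
  stopifnot(is.list(tensors), length(weights) == length(tensors),
            length(weights) >= 1L)
  if (any(weights < -1e-12)) stop("discrete_dtd(): weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-10)
    stop("discrete_dtd(): weights must sum to 1")
  for (D in tensors) {
    if (!isTRUE(all.equal(D, t(D), tolerance = 1e-9)))
      stop("discrete_dtd(): component tensors must be symmetric")
    if (min(eigen(D, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      stop("discrete_dtd(): component tensors must be positive semidefinite")
  }
  structure(list(weights = weights, tensors = tensors), class = "discrete_dtd")
}

#' First two moments of a discrete DTD
#'
#' Computes the Voigt 6-vector of the mean tensor and the Voigt 21-vector of
#' the fourth-order covariance tensor
#' \eqn{C = \langle D^{\otimes 2}\rangle - \langle D\rangle^{\otimes 2}}.
#' The covariance is positive semidefinite by construction (it is a
#' weighted covariance of the component 6-vectors).
#'
#' @param dtd a [discrete_dtd()].
#' @return list with elements `d` (length 6) and `c21` (length 21).
#' @export
moments_from_mixture <- function(dtd) {
  stopifnot(inherits(dtd, "discrete_dtd"))
  V <- vapply(dtd$tensors, voigt6, numeric(6L))      # 6 x K
  w <- dtd$weights
  dbar <- drop(V %*% w)
  S2 <- (V * rep(w, each = 6L)) %*% t(V)             # sum_k w_k v_k v_k'
  C6 <- S2 - tcrossprod(dbar)
  list(d = dbar, c21 = voigt21_mat(C6))
}

#' Exact multi-Gaussian mixture signal
#'
#' The signal of a discrete DTD probed with the scheme's b-tensors,
#' `S0 * sum_k w_k exp(-B:D_k)`.  This is exact (no cumulant truncation) and
#' serves as the oracle against which the cumulant model is a low-b
#' approximation.
#'
#' @param dtd a [discrete_dtd()].
#' @param S0 unweighted signal.
#' @param scheme an [acquisition_scheme()].
#' @return N-vector of signal values.
#' @export
mixture_signal <- function(dtd, S0, scheme) {
  stopifnot(inherits(dtd, "discrete_dtd"), inherits(scheme, "acquisition_scheme"))
  A <- design_matrix(scheme)
  Bv <- -A[, .THETA_D, drop = FALSE]                 # N x 6 voigt6 of b-tensors
  V <- vapply(dtd$tensors, voigt6, numeric(6L))      # 6 x K
  E <- exp(-Bv %*% V)                                # N x K, entries exp(-B:Dk)
  drop(S0 * (E %*% dtd$weights))
}

#' Scalar DTD metrics from a parameter vector
#'
#' Derives the standard rotation-invariant DTD measures from
#' `theta = (log S0, d, c)`.  With `Vbulk = <d⊗2, E_bulk> = MD^2`,
#' `Vshear = <d⊗2, E_shear>`, and second moments `<D⊗2> = d⊗2 + c`:
#' \itemize{
#'   \item `md`: mean diffusivity `(d1+d2+d3)/3`, um^2/ms;
#'   \item `fa`: fractional anisotropy
#'     `sqrt(3/2) sqrt(Vshear / (Vbulk + Vshear))`;
#'   \item `ufa`: microscopic FA, same form evaluated on `<D⊗2>`;
#'   \item `mki`: isotropic kurtosis `3 <c, E_bulk> / MD^2`;
#'   \item `mka`: anisotropic kurtosis `(6/5) <c, E_shear> / MD^2`;
#'   \item `mk`: total mean kurtosis `mki + mka` (exact identity);
#'   \item `op`: order parameter `sqrt(Vshear / Vshear2)` (0 when the
#'     micro-shear `Vshear2` vanishes);
#'   \item `cc`: orientation-coherence index `fa^2 / ufa^2` (0 when `ufa`
#'     is 0).
#' }
#' For non-positive MD (possible in noisy fits) all metrics are returned as
#' `NaN` with a warning rather than an error.
#'
#' @param theta 28-parameter vector.
#' @return named numeric vector with elements
#'   `md, fa, ufa, mki, mka, mk, op, cc`.
#' @export
scalar_metrics <- function(theta) {
  stopifnot(length(theta) == 28L)
  d <- theta[.THETA_D]; c21 <- theta[.THETA_C]
  md <- (d[1L] + d[2L] + d[3L]) / 3
  if (!is.finite(md) || md <= 0) {
    warning("scalar_metrics(): non-positive mean diffusivity; metrics are NaN")
    return(c(md = NaN, fa = NaN, ufa = NaN, mki = NaN, mka = NaN, mk = NaN,
             op = NaN, cc = NaN))
  }
  vbulk_m <- md^2
  # clamp tiny negative rounding residue; shear variances below 1e-12 of
  # the bulk scale are treated as exactly zero (degenerate isotropic case)
  vshear_m <- max(drop(crossprod(d, .E_SHEAR_M %*% d)), 0)
  cb <- sum(c21 * .E_BULK_V); cs <- sum(c21 * .E_SHEAR_V)
  vbulk2 <- vbulk_m + cb
  vshear2 <- vshear_m + cs
  eps2 <- 1e-12 * vbulk_m
  fa <- sqrt(1.5 * vshear_m / (vbulk_m + vshear_m))
  ufa <- if (vbulk2 + vshear2 > 0 && vshear2 > eps2)
    sqrt(1.5 * vshear2 / (vbulk2 + vshear2)) else 0
  mki <- 3 * cb / vbulk_m
  mka <- 1.2 * cs / vbulk_m
  op <- if (vshear2 > eps2) sqrt(vshear_m / vshear2) else 0
  cc <- if (ufa > 0) fa^2 / ufa^2 else 0
  c(md = md, fa = fa, ufa = ufa, mki = mki, mka = mka, mk = mki + mka,
    op = op, cc = cc)
}

.E_BULK_V <- local({ M <- matrix(0, 6L, 6L); M[1L:3L, 1L:3L] <- 1 / 9
  c(diag(M), sqrt(2) * M[which(upper.tri(diag(6)), arr.ind = TRUE)]) })
.E_SHEAR_V <- local({ M <- matrix(0, 6L, 6L); M[1L:3L, 1L:3L] <- -1 / 9
  diag(M) <- c(2, 2, 2, 3, 3, 3) / 9
  c(diag(M), sqrt(2) * M[which(upper.tri(diag(6)), arr.ind = TRUE)]) })

#' Axisymmetric microscopic diffusion tensor
#'
#' Convenience constructor for a cylindrically symmetric tensor with axial
#' diffusivity `ad` and radial diffusivity `rd` about `axis`.
#'
#' @param ad axial diffusivity, um^2/ms.
#' @param rd radial diffusivity, um^2/ms.
#' @param axis unit 3-vector.
#' @return symmetric 3x3 matrix.
#' @export
axisym_tensor <- function(ad, rd, axis = c(0, 0, 1)) {
  axis <- axis / sqrt(sum(axis^2))
  rd * diag(3) + (ad - rd) * tcrossprod(axis)
}

#' Parameter vector of a discrete DTD
#'
#' Shorthand for `qti_theta(S0, moments)`.
#'
#' @param dtd a [discrete_dtd()].
#' @param S0 unweighted signal.
#' @return numeric vector of length 28.
#' @export
theta_from_dtd <- function(dtd, S0 = 1) {
  m <- moments_from_mixture(dtd)
  qti_theta(S0, m$d, m$c21)
}
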