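# Estimators of the 28 cumulant-model parameters from one signal vector:
# unconstrained LLS / WLLS / IWLLS / NLS and the constrained CIWLLS family,
# where every weighted solve becomes a convex quadratic program over a set
# of stacked linear inequalities on (d, c).

.fit_result <- function(theta, A, estimator, iterations = 1L,
                        status = "converged", dropped = 0L,
                        active = integer(0)) {
  theta <- as.numeric(theta)
  structure(list(theta = theta,
                 predicted = forward_signal(theta, A),
                 estimator = estimator,
                 iterations = iterations,
                 status = status,
                 dropped = dropped,
                 active = active),
            class = "qti_fit")
}

#' @export
print.qti_fit <- function(x, ...) {
  cat(sprintf("qti fit [%s]: status %s, %d iteration(s)\n",
              x$estimator, x$status, x$iterations))
  m <- suppressWarnings(scalar_metrics(x$theta))
  cat(sprintf("  S0 = %.4g, MD = %.4g, FA = %.4g, uFA = %.4g, MKi = %.4g, MKa = %.4g\n",
              exp(x$theta[1L]), m["md"], m["fa"], m["ufa"], m["mki"], m["mka"]))
  if (length(x$active)) cat(sprintf("  active constraints: %d\n", length(x$active)))
  invisible(x)
}

# drop non-positive samples for log-domain fits; returns index vector
.log_keep <- function(s) {
  keep <- which(is.finite(s) & s > 0)
  nd <- length(s) - length(keep)
  if (nd > 0L)
    warning(sprintf("%d non-positive signal sample(s) dropped from log-domain fit", nd))
  keep
}

.check_rank <- function(A) {
  q <- qr(A)
  if (q$rank < ncol(A))
    stop(sprintf("model matrix is rank deficient (rank %d < %d)", q$rank, ncol(A)))
  q
}

.as_A <- function(scheme) if (is.matrix(scheme)) scheme else design_matrix(scheme)

#' Ordinary linear least squares fit
#'
#' Minimizes `||log s - A theta||^2` via QR factorization.  Non-positive
#' signal entries are dropped with a warning.
#'
#' @param s positive N-vector of signals.
#' @param A N x 28 model matrix (or an [acquisition_scheme()]).
#' @return a `"qti_fit"` object with elements `theta`, `predicted`,
#'   `estimator`, `iterations`, `status`, `dropped`, `active`.
#' @export
lls_fit <- function(s, A) {
  A <- .as_A(A)
  keep <- .log_keep(s)
  if (length(keep) < ncol(A)) stop("lls_fit(): need at least 28 usable samples")
  q <- .check_rank(A[keep, , drop = FALSE])
  theta <- qr.coef(q, log(s[keep]))
  .fit_result(theta, A, "lls", dropped = length(s) - length(keep))
}

# weighted solve on the row-scaled system (QR, not normal equations)
.wls_theta <- function(A, y, wsqrt) {
  qr.coef(qr(A * wsqrt), y * wsqrt)
}

#' Weighted linear least squares fit
#'
#' Heteroscedasticity-corrected log-domain fit: the variance of `log s` is
#' proportional to `1/s^2`, so the squared residuals are weighted by `s^2`
#' with `s` the observed (noisy) signal.
#'
#' @inheritParams lls_fit
#' @export
wlls_fit <- function(s, A) {
  f <- iwlls_fit(s, A, nmax = 1L)
  f$estimator <- "wlls"
  f
}

#' Iteratively reweighted linear least squares fit
#'
#' Iteration 1 uses observed-signal weights (identical to [wlls_fit()]);
#' each subsequent iteration n rebuilds the weights from the previous
#' prediction `exp(A theta)` and re-solves.  Two iterations are the default:
#' one reweighting from predictions.
#'
#' @inheritParams lls_fit
#' @param nmax number of weighted solves (`nmax = 1` is exactly WLLS).
#' @param w0 optional initial weight vector overriding the observed-signal
#'   weights `s^2` (mainly for validation; `w0 = 1` with `nmax = 1`
#'   reproduces [lls_fit()]).
#' @export
iwlls_fit <- function(s, A, nmax = 2L, w0 = NULL) {
  A <- .as_A(A)
  keep <- .log_keep(s)
  if (length(keep) < ncol(A)) stop("iwlls_fit(): need at least 28 usable samples")
  Ak <- A[keep, , drop = FALSE]
  .check_rank(Ak)
  y <- log(s[keep])
  wsqrt <- if (is.null(w0)) s[keep] else { stopifnot(all(w0 > 0)); rep_len(sqrt(w0), length(keep)) }
  theta <- .wls_theta(Ak, y, wsqrt)
  status <- "converged"; used <- 1L
  if (nmax > 1L) for (it in 2L:nmax) {
    pred <- exp(pmin(pmax(drop(Ak %*% theta), -.EXP_CLIP), .EXP_CLIP))
    th2 <- .wls_theta(Ak, y, pred)
    if (any(!is.finite(th2))) { status <- "max_iter"; break }
    theta <- th2; used <- it
  }
  .fit_result(theta, A, "iwlls", iterations = used, status = status,
              dropped = length(s) - length(keep))
}

#' Unweighted nonlinear least squares fit
#'
#' Minimizes `||s - exp(A theta)||^2` by a damped Gauss-Newton /
#' Levenberg-Marquardt scheme with analytic Jacobian
#' `diag(exp(A theta)) A`, converged when the gradient norm falls below
#' `1e-8` or the step below `1e-10` (at most 200 iterations).
#'
#' @inheritParams lls_fit
#' @param theta0 starting values; defaults to the LLS solution.
#' @export
nls_fit <- function(s, A, theta0 = NULL) {
  A <- .as_A(A)
  if (is.null(theta0)) theta0 <- lls_fit(s, A)$theta
  stopifnot(length(theta0) == 28L, all(is.finite(theta0)))
  r <- .nls_lm_batch(A, matrix(s, ncol = 1L), matrix(theta0, ncol = 1L))
  .fit_result(r$theta[, 1L], A, "nls", iterations = r$niter[1L],
              status = if (r$status[1L] == 0L) "converged" else "max_iter")
}

#' Linear inequality constraints for constrained estimation
#'
#' Realizes the three constraint combinations used by the CIWLLS estimators
#' as stacked linear inequalities `G theta <= h` on the (d, c) blocks,
#' discretized over a finite antipodally symmetric direction set U:
#' \itemize{
#'   \item variant 1: non-negative directional diffusivity
#'     `<u u', D> >= 0` and non-negative directional covariance
#'     `<(u u')⊗2, C> >= 0` for every u in U;
#'   \item variant 2: directional diffusivity plus monotonic signal decay
#'     at the maximum b-value, `<(u u')⊗2, C> - b_max <u u', D> <= 0`
#'     (directional covariance positivity is then implied, not stacked);
#'   \item variant 3: variant 2 plus non-negative isotropic and anisotropic
#'     kurtosis, `<E_bulk, C> >= 0` and `<E_shear, C> >= 0`.
#' }
#' The log-S0 column always has zero coefficients.
#'
#' @param directions matrix of unit row 3-vectors (at least 30 recommended),
#'   e.g. from [electrostatic_directions()].
#' @param variant integer 1, 2 or 3.
#' @param b_max maximum b-value of the acquisition, ms/um^2 (used by the
#'   monotonic-decay rows of variants 2 and 3).
#' @return object of class `"qti_constraints"`: list with `G` (rows x 28),
#'   `h`, `directions`, `variant`, `b_max`.
#' @export
build_constraints <- function(directions, variant, b_max = 2) {
  directions <- as.matrix(directions)
  stopifnot(ncol(directions) == 3L, b_max > 0)
  if (!variant %in% 1:3) stop("build_constraints(): unknown variant (use 1, 2 or 3)")
  directions <- directions / sqrt(rowSums(directions^2))
  nu <- nrow(directions)
  V6 <- t(apply(directions, 1L, function(u) voigt6(tcrossprod(u))))   # nu x 6
  V21 <- t(apply(directions, 1L, function(u) voigt21_outer(tcrossprod(u))))
  zero6 <- matrix(0, nu, 6L); zero21 <- matrix(0, nu, 21L)
  d_rows <- cbind(0, -V6, zero21)                     # -<uu',d> <= 0
  rows <- switch(variant,
    rbind(d_rows, cbind(0, zero6, -V21)),             # variant 1
    rbind(d_rows, cbind(0, -b_max * V6, V21)),        # variant 2
    rbind(d_rows, cbind(0, -b_max * V6, V21),         # variant 3
          rbind(c(0, numeric(6L), -e_bulk()),
                c(0, numeric(6L), -e_shear()))))
  structure(list(G = rows, h = numeric(nrow(rows)),
                 directions = directions, variant = as.integer(variant),
                 b_max = b_max),
            class = "qti_constraints")
}

#' Default constraint direction set for a scheme
#'
#' Sixty electrostatic-repulsion directions (fixed seed) plus the scheme's
#' own principal axes.
#'
#' @param scheme an [acquisition_scheme()] or `NULL`.
#' @param n number of electrostatic directions.
#' @return matrix of unit row vectors.
#' @export
constraint_directions <- function(scheme = NULL, n = 60L) {
  U <- electrostatic_directions(n, seed = 20221223L)
  if (!is.null(scheme)) U <- rbind(U, scheme$directions)
  U
}

#' Constrained iteratively reweighted linear least squares fit
#'
#' Same iteration structure as [iwlls_fit()], but each weighted solve is
#' replaced by the convex quadratic program
#' `min ||W^{1/2}(log s - A theta)||^2` subject to `G theta <= h`.
#' When the unconstrained solution of an iteration is already feasible it is
#' kept unchanged.  A quadratic-programming failure falls back to the
#' unconstrained iterate with status `"infeasible-fallback"`.
#'
#' @inheritParams iwlls_fit
#' @param constraints a `"qti_constraints"` object from [build_constraints()].
#' @param tol feasibility tolerance for the QP.
#' @export
ciwlls_fit <- function(s, A, constraints, nmax = 2L, tol = 1e-9) {
  A <- .as_A(A)
  stopifnot(inherits(constraints, "qti_constraints"))
  keep <- .log_keep(s)
  if (length(keep) < ncol(A)) stop("ciwlls_fit(): need at least 28 usable samples")
  .check_rank(A[keep, , drop = FALSE])
  r <- .ciwlls_batch(A[keep, , drop = FALSE],
                     matrix(s[keep], ncol = 1L),
                     constraints$G, constraints$h, as.integer(nmax), tol)
  status <- c("converged", "max_iter", "infeasible-fallback")[r$status[1L] + 1L]
  if (r$status[1L] == 2L)
    warning("ciwlls_fit(): QP solver failed; returning unconstrained iterate")
  theta <- r$theta[, 1L]
  active <- if (r$nactive[1L] > 0L) {
    viol <- drop(constraints$G %*% theta) - constraints$h
    which(viol > -1e-7)
  } else integer(0)
  .fit_result(theta, A, paste0("ciwlls", constraints$variant),
              iterations = nmax, status = status,
              dropped = length(s) - length(keep),
              active = active)
}

#' Fit one signal vector with a named estimator
#'
#' Dispatches on the estimator name: `"lls"`, `"wlls"`, `"iwlls"`, `"nls"`,
#' `"ciwlls1"`, `"ciwlls2"`, `"ciwlls3"`.  Constrained fits build their
#' default constraint set from the scheme ([constraint_directions()] with
#' `b_max = max(b)`).
#'
#' @param s positive N-vector of signals.
#' @param scheme an [acquisition_scheme()].
#' @param estimator estimator name.
#' @param constraints optional `"qti_constraints"` overriding the default.
#' @param ... passed to the underlying fitter.
#' @return a `"qti_fit"` object.
#' @export
fit_qti <- function(s, scheme, estimator = "iwlls", constraints = NULL, ...) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  A <- design_matrix(scheme)
  switch(estimator,
    lls = lls_fit(s, A),
    wlls = wlls_fit(s, A),
    iwlls = iwlls_fit(s, A, ...),
    nls = nls_fit(s, A, ...),
    ciwlls1 = ,
    ciwlls2 = ,
    ciwlls3 = {
      v <- as.integer(substring(estimator, 7L))
      if (is.null(constraints))
        constraints <- build_constraints(constraint_directions(scheme), v,
                                         b_max = max(scheme$b))
      ciwlls_fit(s, A, constraints, ...)
    },
    stop(sprintf("fit_qti(): unknown estimator '%s'", estimator)))
}

#' Solve an inequality-constrained convex quadratic program
#'
#' Minimizes `0.5 t(x) H x - t(f) x` subject to `G x <= h` for symmetric
#' positive-definite `H`, by a primal active-set method.  Exposed for
#' validation and reuse; the constrained estimators call it internally.
#'
#' @param H p x p symmetric positive-definite matrix.
#' @param f length-p vector.
#' @param G m x p constraint matrix.
#' @param h length-m right-hand side.
#' @param tol feasibility/multiplier tolerance.
#' @param maxit maximum active-set changes.
#' @return list with `solution`, `lambda` (Karush-Kuhn-Tucker multipliers),
#'   `active` (1-based active-row indices), `iterations`, `converged`.
#' @export
solve_qp <- function(H, f, G, h, tol = 1e-9, maxit = 500L) {
  stopifnot(is.matrix(H), is.matrix(G), nrow(H) == ncol(H),
            ncol(G) == nrow(H), length(f) == nrow(H), length(h) == nrow(G))
  out <- .qp_active_set(H, as.numeric(f), G, as.numeric(h), tol,
                        as.integer(maxit))
  out$solution <- drop(out$solution)
  out$lambda <- drop(out$lambda)
  out$active <- drop(out$active)
  out
}
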