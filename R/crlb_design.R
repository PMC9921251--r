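# Fisher information and Cramer-Rao lower bounds for the cumulant model,
# design criteria on raw parameters (log-determinant) and derived metrics
# (weighted CRLB trace), and the acquisition-scheme optimizer: fixed
# electrostatic directions, pattern search over (b, bdelta), shell
# clustering.

#' Fisher information matrix of the cumulant model
#'
#' For independent zero-mean Gaussian noise with standard deviation `sigma`,
#' `I(theta) = (1/sigma^2) t(A) diag(s)^2 A` with `s = exp(A theta)`.
#'
#' @param theta 28-parameter vector.
#' @param scheme an [acquisition_scheme()] or precomputed model matrix.
#' @param sigma noise standard deviation (signal units), positive.
#' @return 28 x 28 symmetric matrix with attribute `"sigma"`.
#' @export
fisher_information <- function(theta, scheme, sigma) {
  stopifnot(sigma > 0)
  A <- .as_A(scheme)
  s <- forward_signal(theta, A)
  I <- crossprod(as.numeric(s) * A) / sigma^2
  attr(I, "sigma") <- sigma
  I
}

# metric values as a plain vector in a fixed name order
.metric_values <- function(theta, metrics) {
  m <- suppressWarnings(scalar_metrics(theta))
  unname(m[metrics])
}

#' Gradients of scalar metrics with respect to theta
#'
#' Central finite differences with per-parameter relative step `1e-5`
#' (absolute floor `1e-8`).
#'
#' @param theta 28-parameter vector.
#' @param metrics character vector of metric names (see [scalar_metrics()]).
#' @return 28 x K matrix; column j is the gradient of metric j.
#' @export
metric_gradients <- function(theta, metrics = c("md", "ufa", "mki", "mka")) {
  K <- length(metrics)
  M <- matrix(0, 28L, K)
  for (i in seq_len(28L)) {
    step <- max(1e-5 * abs(theta[i]), 1e-8)
    tp <- theta; tp[i] <- tp[i] + step
    tm <- theta; tm[i] <- tm[i] - step
    M[i, ] <- (.metric_values(tp, metrics) - .metric_values(tm, metrics)) /
      (2 * step)
  }
  colnames(M) <- metrics
  M
}

#' Cramer-Rao lower bound for derived scalar metrics
#'
#' Delta-method bound `J = t(M) solve(I) M` with `M` the matrix of metric
#' gradients; the diagonal entries are the variance lower bounds.  A
#' numerically singular information matrix falls back to the Moore-Penrose
#' pseudo-inverse with a warning.
#'
#' @inheritParams fisher_information
#' @param metrics character vector of metric names.
#' @return object of class `"metric_crlb"`: list with `J` (K x K bound
#'   matrix), `metrics`, `M` (28 x K gradient matrix), `values` (metric
#'   values at `theta`).
#' @export
metric_crlb <- function(theta, scheme, sigma,
                        metrics = c("md", "ufa", "mki", "mka")) {
  I <- fisher_information(theta, scheme, sigma)
  M <- metric_gradients(theta, metrics)
  IiM <- tryCatch(solve(I, M), error = function(e) {
    warning("metric_crlb(): singular information matrix; using pseudo-inverse")
    MASS::ginv(I) %*% M
  })
  J <- crossprod(M, IiM)
  dimnames(J) <- list(metrics, metrics)
  structure(list(J = J, metrics = metrics, M = M,
                 values = .metric_values(theta, metrics)),
            class = "metric_crlb")
}

#' @export
print.metric_crlb <- function(x, ...) {
  cat("CRLB of derived metrics (variance lower bounds):\n")
  print(data.frame(metric = x$metrics, value = x$values,
                   crlb = diag(x$J), row.names = NULL))
  invisible(x)
}

# cholesky log-determinant; +Inf sentinel when not positive definite
.neg_logdet <- function(I) {
  R <- tryCatch(chol(I), error = function(e) NULL)
  if (is.null(R)) return(Inf)
  -2 * sum(log(diag(R)))
}

#' Determinant design criterion on the raw parameters
#'
#' Returns `-log det I(theta)`, a monotone transform of the determinant of
#' the CRLB matrix (D-optimality): minimizing it minimizes the product of
#' the parameter variance bounds.  The log transform avoids under/overflow
#' of a 28-dimensional determinant; reported values are comparable only
#' under this transform.  A singular information matrix yields `+Inf`.
#'
#' @inheritParams fisher_information
#' @return scalar criterion value (smaller is better).
#' @export
criterion_f2 <- function(theta, scheme, sigma) {
  .neg_logdet(fisher_information(theta, scheme, sigma))
}

#' Weighted-trace design criterion on derived metrics
#'
#' `sum_j w_j J_jj` over the requested metrics, with default weights the
#' squared reciprocals of the metric magnitudes so every metric gains
#' equally in relative precision.  A zero metric value with default weights
#' has its weight replaced by `w_ceiling` (with a warning).
#'
#' @inheritParams metric_crlb
#' @param weights optional positive weights (default `1 / m_j^2`).
#' @param w_ceiling cap used when a default weight would be infinite.
#' @return scalar criterion value (smaller is better).
#' @export
criterion_f3 <- function(theta, scheme, sigma,
                         metrics = c("md", "ufa", "mki", "mka"),
                         weights = NULL, w_ceiling = 1e6) {
  cr <- metric_crlb(theta, scheme, sigma, metrics)
  if (is.null(weights)) {
    weights <- 1 / cr$values^2
    if (any(!is.finite(weights))) {
      warning("criterion_f3(): zero metric value; weight capped")
      weights[!is.finite(weights)] <- w_ceiling
    }
    weights <- pmin(weights, w_ceiling)
  }
  sum(weights * diag(cr$J))
}

#' Population-averaged design criterion
#'
#' Mean of the single-voxel criterion over a list of prior parameter
#' vectors; any non-evaluable (singular) voxel propagates `+Inf`.  The
#' priors are used as given; random per-voxel rotation, when wanted, is the
#' caller's responsibility (see [rotate_theta()] and [synth_population()]).
#'
#' @param priors list of 28-parameter vectors.
#' @param scheme an [acquisition_scheme()].
#' @param sigma noise standard deviation.
#' @param criterion `"f2"` or `"f3"`.
#' @param ... passed to the criterion function (metrics, weights).
#' @return scalar criterion value.
#' @export
population_objective <- function(priors, scheme, sigma, criterion = "f3", ...) {
  stopifnot(length(priors) >= 1L)
  fk <- switch(criterion, f2 = criterion_f2, f3 = criterion_f3,
               stop("population_objective(): criterion must be 'f2' or 'f3'"))
  vals <- vapply(priors, fk, numeric(1L), scheme = scheme, sigma = sigma, ...)
  mean(vals)
}

# fast path used by the optimizer: metric gradients and weights do not
# depend on the scheme, so they are precomputed once per prior set
.pop_objective_fast <- function(cache, scheme) {
  A <- design_matrix(scheme)
  tot <- 0
  s2 <- cache$sigma^2
  for (i in seq_along(cache$priors)) {
    s <- exp(pmin(pmax(drop(A %*% cache$priors[[i]]), -.EXP_CLIP), .EXP_CLIP))
    I <- crossprod(s * A) / s2
    if (cache$criterion == "f2") {
      v <- .neg_logdet(I)
      if (!is.finite(v)) return(Inf)
      tot <- tot + v
    } else {
      M <- cache$M[[i]]
      IiM <- tryCatch(solve(I, M), error = function(e) NULL)
      if (is.null(IiM)) return(Inf)
      tot <- tot + sum(cache$w[[i]] * colSums(M * IiM))
    }
  }
  tot / length(cache$priors)
}

.pop_cache <- function(priors, sigma, criterion, metrics, weights, w_ceiling = 1e6) {
  cache <- list(priors = priors, sigma = sigma, criterion = criterion)
  if (criterion == "f3") {
    cache$M <- lapply(priors, metric_gradients, metrics = metrics)
    cache$w <- lapply(priors, function(th) {
      if (!is.null(weights)) return(weights)
      w <- 1 / .metric_values(th, metrics)^2
      w[!is.finite(w)] <- w_ceiling
      pmin(w, w_ceiling)
    })
  }
  cache
}

#' Electrostatic-repulsion direction set
#'
#' `n` unit vectors distributed over the half-sphere by minimizing the
#' antipodally symmetric Coulomb energy
#' `sum_{i<j} 1/|gi - gj| + 1/|gi + gj|` with projected gradient descent
#' (backtracking step, several seeded restarts; deterministic given the
#' seed).
#'
#' @param n number of directions (>= 1).
#' @param seed integer seed.
#' @param n_restart random restarts (best kept).
#' @param max_iter gradient iterations per restart.
#' @return n x 3 matrix of unit row vectors.
#' @export
electrostatic_directions <- function(n, seed = 1L, n_restart = 4L,
                                     max_iter = 400L) {
  stopifnot(n >= 1L)
  if (n == 1L) return(matrix(c(0, 0, 1), 1L, 3L))
  key <- sprintf("n%d_s%d_r%d_i%d", n, seed, n_restart, max_iter)
  hit <- .electro_cache[[key]]
  if (!is.null(hit)) return(hit)
  best <- NULL; best_e <- Inf
  for (r in seq_len(n_restart)) {
    G <- .with_seed(seed + 7919L * (r - 1L), {
      g <- matrix(stats::rnorm(3L * n), n, 3L)
      g / sqrt(rowSums(g^2))
    })
    res <- .electro_descend(G, max_iter)
    if (res$energy < best_e) { best_e <- res$energy; best <- res$G }
  }
  .electro_cache[[key]] <- best
  best
}

# deterministic results are memoized per (n, seed, restarts, iterations)
.electro_cache <- new.env(parent = emptyenv())

.electro_energy <- function(G) {
  D1 <- as.matrix(stats::dist(G))
  GG <- tcrossprod(G)
  D2 <- sqrt(pmax(2 + 2 * GG, 0))  # |gi + gj|
  ut <- upper.tri(D1)
  sum(1 / D1[ut]) + sum(1 / D2[ut])
}

.electro_descend <- function(G, max_iter) {
  n <- nrow(G)
  e <- .electro_energy(G)
  step <- 0.1
  for (it in seq_len(max_iter)) {
    grad <- matrix(0, n, 3L)
    # pairwise force terms, vectorized over the partner index
    for (i in seq_len(n)) {
      d1 <- G - matrix(G[i, ], n, 3L, byrow = TRUE)   # gj - gi
      d2 <- G + matrix(G[i, ], n, 3L, byrow = TRUE)   # gj + gi
      r1 <- sqrt(rowSums(d1^2)); r2 <- sqrt(rowSums(d2^2))
      r1[i] <- Inf; r2[r2 < 1e-9] <- Inf
      grad[i, ] <- colSums(d1 / r1^3) - colSums(d2 / r2^3)
    }
    # project onto tangent planes
    grad <- grad - G * rowSums(grad * G)
    gnorm <- sqrt(max(rowSums(grad^2)))
    if (gnorm < 1e-10) break
    repeat {
      Gn <- G - step * grad
      Gn <- Gn / sqrt(rowSums(Gn^2))
      en <- .electro_energy(Gn)
      if (en < e) { G <- Gn; e <- en; step <- step * 1.3; break }
      step <- step / 2
      if (step < 1e-12) break
    }
    if (step < 1e-12) break
  }
  list(G = G, energy = e)
}

#' Design problem description
#'
#' Bundles everything the scheme optimizer needs: the prior voxel
#' population, sample count, criterion, metric set and box bounds on
#' b and bdelta.
#'
#' @param priors list of 28-parameter vectors (pre-rotated if rotational
#'   invariance is wanted).
#' @param n_samples number of acquisition samples N.
#' @param criterion `"f2"` or `"f3"`.
#' @param metrics metric set for `"f3"`.
#' @param weights optional `"f3"` weights (default reciprocal squared
#'   magnitudes, per voxel).
#' @param b_range open interval for b-values, ms/um^2.
#' @param bdelta_range interval for b-tensor anisotropy.
#' @param sigma noise standard deviation used in the information matrix;
#'   the default `1/15` corresponds to SNR 15 at unit S0.
#' @param seed integer seed (directions and initialization).
#' @return object of class `"design_problem"`.
#' @export
design_problem <- function(priors, n_samples = 120L, criterion = "f3",
                           metrics = c("md", "ufa", "mki", "mka"),
                           weights = NULL,
                           b_range = c(0.1, 2), bdelta_range = c(-0.5, 1),
                           sigma = 1 / 15, seed = 1L) {
  stopifnot(length(priors) >= 1L, n_samples >= 28L, sigma > 0,
            criterion %in% c("f2", "f3"))
  structure(list(priors = priors, n_samples = as.integer(n_samples),
                 criterion = criterion, metrics = metrics, weights = weights,
                 b_range = b_range, bdelta_range = bdelta_range,
                 sigma = sigma, seed = as.integer(seed)),
            class = "design_problem")
}

#' Optimize an acquisition scheme by pattern search
#'
#' Directions are fixed to an electrostatic-repulsion set; the 2N vector of
#' b-values and b-tensor anisotropies is optimized by derivative-free
#' coordinate polling with step halving (initial step 0.4 of the box width,
#' halved on stalled sweeps down to `step_min`), minimizing the
#' population-averaged criterion.  Deterministic given the problem seed.
#'
#' @param problem a [design_problem()].
#' @param step_init initial poll step as a fraction of each box width.
#' @param step_min terminal step fraction.
#' @param max_evals budget of objective evaluations.
#' @return the optimized [acquisition_scheme()] with attributes
#'   `"objective"` (final value), `"objective_init"` and `"trace"`
#'   (objective after each completed sweep).
#' @export
optimize_scheme <- function(problem, step_init = 0.4, step_min = 1e-3,
                            max_evals = 6000L) {
  stopifnot(inherits(problem, "design_problem"))
  N <- problem$n_samples
  G <- electrostatic_directions(N, seed = problem$seed)
  lo <- c(rep(problem$b_range[1L], N), rep(problem$bdelta_range[1L], N))
  hi <- c(rep(problem$b_range[2L], N), rep(problem$bdelta_range[2L], N))
  width <- hi - lo
  x <- .with_seed(problem$seed, lo + stats::runif(2L * N) * width)
  cache <- .pop_cache(problem$priors, problem$sigma, problem$criterion,
                      problem$metrics, problem$weights)
  mk_scheme <- function(x) acquisition_scheme(G, x[1:N], x[(N + 1L):(2L * N)])
  evals <- 0L
  obj <- function(x) {
    evals <<- evals + 1L
    .pop_objective_fast(cache, mk_scheme(x))
  }
  f <- obj(x)
  if (!is.finite(f))
    stop("optimize_scheme(): criterion not evaluable at the initialization; increase N")
  f_init <- f
  trace <- f
  step <- step_init
  while (step >= step_min && evals < max_evals) {
    improved <- FALSE
    for (i in seq_len(2L * N)) {
      if (evals >= max_evals) break
      for (sgn in c(1, -1)) {
        xi <- x[i] + sgn * step * width[i]
        if (xi < lo[i] || xi > hi[i]) next
        xc <- x; xc[i] <- xi
        fc <- obj(xc)
        if (fc < f) { x <- xc; f <- fc; improved <- TRUE; break }
        if (evals >= max_evals) break
      }
    }
    trace <- c(trace, f)
    if (!improved) step <- step / 2
  }
  out <- mk_scheme(x)
  attr(out, "objective") <- f
  attr(out, "objective_init") <- f_init
  attr(out, "trace") <- trace
  attr(out, "evals") <- evals
  out
}

#' Cluster an optimized scheme into shells
#'
#' Groups samples with similar b-values and b-tensor shapes: bdelta values
#' are clustered (1-D k-means, at most 4 clusters) and each cluster centre
#' within `bdelta_snap_tol` of a quintessential shape (-0.5 planar,
#' 0 spherical, 1 linear) is snapped to it; b-values are clustered with the
#' smallest k (up to `n_b_shells`) whose within-cluster sum of squares is
#' below 1 percent of the total, and each sample takes its cluster centroid.
#' Within each resulting (b, bdelta) group the directions are regenerated by
#' electrostatic repulsion.
#'
#' @param raw an [acquisition_scheme()].
#' @param bdelta_snap_tol snapping tolerance.
#' @param n_b_shells maximum number of b shells.
#' @param seed seed for the per-group direction sets.
#' @return a shelled [acquisition_scheme()] with the same sample count.
#' @export
cluster_scheme <- function(raw, bdelta_snap_tol = 0.15, n_b_shells = 4L,
                           seed = 1L) {
  stopifnot(inherits(raw, "acquisition_scheme"))
  n <- n_samples(raw)
  bd_cl <- .kmeans1d(raw$bdelta, min(4L, n), seed)
  snap <- c(-0.5, 0, 1)
  centres <- vapply(bd_cl$centers, function(m) {
    d <- abs(snap - m)
    if (min(d) <= bdelta_snap_tol) snap[which.min(d)] else m
  }, numeric(1L))
  bdelta <- centres[bd_cl$cluster]
  b_cl <- .kmeans1d_auto(raw$b, n_b_shells, seed)
  b <- b_cl$centers[b_cl$cluster]
  key <- paste(signif(b, 10), signif(bdelta, 10))
  dirs <- raw$directions
  for (k in unique(key)) {
    idx <- which(key == k)
    dirs[idx, ] <- electrostatic_directions(length(idx),
                                            seed = seed + match(k, unique(key)))
  }
  acquisition_scheme(dirs, b, bdelta)
}

# 1-D k-means with fixed k (seeded, multi-start)
.kmeans1d <- function(x, k, seed) {
  ux <- unique(x)
  if (length(ux) <= k)
    return(list(cluster = match(x, ux), centers = ux))
  .with_seed(seed, {
    km <- stats::kmeans(x, centers = k, nstart = 10L, iter.max = 100L)
    list(cluster = km$cluster, centers = as.numeric(km$centers))
  })
}

# smallest k whose within-cluster SS is < 1% of total
.kmeans1d_auto <- function(x, kmax, seed) {
  tot <- sum((x - mean(x))^2)
  if (tot <= 0) return(list(cluster = rep(1L, length(x)), centers = mean(x)))
  for (k in seq_len(kmax)) {
    if (length(unique(x)) <= k) break
    cl <- .with_seed(seed + k, stats::kmeans(x, centers = k, nstart = 10L,
                                             iter.max = 100L))
    if (cl$tot.withinss < 0.01 * tot)
      return(list(cluster = cl$cluster, centers = as.numeric(cl$centers)))
  }
  .kmeans1d(x, min(kmax, length(unique(x))), seed)
}

#' Relative precision gain of one scheme over a reference
#'
#' Ratio of absolute precisions `p_abs = 1/CRLB` (reciprocal variance
#' bounds) of scheme `scheme_i` over `scheme_ref` for a metric name or a raw
#' parameter index; values above 1 mean a precision gain, below 1 a loss.
#' The noise level cancels in the ratio.
#'
#' @param scheme_i candidate [acquisition_scheme()].
#' @param scheme_ref reference [acquisition_scheme()].
#' @param theta 28-parameter vector at which the bounds are evaluated.
#' @param sigma noise standard deviation.
#' @param what metric name (see [scalar_metrics()]) or integer parameter
#'   index in 1..28.
#' @return scalar gain factor.
#' @export
precision_gain <- function(scheme_i, scheme_ref, theta, sigma = 1 / 15,
                           what = "md") {
  crlb_one <- function(scheme) {
    if (is.numeric(what)) {
      I <- fisher_information(theta, scheme, sigma)
      Ii <- tryCatch(solve(I), error = function(e) {
        warning("precision_gain(): singular information matrix; pseudo-inverse used")
        MASS::ginv(I)
      })
      Ii[what, what]
    } else {
      diag(metric_crlb(theta, scheme, sigma, metrics = what)$J)[1L]
    }
  }
  ci <- unname(crlb_one(scheme_i)); cr <- unname(crlb_one(scheme_ref))
  if (!is.finite(ci) || !is.finite(cr) || ci <= 0 || cr <= 0) {
    warning("precision_gain(): zero or infinite variance bound")
    return(NA_real_)
  }
  cr / ci
}
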