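# Synthetic voxel populations and the Monte-Carlo evaluation harness.
#
# The generator emulates brain-like mixtures of Gaussian micro-tensors:
# an anisotropic pool of axisymmetric micro-tensors Watson-dispersed about
# a random mean axis, plus an isotropic pool with gamma-distributed
# diffusivities.  It stands in for in-vivo-derived prior voxels; population
# moments are not calibrated to any specific dataset, so only orderings and
# signs of estimator comparisons are meaningful at population level.

#' Tissue recipe for the synthetic voxel generator
#'
#' Describes one tissue class as distributions over micro-tensor
#' parameters.  Diffusivities are in um^2/ms.
#'
#' @param class label: `"WM-like"`, `"GM-like"` or `"CSF-like"`.
#' @param ad_range uniform range of axial micro-diffusivity.
#' @param rd_range uniform range of radial micro-diffusivity.
#' @param kappa_range log-uniform range of the Watson orientation
#'   concentration (larger = more coherent; ~0 = isotropic dispersion).
#' @param iso_fraction_range uniform range of the isotropic pool's signal
#'   fraction.
#' @param iso_shape,iso_rate gamma parameters of the isotropic pool
#'   diffusivity.
#' @param K number of micro-tensors in the anisotropic pool.
#' @return object of class `"tissue_recipe"`.
#' @export
tissue_recipe <- function(class = "WM-like",
                          ad_range = c(1.8, 2.6), rd_range = c(0.2, 0.7),
                          kappa_range = c(4, 64),
                          iso_fraction_range = c(0, 0.15),
                          iso_shape = 6, iso_rate = 4, K = 50L) {
  stopifnot(all(ad_range >= 0), all(rd_range >= 0),
            diff(ad_range) >= 0, diff(rd_range) >= 0,
            all(kappa_range > 0), diff(kappa_range) >= 0,
            all(iso_fraction_range >= 0), all(iso_fraction_range <= 1),
            iso_shape > 0, iso_rate > 0, K >= 1L)
  structure(list(class = class, ad_range = ad_range, rd_range = rd_range,
                 kappa_range = kappa_range,
                 iso_fraction_range = iso_fraction_range,
                 iso_shape = iso_shape, iso_rate = iso_rate, K = as.integer(K)),
            class = "tissue_recipe")
}

#' Default brain-like recipe mixture
#'
#' White-matter-like (coherent, anisotropic), gray-matter-like (dispersed,
#' mildly anisotropic, larger isotropic pool) and CSF-like (free isotropic
#' water at 3 um^2/ms) classes with sampling probabilities 0.5 / 0.4 / 0.1.
#' With `csf = FALSE` only the WM- and GM-like classes are returned
#' (probabilities 0.55 / 0.45), the appropriate prior for design
#' optimization, which targets tissue rather than fluid.
#'
#' @param csf include the CSF-like class.
#' @return list with elements `recipes` (list of [tissue_recipe()]) and
#'   `prob` (sampling probabilities).
#' @export
default_recipes <- function(csf = TRUE) {
  out <- list(recipes = list(
    tissue_recipe("WM-like", ad_range = c(1.8, 2.6), rd_range = c(0.2, 0.7),
                  kappa_range = c(4, 64), iso_fraction_range = c(0, 0.15),
                  iso_shape = 6, iso_rate = 4, K = 50L),
    tissue_recipe("GM-like", ad_range = c(0.9, 1.5), rd_range = c(0.4, 0.9),
                  kappa_range = c(0.5, 4), iso_fraction_range = c(0.1, 0.3),
                  iso_shape = 8, iso_rate = 8, K = 50L),
    tissue_recipe("CSF-like", ad_range = c(3, 3), rd_range = c(3, 3),
                  kappa_range = c(1, 1), iso_fraction_range = c(1, 1),
                  iso_shape = 3000, iso_rate = 1000, K = 1L)),
    prob = c(0.5, 0.4, 0.1))
  if (!csf) {
    out$recipes <- out$recipes[1:2]
    out$prob <- c(0.55, 0.45)
  }
  out
}

# Watson-distributed unit vectors about mu, density prop. to exp(kappa cos^2)
# (rejection from the uniform sphere)
.rwatson <- function(n, mu, kappa) {
  out <- matrix(0, n, 3L)
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 32L)
    x <- matrix(stats::rnorm(3L * m), m, 3L)
    x <- x / sqrt(rowSums(x^2))
    ct2 <- drop(x %*% mu)^2
    acc <- stats::runif(m) < exp(kappa * (ct2 - 1))
    k <- which(acc)
    if (length(k)) {
      take <- utils::head(k, n - got)
      out[(got + 1L):(got + length(take)), ] <- x[take, , drop = FALSE]
      got <- got + length(take)
    }
  }
  out
}

# one voxel from a recipe; returns the discrete DTD.  Axial/radial
# diffusivities are drawn per micro-tensor, so anisotropic voxels carry
# isotropic-diffusivity heterogeneity (cell-size spread) as well as
# orientation dispersion.
.sample_voxel <- function(recipe) {
  kap <- exp(stats::runif(1L, log(recipe$kappa_range[1L]),
                          log(recipe$kappa_range[2L])))
  fiso <- stats::runif(1L, recipe$iso_fraction_range[1L],
                       recipe$iso_fraction_range[2L])
  tensors <- list(); weights <- numeric(0L)
  if (fiso < 1) {
    ad <- stats::runif(recipe$K, recipe$ad_range[1L], recipe$ad_range[2L])
    rd <- stats::runif(recipe$K, recipe$rd_range[1L], recipe$rd_range[2L])
    swap <- rd > ad
    if (any(swap)) { tmp <- ad[swap]; ad[swap] <- rd[swap]; rd[swap] <- tmp }
    mu <- stats::rnorm(3L); mu <- mu / sqrt(sum(mu^2))
    axes <- .rwatson(recipe$K, mu, kap)
    tensors <- lapply(seq_len(recipe$K),
                      function(k) axisym_tensor(ad[k], rd[k], axes[k, ]))
    weights <- rep((1 - fiso) / recipe$K, recipe$K)
  }
  if (fiso > 0) {
    diso <- stats::rgamma(1L, shape = recipe$iso_shape, rate = recipe$iso_rate)
    tensors <- c(tensors, list(diso * diag(3)))
    weights <- c(weights, fiso)
  }
  discrete_dtd(weights, tensors)
}

#' Generate a synthetic voxel population
#'
#' Draws `n_voxels` voxels: each voxel samples a tissue class, builds its
#' discrete DTD (Watson-dispersed axisymmetric micro-tensors plus an
#' isotropic pool) and converts it to a 28-parameter vector with S0 = 1.
#' Deterministic given the seed.
#'
#' @param n_voxels number of voxels.
#' @param recipes list as returned by [default_recipes()] (`recipes` +
#'   `prob`), or a single [tissue_recipe()].
#' @param seed integer seed.
#' @return list of length `n_voxels`; each element has `theta` (length 28),
#'   `dtd` (the [discrete_dtd()]), `class`, and `metrics`
#'   (ground-truth [scalar_metrics()]).
#' @export
synth_population <- function(n_voxels, recipes = default_recipes(), seed = 1L) {
  stopifnot(n_voxels >= 1L)
  if (inherits(recipes, "tissue_recipe"))
    recipes <- list(recipes = list(recipes), prob = 1)
  .with_seed(seed, {
    lapply(seq_len(n_voxels), function(i) {
      j <- sample.int(length(recipes$recipes), 1L, prob = recipes$prob)
      dtd <- .sample_voxel(recipes$recipes[[j]])
      theta <- theta_from_dtd(dtd, S0 = 1)
      list(theta = theta, dtd = dtd, class = recipes$recipes[[j]]$class,
           metrics = scalar_metrics(theta))
    })
  })
}

#' Add Rician noise to a signal vector
#'
#' Magnitude-MRI noise: `s' = sqrt((s + e1)^2 + e2^2)` with `e1, e2`
#' independent zero-mean Gaussians of standard deviation `sigma`.  The
#' signal-to-noise ratio convention used throughout the package is
#' `SNR = S0 / sigma` at b = 0.
#'
#' @param s non-negative signal vector (or matrix; noise is added
#'   elementwise).
#' @param sigma noise standard deviation, positive.
#' @param seed optional integer seed.
#' @return noisy signal of the same shape.
#' @export
add_rician_noise <- function(s, sigma, seed = NULL) {
  stopifnot(sigma > 0)
  .with_seed(seed, {
    e1 <- stats::rnorm(length(s), sd = sigma)
    e2 <- stats::rnorm(length(s), sd = sigma)
    out <- sqrt((s + e1)^2 + e2^2)
    if (is.matrix(s)) dim(out) <- dim(s)
    out
  })
}

# vectorized scalar metrics over the columns of a 28 x R matrix
.metrics_mat <- function(Theta) {
  d <- Theta[.THETA_D, , drop = FALSE]
  c21 <- Theta[.THETA_C, , drop = FALSE]
  md <- colMeans(d[1:3, , drop = FALSE])
  vbulk_m <- md^2
  vshear_m <- pmax(colSums(d * (.E_SHEAR_M %*% d)), 0)
  cb <- colSums(c21 * .E_BULK_V)
  cs <- colSums(c21 * .E_SHEAR_V)
  vbulk2 <- vbulk_m + cb
  vshear2 <- vshear_m + cs
  eps2 <- 1e-12 * vbulk_m
  fa <- sqrt(1.5 * vshear_m / (vbulk_m + vshear_m))
  ufa <- ifelse(vshear2 > eps2 & vbulk2 + vshear2 > 0,
                sqrt(pmax(1.5 * vshear2 / (vbulk2 + vshear2), 0)), 0)
  mki <- 3 * cb / vbulk_m
  mka <- 1.2 * cs / vbulk_m
  op <- sqrt(pmax(ifelse(vshear2 > eps2, vshear_m / vshear2, 0), 0))
  cc <- ifelse(ufa > 0, fa^2 / ufa^2, 0)
  bad <- !is.finite(md) | md <= 0
  out <- rbind(md = md, fa = fa, ufa = ufa, mki = mki, mka = mka,
               mk = mki + mka, op = op, cc = cc)
  out[, bad] <- NaN
  out
}

# batch fit of the columns of S with a named estimator; returns 28 x R
.fit_batch <- function(S, A, estimator, constraints = NULL, qr_A = NULL) {
  est <- estimator
  if (est == "lls") {
    if (all(S > 0)) {
      q <- if (is.null(qr_A)) qr(A) else qr_A
      th <- qr.coef(q, log(S))
      return(list(theta = th, nfail = 0L))
    }
    est <- "lls_slow"
  }
  switch(est,
    lls_slow = {
      th <- apply(S, 2L, function(s)
        tryCatch(suppressWarnings(lls_fit(s, A)$theta), error = function(e) rep(NA_real_, 28L)))
      list(theta = th, nfail = sum(colSums(is.na(th)) > 0L))
    },
    wlls = {
      r <- .iwlls_batch(A, S, 1L)
      list(theta = r$theta, nfail = sum(r$status != 0L))
    },
    iwlls = {
      r <- .iwlls_batch(A, S, 2L)
      list(theta = r$theta, nfail = sum(r$status != 0L))
    },
    nls = {
      q <- if (is.null(qr_A)) qr(A) else qr_A
      pos <- all(S > 0)
      Th0 <- if (pos) qr.coef(q, log(S)) else
        apply(S, 2L, function(s)
          tryCatch(suppressWarnings(lls_fit(s, A)$theta),
                   error = function(e) c(log(max(mean(s), 1e-6)), rep(0, 27L))))
      r <- .nls_lm_batch(A, S, Th0)
      list(theta = r$theta, nfail = 0L)
    },
    ciwlls1 = ,
    ciwlls2 = ,
    ciwlls3 = {
      stopifnot(!is.null(constraints))
      r <- .ciwlls_batch(A, S, constraints$G, constraints$h, 2L)
      list(theta = r$theta, nfail = sum(r$status == 1L))
    },
    stop(sprintf("unknown estimator '%s'", est)))
}

#' Monte-Carlo evaluation of estimator accuracy and precision
#'
#' For every voxel of a synthetic population: generate the noise-free
#' signal with the cumulant forward model, add Rician noise
#' `n_realizations` times, fit each realization with each named estimator,
#' derive the scalar metrics, and summarize the per-voxel bias, standard
#' deviation and RMSE against the ground truth.  All estimators see the
#' identical noise realizations, and the run is reproducible given the
#' seed.  Per-voxel variance uses the 1/n divisor so that
#' `rmse^2 = bias^2 + sd^2` holds exactly.
#'
#' @param population output of [synth_population()].
#' @param scheme an [acquisition_scheme()].
#' @param estimators character vector of estimator names (see [fit_qti()]).
#' @param snr signal-to-noise ratio `S0 / sigma` at b = 0 (`sigma`
#'   overrides it when given).
#' @param sigma optional noise standard deviation.
#' @param n_realizations noise realizations per voxel.
#' @param seed integer seed.
#' @param metrics metric names to report.
#' @param max_fail_rate abort when the fraction of failed fits of any
#'   estimator exceeds this.
#' @return object of class `"mc_report"`: list with
#'   `per_voxel` (data frame: voxel, class, estimator, metric, truth, bias,
#'   sd, rmse), `summary` (data frame of population medians and quartiles of
#'   bias / relative bias / sd / rmse per estimator and metric),
#'   `n_realizations`, `snr`, `seed`, `failures`.
#' @export
monte_carlo_evaluate <- function(population, scheme, estimators = "iwlls",
                                 snr = 25, sigma = NULL,
                                 n_realizations = 100L, seed = 1L,
                                 metrics = c("md", "fa", "ufa", "mki", "mka", "op"),
                                 max_fail_rate = 0.05) {
  stopifnot(inherits(scheme, "acquisition_scheme"), length(population) >= 1L)
  A <- design_matrix(scheme)
  qr_A <- qr(A)
  need_con <- grepl("^ciwlls", estimators)
  cons <- list()
  for (e in unique(estimators[need_con]))
    cons[[e]] <- build_constraints(constraint_directions(scheme),
                                   as.integer(substring(e, 7L)),
                                   b_max = max(scheme$b))
  nv <- length(population); R <- as.integer(n_realizations)
  rows <- vector("list", nv * length(estimators))
  failures <- stats::setNames(numeric(length(estimators)), estimators)
  ri <- 0L
  for (v in seq_len(nv)) {
    vox <- population[[v]]
    sig <- if (is.null(sigma)) exp(vox$theta[1L]) / snr else sigma
    strue <- forward_signal(vox$theta, A)
    S <- add_rician_noise(matrix(strue, nrow(A), R), sig,
                          seed = seed + 104729L * v)
    truth <- vox$metrics[metrics]
    for (e in estimators) {
      fit <- .fit_batch(S, A, e, constraints = cons[[e]], qr_A = qr_A)
      failures[e] <- failures[e] + fit$nfail
      M <- .metrics_mat(fit$theta)[metrics, , drop = FALSE]
      ok <- colSums(!is.finite(M)) == 0L
      Mo <- M[, ok, drop = FALSE]
      est_mean <- rowMeans(Mo)
      bias <- est_mean - truth
      varr <- rowMeans((Mo - est_mean)^2)
      rmse <- sqrt(bias^2 + varr)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(voxel = v, class = vox$class, estimator = e,
                               metric = metrics, truth = unname(truth),
                               bias = unname(bias), sd = unname(sqrt(varr)),
                               rmse = unname(rmse), n_ok = sum(ok))
    }
  }
  per_voxel <- do.call(rbind, rows[seq_len(ri)])
  fail_rate <- failures / (nv * R)
  if (any(fail_rate > max_fail_rate))
    stop(sprintf("monte_carlo_evaluate(): fit failure rate %.1f%% exceeds %.1f%%",
                 100 * max(fail_rate), 100 * max_fail_rate))
  defined <- abs(per_voxel$truth) > 1e-9
  per_voxel$rel_bias <- ifelse(defined, per_voxel$bias / abs(per_voxel$truth), NA)
  per_voxel$rel_sd <- ifelse(defined, per_voxel$sd / abs(per_voxel$truth), NA)
  med <- stats::aggregate(cbind(bias, sd, rmse, rel_bias, rel_sd) ~
                            estimator + metric, data = per_voxel,
                          FUN = function(x) stats::median(x, na.rm = TRUE),
                          na.action = stats::na.pass)
  names(med)[3:7] <- paste0("median_", names(med)[3:7])
  structure(list(per_voxel = per_voxel, summary = med,
                 n_realizations = R, snr = if (is.null(sigma)) snr else NA,
                 sigma = sigma, seed = seed, failures = failures),
            class = "mc_report")
}

#' @export
print.mc_report <- function(x, ...) {
  cat(sprintf("Monte-Carlo report: %d voxels x %d realizations, SNR %s\n",
              length(unique(x$per_voxel$voxel)), x$n_realizations,
              format(x$snr)))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Population medians of a Monte-Carlo statistic
#'
#' Convenience accessor: the population median of `"bias"`, `"rel_bias"`,
#' `"sd"`, `"rel_sd"` or `"rmse"` for one estimator and metric.
#'
#' @param report an `"mc_report"`.
#' @param estimator estimator name.
#' @param metric metric name.
#' @param stat statistic name.
#' @return scalar.
#' @export
mc_stat <- function(report, estimator, metric, stat = "bias") {
  s <- report$summary
  row <- s[s$estimator == estimator & s$metric == metric, ]
  if (nrow(row) != 1L) stop("mc_stat(): no such estimator/metric")
  row[[paste0("median_", stat)]]
}
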