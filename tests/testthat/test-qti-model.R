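test_that("design rows encode the cumulant expansion", {
  expect_equal(design_row(matrix(0, 3, 3)), c(1, rep(0, 27)))
  expect_length(design_row(btensor_from_shape(c(0, 0, 1), 1, 1)), 28L)
  # DTI limit: with c = 0 the row reproduces S0 exp(-B:D)
  set.seed(5)
  D <- rand_spd3()
  theta <- qti_theta(2.5, voigt6(D), numeric(21))
  for (i in 1:10) {
    B <- btensor_from_shape({g <- rnorm(3); g / sqrt(sum(g^2))},
                            runif(1, 0, 2), runif(1, -0.5, 1))
    expect_equal(exp(sum(design_row(B) * theta)),
                 2.5 * exp(-contract2_bf(B, D)), tolerance = 1e-12)
  }
})

test_that("the vectorized model matrix matches per-row construction", {
  sch <- random_scheme(25, seed = 3)
  A <- design_matrix(sch)
  expect_equal(dim(A), c(25L, 28L))
  for (i in c(1L, 7L, 25L)) {
    B <- btensor_from_shape(sch$directions[i, ], sch$b[i], sch$bdelta[i])
    expect_equal(A[i, ], design_row(B), tolerance = 1e-13)
  }
  # duplicated samples give duplicated rows
  sch2 <- acquisition_scheme(sch$directions[c(1, 1), ], sch$b[c(1, 1)],
                             sch$bdelta[c(1, 1)])
  A2 <- design_matrix(sch2)
  expect_identical(A2[1, ], A2[2, ])
})

test_that("the packaged optimized scheme yields a full-rank model matrix", {
  A <- design_matrix(packaged_scheme("q3hat"))
  expect_equal(dim(A), c(120L, 28L))
  expect_identical(qr(A)$rank, 28L)
})

test_that("forward signal behaves in the limits", {
  sch <- random_scheme(15, seed = 9)
  expect_equal(forward_signal(qti_theta(1), sch), rep(1, 15))
  # b = 0 sample returns S0
  sch0 <- acquisition_scheme(matrix(c(0, 0, 1), 1), 0, 0)
  theta <- small_population(1)[[1]]$theta
  expect_equal(forward_signal(theta, sch0), exp(theta[1]))
  # isotropic theta: signal depends only on b, not direction or shape
  th_iso <- qti_theta(1, 0.8 * c(1, 1, 1, 0, 0, 0), numeric(21))
  set.seed(2)
  for (b in c(0.5, 1.5)) {
    vals <- sapply(1:8, function(i) {
      g <- rnorm(3); g <- g / sqrt(sum(g^2))
      forward_signal(th_iso, acquisition_scheme(matrix(g, 1), b,
                                                runif(1, -0.5, 1)))
    })
    expect_equal(max(vals) - min(vals), 0, tolerance = 1e-12)
    expect_equal(vals[1], exp(-b * 0.8), tolerance = 1e-12)
  }
})

test_that("mixture moments match the brute-force covariance definition", {
  # point distribution has zero covariance
  D <- rand_spd3()
  m1 <- moments_from_mixture(discrete_dtd(1, list(D)))
  expect_equal(m1$c21, numeric(21), tolerance = 1e-14)
  expect_equal(m1$d, voigt6(D), tolerance = 1e-14)
  # two isotropic pools: bulk variance 1, no shear variance
  m2 <- moments_from_mixture(discrete_dtd(c(0.5, 0.5),
                                          list(diag(3), 3 * diag(3))))
  expect_equal(sum(m2$c21 * e_bulk()), 1, tolerance = 1e-12)
  expect_equal(sum(m2$c21 * e_shear()), 0, tolerance = 1e-12)
  # random mixtures against the explicit four-index covariance array
  set.seed(21)
  for (rep in 1:5) {
    K <- 4L
    w <- runif(K); w <- w / sum(w)
    Ds <- replicate(K, rand_spd3(), simplify = FALSE)
    m <- moments_from_mixture(discrete_dtd(w, Ds))
    Cbf <- dtd_cov_array_bf(w, Ds)
    for (probe in 1:4) {
      B <- rand_sym3()
      expect_equal(sum(m$c21 * voigt21_outer(B)),
                   contract4_array_bf(Cbf, B), tolerance = 1e-10)
    }
  }
})

test_that("mixture covariance is positive semidefinite in Voigt form", {
  set.seed(31)
  for (rep in 1:10) {
    K <- sample(2:6, 1)
    w <- runif(K); w <- w / sum(w)
    Ds <- replicate(K, rand_spd3(), simplify = FALSE)
    m <- moments_from_mixture(discrete_dtd(w, Ds))
    C6 <- qtide:::unvoigt21_mat(m$c21)
    expect_gte(min(eigen(C6, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("the cumulant model is a third-order-accurate low-b approximation", {
  vox <- small_population(4, seed = 77)
  dirs <- matrix(c(0, 0, 1, 1, 0, 0, 0, 1, 0), 3, 3, byrow = TRUE)
  for (v in vox) {
    if (v$class == "CSF-like") next
    gap <- function(b) {
      sch <- acquisition_scheme(dirs, rep(b, 3), c(1, 0, -0.5))
      max(abs(mixture_signal(v$dtd, 1, sch) - forward_signal(v$theta, sch)))
    }
    # O(b^3) truncation: halving b shrinks the gap by >= 4x (expect ~8x)
    expect_gte(gap(1.0) / max(gap(0.5), 1e-300), 4)
  }
})

test_that("cumulant truncation error is small in the model's validity regime", {
  sch2 <- packaged_scheme("q3hat")
  low <- acquisition_scheme(sch2$directions, pmin(sch2$b, 1), sch2$bdelta)
  pop <- synth_population(20, recipes = default_recipes(csf = FALSE), seed = 88)
  gaps2 <- vapply(pop, function(v)
    max(abs(mixture_signal(v$dtd, 1, sch2) - forward_signal(v$theta, sch2))),
    numeric(1))
  gaps1 <- vapply(pop, function(v)
    max(abs(mixture_signal(v$dtd, 1, low) - forward_signal(v$theta, low))),
    numeric(1))
  # typical tissue voxel: within 5% of S0 out to b = 2
  expect_lte(median(gaps2), 0.05)
  # moderate-kurtosis voxels: within 5% of S0 at b <= 1; extreme isotropic
  # heterogeneity (large MKi) is the truncation's known failure mode
  moderate <- vapply(pop, function(v) v$metrics[["mki"]] <= 0.5, logical(1))
  expect_gt(sum(moderate), 10)
  expect_lte(max(gaps1[moderate]), 0.05)
})

test_that("fifty micro-tensors are enough for stable voxel metrics", {
  rec <- tissue_recipe("WM-like", ad_range = c(2.0, 2.4),
                       rd_range = c(0.3, 0.5), kappa_range = c(16, 16),
                       iso_fraction_range = c(0, 0), K = 50L)
  M <- vapply(1:20, function(s)
    synth_population(1, recipes = rec, seed = s)[[1]]$metrics, numeric(8))
  rel_sd <- apply(M, 1, sd) / abs(rowMeans(M))
  expect_lt(max(rel_sd[c("md", "fa", "ufa", "op")]), 0.03)
})

test_that("heterogeneity raises the signal above the mean-tensor decay", {
  dtd <- discrete_dtd(c(0.5, 0.5), list(diag(3), 3 * diag(3)))
  sch <- acquisition_scheme(matrix(c(0, 0, 1), 1), 2, 0)
  s_mix <- mixture_signal(dtd, 1, sch)
  s_mean <- exp(-2 * 2)  # mean diffusivity 2 at b = 2
  expect_gt(s_mix, s_mean)
})

test_that("scalar metrics reproduce closed-form limits", {
  # isotropic single tensor
  m <- scalar_metrics(qti_theta(1, voigt6(diag(3)), numeric(21)))
  expect_equal(unname(m[c("md", "fa", "ufa", "mki", "mka", "op")]),
               c(1, 0, 0, 0, 0, 0), tolerance = 1e-12)
  # coherent prolate tensor: FA = uFA from the eigenvalue formula, OP = 1
  lam <- c(2, 0.5, 0.5)
  m2 <- scalar_metrics(qti_theta(1, voigt6(diag(lam)), numeric(21)))
  expect_equal(unname(m2["md"]), 1, tolerance = 1e-12)
  expect_equal(unname(m2["fa"]), fa_eigen_bf(lam), tolerance = 1e-12)
  expect_equal(unname(m2["fa"]), unname(m2["ufa"]), tolerance = 1e-12)
  expect_equal(unname(m2["op"]), 1, tolerance = 1e-12)
  expect_equal(unname(m2[c("mki", "mka")]), c(0, 0), tolerance = 1e-12)
  # equal-weight two-isotropic mixture
  th3 <- theta_from_dtd(discrete_dtd(c(0.5, 0.5), list(diag(3), 3 * diag(3))))
  m3 <- scalar_metrics(th3)
  expect_equal(unname(m3["md"]), 2, tolerance = 1e-12)
  expect_equal(unname(m3["mki"]), 0.75, tolerance = 1e-12)
  expect_equal(unname(m3[c("mka", "ufa")]), c(0, 0), tolerance = 1e-12)
})

test_that("total kurtosis decomposes exactly and metrics are rotation invariant", {
  vox <- small_population(6, seed = 55)
  rots <- random_rotations(6, seed = 8)
  for (i in seq_along(vox)) {
    m <- vox[[i]]$metrics
    expect_identical(unname(m["mk"]), unname(m["mki"] + m["mka"]))
    mr <- scalar_metrics(rotate_theta(vox[[i]]$theta, rots[[i]]))
    # square-root metrics are not Lipschitz at zero anisotropy, so compare
    # with a small absolute floor on top of the relative tolerance
    expect_equal(unname(mr), unname(m), tolerance = 1e-8)
  }
})

test_that("microscopic anisotropy bounds macroscopic anisotropy", {
  vox <- small_population(20, seed = 99)
  for (v in vox) {
    m <- v$metrics
    expect_gte(m[["ufa"]] - m[["fa"]], -1e-10)
    expect_true(all(m[c("fa", "ufa", "op")] >= -1e-9 &
                      m[c("fa", "ufa", "op")] <= 1 + 1e-9))
  }
})

test_that("non-positive mean diffusivity yields NaN metrics with a warning", {
  th <- qti_theta(1, c(-1, -1, -1, 0, 0, 0), numeric(21))
  expect_warning(m <- scalar_metrics(th), "non-positive")
  expect_true(all(is.nan(m)))
})

test_that("vectorized metrics agree with the scalar path", {
  vox <- small_population(10, seed = 4)
  Theta <- vapply(vox, function(v) v$theta, numeric(28))
  M <- qtide:::.metrics_mat(Theta)
  for (i in seq_along(vox))
    expect_equal(M[, i], vox[[i]]$metrics[rownames(M)], tolerance = 1e-12,
                 ignore_attr = TRUE)
})
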