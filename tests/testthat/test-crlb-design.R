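sch <- packaged_scheme("q3hat")
vox1 <- small_population(1, seed = 14)[[1]]

test_that("Fisher information scales, adds, and matches a numeric Jacobian", {
  I1 <- fisher_information(vox1$theta, sch, sigma = 1 / 25)
  expect_true(isSymmetric(I1))
  # 1/sigma^2 scaling
  I2 <- fisher_information(vox1$theta, sch, sigma = 2 / 25)
  expect_equal(I1 / 4, I2, tolerance = 1e-12, ignore_attr = TRUE)
  # additivity over concatenated schemes
  schA <- random_scheme(30, seed = 1)
  schB <- random_scheme(35, seed = 2)
  schAB <- acquisition_scheme(rbind(schA$directions, schB$directions),
                              c(schA$b, schB$b), c(schA$bdelta, schB$bdelta))
  expect_equal(fisher_information(vox1$theta, schAB, 0.1),
               fisher_information(vox1$theta, schA, 0.1) +
                 fisher_information(vox1$theta, schB, 0.1),
               tolerance = 1e-12, ignore_attr = TRUE)
  # central finite-difference Jacobian oracle
  Jnum <- matrix(0, n_samples(sch), 28L)
  for (j in 1:28) {
    st <- 1e-6 * max(abs(vox1$theta[j]), 1)
    tp <- vox1$theta; tp[j] <- tp[j] + st
    tm <- vox1$theta; tm[j] <- tm[j] - st
    Jnum[, j] <- (forward_signal(tp, sch) - forward_signal(tm, sch)) / (2 * st)
  }
  Iref <- crossprod(Jnum) * 25^2
  expect_equal(I1, Iref, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("metric bounds agree with the analytic delta method for MD", {
  sig <- 1 / 25
  cr <- metric_crlb(vox1$theta, sch, sig, metrics = "md")
  # MD is linear: gradient is 1/3 on the first three d entries
  g_md <- c(0, rep(1, 3) / 3, rep(0, 24))
  expect_equal(drop(cr$M), g_md, tolerance = 1e-6, ignore_attr = TRUE)
  I <- fisher_information(vox1$theta, sch, sig)
  expect_equal(drop(cr$J), drop(crossprod(g_md, solve(I, g_md))),
               tolerance = 1e-6)
  expect_gte(min(diag(cr$J)), 0)
})

test_that("the determinant criterion reflects information content", {
  sig <- 1 / 15
  f0 <- criterion_f2(vox1$theta, sch, sig)
  # duplicating all samples doubles the information matrix
  dup <- acquisition_scheme(rbind(sch$directions, sch$directions),
                            rep(sch$b, 2), rep(sch$bdelta, 2))
  expect_equal(criterion_f2(vox1$theta, dup, sig), f0 - 28 * log(2),
               tolerance = 1e-8)
  # row order is irrelevant
  p <- qtide:::.with_seed(3, sample(120))
  perm <- acquisition_scheme(sch$directions[p, ], sch$b[p], sch$bdelta[p])
  expect_equal(criterion_f2(vox1$theta, perm, sig), f0, tolerance = 1e-9)
  # too few informative rows: singular information, +Inf sentinel
  few <- acquisition_scheme(matrix(rep(c(0, 0, 1), 10), 10, 3, byrow = TRUE),
                            rep(1, 10), rep(1, 10))
  expect_identical(criterion_f2(vox1$theta, few, sig), Inf)
})

test_that("the weighted-trace criterion composes as documented", {
  sig <- 1 / 15
  cr <- metric_crlb(vox1$theta, sch, sig, metrics = c("md", "ufa"))
  expect_equal(criterion_f3(vox1$theta, sch, sig, metrics = "md", weights = 1),
               cr$J["md", "md"], tolerance = 1e-10)
  f <- criterion_f3(vox1$theta, sch, sig, metrics = c("md", "ufa"),
                    weights = c(2, 3))
  expect_equal(f, 2 * cr$J["md", "md"] + 3 * cr$J["ufa", "ufa"],
               tolerance = 1e-10)
  expect_equal(criterion_f3(vox1$theta, sch, sig, metrics = c("md", "ufa"),
                            weights = 2 * c(2, 3)), 2 * f, tolerance = 1e-10)
})

test_that("adding measurements never hurts any metric bound", {
  sig <- 1 / 15
  base <- random_scheme(40, seed = 21)
  d0 <- diag(metric_crlb(vox1$theta, base, sig,
                         metrics = c("md", "ufa", "mki", "mka"))$J)
  set.seed(22)
  for (i in 1:25) {
    g <- rnorm(3); g <- g / sqrt(sum(g^2))
    aug <- acquisition_scheme(rbind(base$directions, g),
                              c(base$b, runif(1, 0.1, 2)),
                              c(base$bdelta, runif(1, -0.5, 1)))
    d1 <- diag(metric_crlb(vox1$theta, aug, sig,
                           metrics = c("md", "ufa", "mki", "mka"))$J)
    expect_true(all(d1 <= d0 * (1 + 1e-9)))
  }
})

test_that("design criteria are invariant under joint rotation of scheme and voxel", {
  sig <- 1 / 15
  R <- random_rotations(1, seed = 77)[[1]]
  schR <- acquisition_scheme(sch$directions %*% t(R), sch$b, sch$bdelta)
  thR <- rotate_theta(vox1$theta, R)
  expect_equal(criterion_f2(thR, schR, sig), criterion_f2(vox1$theta, sch, sig),
               tolerance = 1e-8)
  expect_equal(criterion_f3(thR, schR, sig), criterion_f3(vox1$theta, sch, sig),
               tolerance = 1e-4)
})

test_that("the population objective averages and propagates singularities", {
  sig <- 1 / 15
  pop <- small_population(3, seed = 91)
  priors <- lapply(pop, `[[`, "theta")
  vals <- sapply(priors, criterion_f2, scheme = sch, sigma = sig)
  expect_equal(population_objective(priors, sch, sig, "f2"), mean(vals),
               tolerance = 1e-12)
  expect_equal(population_objective(priors[1], sch, sig, "f2"), vals[1],
               tolerance = 1e-12)
  expect_equal(population_objective(rev(priors), sch, sig, "f2"), mean(vals),
               tolerance = 1e-12)
})

test_that("electrostatic direction sets solve the known small-n optima", {
  G2 <- electrostatic_directions(2, seed = 5)
  ang <- acos(abs(sum(G2[1, ] * G2[2, ]))) * 180 / pi
  expect_equal(ang, 90, tolerance = 0.5 / 90)
  G6 <- electrostatic_directions(6, seed = 5)
  expect_equal(sqrt(rowSums(G6^2)), rep(1, 6), tolerance = 1e-10)
  # icosahedron vertices are the 6-direction optimum
  phi <- (1 + sqrt(5)) / 2
  ico <- rbind(c(0, 1, phi), c(0, -1, phi), c(1, phi, 0),
               c(-1, phi, 0), c(phi, 0, 1), c(phi, 0, -1))
  ico <- ico / sqrt(rowSums(ico^2))
  energy <- function(G) {
    D1 <- as.matrix(dist(G)); D2 <- sqrt(pmax(2 + 2 * tcrossprod(G), 0))
    ut <- upper.tri(D1); sum(1 / D1[ut]) + sum(1 / D2[ut])
  }
  expect_lte(energy(G6), energy(ico) * 1.005)
  # determinism
  expect_identical(electrostatic_directions(12, seed = 9),
                   electrostatic_directions(12, seed = 9))
})

test_that("pattern search improves the criterion and is reproducible", {
  pop <- synth_population(6, recipes = default_recipes(csf = FALSE), seed = 33)
  priors <- lapply(pop, `[[`, "theta")
  pr <- design_problem(priors, n_samples = 40, criterion = "f2", seed = 4)
  opt <- optimize_scheme(pr, max_evals = 400)
  expect_lt(attr(opt, "objective"), attr(opt, "objective_init"))
  expect_equal(attr(opt, "objective"),
               population_objective(priors, opt, pr$sigma, "f2"),
               tolerance = 1e-10)
  opt2 <- optimize_scheme(design_problem(priors, n_samples = 40,
                                         criterion = "f2", seed = 4),
                          max_evals = 400)
  expect_identical(opt$b, opt2$b)
  expect_identical(opt$bdelta, opt2$bdelta)
  expect_identical(opt$directions, opt2$directions)
})

test_that("shell clustering preserves counts and respects existing shells", {
  # an already-shelled scheme survives up to direction regeneration
  q3 <- packaged_scheme("q3hat")
  cl <- cluster_scheme(q3, seed = 2)
  expect_identical(n_samples(cl), 120L)
  expect_equal(sort(unique(cl$b)), sort(unique(q3$b)), tolerance = 1e-9)
  expect_equal(table(paste(cl$b, cl$bdelta)), table(paste(q3$b, q3$bdelta)),
               ignore_attr = TRUE)
  # snapping pulls near-quintessential shapes onto -0.5 / 0 / 1
  raw <- acquisition_scheme(electrostatic_directions(30, seed = 3),
                            rep(c(0.5, 2), 15),
                            rep(c(-0.45, 0.1, 0.93), 10))
  cl2 <- cluster_scheme(raw, seed = 2)
  expect_true(all(cl2$bdelta %in% c(-0.5, 0, 1)))
  expect_identical(n_samples(cl2), 30L)
})

test_that("precision gains behave as variance ratios", {
  sig <- 1 / 15
  expect_equal(precision_gain(sch, sch, vox1$theta, sig, "md"), 1,
               tolerance = 1e-12)
  dup <- acquisition_scheme(rbind(sch$directions, sch$directions),
                            rep(sch$b, 2), rep(sch$bdelta, 2))
  for (w in list("md", "mki", 1L, 5L, 23L))
    expect_equal(precision_gain(dup, sch, vox1$theta, sig, w), 2,
                 tolerance = 1e-6)
  # the noise level cancels
  expect_equal(precision_gain(dup, sch, vox1$theta, 1 / 50, "ufa"),
               precision_gain(dup, sch, vox1$theta, 1 / 5, "ufa"),
               tolerance = 1e-9)
})
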