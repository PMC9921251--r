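# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately brute force (explicit index loops, direct
# eigenvalue formulas, plain projected gradient) so it shares no code path
# with the implementation it checks.

rand_sym3 <- function() {
  M <- matrix(stats::rnorm(9L), 3L, 3L)
  (M + t(M)) / 2
}

rand_spd3 <- function(scale = 1) {
  M <- matrix(stats::rnorm(9L), 3L, 3L)
  scale * crossprod(M) / 3
}

# full double contraction sum_ij Tij Uij by explicit loops
contract2_bf <- function(T, U) {
  out <- 0
  for (i in 1:3) for (j in 1:3) out <- out + T[i, j] * U[i, j]
  out
}

# full four-index contraction of T⊗T with U⊗U by explicit loops
contract4_bf <- function(T, U) {
  out <- 0
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
    out <- out + T[i, j] * T[k, l] * U[i, j] * U[k, l]
  out
}

# contraction of a general 4th-order array with B⊗2
contract4_array_bf <- function(C, B) {
  out <- 0
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
    out <- out + C[i, j, k, l] * B[i, j] * B[k, l]
  out
}

# 3x3x3x3 covariance array of a discrete DTD straight from the definition
dtd_cov_array_bf <- function(weights, tensors) {
  Dbar <- Reduce(`+`, Map(`*`, tensors, weights))
  C <- array(0, c(3, 3, 3, 3))
  for (m in seq_along(weights)) {
    D <- tensors[[m]]
    for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
      C[i, j, k, l] <- C[i, j, k, l] + weights[m] * D[i, j] * D[k, l]
  }
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
    C[i, j, k, l] <- C[i, j, k, l] - Dbar[i, j] * Dbar[k, l]
  C
}

# textbook eigenvalue FA
fa_eigen_bf <- function(lambda) {
  md <- mean(lambda)
  sqrt(1.5 * sum((lambda - md)^2) / sum(lambda^2))
}

# a random full-rank scheme (not shelled) for small fitting problems
random_scheme <- function(n, seed = 1L, bmax = 2) {
  set.seed(seed)
  g <- matrix(stats::rnorm(3L * n), n, 3L)
  g <- g / sqrt(rowSums(g^2))
  acquisition_scheme(g, stats::runif(n, 0.05, bmax),
                     stats::runif(n, -0.5, 1))
}

# dual projected-gradient QP oracle for min 1/2 x'Hx - f'x s.t. Gx <= h;
# slow and simple on purpose
qp_pg_oracle <- function(H, f, G, h, iters = 50000L) {
  Hi <- solve(H)
  S <- G %*% Hi %*% t(G)
  q <- drop(G %*% Hi %*% f) - h
  L <- max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  lam <- numeric(nrow(G))
  for (i in seq_len(iters)) {
    lam <- pmax(0, lam - (drop(S %*% lam) - q) / L)
  }
  drop(Hi %*% (f - drop(t(G) %*% lam)))
}

# tiny two-class population with fixed seed, used by several files
small_population <- function(n = 8L, seed = 123L) {
  synth_population(n, seed = seed)
}
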