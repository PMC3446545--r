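# Independent oracles used across the suite.  Everything here is
# deliberately written from the textbook definitions, not by calling
# the package's own machinery.

# Classic linear Kalman filter: x_{k+1} = A x_k + w, y_k = H x_k + v.
# Convention matched to the package runners: the initial belief refers
# to the first observation time (update only at k = 1).
kalman_filter <- function(Y, A, H, Q, R, m0, P0) {
  n <- ncol(Y)
  L <- length(m0)
  m <- m0; P <- P0
  means <- matrix(NA_real_, L, n)
  covs <- vector("list", n)
  for (k in seq_len(n)) {
    if (k > 1L) {
      m <- drop(A %*% m)
      P <- A %*% P %*% t(A) + Q
    }
    S <- H %*% P %*% t(H) + R
    K <- P %*% t(H) %*% solve(S)
    m <- m + drop(K %*% (Y[, k] - drop(H %*% m)))
    P <- P - K %*% S %*% t(K)
    P <- (P + t(P)) / 2
    means[, k] <- m
    covs[[k]] <- P
  }
  list(means = means, covs = covs)
}

# Random stable linear-Gaussian system of dimension L with obs_dim
# observations; spectral radius scaled below 0.95.
random_linear_system <- function(L, obs_dim = 2L) {
  A <- matrix(stats::rnorm(L * L), L, L)
  A <- A * (0.6 + 0.3 * stats::runif(1)) / max(Mod(eigen(A)$values))
  H <- matrix(stats::rnorm(obs_dim * L), obs_dim, L)
  Q <- crossprod(matrix(stats::rnorm(L * L, sd = 0.3), L, L)) + diag(0.05, L)
  R <- crossprod(matrix(stats::rnorm(obs_dim^2, sd = 0.3), obs_dim,
                        obs_dim)) + diag(0.05, obs_dim)
  m0 <- stats::rnorm(L)
  P0 <- crossprod(matrix(stats::rnorm(L * L, sd = 0.5), L, L)) + diag(0.2, L)
  list(A = A, H = H, Q = Q, R = R, m0 = m0, P0 = P0)
}

simulate_linear <- function(sys, n) {
  L <- length(sys$m0)
  obs_dim <- nrow(sys$H)
  cQ <- chol(sys$Q); cR <- chol(sys$R)
  x <- sys$m0 + drop(t(chol(sys$P0)) %*% stats::rnorm(L))
  Y <- matrix(NA_real_, obs_dim, n)
  for (k in seq_len(n)) {
    if (k > 1L) x <- drop(sys$A %*% x) + drop(t(cQ) %*% stats::rnorm(L))
    Y[, k] <- drop(sys$H %*% x) + drop(t(cR) %*% stats::rnorm(obs_dim))
  }
  Y
}

# Full UKF pass over a linear system using the package primitives,
# matching the kalman_filter() convention above.
ukf_linear_run <- function(Y, sys, config = ut_config(),
                           augmented = FALSE) {
  n <- ncol(Y)
  b <- gaussian_belief(sys$m0, sys$P0)
  trans <- function(x) drop(sys$A %*% x)
  obs <- function(x) drop(sys$H %*% x)
  means <- matrix(NA_real_, length(sys$m0), n)
  covs <- vector("list", n)
  for (k in seq_len(n)) {
    if (k > 1L)
      b <- ukf_predict(b, trans, sys$Q, config, augmented = augmented,
                       R = sys$R)
    upd <- ukf_update(b, obs, Y[, k], sys$R, config)
    b <- upd$posterior
    means[, k] <- b$mean
    covs[[k]] <- b$cov
  }
  list(means = means, covs = covs)
}

# Free-parameter prior in filter order, for recovery checks.
free_prior <- function() {
  pr <- hemo_prior()
  i <- match(c("epsilon", "tau_s", "tau_f", "tau_0", "E_0"),
             pr$parameter)
  list(mean = pr$mean[i], sd = pr$sd[i])
}

# Shared small design for fast end-to-end tests.
small_design <- function() block_design(n_blocks = 4L,
                                        scans_per_block = 4L, tr = 2,
                                        lead_in_scans = 4L)
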