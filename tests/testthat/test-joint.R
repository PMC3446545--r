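test_that("block extraction partitions and reassembles exactly", {
  set.seed(12)
  P <- crossprod(matrix(rnorm(81), 9)) + diag(0.1, 9)
  bl <- extract_blocks(P)
  expect_identical(bl$Pxx, P[1:4, 1:4])
  expect_identical(bl$Pxw, P[1:4, 5:9])
  expect_identical(bl$Pwx, P[5:9, 1:4])
  expect_identical(bl$Pww, P[5:9, 5:9])
  expect_equal(bl$Pwx, t(bl$Pxw))
  expect_identical(rbind(cbind(bl$Pxx, bl$Pxw), cbind(bl$Pwx, bl$Pww)), P)

  Pd <- hemodual:::blkdiag(diag(2, 4), diag(3, 5))
  expect_identical(extract_blocks(Pd)$Pxw, matrix(0, 4, 5))
  expect_error(extract_blocks(diag(5)), "9 x 9")
})

test_that("joint filter is self-consistent on noise-free data at truth", {
  sim <- simulate_bold(small_design(), obs_noise_sd = 0, seed = 2)
  st <- make_block_stimulus(small_design())
  pr <- free_prior()
  fit <- run_joint_ukf(sim$y, st,
                       init_params = gaussian_belief(pr$mean, diag(1e-10, 5)),
                       init_state = gaussian_belief(c(1, 0, 1, 1),
                                                    diag(1e-10, 4)),
                       Q = 1e-12, R = 1e-8, R_r = diag(0, 5))
  expect_lt(max(abs(fit$innovation)), 1e-6)
  expect_lt(max(abs(sweep(fit$param_mean, 2, pr$mean))), 1e-3)
})

test_that("joint filter develops state-parameter cross-covariance", {
  # the modeled interaction: P_xw leaves zero once stimulation starts
  pr <- free_prior()
  sim <- simulate_bold(seed = 4)
  st <- make_block_stimulus(block_design())
  fit <- run_joint_ukf(sim$y, st,
                       init_params = gaussian_belief(pr$mean + pr$sd,
                                                     diag(pr$sd^2)),
                       R = attr(sim, "obs_noise_sd")^2)
  first_stim <- min(which(st$u > 0))
  end_first_block <- first_stim + 7L
  expect_gt(max(fit$cross_max[seq_len(end_first_block)]), 1e-8)
  expect_identical(dim(fit$final_joint$cov), c(9L, 9L))
})

test_that("dual and joint Cholesky dimensions match the two schemes", {
  expect_identical(unname(filter_dimensions("dual", "plain")), c(4L, 5L))
  expect_identical(unname(filter_dimensions("joint", "plain")), 9L)
  expect_identical(unname(filter_dimensions("dual", "augmented")),
                   c(9L, 11L))
  expect_identical(unname(filter_dimensions("joint", "augmented")), 19L)
})

test_that("zeroing the cross blocks bridges joint to dual on a toy model", {
  # linear toy: 2 states with stable dynamics, 1 inert parameter that
  # enters neither the transition nor the observation.  With the cross
  # blocks forced to zero the joint filter must reproduce the dual
  # scheme (separate state filter; parameter filter with zero gain).
  set.seed(13)
  A <- matrix(c(0.9, 0.2, -0.1, 0.7), 2)
  H <- matrix(c(1, 0.5), 1)
  Q <- diag(0.01, 2); R <- 0.05; R_r <- 0.001
  n <- 40
  x <- c(1, -1); Y <- numeric(n)
  for (k in 1:n) {
    if (k > 1) x <- drop(A %*% x)
    Y[k] <- drop(H %*% x)            # noise-free observations
  }

  # dual route: 2-D state filter + scalar parameter filter
  bx <- gaussian_belief(c(0.5, -0.5), diag(0.5, 2))
  bw <- gaussian_belief(0.3, matrix(0.2))
  dual_x <- matrix(NA_real_, 2, n); dual_w <- numeric(n)
  for (k in 1:n) {
    if (k > 1) bx <- ukf_predict(bx, function(z) drop(A %*% z), Q)
    bx <- ukf_update(bx, function(z) drop(H %*% z), Y[k], R)$posterior
    bw <- parameter_time_update(bw, R_r)  # zero-gain measurement step
    dual_x[, k] <- bx$mean; dual_w[k] <- bw$mean
  }

  # joint route with forced decoupling
  bj <- gaussian_belief(c(0.5, -0.5, 0.3),
                        hemodual:::blkdiag(diag(0.5, 2), matrix(0.2)))
  joint_x <- matrix(NA_real_, 2, n); joint_w <- numeric(n)
  for (k in 1:n) {
    if (k > 1)
      bj <- ukf_predict(bj, function(z) c(drop(A %*% z[1:2]), z[3]),
                        hemodual:::blkdiag(Q, matrix(R_r)))
    bj <- ukf_update(bj, function(z) drop(H %*% z[1:2]), Y[k], R)$posterior
    P <- bj$cov; P[1:2, 3] <- 0; P[3, 1:2] <- 0
    bj <- gaussian_belief(bj$mean, P)
    joint_x[, k] <- bj$mean[1:2]; joint_w[k] <- bj$mean[3]
  }

  expect_equal(joint_x, dual_x, tolerance = 1e-6)
  expect_equal(joint_w, dual_w, tolerance = 1e-6)
})

test_that("zero_cross flag keeps the Balloon joint filter decoupled", {
  sim <- simulate_bold(small_design(), seed = 7)
  st <- make_block_stimulus(small_design())
  fit <- run_joint_ukf(sim$y, st, zero_cross = TRUE)
  expect_identical(max(fit$cross_max), 0)
})
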