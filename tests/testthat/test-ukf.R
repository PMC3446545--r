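test_that("sigma points reproduce the source moments", {
  # closed-form 1-D construction: lambda = 2, spread sqrt(3) sigma
  b <- gaussian_belief(2, matrix(4))
  sp <- generate_sigma_points(b)
  expect_equal(sort(drop(sp$points)),
               sort(c(2, 2 + sqrt(3) * 2, 2 - sqrt(3) * 2)))
  expect_equal(sum(sp$Wm), 1, tolerance = 1e-14)

  # random SPD covariances up to the joint-augmented dimension
  set.seed(3)
  for (L in c(2, 4, 5, 9, 11, 19)) {
    m <- rnorm(L)
    P <- crossprod(matrix(rnorm(L * L), L, L)) + diag(0.1, L)
    sp <- generate_sigma_points(gaussian_belief(m, P))
    expect_equal(sum(sp$Wm), 1, tolerance = 1e-14)
    expect_equal(drop(sp$points %*% sp$Wm), m, tolerance = 1e-12)
    D <- sp$points - m
    expect_equal(D %*% (sp$Wc * t(D)), P,
                 tolerance = 1e-10)
  }
})

test_that("unscented transform is exact for affine and quadratic maps", {
  set.seed(4)
  b <- gaussian_belief(rnorm(3), {
    M <- matrix(rnorm(9), 3); crossprod(M) + diag(0.2, 3)
  })
  sp <- generate_sigma_points(b)

  tr_id <- unscented_transform(sp, identity)
  expect_equal(tr_id$mean, b$mean, tolerance = 1e-12)
  expect_equal(tr_id$cov, b$cov, tolerance = 1e-12)

  A <- matrix(rnorm(6), 2, 3); bias <- rnorm(2)
  tr_aff <- unscented_transform(sp, function(x) drop(A %*% x) + bias)
  expect_equal(tr_aff$mean, drop(A %*% b$mean) + bias, tolerance = 1e-12)
  expect_equal(tr_aff$cov, A %*% b$cov %*% t(A), tolerance = 1e-12)

  # E[x^2] = 1 for standard normal: the UT is exact on quadratics
  sp1 <- generate_sigma_points(gaussian_belief(0, matrix(1)))
  expect_equal(unscented_transform(sp1, function(x) x^2)$mean, 1,
               tolerance = 1e-12)
})

test_that("predict matches the analytic Kalman prediction", {
  set.seed(5)
  b <- gaussian_belief(rnorm(3), crossprod(matrix(rnorm(9), 3)) + diag(0.2, 3))
  expect_equal(ukf_predict(b, identity, 0)$mean, b$mean, tolerance = 1e-12)
  expect_equal(ukf_predict(b, identity, 0)$cov, b$cov, tolerance = 1e-10)

  A <- matrix(rnorm(9), 3)
  Q <- crossprod(matrix(rnorm(9, sd = 0.5), 3)) + diag(0.1, 3)
  pred <- ukf_predict(b, function(x) drop(A %*% x), Q)
  expect_equal(pred$mean, drop(A %*% b$mean), tolerance = 1e-10)
  expect_equal(pred$cov, A %*% b$cov %*% t(A) + Q, tolerance = 1e-10)
})

test_that("update matches the conjugate-Gaussian closed form", {
  b <- gaussian_belief(1.3, matrix(0.7))
  R <- 0.4; y <- 2.1
  upd <- ukf_update(b, identity, y, R)
  K <- 0.7 / (0.7 + R)
  expect_equal(upd$posterior$mean, 1.3 + K * (y - 1.3), tolerance = 1e-12)
  expect_equal(drop(upd$posterior$cov), 0.7 - K^2 * (0.7 + R),
               tolerance = 1e-12)

  # zero innovation leaves the mean fixed
  upd0 <- ukf_update(b, identity, 1.3, R)
  expect_equal(upd0$posterior$mean, 1.3, tolerance = 1e-12)

  # infinite observation noise carries no information
  updInf <- ukf_update(b, identity, 5, 1e12)
  expect_equal(updInf$posterior$mean, 1.3, tolerance = 1e-6)
  expect_equal(drop(updInf$posterior$cov), 0.7, tolerance = 1e-6)
})

test_that("full UKF trajectory matches the textbook Kalman filter", {
  # the module's master oracle: random stable linear-Gaussian systems
  set.seed(7)
  for (rep in 1:3) {
    sys <- random_linear_system(4)
    Y <- simulate_linear(sys, 100)
    kf <- kalman_filter(Y, sys$A, sys$H, sys$Q, sys$R, sys$m0, sys$P0)
    uk <- ukf_linear_run(Y, sys)
    scale <- max(abs(kf$means))
    expect_lt(max(abs(uk$means - kf$means)) / scale, 1e-8)
    expect_lt(max(mapply(function(a, b) max(abs(a - b)),
                         uk$covs, kf$covs)), 1e-8)
  }
})

test_that("augmented and plain modes agree for additive noise", {
  set.seed(8)
  sys <- random_linear_system(3)
  Y <- simulate_linear(sys, 50)
  plain <- ukf_linear_run(Y, sys, augmented = FALSE)
  aug <- ukf_linear_run(Y, sys, augmented = TRUE)
  expect_equal(plain$means, aug$means, tolerance = 1e-10)
  expect_lt(max(mapply(function(a, b) max(abs(a - b)),
                       plain$covs, aug$covs)), 1e-10)
})

test_that("augmented dimension bookkeeping follows L_x + L_v + L_n", {
  expect_identical(augment_dimensions(4)$L_aug, 9L)       # state filter
  expect_identical(augment_dimensions(5, 5)$L_aug, 11L)   # parameter filter
  expect_identical(augment_dimensions(9)$L_aug, 19L)      # joint filter
})

test_that("batched scalar update agrees with the generic update", {
  set.seed(9)
  b <- gaussian_belief(rnorm(4), crossprod(matrix(rnorm(16), 4)) + diag(0.2, 4))
  h <- rnorm(4)
  gen <- ukf_update(b, function(x) sum(h * x), 0.7, 0.3)
  bat <- hemodual:::scalar_update_batched(b, function(X) drop(h %*% X),
                                          0.7, 0.3, ut_config())
  expect_equal(gen$posterior$mean, bat$posterior$mean, tolerance = 1e-12)
  expect_equal(gen$posterior$cov, bat$posterior$cov, tolerance = 1e-12)
  expect_equal(drop(gen$S), bat$S, tolerance = 1e-12)
})

test_that("covariance conditioning jitters and then fails loudly", {
  # rank-deficient covariance: jitter rescues the factorization
  P <- matrix(1, 2, 2)
  sp <- generate_sigma_points(gaussian_belief(c(0, 0), P))
  D <- sp$points - 0
  expect_equal(D %*% (sp$Wc * t(D)), P, tolerance = 1e-6)
  # an indefinite covariance beyond the jitter budget cannot be rescued
  expect_error(generate_sigma_points(
    gaussian_belief(c(0, 0), diag(c(-1, 1)))),
    "Cholesky")
})
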