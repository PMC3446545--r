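test_that("rest is an exact fixed point for any valid parameter draw", {
  draws <- draw_parameters(100, seed = 11)
  for (i in seq_len(nrow(draws))) {
    p <- as_hemo_params(draws[i, ])
    d <- balloon_derivatives(c(1, 0, 1, 1), p, u = 0)
    expect_identical(unname(d), c(0, 0, 0, 0))
    expect_identical(bold_observe(c(1, 0, 1, 1), p), 0)
  }
})

test_that("derivatives match independent term-by-term evaluation", {
  p <- hemo_params()  # prior means, alpha = 0.33

  # at rest under input only the efficacy term of the flow signal fires
  d <- balloon_derivatives(c(1, 0, 1, 1), p, u = 1)
  expect_equal(unname(d), c(0, 0.54, 0, 0))

  # raised flow, independent hand evaluation of each equation
  d <- balloon_derivatives(c(1.2, 0, 1, 1), p, u = 0)
  expect_equal(d[["f"]], 0)
  expect_equal(d[["s"]], -(1.2 - 1) / 2.46, tolerance = 1e-12)
  expect_equal(d[["v"]], (1.2 - 1) / 0.98, tolerance = 1e-12)
  expect_equal(d[["q"]],
               (1.2 * (1 - 0.66^(1 / 1.2)) / 0.34 - 1) / 0.98,
               tolerance = 1e-12)

  expect_error(balloon_derivatives(c(-1, 0, 1, 1), p, 0), "positiv")
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(hemo_params(alpha = 1.2), "alpha")
  expect_error(hemo_params(E_0 = 0), "E_0")
  expect_error(hemo_params(tau_s = -1), "positive")
  expect_error(as_hemo_params(list(epsilon = 1)), "missing parameter")
})

test_that("BOLD coefficients follow the 1.5 T calibration", {
  expect_equal(unname(bold_coefficients(0.34)), c(2.38, 2, 0.48))
  expect_equal(unname(bold_coefficients(0.1)), c(0.7, 2, 0))
  for (E0 in seq(0.05, 0.95, by = 0.1))
    expect_identical(bold_coefficients(E0)[["k2"]], 2)
  expect_error(bold_coefficients(1.2), "E_0")
  expect_error(bold_coefficients(0), "E_0")
})

test_that("BOLD observation matches hand evaluation and rests at zero", {
  p <- hemo_params(E_0 = 0.34, V_0 = 0.02)
  expect_equal(bold_observe(c(1, 0, 0.8, 1.1), p),
               0.02 * (2.38 * 0.2 + 2 * (1 - 0.8 / 1.1) + 0.48 * (-0.1)),
               tolerance = 1e-12)
  expect_equal(bold_observe(c(1, 0, 1, 1.2), p),
               0.02 * (2 * (1 - 1 / 1.2) + 0.48 * (-0.2)),
               tolerance = 1e-12)
  expect_error(bold_observe(c(1, 0, 1, -0.1), p), "v must")
})

test_that("integrator preserves the fixed point and responds to input", {
  p <- hemo_params()
  x <- integrate_step(c(1, 0, 1, 1), p, u = 0, tr = 2, dt_sub = 0.1)
  expect_equal(unname(x), c(1, 0, 1, 1), tolerance = 1e-14)

  x1 <- integrate_step(c(1, 0, 1, 1), p, u = 1, tr = 2, dt_sub = 0.1)
  ref <- integrate_step(c(1, 0, 1, 1), p, u = 1, tr = 2, dt_sub = 0.002)
  expect_gt(x1[["f"]], 1)   # flow rises under stimulation
  expect_gt(x1[["v"]], 1)   # volume follows
  expect_equal(unname(x1), unname(ref), tolerance = 1e-5)
})

test_that("integration error shrinks at fourth order in the substep", {
  p <- hemo_params()
  x0 <- c(1.1, 0.3, 0.95, 1.05)
  ref <- integrate_step(x0, p, u = 1, tr = 2, dt_sub = 0.001)
  hs <- c(0.2, 0.1, 0.05, 0.025)
  err <- vapply(hs, function(h)
    max(abs(integrate_step(x0, p, u = 1, tr = 2, dt_sub = h) - ref)), 0)
  slope <- unname(stats::coef(stats::lm(log(err) ~ log(hs)))[2])
  expect_gt(slope, 3.7)
  expect_lt(slope, 4.3)
})

test_that("flow peaks before volume and dHb returns to baseline", {
  p <- hemo_params()
  x <- rest_state <- c(1, 0, 1, 1)
  n <- 600
  F <- V <- Q <- numeric(n)
  for (k in seq_len(n)) {  # 60 s at 0.1 s resolution, 16 s boxcar
    x <- integrate_step(x, p, u = as.numeric(k * 0.1 <= 16), tr = 0.1,
                        dt_sub = 0.1)
    F[k] <- x[1]; Q[k] <- x[3]; V[k] <- x[4]
  }
  expect_lt(which.max(F), which.max(V))
  expect_lt(abs(Q[n] - 1), 0.05 * max(abs(Q - 1)))
})

test_that("batched propagation agrees with the scalar path", {
  p <- hemo_params(epsilon = 0.6, tau_0 = 1.1, E_0 = 0.4)
  X0 <- cbind(c(1, 0, 1, 1), c(1.1, 0.2, 0.9, 1.05), c(0.9, -0.1, 1.1, 0.95))
  u_seq <- c(1, 0, 1)
  Xb <- hemodual:::integrate_mat(X0, p$epsilon, 1 / p$tau_s, 1 / p$tau_f,
                                 1 / p$tau_0, 1 / p$alpha, p$E_0,
                                 u_seq, tr = 2, dt_sub = 0.1)
  for (j in 1:3) {
    x <- X0[, j]
    for (u in u_seq) x <- integrate_step(x, p, u, tr = 2, dt_sub = 0.1)
    expect_equal(Xb[, j], unname(x), tolerance = 1e-13)
  }
  expect_equal(hemodual:::bold_observe_mat(Xb, p$E_0, p$V_0),
               vapply(1:3, function(j) bold_observe(Xb[, j], p), 0),
               tolerance = 1e-14)
})
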