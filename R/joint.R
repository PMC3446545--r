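#' Joint unscented Kalman filter for the Balloon model
#'
#' Baseline estimator: a single UKF over the concatenated 9-dimensional
#' vector `[f, s, q, v, epsilon, tau_s, tau_f, tau_0, E_0]`.  The
#' transition propagates the state block through the Balloon dynamics
#' under each sigma point's *own* parameter block and applies the
#' identity (plus random-walk noise `R_r`) to the parameter block; the
#' observation evaluates the BOLD equation with the sigma point's own
#' `E_0`.  Unlike the dual filter, the full state-parameter
#' cross-covariance `P_xw` is represented and propagated.
#'
#' @inheritParams run_dual_ukf
#' @param init optional initial [gaussian_belief()] of dimension 9
#'   (block order states then parameters); by default assembled from
#'   `init_state` and `init_params`.
#' @param zero_cross logical; if `TRUE` the off-diagonal
#'   state-parameter blocks are forced to zero after every update
#'   (a diagnostic bridge towards the dual scheme, not a recommended
#'   estimator).
#' @return An object of class `c("joint_ukf_fit", "ukf_fit")` with the
#'   same trace fields as [run_dual_ukf()] plus `cross_max`, the
#'   per-step maximum absolute entry of the `P_xw` block, and
#'   `final_joint`, the full 9-dimensional terminal belief.
#' @seealso [extract_blocks()] to partition the joint covariance.
#' @export
run_joint_ukf <- function(y, stimulus, init = NULL, init_state = NULL,
                          init_params = NULL, Q = 1e-6, R = NULL,
                          R_r = NULL, config = ut_config(),
                          dt_sub = 0.1, alpha = 0.33, V_0 = 0.02,
                          augmented = FALSE, anneal = NULL,
                          zero_cross = FALSE) {
  inp <- prepare_filter_inputs(y, stimulus, init_state, init_params,
                               Q, R, R_r)
  n <- length(inp$y)
  tr <- inp$tr
  if (is.null(init))
    init <- gaussian_belief(c(inp$init_state$mean, inp$init_params$mean),
                            blkdiag(inp$init_state$cov,
                                    inp$init_params$cov))
  stopifnot(length(init$mean) == 9L)
  b <- init
  R_r_k <- inp$R_r
  n_clip <- n_floor <- 0L
  ukf_diag_start()

  transition_at <- function(u_prev) function(z) {
    w <- project_parameters(z[5:9])
    pk <- w_to_params(w, alpha, V_0)
    x <- integrate_step_vec(floor_state(z[1:4]), pk$epsilon,
                            1 / pk$tau_s, 1 / pk$tau_f, 1 / pk$tau_0,
                            1 / pk$alpha, pk$E_0, u_prev, tr, dt_sub)
    c(x, z[5:9])
  }
  obs_fn <- function(z) {
    E0 <- min(max(z[9L], W_LO[5L]), W_HI[5L])
    bold_observe_vec(floor_state(z[1:4]), E0, V_0)
  }

  state_mean <- matrix(NA_real_, n, 4,
                       dimnames = list(NULL, c("f", "s", "q", "v")))
  state_sd <- state_mean
  param_mean <- matrix(NA_real_, n, 5, dimnames = list(NULL, W_NAMES))
  param_sd <- param_mean
  y_pred <- innov <- innov_var <- pw_trace <- cross_max <- numeric(n)

  obs_mat <- function(Z) {
    E0 <- pmin(pmax(Z[9L, ], W_LO[5L]), W_HI[5L])
    bold_observe_mat(floor_mat(Z[1:4, , drop = FALSE]), E0, V_0)
  }

  for (k in seq_len(n)) {
    if (k == 1L) prior <- b
    else if (augmented) {
      Qj <- blkdiag(inp$Q, R_r_k)
      prior <- ukf_predict(b, transition_at(inp$u[k - 1L]), Qj, config,
                           augmented = TRUE, R = inp$R)
    } else {
      sp <- generate_sigma_points(b, config)
      Z <- sp$points
      W <- pmin(pmax(Z[5:9, , drop = FALSE], W_LO), W_HI)
      X <- integrate_mat(floor_mat(Z[1:4, , drop = FALSE]), W[1L, ],
                         1 / W[2L, ], 1 / W[3L, ], 1 / W[4L, ],
                         1 / alpha, W[5L, ], inp$u[k - 1L], tr, dt_sub)
      Zp <- rbind(X, Z[5:9, , drop = FALSE])
      mom <- weighted_moments(Zp, sp$Wm, sp$Wc)
      prior <- gaussian_belief(mom$mean, mom$cov + blkdiag(inp$Q, R_r_k))
    }
    upd <- if (augmented && k > 1L)
      ukf_update(prior, obs_fn, inp$y[k], inp$R, config)
    else scalar_update_batched(prior, obs_mat, inp$y[k], drop(inp$R),
                               config)
    m <- upd$posterior$mean
    mx <- floor_state(m[1:4])
    if (any(mx != m[1:4])) n_floor <- n_floor + 1L
    mw <- project_parameters(m[5:9])
    if (attr(mw, "clipped")) n_clip <- n_clip + 1L
    P <- upd$posterior$cov
    if (zero_cross) {
      P[1:4, 5:9] <- 0
      P[5:9, 1:4] <- 0
    }
    b <- gaussian_belief(c(mx, as.numeric(mw)), P)
    if (!is.null(anneal)) R_r_k <- R_r_k * anneal

    state_mean[k, ] <- b$mean[1:4]
    state_sd[k, ] <- sqrt(pmax(diag(P)[1:4], 0))
    param_mean[k, ] <- b$mean[5:9]
    param_sd[k, ] <- sqrt(pmax(diag(P)[5:9], 0))
    pw_trace[k] <- sum(diag(P)[5:9])
    cross_max[k] <- max(abs(P[1:4, 5:9]))
    y_pred[k] <- upd$y_pred
    innov[k] <- upd$innovation
    innov_var[k] <- drop(upd$S)
  }

  structure(list(
    scheme = "joint", time = inp$times, u = inp$u, y = inp$y,
    state_mean = state_mean, state_sd = state_sd,
    param_mean = param_mean, param_sd = param_sd,
    y_pred = y_pred, innovation = innov, innovation_var = innov_var,
    param_cov_trace = pw_trace, cross_max = cross_max,
    final_joint = b,
    final_state = gaussian_belief(b$mean[1:4], b$cov[1:4, 1:4]),
    final_params = gaussian_belief(b$mean[5:9], b$cov[5:9, 5:9]),
    diagnostics = list(n_param_clip = n_clip, n_state_floor = n_floor,
                       log = ukf_diag_collect()),
    settings = list(Q = inp$Q, R = inp$R, R_r = inp$R_r,
                    dt_sub = dt_sub, alpha = alpha, V_0 = V_0,
                    augmented = augmented, anneal = anneal,
                    zero_cross = zero_cross, config = config)),
    class = c("joint_ukf_fit", "ukf_fit"))
}

#' Partition a joint covariance into state/parameter blocks
#'
#' Splits a 9 x 9 joint covariance (or a `gaussian_belief` holding
#' one) into the four blocks `P_xx` (4 x 4), `P_xw` (4 x 5), `P_wx`
#' (5 x 4) and `P_ww` (5 x 5), following the block layout
#' `[states; parameters]`.
#'
#' @param x a 9 x 9 matrix, a [gaussian_belief()] of dimension 9, or a
#'   `joint_ukf_fit`.
#' @return A list with elements `Pxx`, `Pxw`, `Pwx`, `Pww`.
#' @export
extract_blocks <- function(x) {
  if (inherits(x, "joint_ukf_fit")) x <- x$final_joint
  P <- if (inherits(x, "gaussian_belief")) x$cov else as.matrix(x)
  if (!all(dim(P) == c(9L, 9L)))
    stop("expected a 9 x 9 joint covariance, got ",
         paste(dim(P), collapse = " x "))
  list(Pxx = P[1:4, 1:4], Pxw = P[1:4, 5:9],
       Pwx = P[5:9, 1:4], Pww = P[5:9, 5:9])
}
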