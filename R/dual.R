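#' Prior distribution of the Balloon parameters
#'
#' Independent normal priors for the seven Balloon parameters, used to
#' draw simulation truths and to initialize the parameter filter.
#'
#' @return A data frame with columns `parameter`, `mean`, `sd`.
#' @export
hemo_prior <- function() {
  data.frame(
    parameter = c("epsilon", "tau_s", "tau_f", "tau_0", "alpha",
                  "E_0", "V_0"),
    mean = c(0.54, 1.54, 2.46, 0.98, 0.33, 0.34, 0.02),
    sd   = c(0.10, 0.25, 0.25, 0.25, 0.045, 0.10, 0.005),
    stringsAsFactors = FALSE)
}

# The five parameters estimated by the filters (alpha and V_0 are held
# fixed: V_0 is unidentifiable jointly with the others since only their
# product enters each measurement, and alpha is a nominal factor).
W_NAMES <- c("epsilon", "tau_s", "tau_f", "tau_0", "E_0")
W_LO <- c(1e-3, 0.05, 0.05, 0.05, 0.01)
W_HI <- c(5, 20, 20, 20, 0.99)

# Prior mean/sd restricted to the free parameters, in filter order.
w_prior <- function() {
  pr <- hemo_prior()
  i <- match(W_NAMES, pr$parameter)
  list(mean = pr$mean[i], sd = pr$sd[i])
}

#' Project a free-parameter vector onto its validity box
#'
#' Clips the five filtered parameters `(epsilon, tau_s, tau_f, tau_0,
#' E_0)` to their admissible ranges: efficacy to `[1e-3, 5]`, the three
#' time constants to `[0.05, 20]` s, and `E_0` to `[0.01, 0.99]`.
#' Idempotent.  The returned vector carries a logical attribute
#' `"clipped"` indicating whether any component was moved.
#'
#' @param w numeric vector of length 5 in the order above.
#' @return The projected vector (same order), with attribute
#'   `"clipped"`.
#' @export
project_parameters <- function(w) {
  w <- as.numeric(w)
  stopifnot(length(w) == 5L)
  out <- pmin(pmax(w, W_LO), W_HI)
  attr(out, "clipped") <- any(out != w)
  out
}

# Fast unchecked hemo_params from a free-parameter vector.
w_to_params <- function(w, alpha, V_0) {
  structure(list(epsilon = w[1L], tau_s = w[2L], tau_f = w[3L],
                 tau_0 = w[4L], alpha = alpha, E_0 = w[5L], V_0 = V_0),
            class = "hemo_params")
}

#' Extract the free-parameter vector from a parameter set
#'
#' @param params a [hemo_params()] object (or coercible).
#' @return Named numeric vector `(epsilon, tau_s, tau_f, tau_0, E_0)`.
#' @export
params_to_w <- function(params) {
  params <- as_hemo_params(params)
  stats::setNames(c(params$epsilon, params$tau_s, params$tau_f,
                    params$tau_0, params$E_0), W_NAMES)
}

#' Random-walk time update of the parameter belief
#'
#' The parameter filter models the parameters as a stationary process
#' with identity transition driven by a small random-walk noise:
#' the time update leaves the mean unchanged and adds `R_r` to the
#' covariance.
#'
#' @param belief a [gaussian_belief()] over the free parameters.
#' @param R_r random-walk covariance (matrix, diagonal vector or
#'   scalar).
#' @return The updated [gaussian_belief()].
#' @export
parameter_time_update <- function(belief, R_r) {
  gaussian_belief(belief$mean, belief$cov + as_cov(R_r, length(belief$mean)))
}

# Shared input validation / defaults for the two runners.
prepare_filter_inputs <- function(y, stimulus, init_state, init_params,
                                  Q, R, R_r) {
  stopifnot(inherits(stimulus, "stimulus_train"))
  y <- as.numeric(y)
  if (length(y) != length(stimulus$u))
    stop("observations and stimulus must share the acquisition grid")
  tr <- attr(stimulus, "tr")
  pr <- w_prior()
  if (is.null(init_state))
    init_state <- gaussian_belief(rest_state(), diag(1e-2, 4))
  if (is.null(init_params))
    init_params <- gaussian_belief(pr$mean, diag(pr$sd^2))
  if (is.null(R)) R <- (0.1 * max(abs(y)))^2
  if (is.null(R_r)) R_r <- diag(1e-4 * pr$sd^2)
  list(y = y, u = stimulus$u, times = stimulus$times, tr = tr,
       init_state = init_state, init_params = init_params,
       Q = as_cov(Q, 4L), R = as_cov(R, 1L), R_r = as_cov(R_r, 5L))
}

#' Dual unscented Kalman filter for the Balloon model
#'
#' Runs two UKFs alternately at every acquisition: a 4-dimensional
#' state filter over `(f, s, q, v)` and a 5-dimensional parameter
#' filter over `(epsilon, tau_s, tau_f, tau_0, E_0)`.  The current
#' parameter mean is handed to the state filter as a known input and
#' the previous state posterior mean is handed to the parameter filter,
#' so no state-parameter cross-covariance is ever represented — the
#' two problems are statistically decoupled.
#'
#' The parameter filter's measurement map takes the state estimate from
#' `horizon` acquisitions back, propagates it to the current
#' acquisition under each candidate parameter vector (with the known
#' input history), and evaluates the BOLD equation with that
#' candidate's `E_0` (the observation coefficients are recomputed from
#' the current `E_0` at every evaluation).  A multi-scan horizon is
#' essential for balanced parameter observability: over a single
#' repetition time the signal is sensitive almost only to `E_0`
#' (which enters the observation directly), so a one-step map lets
#' `E_0` absorb amplitude errors that belong to the dynamical
#' parameters; over a horizon of about one stimulation block the
#' integrated effects of `epsilon` and the time constants become
#' visible.  Parameter sigma points and posterior means are projected
#' onto the validity box by [project_parameters()] (a diagnostic
#' counter records every clip).
#'
#' @param y numeric vector of BOLD observations, one per acquisition.
#' @param stimulus a [stimulus_train()] on the same grid.
#' @param init_state initial [gaussian_belief()] over the state;
#'   default: rest `(1, 0, 1, 1)` with diagonal covariance `1e-2`.
#' @param init_params initial [gaussian_belief()] over the free
#'   parameters; default: prior means with prior variances.
#' @param Q state process-noise covariance (default `1e-6` diagonal).
#' @param R observation-noise variance; default `(0.1 max|y|)^2`.
#' @param R_r parameter random-walk covariance; default diagonal,
#'   `1e-4` times the prior variances.
#' @param config a [ut_config()].
#' @param dt_sub integration substep, seconds.
#' @param alpha,V_0 the two parameters held fixed during estimation.
#' @param order which filter runs first within a step;
#'   `"state_first"` (default) uses the previous parameter mean in the
#'   state filter, `"param_first"` the reverse.
#' @param horizon measurement-map prediction horizon of the parameter
#'   filter, in acquisitions (default 8, about one stimulation block
#'   of the default design; 1 recovers the one-step map).
#' @param augmented logical; use the noise-augmented sigma-point form
#'   (augmented dimensions 9 for the state filter, 11 for the
#'   parameter filter).
#' @param anneal optional scalar in (0, 1]; `R_r` is multiplied by it
#'   after every step (exponential annealing of the random walk).
#' @param log_space logical; filter the parameters on the log scale
#'   (the measurement map exponentiates; the initial belief is moved to
#'   log scale by the delta method).
#' @return An object of class `c("dual_ukf_fit", "ukf_fit")`: a list
#'   with per-acquisition matrices `state_mean`, `state_sd`,
#'   `param_mean`, `param_sd`, vectors `y_pred`, `innovation`,
#'   `innovation_var`, `param_cov_trace`, the inputs, and a
#'   `diagnostics` list (clip/floor/jitter counters).  No joint
#'   state-parameter covariance exists anywhere in the result.
#' @seealso [run_joint_ukf()] for the baseline it is compared against,
#'   [hemofit()] for the modelling-style interface.
#' @export
run_dual_ukf <- function(y, stimulus, init_state = NULL,
                         init_params = NULL, Q = 1e-6, R = NULL,
                         R_r = NULL, config = ut_config(),
                         dt_sub = 0.1, alpha = 0.33, V_0 = 0.02,
                         order = c("state_first", "param_first"),
                         horizon = 8L, augmented = FALSE,
                         anneal = NULL, log_space = FALSE) {
  order <- match.arg(order)
  horizon <- max(1L, as.integer(horizon))
  inp <- prepare_filter_inputs(y, stimulus, init_state, init_params,
                               Q, R, R_r)
  n <- length(inp$y)
  tr <- inp$tr
  b_x <- inp$init_state
  b_w <- inp$init_params
  if (log_space) {
    m <- b_w$mean
    b_w <- gaussian_belief(log(m), diag(1 / m) %*% b_w$cov %*% diag(1 / m))
  }
  R_r_k <- inp$R_r
  if (log_space) {
    m <- inp$init_params$mean
    R_r_k <- diag(1 / m) %*% R_r_k %*% diag(1 / m)
  }
  w_of <- function(b) if (log_space) exp(b$mean) else b$mean

  state_mean <- matrix(NA_real_, n, 4,
                       dimnames = list(NULL, c("f", "s", "q", "v")))
  state_sd <- state_mean
  param_mean <- matrix(NA_real_, n, 5, dimnames = list(NULL, W_NAMES))
  param_sd <- param_mean
  y_pred <- innov <- innov_var <- pw_trace <- numeric(n)
  n_clip <- n_floor <- 0L
  ukf_diag_start()

  state_step <- function(k) {
    w_hat <- project_parameters(w_of(b_w))
    pk <- w_to_params(w_hat, alpha, V_0)
    if (k == 1L) prior <- b_x
    else if (augmented) {
      u_prev <- inp$u[k - 1L]
      transition <- function(x)
        integrate_step_vec(floor_state(x), pk$epsilon, 1 / pk$tau_s,
                           1 / pk$tau_f, 1 / pk$tau_0, 1 / pk$alpha,
                           pk$E_0, u_prev, tr, dt_sub)
      prior <- ukf_predict(b_x, transition, inp$Q, config,
                           augmented = TRUE, R = inp$R)
    } else {
      sp <- generate_sigma_points(b_x, config)
      Xp <- integrate_mat(floor_mat(sp$points), pk$epsilon,
                          1 / pk$tau_s, 1 / pk$tau_f, 1 / pk$tau_0,
                          1 / pk$alpha, pk$E_0, inp$u[k - 1L], tr,
                          dt_sub)
      mom <- weighted_moments(Xp, sp$Wm, sp$Wc)
      prior <- gaussian_belief(mom$mean, mom$cov + inp$Q)
    }
    upd <- if (augmented && k > 1L)
      ukf_update(prior, function(x)
        bold_observe_vec(floor_state(x), pk$E_0, V_0),
        inp$y[k], inp$R, config)
    else
      scalar_update_batched(prior, function(X)
        bold_observe_mat(floor_mat(X), pk$E_0, V_0),
        inp$y[k], drop(inp$R), config)
    m <- upd$posterior$mean
    mf <- floor_state(m)
    if (any(mf != m)) n_floor <<- n_floor + 1L
    b_x <<- gaussian_belief(mf, upd$posterior$cov)
    y_pred[k] <<- upd$y_pred
    innov[k] <<- drop(upd$innovation)
    innov_var[k] <<- drop(upd$S)
  }

  # state posterior means, for the parameter filter's reference
  post_x <- matrix(NA_real_, n, 4)

  param_step <- function(k) {
    # reference: the state estimate `hh` acquisitions back, propagated
    # to the current acquisition under the candidate parameters with
    # the known inputs u[k-hh], ..., u[k-1]
    hh <- min(horizon, k - 1L)
    s0 <- k - hh
    x_ref <- if (k == 1L) inp$init_state$mean else post_x[s0, ]
    u_seq <- if (hh > 0L) inp$u[s0:(k - 1L)] else numeric(0)
    if (augmented) {
      G <- function(wv) {
        w <- if (log_space) exp(wv) else wv
        w <- project_parameters(w)
        pk <- w_to_params(w, alpha, V_0)
        xp <- floor_state(x_ref)
        for (u in u_seq)
          xp <- integrate_step_vec(xp, pk$epsilon, 1 / pk$tau_s,
                                   1 / pk$tau_f, 1 / pk$tau_0,
                                   1 / pk$alpha, pk$E_0, u, tr, dt_sub)
        bold_observe_vec(xp, pk$E_0, V_0)
      }
      prior <- ukf_predict(b_w, identity, R_r_k, config,
                           augmented = TRUE, R = inp$R)
      upd <- ukf_update(prior, G, inp$y[k], inp$R, config)
    } else {
      prior <- parameter_time_update(b_w, R_r_k)
      Gmat <- function(W) {
        if (log_space) W <- exp(W)
        W <- pmin(pmax(W, W_LO), W_HI)
        X <- matrix(floor_state(x_ref), 4L, ncol(W))
        if (length(u_seq))
          X <- integrate_mat(X, W[1L, ], 1 / W[2L, ], 1 / W[3L, ],
                             1 / W[4L, ], 1 / alpha, W[5L, ], u_seq,
                             tr, dt_sub)
        bold_observe_mat(X, W[5L, ], V_0)
      }
      upd <- scalar_update_batched(prior, Gmat, inp$y[k],
                                   drop(inp$R), config)
    }
    m <- upd$posterior$mean
    if (!log_space) {
      mp <- project_parameters(m)
      if (attr(mp, "clipped")) n_clip <<- n_clip + 1L
      m <- as.numeric(mp)
    }
    b_w <<- gaussian_belief(m, upd$posterior$cov)
    if (!is.null(anneal)) R_r_k <<- R_r_k * anneal
  }

  for (k in seq_len(n)) {
    if (order == "state_first") {
      state_step(k); param_step(k)
    } else {
      param_step(k); state_step(k)
    }
    post_x[k, ] <- b_x$mean
    state_mean[k, ] <- b_x$mean
    state_sd[k, ] <- sqrt(pmax(diag(b_x$cov), 0))
    w_hat <- w_of(b_w)
    param_mean[k, ] <- w_hat
    psd <- sqrt(pmax(diag(b_w$cov), 0))
    param_sd[k, ] <- if (log_space) psd * w_hat else psd
    pw_trace[k] <- sum(diag(b_w$cov))
  }

  structure(list(
    scheme = "dual", time = inp$times, u = inp$u, y = inp$y,
    state_mean = state_mean, state_sd = state_sd,
    param_mean = param_mean, param_sd = param_sd,
    y_pred = y_pred, innovation = innov, innovation_var = innov_var,
    param_cov_trace = pw_trace,
    final_state = b_x,
    final_params = if (log_space)
      gaussian_belief(exp(b_w$mean), b_w$cov) else b_w,
    diagnostics = list(n_param_clip = n_clip, n_state_floor = n_floor,
                       log = ukf_diag_collect()),
    settings = list(Q = inp$Q, R = inp$R, R_r = inp$R_r,
                    dt_sub = dt_sub, alpha = alpha, V_0 = V_0,
                    order = order, horizon = horizon,
                    augmented = augmented, anneal = anneal,
                    log_space = log_space, config = config)),
    class = c("dual_ukf_fit", "ukf_fit"))
}

#' Total variation of parameter traces after an initial transient
#'
#' Sums, over the five filtered parameters, the absolute step-to-step
#' changes of the posterior parameter means from acquisition
#' `from_scan` onwards, each parameter normalized by its prior standard
#' deviation so the scales are comparable.  Used to quantify how much
#' the parameter estimates keep moving once filtering is under way —
#' the dual filter's traces are expected to be much flatter than the
#' joint filter's.
#'
#' @param fit a `dual_ukf_fit` or `joint_ukf_fit`.
#' @param from_scan first acquisition (1-based) included.
#' @return Scalar normalized total variation.
#' @export
trace_total_variation <- function(fit, from_scan = 1L) {
  W <- fit$param_mean[from_scan:nrow(fit$param_mean), , drop = FALSE]
  sds <- w_prior()$sd
  sum(vapply(seq_len(ncol(W)),
             function(j) sum(abs(diff(W[, j]))) / sds[j], 0))
}
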