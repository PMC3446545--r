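#' Gaussian belief
#'
#' A filter posterior at one time step: a mean vector and a symmetric
#' positive-semidefinite covariance matrix.
#'
#' @param mean numeric mean vector of length L.
#' @param cov L x L covariance matrix (a scalar is promoted to a 1 x 1
#'   matrix, a vector to a diagonal matrix).
#' @return An object of class `gaussian_belief`.
#' @export
gaussian_belief <- function(mean, cov) {
  mean <- as.numeric(mean)
  if (is.null(dim(cov))) {
    cov <- if (length(cov) == 1L && length(mean) > 1L)
      diag(rep(cov, length(mean)), length(mean))
    else diag(as.numeric(cov), length(mean))
  }
  cov <- as.matrix(cov)
  stopifnot(nrow(cov) == length(mean), ncol(cov) == length(mean))
  structure(list(mean = mean, cov = cov), class = "gaussian_belief")
}

#' @export
print.gaussian_belief <- function(x, ...) {
  cat("Gaussian belief, dimension", length(x$mean), "\n")
  cat("mean:", format(x$mean, digits = 4), "\n")
  invisible(x)
}

#' Unscented-transform scaling configuration
#'
#' Scaling constants of the scaled sigma-point construction.  The
#' composite scaling is `lambda = alpha^2 (L + kappa) - L`; with the
#' defaults `alpha = 1`, `kappa = 3 - L` this gives `L + lambda = 3`,
#' the classic choice that matches Gaussian fourth moments in the
#' scalar quadratic case.  `beta = 2` is optimal for Gaussian priors.
#'
#' @param alpha spread parameter, in (0, 1].
#' @param beta prior-distribution parameter (2 for Gaussians).
#' @param kappa secondary scaling; `NULL` (default) means `3 - L`,
#'   resolved when the dimension is known.
#' @return An object of class `ut_config`.
#' @export
ut_config <- function(alpha = 1, beta = 2, kappa = NULL) {
  stopifnot(alpha > 0, alpha <= 1)
  structure(list(alpha = alpha, beta = beta, kappa = kappa),
            class = "ut_config")
}

# Resolve weights for dimension L.  Returns list(lambda, gamma, Wm, Wc).
ut_weights <- function(L, config = ut_config()) {
  kappa <- if (is.null(config$kappa)) 3 - L else config$kappa
  lambda <- config$alpha^2 * (L + kappa) - L
  if (L + lambda <= 0) stop("invalid UT scaling: L + lambda must be > 0")
  Wm <- c(lambda / (L + lambda), rep(1 / (2 * (L + lambda)), 2L * L))
  Wc <- Wm
  Wc[1L] <- Wc[1L] + (1 - config$alpha^2 + config$beta)
  list(lambda = lambda, gamma = sqrt(L + lambda), Wm = Wm, Wc = Wc)
}

# Symmetrize and, if Cholesky fails, add escalating jitter
# (1e-9 * trace/L, x10, up to three escalations) before giving up.
# Returns the lower-triangular factor S with S %*% t(S) = P.
safe_chol_lower <- function(P, where = "covariance") {
  P <- (P + t(P)) / 2
  L <- nrow(P)
  jitter <- 0
  base <- 1e-9 * sum(diag(P)) / L
  if (!is.finite(base) || base <= 0) base <- 1e-12
  for (k in 0:3) {
    R <- tryCatch(chol(P + diag(jitter, L)), error = function(e) NULL)
    if (!is.null(R)) {
      if (k > 0)
        ukf_note(sprintf("jitter %g applied to %s Cholesky", jitter, where))
      return(structure(t(R), jitter_level = k))
    }
    jitter <- if (k == 0) base else jitter * 10
  }
  stop("Cholesky factorization of ", where,
       " failed even after jitter escalation (diverging filter?)")
}

# Lightweight diagnostics channel: counts events per category in an
# environment that callers can install; defaults to a no-op.
.ukf_diag <- new.env(parent = emptyenv())
ukf_note <- function(msg) {
  if (!is.null(.ukf_diag$log)) .ukf_diag$log <- c(.ukf_diag$log, msg)
  invisible(NULL)
}
ukf_diag_start <- function() .ukf_diag$log <- character(0)
ukf_diag_collect <- function() {
  out <- .ukf_diag$log
  .ukf_diag$log <- NULL
  out
}

#' Generate sigma points
#'
#' Deterministic 2L+1-point set capturing the mean and covariance of a
#' Gaussian belief exactly: the mean, plus/minus scaled columns of the
#' lower-triangular Cholesky factor of the covariance.
#'
#' @param belief a [gaussian_belief()].
#' @param config a [ut_config()].
#' @return A list with `points` (L x (2L+1) matrix), `Wm`, `Wc`
#'   (weights) and `gamma` (the column scaling).
#' @export
generate_sigma_points <- function(belief, config = ut_config()) {
  m <- belief$mean
  L <- length(m)
  w <- ut_weights(L, config)
  S <- safe_chol_lower(belief$cov, "belief covariance")
  pts <- matrix(m, nrow = L, ncol = 2L * L + 1L)
  shift <- w$gamma * S
  pts[, 2:(L + 1L)] <- pts[, 2:(L + 1L)] + shift
  pts[, (L + 2L):(2L * L + 1L)] <- pts[, (L + 2L):(2L * L + 1L)] - shift
  list(points = pts, Wm = w$Wm, Wc = w$Wc, gamma = w$gamma)
}

# Weighted mean and covariance of a point set (columns = points).
weighted_moments <- function(Y, Wm, Wc) {
  m <- drop(Y %*% Wm)
  D <- Y - m
  P <- D %*% (Wc * t(D))
  list(mean = m, cov = (P + t(P)) / 2)
}

#' Unscented transform
#'
#' Propagates a sigma-point set through a nonlinear map and returns the
#' weighted mean and covariance of the images, together with the mapped
#' points (needed for cross-covariances).
#'
#' @param sp a sigma-point set from [generate_sigma_points()].
#' @param map a function taking one point (numeric vector) and
#'   returning a numeric vector (constant length across points).
#' @return A list with `mean`, `cov` and `points` (mapped points).
#' @export
unscented_transform <- function(sp, map) {
  n <- ncol(sp$points)
  y1 <- tryCatch(map(sp$points[, 1L]),
                 error = function(e) stop("map failed on sigma point 1: ",
                                          conditionMessage(e)))
  Y <- matrix(0, nrow = length(y1), ncol = n)
  Y[, 1L] <- y1
  for (j in 2:n)
    Y[, j] <- tryCatch(map(sp$points[, j]),
                       error = function(e) stop("map failed on sigma point ",
                                                j, ": ", conditionMessage(e)))
  mom <- weighted_moments(Y, sp$Wm, sp$Wc)
  list(mean = mom$mean, cov = mom$cov, points = Y)
}

# Block-diagonal assembly of a list of matrices.
blkdiag <- function(...) {
  mats <- lapply(list(...), as.matrix)
  ns <- vapply(mats, nrow, 1L)
  out <- matrix(0, sum(ns), sum(ns))
  at <- 0L
  for (M in mats) {
    idx <- at + seq_len(nrow(M))
    out[idx, idx] <- M
    at <- at + nrow(M)
  }
  out
}

#' UKF time update (predict)
#'
#' Propagates a Gaussian belief through a nonlinear transition.  In the
#' plain (non-augmented) mode the process-noise covariance `Q` is added
#' to the transformed covariance.  In the augmented mode the state is
#' extended with process- and observation-noise dimensions drawn from
#' the block-diagonal covariance `diag(P, Q, R)`, noise rides inside
#' the sigma points (the transition receives the state part and the
#' process-noise part is added to its output), and nothing is added
#' afterwards; the propagated points are carried on the returned belief
#' so [ukf_update()] can reuse them.
#'
#' @param belief prior [gaussian_belief()] at time k.
#' @param transition function mapping a state vector to the next state
#'   vector (same length).
#' @param Q process-noise covariance (matrix, vector of diagonal
#'   entries, or scalar).
#' @param config a [ut_config()].
#' @param augmented logical; use the noise-augmented sigma-point form.
#' @param R observation-noise covariance, required when
#'   `augmented = TRUE` (the observation-noise dimensions enter the
#'   augmented state).
#' @return Predicted [gaussian_belief()] for time k+1.  In augmented
#'   mode it carries an `"aug"` attribute with the propagated points.
#' @export
ukf_predict <- function(belief, transition, Q, config = ut_config(),
                        augmented = FALSE, R = NULL) {
  L <- length(belief$mean)
  Q <- as_cov(Q, L)
  if (!augmented) {
    sp <- generate_sigma_points(belief, config)
    tr <- unscented_transform(sp, transition)
    return(gaussian_belief(tr$mean, tr$cov + Q))
  }
  if (is.null(R)) stop("augmented mode needs the observation noise R")
  R <- as.matrix(R)
  Ln <- nrow(R)
  m_a <- c(belief$mean, rep(0, L), rep(0, Ln))
  P_a <- blkdiag(belief$cov, Q, R)
  sp <- generate_sigma_points(gaussian_belief(m_a, P_a), config)
  npts <- ncol(sp$points)
  X <- matrix(0, L, npts)
  for (j in seq_len(npts)) {
    p <- sp$points[, j]
    X[, j] <- transition(p[seq_len(L)]) + p[L + seq_len(L)]
  }
  mom <- weighted_moments(X, sp$Wm, sp$Wc)
  out <- gaussian_belief(mom$mean, mom$cov)
  attr(out, "aug") <- list(X = X, N = sp$points[L + L + seq_len(Ln), ,
                                                drop = FALSE],
                           Wm = sp$Wm, Wc = sp$Wc)
  out
}

as_cov <- function(Q, L) {
  if (is.null(dim(Q))) {
    Q <- if (length(Q) == 1L) diag(rep(as.numeric(Q), L), L)
         else diag(as.numeric(Q), L)
  }
  as.matrix(Q)
}

#' UKF measurement update
#'
#' Standard unscented measurement update: the posterior mean and
#' covariance follow from the cross-covariance between state and
#' predicted observation and the innovation covariance (inverted via a
#' Cholesky solve, never an explicit inverse).  If the prior carries
#' propagated augmented sigma points (from [ukf_predict()] with
#' `augmented = TRUE`) those are reused and the observation-noise
#' sigma components are added to the mapped observations; otherwise a
#' fresh point set is drawn from the prior and `R` is added to the
#' innovation covariance.
#'
#' @param prior predicted [gaussian_belief()].
#' @param observation_fn function mapping a state vector to an
#'   observation vector.
#' @param y observed vector.
#' @param R observation-noise covariance.
#' @param config a [ut_config()].
#' @return A list with `posterior` (a [gaussian_belief()]),
#'   `innovation`, `y_pred` (predicted observation) and `S`
#'   (innovation covariance).
#' @export
ukf_update <- function(prior, observation_fn, y, R, config = ut_config()) {
  y <- as.numeric(y)
  aug <- attr(prior, "aug")
  if (is.null(aug)) {
    R <- as_cov(R, length(y))
    sp <- generate_sigma_points(prior, config)
    X <- sp$points
    Wm <- sp$Wm; Wc <- sp$Wc
    tr <- unscented_transform(sp, observation_fn)
    Y <- tr$points
    S <- tr$cov + R
  } else {
    X <- aug$X
    Wm <- aug$Wm; Wc <- aug$Wc
    npts <- ncol(X)
    Y <- matrix(0, length(y), npts)
    for (j in seq_len(npts))
      Y[, j] <- observation_fn(X[, j]) + aug$N[, j]
    momY <- weighted_moments(Y, Wm, Wc)
    S <- momY$cov
  }
  y_pred <- drop(Y %*% Wm)
  Dy <- Y - y_pred
  Dx <- X - prior$mean
  Pxy <- Dx %*% (Wc * t(Dy))
  cS <- tryCatch(chol((S + t(S)) / 2), error = function(e)
    stop("innovation covariance numerically singular ",
         "(observation noise too small?)"))
  # K = Pxy S^-1 via two triangular solves
  K <- t(backsolve(cS, forwardsolve(t(cS), t(Pxy))))
  innov <- y - y_pred
  m_post <- prior$mean + drop(K %*% innov)
  P_post <- prior$cov - K %*% S %*% t(K)
  P_post <- (P_post + t(P_post)) / 2
  list(posterior = gaussian_belief(m_post, P_post),
       innovation = innov, y_pred = y_pred, S = S)
}

# Scalar-observation UKF update with a batched observation evaluator:
# Yfun takes the L x (2L+1) sigma matrix and returns one predicted
# observation per column.  Algebraically identical to ukf_update() for
# a 1-dimensional observation; used by the filter runners for speed.
scalar_update_batched <- function(prior, Yfun, y, R, config) {
  sp <- generate_sigma_points(prior, config)
  Y <- Yfun(sp$points)
  y_pred <- sum(sp$Wm * Y)
  dY <- Y - y_pred
  S <- sum(sp$Wc * dY * dY) + R
  if (S <= 0) stop("innovation covariance numerically singular")
  K <- drop((sp$points - prior$mean) %*% (sp$Wc * dY)) / S
  innov <- y - y_pred
  P <- prior$cov - tcrossprod(K) * S
  list(posterior = gaussian_belief(prior$mean + K * innov,
                                   (P + t(P)) / 2),
       innovation = innov, y_pred = y_pred, S = S)
}

#' Noise-augmented dimensions
#'
#' Dimension bookkeeping for the noise-augmented sigma-point form: the
#' augmented state stacks the state, the process-noise and the
#' observation-noise vectors, so `L_aug = L_x + L_v + L_n`, and sigma
#' points are drawn from the block-diagonal covariance
#' `diag(P_x, R_v, R_n)`.
#'
#' @param L_x state dimension.
#' @param L_v process-noise dimension (defaults to `L_x`, additive
#'   full-state noise).
#' @param L_n observation-noise dimension (default 1, a scalar BOLD
#'   signal).
#' @return A list with `L_x`, `L_v`, `L_n` and `L_aug`.
#' @export
#' @examples
#' augment_dimensions(4)$L_aug   # 9 : the state filter
#' augment_dimensions(5, 5)$L_aug # 11: the parameter filter
#' augment_dimensions(9)$L_aug   # 19: the joint filter
augment_dimensions <- function(L_x, L_v = L_x, L_n = 1L) {
  stopifnot(L_x >= 1, L_v >= 0, L_n >= 0)
  list(L_x = as.integer(L_x), L_v = as.integer(L_v),
       L_n = as.integer(L_n), L_aug = as.integer(L_x + L_v + L_n))
}
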