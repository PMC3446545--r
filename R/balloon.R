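#' Balloon model parameters
#'
#' Constructs and validates the seven-parameter set of the Balloon
#' hemodynamic model: neuronal efficacy `epsilon`, signal-decay time
#' constant `tau_s` (s), autoregulatory-feedback time constant `tau_f`
#' (s), mean transit time `tau_0` (s), stiffness exponent `alpha`,
#' resting oxygen extraction fraction `E_0` and resting blood volume
#' fraction `V_0`.  All states driven by these parameters are
#' dimensionless, normalized to their resting values.
#'
#' @param epsilon neuronal efficacy (gain from stimulus to the
#'   flow-inducing signal), dimensionless.
#' @param tau_s signal decay time constant, seconds (> 0).
#' @param tau_f autoregulatory feedback time constant, seconds (> 0).
#' @param tau_0 mean venous transit time, seconds (> 0).
#' @param alpha stiffness exponent of the volume-outflow relation
#'   `v^(1/alpha)`, in (0, 1).
#' @param E_0 resting oxygen extraction fraction, in (0, 1).
#' @param V_0 resting blood volume fraction, in (0, 1).
#' @return An object of class `hemo_params` (a named list).
#' @seealso [default_params()] for the prior-mean parameter set,
#'   [hemo_prior()] for the full prior table.
#' @export
#' @examples
#' p <- hemo_params()
#' p$E_0
hemo_params <- function(epsilon = 0.54, tau_s = 1.54, tau_f = 2.46,
                        tau_0 = 0.98, alpha = 0.33, E_0 = 0.34,
                        V_0 = 0.02) {
  p <- list(epsilon = as.numeric(epsilon), tau_s = as.numeric(tau_s),
            tau_f = as.numeric(tau_f), tau_0 = as.numeric(tau_0),
            alpha = as.numeric(alpha), E_0 = as.numeric(E_0),
            V_0 = as.numeric(V_0))
  if (!all(vapply(p, function(z) is.finite(z) && length(z) == 1L, TRUE)))
    stop("all parameters must be finite scalars")
  if (p$tau_s <= 0 || p$tau_f <= 0 || p$tau_0 <= 0)
    stop("time constants tau_s, tau_f, tau_0 must be positive")
  if (p$alpha <= 0 || p$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (p$E_0 <= 0 || p$E_0 >= 1) stop("E_0 must lie in (0, 1)")
  if (p$V_0 <= 0 || p$V_0 >= 1) stop("V_0 must lie in (0, 1)")
  class(p) <- "hemo_params"
  p
}

#' @rdname hemo_params
#' @export
default_params <- function() hemo_params()

#' @export
print.hemo_params <- function(x, ...) {
  cat("Balloon model parameters:\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' Coerce to a Balloon parameter set
#'
#' Accepts a `hemo_params` object, a named list, a named numeric vector
#' or a one-row data frame with (at least) the seven parameter names.
#'
#' @param x object to coerce.
#' @return A `hemo_params` object.
#' @export
as_hemo_params <- function(x) {
  if (inherits(x, "hemo_params")) return(x)
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- as.list(x)
  }
  x <- as.list(x)
  need <- c("epsilon", "tau_s", "tau_f", "tau_0", "alpha", "E_0", "V_0")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing parameter(s): ", paste(miss, collapse = ", "))
  do.call(hemo_params, x[need])
}

# Resting state (f, s, q, v) = (1, 0, 1, 1): the model's fixed point.
rest_state <- function() c(f = 1, s = 0, q = 1, v = 1)

# Positivity floor applied to f, q, v (the states entering fractional
# powers); s may take any sign.  Returns the floored vector.
STATE_FLOOR <- 1e-6
floor_state <- function(x) {
  x[c(1L, 3L, 4L)] <- pmax(x[c(1L, 3L, 4L)], STATE_FLOOR)
  x
}

#' Balloon model time derivatives
#'
#' Instantaneous time derivatives of the four hemodynamic states
#' `x = (f, s, q, v)`: normalized blood flow `f`, its rate-of-change
#' signal `s`, normalized deoxyhemoglobin content `q` and normalized
#' venous volume `v`.  The dynamics are
#' \deqn{\dot f = s,\quad
#'       \dot s = \epsilon u - s/\tau_s - (f - 1)/\tau_f,\quad
#'       \dot v = (f - v^{1/\alpha})/\tau_0,}
#' \deqn{\dot q = \frac{1}{\tau_0}\left(
#'       f\,\frac{1 - (1 - E_0)^{1/f}}{E_0} -
#'       v^{1/\alpha}\,\frac{q}{v}\right).}
#' At rest (`f = q = v = 1`, `s = 0`, `u = 0`) all derivatives vanish.
#'
#' @param state numeric vector `c(f, s, q, v)` (names optional); `f`,
#'   `q`, `v` must be strictly positive.
#' @param params a [hemo_params()] object (or coercible).
#' @param u scalar neuronal input.
#' @return Named numeric vector of the four derivatives.
#' @export
#' @examples
#' balloon_derivatives(c(1, 0, 1, 1), hemo_params(), u = 1)
balloon_derivatives <- function(state, params, u = 0) {
  params <- as_hemo_params(params)
  state <- as.numeric(state)
  stopifnot(length(state) == 4L, is.finite(u))
  if (state[1L] <= 0 || state[4L] <= 0)
    stop("f and v must be strictly positive (positivity policy violated)")
  d <- balloon_deriv_vec(state, params$epsilon, 1 / params$tau_s,
                         1 / params$tau_f, 1 / params$tau_0,
                         1 / params$alpha, params$E_0, u)
  names(d) <- c("f", "s", "q", "v")
  d
}

# Fast unchecked derivative kernel; x = c(f, s, q, v).
balloon_deriv_vec <- function(x, eps, itau_s, itau_f, itau_0, ialpha,
                              E_0, u) {
  f <- x[1L]; s <- x[2L]; q <- x[3L]; v <- x[4L]
  fout <- v^ialpha                       # outflow from the venous balloon
  # oxygen extraction relative to rest; analytically 1 at f = 1, and
  # evaluated as such so the resting point is an exact fixed point
  ext <- if (f == 1) 1 else (1 - (1 - E_0)^(1 / f)) / E_0
  c(s,
    eps * u - s * itau_s - (f - 1) * itau_f,
    itau_0 * (f * ext - fout * q / v),
    itau_0 * (f - fout))
}

#' Advance the Balloon state over one acquisition interval
#'
#' Integrates the Balloon dynamics over one repetition time with a
#' fixed-step classical 4th-order Runge-Kutta scheme, holding the input
#' `u` constant over the interval (zero-order hold).  After every
#' substep the positivity floor (`1e-6`) is applied to `f`, `q`, `v` so
#' the fractional powers in the dynamics stay defined.
#'
#' @param state numeric vector `c(f, s, q, v)`.
#' @param params a [hemo_params()] object (or coercible).
#' @param u scalar input held over the interval.
#' @param tr interval length (the repetition time), seconds.
#' @param dt_sub substep length, seconds; the interval is divided into
#'   `round(tr / dt_sub)` equal substeps (default 0.1 s, i.e. 20
#'   substeps per TR = 2 s).
#' @return The state at the end of the interval (named numeric vector).
#' @export
integrate_step <- function(state, params, u, tr = 2, dt_sub = 0.1) {
  params <- as_hemo_params(params)
  x <- integrate_step_vec(as.numeric(state), params$epsilon,
                          1 / params$tau_s, 1 / params$tau_f,
                          1 / params$tau_0, 1 / params$alpha,
                          params$E_0, u, tr, dt_sub)
  names(x) <- c("f", "s", "q", "v")
  x
}

integrate_step_vec <- function(x, eps, itau_s, itau_f, itau_0, ialpha,
                               E_0, u, tr, dt_sub) {
  n_sub <- max(1L, as.integer(round(tr / dt_sub)))
  h <- tr / n_sub
  for (i in seq_len(n_sub)) {
    k1 <- balloon_deriv_vec(x, eps, itau_s, itau_f, itau_0, ialpha, E_0, u)
    k2 <- balloon_deriv_vec(floor_state(x + 0.5 * h * k1),
                            eps, itau_s, itau_f, itau_0, ialpha, E_0, u)
    k3 <- balloon_deriv_vec(floor_state(x + 0.5 * h * k2),
                            eps, itau_s, itau_f, itau_0, ialpha, E_0, u)
    k4 <- balloon_deriv_vec(floor_state(x + h * k3),
                            eps, itau_s, itau_f, itau_0, ialpha, E_0, u)
    x <- floor_state(x + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4))
    if (!all(is.finite(x)))
      stop("non-finite state during integration at substep ", i,
           " of ", n_sub)
  }
  x
}

#' BOLD observation coefficients
#'
#' The three dimensionless weights of the BOLD observation equation at
#' 1.5 T: `k1 = 7 E_0`, `k2 = 2`, `k3 = 2 E_0 - 0.2`.  They are
#' recomputed from the current `E_0` whenever that parameter changes.
#'
#' @param E_0 resting oxygen extraction fraction, in (0, 1).
#' @return Named numeric vector `c(k1, k2, k3)`.
#' @export
#' @examples
#' bold_coefficients(0.34)  # c(2.38, 2, 0.48)
bold_coefficients <- function(E_0) {
  if (!is.finite(E_0) || E_0 <= 0 || E_0 >= 1)
    stop("E_0 must lie in (0, 1)")
  c(k1 = 7 * E_0, k2 = 2, k3 = 2 * E_0 - 0.2)
}

#' BOLD observation equation
#'
#' Maps a hemodynamic state to the (noise-free) BOLD signal
#' \deqn{y = V_0\left(k_1 (1 - q) + k_2 (1 - q/v) + k_3 (1 - v)\right)}
#' with coefficients from [bold_coefficients()].  At rest
#' (`q = v = 1`) the signal is exactly zero.
#'
#' @inheritParams balloon_derivatives
#' @return Scalar BOLD signal (fractional signal change).
#' @export
bold_observe <- function(state, params) {
  params <- as_hemo_params(params)
  state <- as.numeric(state)
  if (state[4L] <= 0) stop("v must be strictly positive")
  bold_observe_vec(state, params$E_0, params$V_0)
}

bold_observe_vec <- function(x, E_0, V_0) {
  q <- x[3L]; v <- x[4L]
  V_0 * (7 * E_0 * (1 - q) + 2 * (1 - q / v) + (2 * E_0 - 0.2) * (1 - v))
}

# ---- batched kernels: one column per sigma point -------------------
# X is a 4 x m state matrix; the parameters may be scalars (state
# filter: one parameter set for all points) or length-m vectors
# (parameter/joint filter: each point carries its own parameters).

floor_mat <- function(X) {
  X[c(1L, 3L, 4L), ] <- pmax(X[c(1L, 3L, 4L), ], STATE_FLOOR)
  X
}

balloon_deriv_mat <- function(X, eps, itau_s, itau_f, itau_0, ialpha,
                              E_0, u) {
  f <- X[1L, ]; s <- X[2L, ]; q <- X[3L, ]; v <- X[4L, ]
  fout <- v^ialpha
  ext <- (1 - (1 - E_0)^(1 / f)) / E_0
  at_rest <- f == 1
  if (any(at_rest)) ext[at_rest] <- 1
  out <- X
  out[1L, ] <- s
  out[2L, ] <- eps * u - s * itau_s - (f - 1) * itau_f
  out[3L, ] <- itau_0 * (f * ext - fout * q / v)
  out[4L, ] <- itau_0 * (f - fout)
  out
}

# Advance all columns over the input sequence u_seq (one interval of
# length tr per element, zero-order hold), RK4 with positivity floor.
integrate_mat <- function(X, eps, itau_s, itau_f, itau_0, ialpha, E_0,
                          u_seq, tr, dt_sub) {
  n_sub <- max(1L, as.integer(round(tr / dt_sub)))
  h <- tr / n_sub
  for (u in u_seq) {
    for (i in seq_len(n_sub)) {
      k1 <- balloon_deriv_mat(X, eps, itau_s, itau_f, itau_0, ialpha,
                              E_0, u)
      k2 <- balloon_deriv_mat(floor_mat(X + 0.5 * h * k1), eps, itau_s,
                              itau_f, itau_0, ialpha, E_0, u)
      k3 <- balloon_deriv_mat(floor_mat(X + 0.5 * h * k2), eps, itau_s,
                              itau_f, itau_0, ialpha, E_0, u)
      k4 <- balloon_deriv_mat(floor_mat(X + h * k3), eps, itau_s,
                              itau_f, itau_0, ialpha, E_0, u)
      X <- floor_mat(X + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4))
    }
  }
  if (!all(is.finite(X))) stop("non-finite state during integration")
  X
}

bold_observe_mat <- function(X, E_0, V_0) {
  q <- X[3L, ]; v <- X[4L, ]
  V_0 * (7 * E_0 * (1 - q) + 2 * (1 - q / v) + (2 * E_0 - 0.2) * (1 - v))
}
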