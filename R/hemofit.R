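#' Fit the Balloon model to a BOLD time series
#'
#' The package's modelling interface: inverts the Balloon hemodynamic
#' model from a single-voxel BOLD series by sigma-point filtering and
#' returns a fitted-model object with the usual methods ([coef()],
#' [fitted()], [residuals()], `summary()`, `plot()`, [predict()],
#' [simulate()]).  The estimator is either the dual filter (separate
#' state and parameter filters alternating each acquisition, no
#' modelled state-parameter interaction — the recommended scheme) or
#' the baseline joint filter over the concatenated 9-dimensional
#' state.
#'
#' @param data a data frame with columns `time` (s), `u` (stimulus)
#'   and `y` (BOLD signal), a path to such a file, or a
#'   [simulate_bold()] result.
#' @param scheme `"dual"` (default) or `"joint"`.
#' @param ... further arguments passed to [run_dual_ukf()] or
#'   [run_joint_ukf()] (`Q`, `R`, `R_r`, `init_params`, `augmented`,
#'   `dt_sub`, ...).
#' @return An object of class `hemofit`.
#' @export
#' @examples
#' sim <- simulate_bold(block_design(n_blocks = 4), seed = 1)
#' fit <- hemofit(sim)
#' coef(fit)
hemofit <- function(data, scheme = c("dual", "joint"), ...) {
  scheme <- match.arg(scheme)
  cl <- match.call()
  if (is.character(data)) data <- read_series(data)$data
  stopifnot(is.data.frame(data),
            all(c("time", "u", "y") %in% names(data)))
  stim <- stimulus_train(data$time, data$u)
  fit <- if (scheme == "dual") run_dual_ukf(data$y, stim, ...)
         else run_joint_ukf(data$y, stim, ...)
  structure(list(call = cl, scheme = scheme, data = data, fit = fit),
            class = "hemofit")
}

#' @export
print.hemofit <- function(x, ...) {
  cat("Balloon model fit (", x$scheme, " unscented Kalman filter)\n",
      sep = "")
  cat("  ", length(x$fit$y), " acquisitions, TR ",
      format(attr(stimulus_train(x$data$time, x$data$u), "tr")),
      " s\n", sep = "")
  cat("Final parameter estimates:\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
coef.hemofit <- function(object, ...) {
  n <- nrow(object$fit$param_mean)
  stats::setNames(object$fit$param_mean[n, ], W_NAMES)
}

#' @export
fitted.hemofit <- function(object, ...) object$fit$y_pred

#' @export
residuals.hemofit <- function(object, ...) object$fit$innovation

#' @export
logLik.hemofit <- function(object, ...) {
  f <- object$fit
  ll <- -0.5 * sum(log(2 * pi * f$innovation_var) +
                   f$innovation^2 / f$innovation_var)
  structure(ll, df = 5, nobs = length(f$y), class = "logLik")
}

#' @export
summary.hemofit <- function(object, ...) {
  f <- object$fit
  n <- length(f$y)
  tab <- data.frame(estimate = f$param_mean[n, ],
                    sd = f$param_sd[n, ],
                    prior_mean = w_prior()$mean,
                    prior_sd = w_prior()$sd,
                    row.names = W_NAMES)
  out <- list(call = object$call, scheme = object$scheme, n = n,
              parameters = tab,
              fixed = c(alpha = f$settings$alpha, V_0 = f$settings$V_0),
              innovation_rmse = sqrt(mean(f$innovation^2)),
              logLik = as.numeric(logLik(object)),
              diagnostics = f$diagnostics[c("n_param_clip",
                                            "n_state_floor")])
  class(out) <- "summary.hemofit"
  out
}

#' @export
print.summary.hemofit <- function(x, ...) {
  cat("Balloon model fit (", x$scheme, " UKF), ", x$n,
      " acquisitions\n\n", sep = "")
  cat("Parameters (posterior at the final acquisition):\n")
  print(round(x$parameters, 4))
  cat("\nFixed: alpha =", x$fixed[["alpha"]], ", V_0 =",
      x$fixed[["V_0"]], "\n")
  cat(sprintf("Innovation RMSE: %.4g   log-likelihood: %.2f\n",
              x$innovation_rmse, x$logLik))
  d <- x$diagnostics
  if (d$n_param_clip > 0 || d$n_state_floor > 0)
    cat(sprintf("Diagnostics: %d parameter clips, %d state floors\n",
                d$n_param_clip, d$n_state_floor))
  invisible(x)
}

#' Predict the clean BOLD response under the fitted parameters
#'
#' Re-integrates the Balloon model from rest under a stimulus train
#' using the final parameter estimates and returns the noise-free BOLD
#' signal on the acquisition grid.
#'
#' @param object a [hemofit()] object.
#' @param newdata optional data frame with `time` and `u` columns (or
#'   a [stimulus_train()]); default: the training stimulus.
#' @param ... unused.
#' @return Numeric vector of predicted BOLD values.
#' @export
predict.hemofit <- function(object, newdata = NULL, ...) {
  stim <- if (is.null(newdata))
    stimulus_train(object$data$time, object$data$u)
  else if (inherits(newdata, "stimulus_train")) newdata
  else stimulus_train(newdata$time, newdata$u)
  w <- coef(object)
  p <- w_to_params(as.numeric(w), object$fit$settings$alpha,
                   object$fit$settings$V_0)
  n <- length(stim$u)
  tr <- attr(stim, "tr")
  x <- rest_state()
  out <- numeric(n)
  out[1L] <- bold_observe_vec(x, p$E_0, p$V_0)
  for (k in seq_len(n - 1L)) {
    x <- integrate_step_vec(x, p$epsilon, 1 / p$tau_s, 1 / p$tau_f,
                            1 / p$tau_0, 1 / p$alpha, p$E_0,
                            stim$u[k], tr, object$fit$settings$dt_sub)
    out[k + 1L] <- bold_observe_vec(x, p$E_0, p$V_0)
  }
  out
}

#' Simulate new BOLD series from a fitted model
#'
#' Draws `nsim` noisy replicates: the clean response under the fitted
#' parameters plus Gaussian observation noise at the innovation RMSE.
#'
#' @param object a [hemofit()] object.
#' @param nsim number of replicates.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A data frame with `nsim` columns, one replicate each.
#' @export
simulate.hemofit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  sdev <- sqrt(mean(residuals(object)^2))
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0,
                                                         sdev)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a fitted Balloon model
#'
#' Three base-graphics panels: observed vs fitted BOLD signal with the
#' stimulus shading, the four state estimates, and the parameter
#' traces (each normalized by its prior SD about the prior mean).
#'
#' @param x a [hemofit()] object.
#' @param which subset of panels (1 = signal, 2 = states,
#'   3 = parameters).
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.hemofit <- function(x, which = 1:3, ...) {
  f <- x$fit
  old <- graphics::par(mfrow = c(length(which), 1),
                       mar = c(3.5, 4, 2, 1))
  on.exit(graphics::par(old))
  shade <- function() {
    on <- which(f$u > 0)
    if (length(on)) {
      tr <- diff(f$time[1:2])
      for (i in on)
        graphics::rect(f$time[i] - tr / 2, graphics::par("usr")[3],
                       f$time[i] + tr / 2, graphics::par("usr")[4],
                       col = "#00000010", border = NA)
    }
  }
  if (1 %in% which) {
    graphics::plot(f$time, f$y, pch = 16, cex = 0.5, col = "grey40",
                   xlab = "time (s)", ylab = "BOLD",
                   main = paste(x$scheme, "UKF fit"))
    shade()
    graphics::lines(f$time, f$y_pred, col = "firebrick", lwd = 1.5)
  }
  if (2 %in% which) {
    graphics::matplot(f$time, f$state_mean, type = "l", lty = 1,
                      xlab = "time (s)", ylab = "state",
                      main = "hemodynamic states")
    shade()
    graphics::legend("topright", colnames(f$state_mean), lty = 1,
                     col = 1:4, bty = "n", cex = 0.8)
  }
  if (3 %in% which) {
    Z <- sweep(sweep(f$param_mean, 2, w_prior()$mean), 2, w_prior()$sd,
               "/")
    graphics::matplot(f$time, Z, type = "l", lty = 1,
                      xlab = "time (s)",
                      ylab = "(estimate - prior mean) / prior SD",
                      main = "parameter traces")
    shade()
    graphics::legend("topright", W_NAMES, lty = 1, col = 1:5,
                     bty = "n", cex = 0.8)
  }
  invisible(x)
}
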