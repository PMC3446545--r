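# File-facing helpers: tabular series IO, run configuration, trace and
# summary writers.  All numbers are written with 17 significant digits
# so write-then-read round-trips at full double precision, and outputs
# carry no timestamps — identical inputs give byte-identical files.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  out
}

#' Read an observed BOLD series
#'
#' Reads a tab- or comma-delimited file with a header row containing at
#' least the columns `time` (seconds), `u` (stimulus) and `y` (BOLD
#' signal).  The delimiter is sniffed from the header line.  The time
#' grid must be uniform to within `1e-6` relative jitter and all values
#' finite.
#'
#' @param path file path.
#' @return A list with `stimulus` (a [stimulus_train()]), `y` (numeric
#'   vector) and `data` (the full data frame).
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  for (col in c("time", "u", "y")) {
    if (!col %in% names(df))
      stop("missing required column '", col, "' in ", path)
    if (!all(is.finite(df[[col]])))
      stop("non-finite values in column '", col, "'")
  }
  d <- diff(df$time)
  if (length(d) && max(abs(d - d[1L])) > 1e-6 * abs(d[1L]))
    stop("non-uniform time grid in ", path)
  list(stimulus = stimulus_train(df$time, df$u), y = df$y, data = df)
}

#' Write a simulated or observed series
#'
#' Writes a tab-delimited file with header `time, u, y` plus any
#' ground-truth columns present (`y_clean`, `f`, `s`, `q`, `v`), at
#' full double precision.
#'
#' @param data a data frame (e.g. from [simulate_bold()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_series <- function(data, path) {
  keep <- intersect(c("time", "u", "y", "y_clean", "f", "s", "q", "v"),
                    names(data))
  df <- data[, keep, drop = FALSE]
  lines <- c(paste(keep, collapse = "\t"),
             apply(vapply(df, fmt_num, character(nrow(df))), 1L,
                   paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write a per-acquisition filter trace
#'
#' One row per acquisition: time, observation, predicted observation,
#' the four state estimates, the five parameter estimates, and the
#' innovation.
#'
#' @param fit a `dual_ukf_fit` or `joint_ukf_fit` (or a [hemofit()]
#'   object).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(fit, path) {
  if (inherits(fit, "hemofit")) fit <- fit$fit
  df <- data.frame(time = fit$time, y = fit$y, y_hat = fit$y_pred,
                   f_hat = fit$state_mean[, 1L],
                   s_hat = fit$state_mean[, 2L],
                   q_hat = fit$state_mean[, 3L],
                   v_hat = fit$state_mean[, 4L],
                   epsilon_hat = fit$param_mean[, 1L],
                   tau_s_hat = fit$param_mean[, 2L],
                   tau_f_hat = fit$param_mean[, 3L],
                   tau_0_hat = fit$param_mean[, 4L],
                   E_0_hat = fit$param_mean[, 5L],
                   innovation = fit$innovation)
  lines <- c(paste(names(df), collapse = "\t"),
             apply(vapply(df, fmt_num, character(nrow(df))), 1L,
                   paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write a JSON fit summary
#'
#' Final parameter means and standard deviations, innovation
#' statistics (an innovation-based Gaussian log-likelihood proxy among
#' them), diagnostic counters and the package version.
#'
#' @inheritParams write_trace
#' @return `path`, invisibly.
#' @export
write_summary <- function(fit, path) {
  if (inherits(fit, "hemofit")) fit <- fit$fit
  n <- length(fit$y)
  ll <- -0.5 * sum(log(2 * pi * fit$innovation_var) +
                   fit$innovation^2 / fit$innovation_var)
  out <- list(
    scheme = fit$scheme,
    n_acquisitions = n,
    parameters = list(
      mean = as.list(stats::setNames(fit$param_mean[n, ], W_NAMES)),
      sd = as.list(stats::setNames(fit$param_sd[n, ], W_NAMES))),
    fixed = list(alpha = fit$settings$alpha, V_0 = fit$settings$V_0),
    innovation = list(log_likelihood = ll,
                      rmse = sqrt(mean(fit$innovation^2))),
    diagnostics = fit$diagnostics[c("n_param_clip", "n_state_floor")],
    package_version = as.character(utils::packageVersion("hemodual")))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# ---- run configuration ----------------------------------------------

# Known keys, with defaults.  Unknown keys anywhere are rejected.
default_run_config <- function() {
  list(
    dt_sub = 0.1,
    ut = list(alpha = 1, beta = 2, kappa = NULL),
    noise = list(Q = 1e-6, R = NULL, R_r_scale = 1e-4),
    mode = list(augmented = FALSE, order = "state_first",
                log_space = FALSE),
    fixed = list(alpha = 0.33, V_0 = 0.02),
    init = list(state_var = 1e-2, param_shift_sd = 0),
    seed = 1L)
}

#' Read a run configuration
#'
#' Reads a JSON run configuration and merges it over the documented
#' defaults.  Unknown keys (top-level or nested) are rejected with an
#' explicit error, so typos cannot silently fall back to defaults.
#'
#' @param path JSON file path, or `NULL` for the defaults.
#' @return A named list of settings.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  merge_config(cfg, user, "config")
}

merge_config <- function(base, user, where) {
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop("unknown ", where, " key(s): ", paste(unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]])))
      base[[k]] <- merge_config(base[[k]], as.list(user[[k]]),
                                paste0(where, "$", k))
    else base[[k]] <- user[[k]]
  }
  base
}

# Build filter arguments from a run configuration and the data.
config_to_args <- function(cfg, y) {
  pr <- w_prior()
  shift <- cfg$init$param_shift_sd
  init_params <- gaussian_belief(pr$mean + shift * pr$sd, diag(pr$sd^2))
  R <- if (is.null(cfg$noise$R)) (0.1 * max(abs(y)))^2 else cfg$noise$R
  list(Q = cfg$noise$Q, R = R,
       R_r = diag(cfg$noise$R_r_scale * pr$sd^2),
       config = ut_config(cfg$ut$alpha, cfg$ut$beta, cfg$ut$kappa),
       dt_sub = cfg$dt_sub, alpha = cfg$fixed$alpha,
       V_0 = cfg$fixed$V_0,
       init_state = gaussian_belief(rest_state(),
                                    diag(cfg$init$state_var, 4)),
       init_params = init_params,
       augmented = isTRUE(cfg$mode$augmented))
}
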