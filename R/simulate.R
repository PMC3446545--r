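#' Block experimental design
#'
#' Describes an alternating rest/stimulation block design on a uniform
#' acquisition grid.  The default reproduces the auditory paradigm the
#' package's recovery studies emulate: 16 alternating 16-second blocks
#' of 8 scans at a repetition time of 2 s, starting with rest, plus an
#' 8-scan rest lead-in — 136 acquisitions in total.
#'
#' @param n_blocks number of alternating blocks.
#' @param scans_per_block acquisitions per block.
#' @param tr repetition time, seconds.
#' @param lead_in_scans rest acquisitions prepended before the first
#'   block.
#' @param start_rest logical; if `TRUE` the first block is rest.
#' @return An object of class `block_design`.
#' @export
block_design <- function(n_blocks = 16L, scans_per_block = 8L, tr = 2,
                         lead_in_scans = 8L, start_rest = TRUE) {
  stopifnot(n_blocks >= 0, scans_per_block >= 1, tr > 0,
            lead_in_scans >= 0)
  structure(list(n_blocks = as.integer(n_blocks),
                 scans_per_block = as.integer(scans_per_block),
                 tr = tr, lead_in_scans = as.integer(lead_in_scans),
                 start_rest = isTRUE(start_rest)),
            class = "block_design")
}

#' @export
print.block_design <- function(x, ...) {
  n <- x$lead_in_scans + x$n_blocks * x$scans_per_block
  cat(sprintf(
    "Block design: %d blocks x %d scans (TR %g s), %d-scan lead-in, %s first; %d acquisitions (%g s)\n",
    x$n_blocks, x$scans_per_block, x$tr, x$lead_in_scans,
    if (x$start_rest) "rest" else "stimulation", n, n * x$tr))
  invisible(x)
}

#' Stimulus train on the acquisition grid
#'
#' @param times strictly increasing, uniformly spaced timestamps (s).
#' @param u input amplitude at each timestamp.
#' @return An object of class `stimulus_train` with attribute `"tr"`
#'   (the grid spacing).
#' @export
stimulus_train <- function(times, u) {
  times <- as.numeric(times); u <- as.numeric(u)
  stopifnot(length(times) == length(u), length(times) >= 1L)
  if (length(times) > 1L) {
    d <- diff(times)
    if (any(d <= 0)) stop("times must be strictly increasing")
    if (max(abs(d - d[1L])) > 1e-9 * abs(d[1L]))
      stop("times must be uniformly spaced")
    tr <- d[1L]
  } else tr <- NA_real_
  structure(list(times = times, u = u), class = "stimulus_train",
            tr = tr)
}

#' Boxcar stimulus for a block design
#'
#' Builds the 0/1 boxcar input on the acquisition grid: zeros over the
#' lead-in, then alternating blocks (rest first when
#' `design$start_rest`).
#'
#' @param design a [block_design()].
#' @return A [stimulus_train()].
#' @export
#' @examples
#' st <- make_block_stimulus(block_design())
#' length(st$u)  # 136
#' sum(st$u)     # 64 stimulated scans
make_block_stimulus <- function(design = block_design()) {
  n <- design$lead_in_scans + design$n_blocks * design$scans_per_block
  u <- numeric(n)
  first_on <- if (design$start_rest) 2L else 1L
  if (design$n_blocks >= first_on) {
    for (b in seq(first_on, design$n_blocks, by = 2L)) {
      i0 <- design$lead_in_scans + (b - 1L) * design$scans_per_block
      u[i0 + seq_len(design$scans_per_block)] <- 1
    }
  }
  stimulus_train(times = (seq_len(n) - 1L) * design$tr, u = u)
}

#' Draw Balloon parameters from the prior
#'
#' Draws independent normal samples from the parameter prior (see
#' [hemo_prior()]) and clips each draw to its validity range (time
#' constants to `[0.05, 20]` s, `epsilon` to `[1e-3, 5]`, `alpha` and
#' `E_0` to `[0.01, 0.99]`, `V_0` to `[0.001, 0.2]`).  Deterministic
#' given `seed`.
#'
#' @param n number of draws.
#' @param seed optional integer seed (sets the RNG via [set.seed()]).
#' @return For `n = 1` a [hemo_params()] object; for `n > 1` a data
#'   frame with one row per draw and the seven parameter columns.
#' @export
draw_parameters <- function(n = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pr <- hemo_prior()
  lo <- c(1e-3, 0.05, 0.05, 0.05, 0.01, 0.01, 0.001)
  hi <- c(5, 20, 20, 20, 0.99, 0.99, 0.2)
  draws <- vapply(seq_len(nrow(pr)), function(j)
    pmin(pmax(stats::rnorm(n, pr$mean[j], pr$sd[j]), lo[j]), hi[j]),
    numeric(n))
  if (n == 1L) draws <- matrix(draws, nrow = 1L)
  colnames(draws) <- pr$parameter
  df <- as.data.frame(draws)
  if (n == 1L) as_hemo_params(df) else df
}

#' Simulate block-design BOLD data from the Balloon model
#'
#' Integrates the Balloon dynamics from rest under a boxcar stimulus
#' and samples the BOLD observation on the acquisition grid.  Process
#' noise, when requested, enters as additive Gaussian perturbations of
#' the state at every integration substep, scaled by `sqrt(dt_sub)`
#' (the Euler-Maruyama-consistent discretization of continuous white
#' noise); observation noise is added per acquisition.  The state
#' recorded at acquisition `k+1` is the state at `k` advanced over one
#' repetition time under input `u[k]` — the same convention the
#' filters use.
#'
#' @param design a [block_design()].
#' @param params true [hemo_params()] (default: the prior means).
#' @param process_noise_sd per-state process noise standard deviations
#'   (length 4 or scalar), in state units per sqrt(second); default 0.
#' @param obs_noise_sd observation noise SD; if `NULL` it is set to
#'   `obs_noise_frac` times the peak absolute clean signal.
#' @param obs_noise_frac fraction of the clean-signal peak used when
#'   `obs_noise_sd` is `NULL` (default 0.1, i.e. 10% of peak).
#' @param dt_sub integration substep, seconds.
#' @param seed integer seed; fully determines the output.
#' @return A data frame of class `bold_sim` with columns `time`, `u`,
#'   `y` (noisy), `y_clean`, and the true states `f`, `s`, `q`, `v`;
#'   attributes `params`, `seed`, `obs_noise_sd`, `design`.
#' @export
simulate_bold <- function(design = block_design(),
                          params = default_params(),
                          process_noise_sd = 0, obs_noise_sd = NULL,
                          obs_noise_frac = 0.1, dt_sub = 0.1,
                          seed = 1L) {
  params <- as_hemo_params(params)
  stim <- make_block_stimulus(design)
  n <- length(stim$u)
  psd <- rep(as.numeric(process_noise_sd), length.out = 4L)
  stopifnot(all(psd >= 0))
  set.seed(seed)

  eps <- params$epsilon; itau_s <- 1 / params$tau_s
  itau_f <- 1 / params$tau_f; itau_0 <- 1 / params$tau_0
  ialpha <- 1 / params$alpha; E_0 <- params$E_0; V_0 <- params$V_0

  X <- matrix(NA_real_, n, 4, dimnames = list(NULL, c("f", "s", "q", "v")))
  x <- rest_state()
  X[1L, ] <- x
  n_sub <- max(1L, as.integer(round(design$tr / dt_sub)))
  h <- design$tr / n_sub
  noisy_states <- any(psd > 0)
  for (k in seq_len(n - 1L)) {
    u <- stim$u[k]
    if (!noisy_states) {
      x <- integrate_step_vec(x, eps, itau_s, itau_f, itau_0, ialpha,
                              E_0, u, design$tr, dt_sub)
    } else {
      for (i in seq_len(n_sub)) {
        x <- integrate_step_vec(x, eps, itau_s, itau_f, itau_0, ialpha,
                                E_0, u, h, h)
        x <- floor_state(x + sqrt(h) * psd * stats::rnorm(4L))
        if (!all(is.finite(x)))
          stop("non-finite trajectory (process noise too large?)")
      }
    }
    X[k + 1L, ] <- x
  }

  y_clean <- vapply(seq_len(n),
                    function(k) bold_observe_vec(X[k, ], E_0, V_0), 0)
  if (is.null(obs_noise_sd))
    obs_noise_sd <- obs_noise_frac * max(abs(y_clean))
  y <- y_clean + stats::rnorm(n, 0, obs_noise_sd)

  out <- data.frame(time = stim$times, u = stim$u, y = y,
                    y_clean = y_clean, f = X[, 1L], s = X[, 2L],
                    q = X[, 3L], v = X[, 4L])
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  attr(out, "obs_noise_sd") <- obs_noise_sd
  attr(out, "design") <- design
  class(out) <- c("bold_sim", "data.frame")
  out
}
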