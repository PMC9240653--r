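# Stochastic virtual tappers.
#
# Each tapper is a Wing-Kristofferson two-level timing generator with linear
# phase correction layered on top. Observed tap times follow
#
#   tap[n+1] = tap[n] + period - beta * async[n] + T[n] + (M[n+1] - M[n])
#
# where T ~ N(0, sigma_timekeeper^2) is central timekeeper noise, M ~
# N(0, sigma_motor^2) is the motor implementation delay (whose differencing
# induces the classic MA(1) structure in inter-tap intervals), beta is the
# tapper's phase-correction gain — the human-side analogue of the metronome's
# alpha — and async[n] is the tapper's own asynchrony to the most recent tone.
# Coupled to the adaptive metronome, the single-tapper asynchrony follows
#
#   a[n+1] = phi * a[n] + T[n] + M[n+1] - M[n],   phi = 1 - alpha - beta,
#
# an ARMA(1,1) whose stationary variance is available in closed form
# (see stationary_async_sd), giving an analytic oracle for the simulator.

#' Virtual tapper parameters
#'
#' @param beta Phase-correction gain: fraction of the last asynchrony
#'   subtracted from the next planned inter-tap interval. Typically 0-1.
#' @param sigma_timekeeper SD of the central timekeeper interval noise (ms).
#' @param sigma_motor SD of the peripheral motor delay (ms).
#' @param p_miss Per-window probability of a missed (unregistered) tap,
#'   in `[0, 1)`. On a miss the tapper still plans a covert tap and corrects
#'   from its covert asynchrony — humans continue their internal cycle when a
#'   tap fails to register.
#' @param period_mode `"nominal"` (default): the timekeeper targets the
#'   nominal IOI and never re-estimates tempo, keeping the closed-form
#'   stationary oracle valid. `"tracking"`: the timekeeper targets the last
#'   observed inter-tone interval.
#' @param initial_async Asynchrony of the tapper's first tap (ms), before any
#'   correction; default 0.
#' @return An object of class `gem_tapper_params`.
#' @export
#' @examples
#' tapper_params(beta = 0.2, sigma_timekeeper = 10, sigma_motor = 10)
tapper_params <- function(beta = 0.2, sigma_timekeeper = 10, sigma_motor = 10,
                          p_miss = 0, period_mode = c("nominal", "tracking"),
                          initial_async = 0) {
  period_mode <- match.arg(period_mode)
  if (sigma_timekeeper < 0 || sigma_motor < 0)
    stop("noise SDs must be >= 0", call. = FALSE)
  if (p_miss < 0 || p_miss >= 1)
    stop("`p_miss` must be in [0, 1)", call. = FALSE)
  structure(
    list(beta = as.numeric(beta),
         sigma_timekeeper = as.numeric(sigma_timekeeper),
         sigma_motor = as.numeric(sigma_motor),
         p_miss = as.numeric(p_miss),
         period_mode = period_mode,
         initial_async = as.numeric(initial_async)),
    class = "gem_tapper_params"
  )
}

#' @export
print.gem_tapper_params <- function(x, ...) {
  cat(sprintf(
    "Virtual tapper: beta = %g, sigma_T = %g ms, sigma_M = %g ms, p_miss = %g, period '%s'\n",
    x$beta, x$sigma_timekeeper, x$sigma_motor, x$p_miss, x$period_mode))
  invisible(x)
}

# Deterministic 32-bit seed mixer (MINSTD-style), so every tapper and every
# trial gets an independent, reproducible stream derived from one master seed.
mix_seed <- function(seed, k) {
  m <- 2147483647
  x <- (as.double(seed) %% m) + 1
  x <- (x * 48271) %% m
  x <- (x + (as.double(k) %% m) * 69621) %% m
  x <- (x * 48271) %% m
  as.integer(x)
}

#' Build a tap source from virtual tappers
#'
#' Returns the `(window, tone_time)` callback consumed by
#' [run_trial_engine()], closing over one pre-drawn, independently seeded
#' noise stream per tapper. Tappers join at `first_tap_tone` (default 3,
#' matching the instruction to start with the third tone); before that they
#' return NA (no tap).
#'
#' @param tappers A single [tapper_params()] or a list of them (one per
#'   tapper).
#' @param cfg A [trial_config()]; `cfg$n_tappers` must equal the number of
#'   tappers.
#' @param seed Integer master seed for the trial.
#' @param first_tap_tone 1-based index of the first tone the tappers tap to.
#' @return A function `(w, tone_time) -> numeric(n_tappers)` of absolute tap
#'   times, NA where the tap was missed.
#' @export
tapper_source <- function(tappers, cfg, seed, first_tap_tone = 3) {
  if (inherits(tappers, "gem_tapper_params")) tappers <- list(tappers)
  stopifnot(length(tappers) == cfg$n_tappers)
  I <- length(tappers)
  n <- cfg$n_tones
  betas <- vapply(tappers, `[[`, numeric(1), "beta")
  a0 <- vapply(tappers, `[[`, numeric(1), "initial_async")
  tracking <- vapply(tappers, function(p) p$period_mode == "tracking", logical(1))
  # one independent stream per tapper; drawn up front for speed and replay
  Tn <- matrix(0, n, I); Mn <- matrix(0, n + 1L, I); missed <- matrix(FALSE, n, I)
  for (i in seq_len(I)) {
    p <- tappers[[i]]
    set.seed(mix_seed(seed, i))
    Tn[, i] <- stats::rnorm(n, 0, p$sigma_timekeeper)
    Mn[, i] <- stats::rnorm(n + 1L, 0, p$sigma_motor)
    if (p$p_miss > 0) missed[, i] <- stats::runif(n) < p$p_miss
  }
  planned <- rep(NA_real_, I)   # committed tap for the current window
  prev_tone <- NA_real_
  function(w, tone_time) {
    if (w == first_tap_tone)
      planned <<- tone_time + a0 + Mn[w, ]
    out <- planned
    out[missed[w, ]] <- NA_real_
    if (!any(is.na(planned))) {
      async <- planned - tone_time          # covert async, even on a miss
      period <- rep(cfg$ioi, I)
      if (any(tracking) && !is.na(prev_tone))
        period[tracking] <- tone_time - prev_tone
      planned <<- planned + period - betas * async + Tn[w, ] +
        (Mn[w + 1L, ] - Mn[w, ])
    }
    prev_tone <<- tone_time
    out
  }
}

#' Stationary SD of tap asynchronies under the coupled model
#'
#' Closed-form long-run standard deviation of the asynchrony of a single
#' phase-correcting Wing-Kristofferson tapper coupled to the adaptive
#' metronome. With `phi = 1 - alpha - beta`, the asynchrony recursion
#' `a[n+1] = phi a[n] + T[n] + M[n+1] - M[n]` is ARMA(1,1); its stationary
#' variance is
#'
#'   (sigma_T^2 + 2 (1 - phi) sigma_M^2) / (1 - phi^2)
#'
#' Derivation: the innovation `u[n] = T[n] + M[n+1] - M[n]` has variance
#' `sigma_T^2 + 2 sigma_M^2` and covariance `-sigma_M^2` with `a[n]` (through
#' the shared `M[n]`), so `g0 = phi^2 g0 + Var(u) + 2 phi Cov(a, u)`.
#' Validated against long-run simulation in the test-suite.
#'
#' @param alpha Metronome adaptivity fraction.
#' @param beta Tapper phase-correction gain.
#' @param sigma_timekeeper,sigma_motor Noise SDs (ms).
#' @return Stationary asynchrony SD in ms.
#' @export
#' @examples
#' stationary_async_sd(0.35, 0.2, 10, 10)  # ~16.23 ms
#' stationary_async_sd(0,    0.2, 10, 10)  # ~19.72 ms
stationary_async_sd <- function(alpha, beta, sigma_timekeeper, sigma_motor) {
  phi <- 1 - alpha - beta
  if (any(abs(phi) >= 1))
    stop("non-stationary parameters: need |1 - alpha - beta| < 1", call. = FALSE)
  sqrt((sigma_timekeeper^2 + 2 * (1 - phi) * sigma_motor^2) / (1 - phi^2))
}
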