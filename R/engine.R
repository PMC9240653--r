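# Adaptive-metronome timing engine.
#
# The metronome emits tones separated nominally by `ioi` milliseconds and, from
# the third tone on, shifts each upcoming tone by alpha times the mean tap
# asynchrony registered in the current tone's attribution window:
#
#   t[n+1] = t[n] + IOI + alpha * mean(async[n, ])
#
# A missed tap contributes an asynchrony of 0 to the adaptation (so a fully
# missed window leaves the next tone at the default IOI), but is preserved as
# NA in the trial record so downstream metrics can exclude rather than
# zero-fill it.

#' Trial configuration
#'
#' Bundles the timing parameters of one metronome trial ("round" of tapping).
#'
#' @param ioi Nominal inter-onset interval between metronome tones, in
#'   milliseconds. Must be positive. Default 500 ms (120 bpm).
#' @param alpha Adaptivity fraction: the proportion of the current group-mean
#'   asynchrony added to the next inter-onset interval. `alpha = 0` is a
#'   standard, non-adaptive metronome. Typically in `[0, 1]`.
#' @param n_tones Number of metronome tones in the trial; at least 2 (the
#'   first two tones establish the tempo and are never adapted).
#' @param n_tappers Group size, 1 to 4 tappers.
#' @param feedback Auditory-feedback condition tag, one of `"none"`, `"self"`,
#'   `"all"`. Metadata only; the engine does not model audition.
#' @param start_time Time of the first tone, in milliseconds.
#'
#' @return An object of class `gem_trial_config`.
#' @export
#' @examples
#' trial_config(alpha = 0.25)
trial_config <- function(ioi = 500, alpha = 0, n_tones = 25, n_tappers = 1,
                         feedback = c("none", "self", "all"), start_time = 0) {
  feedback <- match.arg(feedback)
  if (!is.numeric(ioi) || length(ioi) != 1L || !is.finite(ioi) || ioi <= 0)
    stop("`ioi` must be a single positive number (ms)", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha < 0)
    stop("`alpha` must be a single non-negative number", call. = FALSE)
  if (!is.numeric(n_tones) || length(n_tones) != 1L || n_tones < 2 ||
      n_tones != round(n_tones))
    stop("`n_tones` must be an integer >= 2", call. = FALSE)
  if (!is.numeric(n_tappers) || length(n_tappers) != 1L || n_tappers < 1 ||
      n_tappers > 4 || n_tappers != round(n_tappers))
    stop("`n_tappers` must be an integer in 1..4", call. = FALSE)
  structure(
    list(ioi = as.numeric(ioi), alpha = as.numeric(alpha),
         n_tones = as.integer(n_tones), n_tappers = as.integer(n_tappers),
         feedback = feedback, start_time = as.numeric(start_time)),
    class = "gem_trial_config"
  )
}

#' @export
print.gem_trial_config <- function(x, ...) {
  cat(sprintf(
    "Adaptive metronome trial config: %d tones @ IOI %g ms, alpha = %g, %d tapper(s), feedback '%s'\n",
    x$n_tones, x$ioi, x$alpha, x$n_tappers, x$feedback))
  invisible(x)
}

#' Tap attribution window around a metronome tone
#'
#' Taps are ascribed to a tone if they fall within plus or minus half the
#' nominal IOI of it. The interval is half-open on the right,
#' `[tone - IOI/2, tone + IOI/2)`, so a tap landing exactly half an IOI after
#' a tone belongs to the next tone.
#'
#' @param tone_time Tone onset time in ms.
#' @param ioi Nominal inter-onset interval in ms (positive).
#' @return Numeric vector `c(lo, hi)`; the window is `[lo, hi)`.
#' @export
#' @examples
#' attribution_window(10000, 500)  # [9750, 10250)
attribution_window <- function(tone_time, ioi) {
  if (!is.numeric(ioi) || length(ioi) != 1L || !is.finite(ioi) || ioi <= 0)
    stop("`ioi` must be a single positive number (ms)", call. = FALSE)
  c(tone_time - ioi / 2, tone_time + ioi / 2)
}

#' Per-tapper asynchronies used for metronome adaptation
#'
#' Maps a window's relative tap times to the asynchrony vector fed to the
#' adaptation rule: observed taps contribute `tap - tone` unchanged; missed
#' taps (NA) contribute 0, per the device's rule that a failure to tap leaves
#' the next tone at the default IOI. The missingness itself is preserved in
#' the trial record so metrics can exclude missed windows instead.
#'
#' @param tap_rel Numeric vector of relative tap times (ms), NA = missed.
#' @return Numeric vector of the same length with NAs replaced by 0.
#' @export
window_asynchronies <- function(tap_rel) {
  out <- as.numeric(tap_rel)
  out[is.na(out)] <- 0
  out
}

#' Time of the next metronome tone
#'
#' Implements the adaptation rule `t[n+1] = t[n] + IOI + alpha * mean(asyncs)`.
#' With a single tapper the mean is that tapper's asynchrony; with a group it
#' is the group average.
#'
#' @param tone_time Current tone time (ms).
#' @param asyncs Asynchrony vector for the current window, one element per
#'   tapper, with misses already mapped to 0 (see [window_asynchronies()]).
#' @param cfg A [trial_config()].
#' @return Next tone time in ms.
#' @export
next_tone_time <- function(tone_time, asyncs, cfg) {
  tone_time + cfg$ioi + cfg$alpha * mean(asyncs)
}

#' Run the metronome engine against a tap source
#'
#' Drives a full trial: tones are emitted one by one and, once each tone's
#' attribution window has closed, the registered taps determine the next tone
#' time. `tap_source` abstracts the tappers (human playback or simulated): it
#' is called once per window, after the tone time is fixed, and must return
#' that window's absolute tap times.
#'
#' Tones 1 and 2 are always scheduled at the nominal IOI (they establish the
#' tempo; tappers are instructed to join at tone 3). Tone 3 is the first that
#' can be adapted, using window-2 asynchronies — zero when no taps were
#' registered there, in which case the first two inter-tone intervals are
#' exactly the nominal IOI.
#'
#' A tap falling outside the current tone's attribution window is dropped
#' with a warning and recorded as missed: the hardware only registers taps
#' within the current window.
#'
#' @param cfg A [trial_config()].
#' @param tap_source Function `(window_index, tone_time) -> numeric(n_tappers)`
#'   of absolute tap times in ms, NA for a missed tap. `window_index` is
#'   1-based.
#' @param seed Optional integer recorded as provenance on the result (the
#'   engine itself is deterministic given `tap_source`).
#' @return A `gem_trial` object: list with `config`, `tone_times`
#'   (length `n_tones`), `tap_rel` (`n_tones` x `n_tappers` matrix of relative
#'   tap times, NA = missed), `miss_counts` (per tapper), and `seed`.
#' @export
#' @examples
#' # a perfect tapper: taps exactly on every tone from tone 3 on
#' cfg <- trial_config(alpha = 0.5, n_tones = 6)
#' trial <- run_trial_engine(cfg, function(w, tone) if (w >= 3) tone else NA_real_)
#' diff(trial$tone_times)  # all exactly 500
run_trial_engine <- function(cfg, tap_source, seed = NA_integer_) {
  stopifnot(inherits(cfg, "gem_trial_config"))
  n <- cfg$n_tones
  I <- cfg$n_tappers
  half <- cfg$ioi / 2
  tone_times <- numeric(n)
  tap_rel <- matrix(NA_real_, nrow = n, ncol = I)
  tone_times[1] <- cfg$start_time
  tone_times[2] <- cfg$start_time + cfg$ioi
  n_dropped <- 0L
  for (w in seq_len(n)) {
    taps <- as.numeric(tap_source(w, tone_times[w]))
    if (length(taps) != I)
      stop(sprintf("tap_source returned %d taps for %d tappers at window %d",
                   length(taps), I, w), call. = FALSE)
    rel <- taps - tone_times[w]
    outside <- !is.na(rel) & (rel < -half | rel >= half)
    if (any(outside)) {
      n_dropped <- n_dropped + sum(outside)
      rel[outside] <- NA_real_
    }
    tap_rel[w, ] <- rel
    if (w >= 2 && w < n) {
      nxt <- next_tone_time(tone_times[w], window_asynchronies(rel), cfg)
      if (nxt <= tone_times[w] + half)
        warning(sprintf(
          "window %d: next tone scheduled at/before current window close (extreme adaptation)", w),
          call. = FALSE)
      tone_times[w + 1] <- nxt
    }
  }
  if (n_dropped > 0L)
    warning(sprintf("%d tap(s) outside their attribution window dropped and recorded as missed",
                    n_dropped), call. = FALSE)
  new_gem_trial(cfg, tone_times, tap_rel, seed)
}

new_gem_trial <- function(cfg, tone_times, tap_rel, seed = NA_integer_,
                          trial_id = NA_character_) {
  structure(
    list(config = cfg,
         tone_times = tone_times,
         tap_rel = tap_rel,
         miss_counts = colSums(is.na(tap_rel)),
         seed = seed,
         trial_id = trial_id),
    class = "gem_trial"
  )
}

#' @export
print.gem_trial <- function(x, ...) {
  cat(sprintf(
    "gem_trial: %d windows, %d tapper(s), alpha = %g, IOI %g ms; misses per tapper: %s\n",
    x$config$n_tones, x$config$n_tappers, x$config$alpha, x$config$ioi,
    paste(x$miss_counts, collapse = "/")))
  invisible(x)
}

#' Replay a recorded trial through the engine
#'
#' Feeds a trial's registered taps back through [run_trial_engine()]. Because
#' each next tone depends only on the current window's asynchronies, replay
#' regenerates the identical tone schedule — a determinism check used in the
#' test-suite and useful for validating recorded data files.
#'
#' @param trial A `gem_trial`.
#' @return A `gem_trial` with an identical schedule.
#' @export
replay_trial <- function(trial) {
  stopifnot(inherits(trial, "gem_trial"))
  rel <- trial$tap_rel
  src <- function(w, tone_time) tone_time + rel[w, ]
  run_trial_engine(trial$config, src, seed = trial$seed)
}
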