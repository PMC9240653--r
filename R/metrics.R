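# Per-trial synchrony metrics.
#
# The primary stability measure is the standard deviation of asynchronies
# over a trial's windows (for a group, the SD of the per-window group-mean
# asynchrony). Individual-vs-group stability is the difference between the
# individual's SD asynchrony and the group's; within-window cross-tapper
# spread and its SD over time index how tightly group members track each
# other, independent of the metronome. All SDs use the population form
# (denominator N) to match the defining formulas; the sample form is
# available behind a flag. Metrics exclude missed taps (the engine, by
# contrast, substitutes 0 for adaptation) — zero-filling would bias SDs
# toward 0.

#' Standard deviation of an asynchrony series
#'
#' Population SD by default (denominator `N`, matching the defining
#' formulas); set `sample = TRUE` for the `N - 1` form.
#'
#' @param x Numeric series (NAs dropped).
#' @param sample Use the sample (`N - 1`) denominator?
#' @return SD in the units of `x`.
#' @export
#' @examples
#' sd_async(c(5, -5, 5, -5))  # 5
sd_async <- function(x, sample = FALSE) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (sample) {
    if (n < 2L) return(NA_real_)
    return(stats::sd(x))
  }
  sqrt(sum((x - mean(x))^2) / n)
}

#' Per-tapper asynchrony series
#'
#' The asynchrony of tapper `i` in window `w` is `tap[w, i] - tone[w]`; taps
#' are stored relative to their tone, so this returns the stored values. Rows
#' are windows (0-based `tone_index` in the rownames), columns tappers;
#' missed taps are NA and are excluded from that tapper's series by
#' downstream SDs, with window indices preserved.
#'
#' @param trial A `gem_trial`.
#' @return `n_tones` x `n_tappers` numeric matrix (NA = missed), with
#'   attribute `n_missed` giving per-tapper exclusion counts.
#' @export
individual_asyncs <- function(trial) {
  stopifnot(inherits(trial, "gem_trial"))
  m <- trial$tap_rel
  rownames(m) <- seq_len(nrow(m)) - 1L
  colnames(m) <- sprintf("tapper%d", seq_len(ncol(m)))
  attr(m, "n_missed") <- as.integer(colSums(is.na(m)))
  m
}

#' Per-window group-mean asynchrony
#'
#' Mean asynchrony over the tappers with an observed tap in each window;
#' windows in which nobody tapped are NA (excluded and flagged).
#'
#' @param trial A `gem_trial`.
#' @return Numeric vector, one element per window, with attribute
#'   `n_empty_windows`.
#' @export
group_asyncs <- function(trial) {
  a <- individual_asyncs(trial)
  g <- rowMeans(a, na.rm = TRUE)
  g[is.nan(g)] <- NA_real_
  attr(g, "n_empty_windows") <- sum(is.na(g))
  g
}

#' Individual-minus-group SD asynchrony difference
#'
#' For each tapper, the SD of its own asynchrony series minus the SD of the
#' per-window group-mean series, each over its own retained (non-missing)
#' windows. Negative values mean the individual taps more stably than the
#' group-average series; for a single tapper the difference is identically 0.
#'
#' @param trial A `gem_trial`.
#' @param sample Passed to [sd_async()].
#' @return Numeric vector, one value per tapper.
#' @export
sd_async_difference <- function(trial, sample = FALSE) {
  a <- individual_asyncs(trial)
  g_sd <- sd_async(group_asyncs(trial), sample = sample)
  apply(a, 2, sd_async, sample = sample) - g_sd
}

#' Within-window cross-tapper spread
#'
#' SD of the observed tappers' asynchronies within each window (population
#' form over the taps present); NA where fewer than one tap was observed.
#'
#' @param trial A `gem_trial`.
#' @param sample Passed to [sd_async()].
#' @return Numeric vector, one value per window.
#' @export
within_window_sd <- function(trial, sample = FALSE) {
  a <- individual_asyncs(trial)
  apply(a, 1, sd_async, sample = sample)
}

#' SD over time of the within-window spread
#'
#' The standard deviation, across windows, of the within-window cross-tapper
#' SDs: how variable group members' taps are with respect to each other,
#' independent of the metronome.
#'
#' @param trial A `gem_trial`.
#' @param sample Passed to [sd_async()].
#' @return SD in ms.
#' @export
sd_of_sd <- function(trial, sample = FALSE) {
  sd_async(within_window_sd(trial, sample = sample), sample = sample)
}

#' Rank tappers by absolute individual-minus-group difference
#'
#' Rank 1 goes to the smallest absolute SD asynchrony difference (the tapper
#' closest in stability to the group-average series); ties are broken by
#' tapper index for determinism.
#'
#' @param sd_diffs Per-tapper SD asynchrony differences (ms).
#' @return Integer ranks, a permutation of `1..length(sd_diffs)`.
#' @export
#' @examples
#' rank_tappers(c(10.9, -7.8, 6.5, 15.4))  # 3 2 1 4
rank_tappers <- function(sd_diffs) {
  as.integer(rank(abs(sd_diffs), ties.method = "first"))
}

#' Per-trial metric table
#'
#' One row per trial: realized alpha, group SD asynchrony (SD over windows of
#' the group-mean asynchrony — the primary stability measure), the SD of the
#' within-window spread, and per-tapper SD asynchrony, SD difference, rank,
#' and miss count in wide columns.
#'
#' @param trials A `gem_trial` or list of them; practice trials are dropped.
#' @param sample Passed to [sd_async()].
#' @return A `data.frame`, one row per trial.
#' @export
metric_table <- function(trials, sample = FALSE) {
  if (inherits(trials, "gem_trial")) trials <- list(trials)
  trials <- Filter(function(tr) !isTRUE(tr$practice), trials)
  rows <- lapply(seq_along(trials), function(k) {
    tr <- trials[[k]]
    I <- tr$config$n_tappers
    a <- individual_asyncs(tr)
    sds <- apply(a, 2, sd_async, sample = sample)
    diffs <- sd_async_difference(tr, sample = sample)
    ranks <- rank_tappers(diffs)
    row <- data.frame(
      trial_id = if (is.na(tr$trial_id)) sprintf("trial%03d", k) else tr$trial_id,
      alpha = tr$config$alpha,
      n_tappers = I,
      group_sd_async = sd_async(group_asyncs(tr), sample = sample),
      sd_of_sd = sd_of_sd(tr, sample = sample),
      stringsAsFactors = FALSE
    )
    for (i in seq_len(I)) {
      row[[sprintf("sd_async_%d", i)]] <- sds[i]
      row[[sprintf("sd_diff_%d", i)]] <- diffs[i]
      row[[sprintf("rank_%d", i)]] <- ranks[i]
      row[[sprintf("n_missed_%d", i)]] <- sum(is.na(a[, i]))
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Adaptivity benefit
#'
#' Difference in tapping performance between the baseline (non-adaptive) and
#' the optimally adaptive condition: mean group SD asynchrony at
#' `baseline_alpha` minus the mean at `optimal_alpha`. A positive value
#' corresponds to improved tapping synchrony under adaptivity.
#'
#' @param metrics A [metric_table()] data frame.
#' @param baseline_alpha Baseline adaptivity level (default 0).
#' @param optimal_alpha Optimally adaptive level (e.g. 0.25 single-tapper,
#'   0.35 group).
#' @return Benefit in ms.
#' @export
adaptivity_benefit <- function(metrics, baseline_alpha = 0, optimal_alpha) {
  base <- metrics$group_sd_async[metrics$alpha == baseline_alpha]
  opt <- metrics$group_sd_async[metrics$alpha == optimal_alpha]
  if (!length(base) || !length(opt))
    stop("requested alpha level absent from the metric table", call. = FALSE)
  mean(base, na.rm = TRUE) - mean(opt, na.rm = TRUE)
}
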