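# Post-trial rating normalization and Enjoyment scoring.
#
# After every round, participants rate (5-point scales) how in the groove
# they felt, how in synchrony with the metronome (and, in groups, with the
# others), how much they liked the task, how difficult it was, and how much
# influence they felt over the pulse. Ratings are z-scored within each
# participant and scale across that participant's trials; in group designs
# the z-scores are then averaged across participants within the group per
# trial. The single Enjoyment factor score is a fixed-loading weighted sum
# of the z-scored items (difficulty weighted negatively); items loading
# below |0.3| — felt influence — are excluded from the score. Fixed-loading
# scoring is a documented stand-in for regression-method factor scores from
# a fitted model; user-supplied weights are pluggable.

#' Published Enjoyment factor loadings
#'
#' Item loadings of the single latent Enjoyment factor: `"single"` from the
#' single-tapper factor analysis (groove 0.663, synchrony-with-metronome
#' 0.836, liking 0.460, difficulty -0.772), `"group"` from the group analysis
#' (groove 0.893, synchrony-with-metronome 0.937, synchrony-with-group 0.823,
#' liking 0.517, difficulty -0.792). Influence loaded below 0.3 and is
#' excluded.
#'
#' @param which `"single"` or `"group"`.
#' @return Named numeric vector of loadings.
#' @export
#' @examples
#' sum(enjoyment_loadings("single"))  # 1.187
enjoyment_loadings <- function(which = c("single", "group")) {
  which <- match.arg(which)
  switch(which,
    single = c(groove = 0.663, synchrony_metronome = 0.836,
               liking = 0.460, difficulty = -0.772),
    group = c(groove = 0.893, synchrony_metronome = 0.937,
              synchrony_group = 0.823, liking = 0.517, difficulty = -0.792)
  )
}

#' Z-normalize ratings within participant and scale
#'
#' For each participant x item, subtracts that participant's mean for the
#' item across trials and divides by the sample SD (`N - 1`). Degenerate
#' scales (constant ratings, SD 0, or a single trial) map to 0 with a
#' warning. With `group = TRUE` the z-scores are additionally averaged
#' across participants within each trial, yielding one row per trial x item
#' with `participant_id = "group"`.
#'
#' @param ratings Long table with columns `trial_id`, `participant_id`,
#'   `item`, `value` (values on the original rating scale).
#' @param group Average across participants within each trial after
#'   z-scoring?
#' @return The table with `value` replaced by the z-score (column `z`).
#' @export
#' @examples
#' r <- data.frame(trial_id = c("t1", "t2", "t3"), participant_id = "p1",
#'                 item = "groove", value = c(1, 3, 5))
#' znormalize(r)$z  # -1 0 1
znormalize <- function(ratings, group = FALSE) {
  needed <- c("trial_id", "participant_id", "item", "value")
  if (!all(needed %in% names(ratings)))
    stop("ratings need columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  key <- interaction(ratings$participant_id, ratings$item, drop = TRUE)
  z <- stats::ave(ratings$value, key, FUN = function(v) {
    s <- stats::sd(v)
    if (length(v) < 2L || is.na(s) || s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
  })
  degenerate <- tapply(ratings$value, key, function(v)
    length(v) < 2L || stats::sd(v) == 0)
  if (any(degenerate))
    warning(sprintf("%d participant x scale cell(s) with zero variance mapped to z = 0",
                    sum(degenerate)), call. = FALSE)
  out <- ratings
  out$z <- z
  out$value <- NULL
  if (group) {
    agg <- stats::aggregate(z ~ trial_id + item, data = out, FUN = mean)
    agg$participant_id <- "group"
    out <- agg[c("trial_id", "participant_id", "item", "z")]
  }
  out
}

#' Enjoyment factor score from fixed loadings
#'
#' Weighted sum of the z-scored rating items by the factor loadings, per
#' trial (and participant, if still present). Items with an absolute loading
#' below `min_loading` (default 0.3 — felt influence) or absent from
#' `loadings` are excluded from the score.
#'
#' @param z_table Output of [znormalize()].
#' @param loadings Named loading vector; see [enjoyment_loadings()].
#' @param min_loading Absolute-loading inclusion threshold.
#' @return Data frame `trial_id`, `participant_id`, `enjoyment`.
#' @export
enjoyment_score <- function(z_table, loadings = enjoyment_loadings("single"),
                            min_loading = 0.3) {
  loadings <- loadings[abs(loadings) >= min_loading]
  tab <- z_table[z_table$item %in% names(loadings), , drop = FALSE]
  tab$w <- loadings[tab$item] * tab$z
  out <- stats::aggregate(w ~ trial_id + participant_id, data = tab,
                          FUN = sum)
  names(out)[names(out) == "w"] <- "enjoyment"
  out[order(out$participant_id, out$trial_id), , drop = FALSE]
}

#' Read a ratings CSV
#'
#' Expects columns `trial_id`, `participant_id`, `item`, `value`.
#'
#' @param path CSV path.
#' @return Long ratings data frame.
#' @export
read_ratings_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("trial_id", "participant_id", "item", "value")
  if (!all(needed %in% names(df)))
    stop("ratings CSV needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  df[needed]
}
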