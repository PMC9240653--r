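# Missed-tap exclusion rules.
#
# Single-tapper rules, applied in order to the tidy window-level table:
#   1. a participant missing >= 30% of their required taps overall is dropped;
#   2. of the remaining data, any round missing > 30% of its taps is dropped;
#   3. a participant left with no observations in some adaptivity condition
#      is dropped entirely.
# Note the deliberate asymmetry (>= at the participant level, > at the round
# level), preserved from the original analysis text. Group rule: a group in
# which 30% or more of the required taps were missed, pooled across the
# entire group, is dropped; the round-level rule (pooled across the group)
# then applies to what remains.
#
# "Required taps" counts all windows of a round by default; set
# `exclude_lead_in = TRUE` to discount the two tempo-establishing lead-in
# tones nobody taps to.

count_misses <- function(df, by, exclude_lead_in) {
  if (exclude_lead_in) df <- df[df$tone_index >= 2L, , drop = FALSE]
  agg <- stats::aggregate(df$missed, by = df[, by, drop = FALSE],
                          FUN = function(m) c(missed = sum(m), total = length(m)))
  out <- cbind(agg[by], as.data.frame(agg$x))
  out$frac <- out$missed / out$total
  out
}

new_cleaning_report <- function(kind, dropped_participants = character(),
                                dropped_runs = data.frame(),
                                dropped_groups = character(),
                                reasons = list(), n_input_rows = 0L,
                                n_retained_rows = 0L) {
  structure(
    list(kind = kind,
         dropped_participants = dropped_participants,
         dropped_runs = dropped_runs,
         dropped_groups = dropped_groups,
         reasons = reasons,
         n_input_rows = n_input_rows,
         n_retained_rows = n_retained_rows),
    class = "gem_cleaning_report"
  )
}

#' @export
print.gem_cleaning_report <- function(x, ...) {
  cat(sprintf("Cleaning report (%s): %d -> %d rows\n", x$kind,
              x$n_input_rows, x$n_retained_rows))
  if (length(x$dropped_groups))
    cat("  dropped groups:", paste(x$dropped_groups, collapse = ", "), "\n")
  if (length(x$dropped_participants))
    cat("  dropped participants:",
        paste(x$dropped_participants, collapse = ", "), "\n")
  if (nrow(x$dropped_runs))
    cat(sprintf("  dropped runs: %d\n", nrow(x$dropped_runs)))
  invisible(x)
}

#' Single-tapper missed-tap exclusions
#'
#' Applies, in order: participant-level `>= threshold` overall miss fraction;
#' run-level `> threshold` miss fraction; removal of participants left
#' without observations in some adaptivity condition. Thresholds default to
#' the published 30% rules.
#'
#' @param df Tidy window-level table (see [trial_to_df()]) with `tapper_id`
#'   as the participant identifier; may span many trials/participants.
#' @param miss_threshold Miss-fraction threshold (default 0.30).
#' @param exclude_lead_in Discount the two lead-in tones from the required
#'   taps? Default `FALSE` (all windows counted).
#' @return List with `data` (the retained rows) and `report`
#'   (`gem_cleaning_report`). Cleaning is idempotent.
#' @export
clean_single <- function(df, miss_threshold = 0.30, exclude_lead_in = FALSE) {
  n_in <- nrow(df)
  if (n_in == 0L)
    return(list(data = df, report = new_cleaning_report("single",
                                                        n_input_rows = 0L)))
  reasons <- list()

  # 1. participant-level: >= threshold overall
  per_part <- count_misses(df, "tapper_id", exclude_lead_in)
  bad_part <- per_part$tapper_id[per_part$frac >= miss_threshold]
  if (length(bad_part))
    reasons$participant_overall <- sprintf(
      "%s: missed %.0f%% >= %.0f%% of required taps",
      bad_part, 100 * per_part$frac[match(bad_part, per_part$tapper_id)],
      100 * miss_threshold)
  df <- df[!df$tapper_id %in% bad_part, , drop = FALSE]

  # 2. run-level: > threshold within a participant's round
  dropped_runs <- data.frame()
  if (nrow(df)) {
    per_run <- count_misses(df, c("tapper_id", "trial_id"), exclude_lead_in)
    bad_run <- per_run[per_run$frac > miss_threshold, , drop = FALSE]
    if (nrow(bad_run)) {
      dropped_runs <- bad_run[c("tapper_id", "trial_id", "frac")]
      key <- paste(df$tapper_id, df$trial_id)
      df <- df[!key %in% paste(bad_run$tapper_id, bad_run$trial_id), ,
               drop = FALSE]
    }
  }

  # 3. participants with an empty adaptivity cell
  empty_cell <- character()
  if (nrow(df)) {
    all_alphas <- sort(unique(df$alpha))
    got <- table(df$tapper_id, df$alpha) > 0
    empty_cell <- rownames(got)[rowSums(got) < length(all_alphas)]
    if (length(empty_cell)) {
      reasons$empty_condition_cell <- sprintf(
        "%s: no observations left in some adaptivity condition", empty_cell)
      df <- df[!df$tapper_id %in% empty_cell, , drop = FALSE]
    }
  }

  report <- new_cleaning_report(
    "single",
    dropped_participants = c(as.character(bad_part), empty_cell),
    dropped_runs = dropped_runs,
    reasons = reasons,
    n_input_rows = n_in, n_retained_rows = nrow(df))
  list(data = df, report = report)
}

#' Group missed-tap exclusions
#'
#' Drops groups in which `>= threshold` of the required taps were missed,
#' pooled across the entire group, then applies the run-level rule (pooled
#' miss fraction `> threshold` within a round) to what remains.
#'
#' @param df Tidy window-level table with a `group_id` column (added as a
#'   single group `"g1"` if absent).
#' @inheritParams clean_single
#' @return List with `data` and `report`.
#' @export
clean_group <- function(df, miss_threshold = 0.30, exclude_lead_in = FALSE) {
  n_in <- nrow(df)
  if (is.null(df$group_id)) df$group_id <- "g1"
  if (n_in == 0L)
    return(list(data = df, report = new_cleaning_report("group",
                                                        n_input_rows = 0L)))
  reasons <- list()

  per_group <- count_misses(df, "group_id", exclude_lead_in)
  bad_group <- per_group$group_id[per_group$frac >= miss_threshold]
  if (length(bad_group))
    reasons$group_pooled <- sprintf(
      "%s: pooled miss fraction %.0f%% >= %.0f%%",
      bad_group, 100 * per_group$frac[match(bad_group, per_group$group_id)],
      100 * miss_threshold)
  df <- df[!df$group_id %in% bad_group, , drop = FALSE]

  dropped_runs <- data.frame()
  if (nrow(df)) {
    per_run <- count_misses(df, c("group_id", "trial_id"), exclude_lead_in)
    bad_run <- per_run[per_run$frac > miss_threshold, , drop = FALSE]
    if (nrow(bad_run)) {
      dropped_runs <- bad_run[c("group_id", "trial_id", "frac")]
      key <- paste(df$group_id, df$trial_id)
      df <- df[!key %in% paste(bad_run$group_id, bad_run$trial_id), ,
               drop = FALSE]
    }
  }

  report <- new_cleaning_report(
    "group",
    dropped_groups = as.character(bad_group),
    dropped_runs = dropped_runs,
    reasons = reasons,
    n_input_rows = n_in, n_retained_rows = nrow(df))
  list(data = df, report = report)
}

#' Serialize a cleaning report to JSON
#'
#' @param report A `gem_cleaning_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cleaning_report <- function(report, path) {
  stopifnot(inherits(report, "gem_cleaning_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
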