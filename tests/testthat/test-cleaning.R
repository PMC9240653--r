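# build a window-level table directly: one participant-round per call
fake_run <- function(trial_id, tapper_id, n_miss, n_tones = 25, alpha = 0,
                     group_id = NULL) {
  missed <- rep(0L, n_tones)
  if (n_miss > 0) missed[seq_len(n_miss)] <- 1L
  df <- data.frame(
    trial_id = trial_id, alpha = alpha, tone_index = seq_len(n_tones) - 1L,
    tone_time = (seq_len(n_tones) - 1L) * 500,
    tapper_id = tapper_id,
    tap_rel = ifelse(missed == 1L, NA_real_, 10),
    missed = missed, stringsAsFactors = FALSE)
  if (!is.null(group_id)) df$group_id <- group_id
  df
}

test_that("round-level rule drops > 30% but retains exactly 28% missing", {
  df <- rbind(
    fake_run("r1", "p1", n_miss = 8),   # 32% of 25 -> dropped
    fake_run("r2", "p1", n_miss = 7),   # 28% -> retained
    fake_run("r3", "p1", n_miss = 0)
  )
  res <- clean_single(df)
  expect_setequal(unique(res$data$trial_id), c("r2", "r3"))
  expect_equal(nrow(res$report$dropped_runs), 1)
  expect_equal(res$report$dropped_runs$trial_id, "r1")
})

test_that("participant-level rule uses >= 30% overall, before the round rule", {
  # exactly 30% overall: dropped (the rule is '30% or more')
  df <- rbind(
    fake_run("r1", "p1", n_miss = 15, n_tones = 50),  # 30% overall
    fake_run("r1", "p2", n_miss = 2, n_tones = 50)
  )
  res <- clean_single(df)
  expect_false("p1" %in% res$data$tapper_id)
  expect_true("p2" %in% res$data$tapper_id)
  expect_true("p1" %in% res$report$dropped_participants)
  # 29% overall: retained at participant level
  df2 <- fake_run("r1", "p3", n_miss = 29, n_tones = 100)
  expect_true("p3" %in% clean_single(df2)$data$tapper_id)
})

test_that("participants left with an empty adaptivity cell are removed", {
  df <- rbind(
    fake_run("r1", "p1", n_miss = 0, alpha = 0),
    fake_run("r2", "p1", n_miss = 10, alpha = 0.5),  # 40%: only alpha-0.5 run
    fake_run("r1", "p2", n_miss = 0, alpha = 0),
    fake_run("r2", "p2", n_miss = 0, alpha = 0.5)
  )
  res <- clean_single(df)
  # p1 overall miss 20% (< 30) but loses its only alpha = 0.5 run
  expect_false("p1" %in% res$data$tapper_id)
  expect_true(all(c("r1", "r2") %in% res$data$trial_id[res$data$tapper_id == "p2"]))
})

test_that("group rule pools misses across the entire group", {
  # one tapper missing 100%, three missing 0%: pooled 25% < 30% -> retained
  df <- do.call(rbind, c(
    list(fake_run("r1", "p1", n_miss = 25, group_id = "g1")),
    lapply(c("p2", "p3", "p4"),
           function(p) fake_run("r1", p, n_miss = 0, group_id = "g1"))))
  res <- clean_group(df)
  expect_equal(nrow(res$data), nrow(df))
  expect_length(res$report$dropped_groups, 0)
  # pooled 30% -> the whole group goes
  df2 <- do.call(rbind, lapply(c("p1", "p2", "p3", "p4"), function(p)
    fake_run("r1", p, n_miss = 8, n_tones = 25, group_id = "g2")))
  i4 <- which(df2$tapper_id == "p4")[7:8]      # 8+8+8+6 = 30 of 100
  df2$missed[i4] <- 0L
  df2$tap_rel[i4] <- 10
  expect_equal(sum(df2$missed) / nrow(df2), 0.30)
  res2 <- clean_group(df2)
  expect_equal(nrow(res2$data), 0)
  expect_identical(res2$report$dropped_groups, "g2")
})

test_that("cleaning is idempotent and a no-op on clean or empty data", {
  df <- rbind(fake_run("r1", "p1", 8), fake_run("r2", "p1", 0),
              fake_run("r1", "p2", 2))
  once <- clean_single(df)
  twice <- clean_single(once$data)
  expect_identical(twice$data, once$data)
  expect_equal(nrow(twice$report$dropped_runs), 0)

  zero <- clean_single(df[0, ])
  expect_equal(nrow(zero$data), 0)
  expect_equal(zero$report$n_input_rows, 0)
  all_clean <- clean_group(fake_run("r1", "p1", 0, group_id = "g1"))
  expect_equal(nrow(all_clean$data), 25)
})

test_that("lead-in exclusion and thresholds are configurable", {
  # 9 misses of 27 tones = 33% counting all windows, but the first two are
  # the lead-in nobody taps: 7 of 25 = 28% with exclude_lead_in
  df <- fake_run("r1", "p1", n_miss = 9, n_tones = 27)
  expect_false("r1" %in% clean_single(df)$data$trial_id)
  expect_true("r1" %in%
                clean_single(df, exclude_lead_in = TRUE)$data$trial_id)
  expect_false("r1" %in%
                 clean_single(df, miss_threshold = 0.2,
                              exclude_lead_in = TRUE)$data$trial_id)
})

test_that("cleaning reports serialize to JSON", {
  df <- rbind(fake_run("r1", "p1", 8), fake_run("r2", "p1", 0))
  res <- clean_single(df)
  path <- withr::local_tempfile(fileext = ".json")
  write_cleaning_report(res$report, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$n_input_rows, 50)
  expect_equal(back$dropped_runs$trial_id, "r1")
})
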