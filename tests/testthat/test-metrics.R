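make_trial <- function(tap_rel, ioi = 500, alpha = 0) {
  tap_rel <- as.matrix(tap_rel)
  n <- nrow(tap_rel)
  # built directly so single-window fixtures bypass the n_tones >= 2 rule
  cfg <- structure(
    list(ioi = ioi, alpha = alpha, n_tones = n,
         n_tappers = ncol(tap_rel), feedback = "none", start_time = 0),
    class = "gem_trial_config")
  gemsim:::new_gem_trial(cfg, seq(0, by = ioi, length.out = n), tap_rel)
}

test_that("population SD matches hand-computed values", {
  expect_equal(sd_async(c(5, -5, 5, -5)), 5)
  expect_equal(sd_async(rep(3, 10)), 0)
  expect_equal(sd_async(c(0, 10, 0, 10)), 5)
  expect_equal(sd_async(c(1, 2, 3, 4), sample = TRUE), sd(c(1, 2, 3, 4)))
  expect_true(is.na(sd_async(numeric(0))))
})

test_that("individual series exclude misses but keep window indices", {
  m <- matrix(c(0, 10, NA, 10, 0, 0, 0, 0, 0, 0), ncol = 2)
  tr <- make_trial(m)
  a <- individual_asyncs(tr)
  expect_equal(a, m, ignore_attr = TRUE)
  expect_identical(unname(attr(a, "n_missed")), c(1L, 0L))
  series <- a[, 1][!is.na(a[, 1])]
  expect_length(series, 4)
  expect_identical(names(series), c("0", "1", "3", "4"))  # 0-based windows
})

test_that("group asynchrony averages the observed taps per window", {
  tr <- make_trial(matrix(c(-20, 10, -10, 40), 1))
  expect_equal(as.numeric(group_asyncs(tr)), 5)
  # one of four missing: mean over the 3 observed
  tr <- make_trial(matrix(c(0, NA, 0, 0), 1))
  expect_equal(as.numeric(group_asyncs(tr)), 0)
  # single tapper: identical to the individual series
  m <- matrix(rnorm(10), 10, 1)
  tr <- make_trial(m)
  expect_equal(as.numeric(group_asyncs(tr)), m[, 1])
})

test_that("individual-minus-group SD differences match worked examples", {
  # tapper [0,10,0,10] against three constant co-tappers averaging to 0-ish:
  # build directly: individual SD 5, group series constant 0 after averaging
  m <- cbind(c(0, 10, 0, 10), c(0, -10, 0, -10))
  tr <- make_trial(m)
  # group means are 0 in every window -> group SD 0; each tapper SD 5
  expect_equal(sd_async_difference(tr), c(5, 5), ignore_attr = TRUE)
  # single tapper: difference identically zero
  tr1 <- make_trial(matrix(rnorm(20), 20, 1))
  expect_equal(as.numeric(sd_async_difference(tr1)), 0)
})

test_that("within-window spread and its SD over time match brute force", {
  tr <- make_trial(matrix(c(-20, 10, -10, 40), 1))
  expect_equal(as.numeric(within_window_sd(tr)), sqrt(525), tolerance = 1e-12)
  # identical tappers -> all zeros
  tr <- make_trial(matrix(5, 6, 4))
  expect_equal(as.numeric(within_window_sd(tr)), rep(0, 6))
  expect_equal(sd_of_sd(tr), 0)
  # constant spread c over windows -> SD of SD = 0
  tr <- make_trial(cbind(rep(0, 5), rep(10, 5)))
  expect_equal(as.numeric(within_window_sd(tr)), rep(5, 5))
  expect_equal(sd_of_sd(tr), 0)
})

test_that("tapper ranking sorts by absolute difference, ties by index", {
  expect_identical(rank_tappers(c(10.9, -7.8, 6.5, 15.4)), c(3L, 2L, 1L, 4L))
  expect_identical(rank_tappers(c(1, 2, 3, 4)), 1:4)
  expect_identical(rank_tappers(c(-5, 5, -5, 5)), 1:4)
})

test_that("all five defining metrics agree with brute-force loops", {
  set.seed(77)
  for (k in 1:100) {
    tr <- random_trial(n_windows = sample(5:30, 1),
                       n_tappers = sample(1:4, 1))
    oracle <- brute_metrics(tr)
    expect_equal(unname(individual_asyncs(tr)), oracle$individual,
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(as.numeric(group_asyncs(tr)), oracle$group,
                 tolerance = 1e-12)
    expect_equal(sd_async(group_asyncs(tr)), oracle$group_sd,
                 tolerance = 1e-12)
    expect_equal(unname(sd_async_difference(tr)), oracle$sd_diff,
                 tolerance = 1e-12)
    expect_equal(as.numeric(within_window_sd(tr)), oracle$window_sd,
                 tolerance = 1e-12)
    expect_equal(sd_of_sd(tr), oracle$sd_of_sd, tolerance = 1e-12)
  }
})

test_that("group metrics are invariant to tapper order", {
  set.seed(88)
  tr <- random_trial(20, 4)
  perm <- sample(4)
  tr2 <- tr
  tr2$tap_rel <- tr$tap_rel[, perm]
  expect_equal(sd_async(group_asyncs(tr2)), sd_async(group_asyncs(tr)))
  expect_equal(sd_of_sd(tr2), sd_of_sd(tr))
  expect_equal(unname(sd_async_difference(tr2)),
               unname(sd_async_difference(tr))[perm])
})

test_that("group-mean SD scales as 1/sqrt(K) for independent identical tappers", {
  # alpha = 0, sigma_M = 0: each tapper is an independent AR(1); averaging K
  # of them divides the stationary SD by sqrt(K)
  tp <- tapper_params(beta = 0.3, sigma_timekeeper = 12, sigma_motor = 0)
  sd_for_k <- function(K, seed) {
    cfg <- trial_config(alpha = 0, n_tones = 6000, n_tappers = K)
    tr <- run_trial(cfg, tp, seed = seed, first_tap_tone = 1)
    sd_async(group_asyncs(tr)[-(1:500)])
  }
  s1 <- mean(vapply(1:6, function(s) sd_for_k(1, s), numeric(1)))
  s4 <- mean(vapply(7:12, function(s) sd_for_k(4, s), numeric(1)))
  expect_equal(s4, s1 / 2, tolerance = 0.08)
})

test_that("metric pipeline is consistent under engine replay", {
  set.seed(99)
  tr <- run_trial(trial_config(alpha = 0.5, n_tones = 40, n_tappers = 4),
                  tapper_params(p_miss = 0.1), seed = 123)
  tr2 <- replay_trial(tr)
  expect_equal(metric_table(tr2)[-1], metric_table(tr)[-1])
})

test_that("metric table and adaptivity benefit wire together", {
  trials <- list(
    make_trial(matrix(c(0, 20, 0, 20), 4, 1), alpha = 0),
    make_trial(matrix(c(0, 8, 0, 8), 4, 1), alpha = 0.25)
  )
  trials[[1]]$trial_id <- "a"; trials[[2]]$trial_id <- "b"
  mt <- metric_table(trials)
  expect_equal(nrow(mt), 2)
  expect_equal(mt$group_sd_async, c(10, 4))
  expect_equal(adaptivity_benefit(mt, 0, 0.25), 6)
  expect_equal(adaptivity_benefit(mt, 0, 0), 0)
  expect_error(adaptivity_benefit(mt, 0, 0.5), "absent")
})
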