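# Shared fixtures and independent brute-force oracles for the metric tests.
# The oracles deliberately re-implement the defining formulas as plain loops,
# independent of the package's vectorized code paths.

# deterministic tap source: taps `offset` ms after every tone from
# `from_tone` on (NA before)
constant_tap_source <- function(offset, from_tone = 1L) {
  function(w, tone_time) if (w >= from_tone) tone_time + offset else NA_real_
}

# random small trial: tone times on a jittered grid, taps uniform within the
# window, each tap missing with probability p_miss
random_trial <- function(n_windows, n_tappers, p_miss = 0.15, ioi = 500,
                         alpha = 0.5) {
  tone_times <- cumsum(c(0, ioi + runif(n_windows - 1, -50, 50)))
  tap_rel <- matrix(runif(n_windows * n_tappers, -ioi / 2, ioi / 2 - 1),
                    n_windows, n_tappers)
  tap_rel[matrix(runif(n_windows * n_tappers) < p_miss,
                 n_windows, n_tappers)] <- NA_real_
  gemsim:::new_gem_trial(
    trial_config(ioi = ioi, alpha = alpha, n_tones = n_windows,
                 n_tappers = n_tappers),
    tone_times, tap_rel)
}

# population SD by direct looping over the defining radical
brute_pop_sd <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  mu <- sum(x) / length(x)
  acc <- 0
  for (v in x) acc <- acc + (v - mu)^2
  sqrt(acc / length(x))
}

# Eqs. 3-7 recomputed with explicit loops over windows and tappers
brute_metrics <- function(trial) {
  n <- trial$config$n_tones
  I <- trial$config$n_tappers
  indiv <- trial$tap_rel                      # Eq. 3: tap - tone, stored
  grp <- rep(NA_real_, n)                     # Eq. 4
  win_sd <- rep(NA_real_, n)                  # Eq. 6
  for (w in seq_len(n)) {
    obs <- indiv[w, ][!is.na(indiv[w, ])]
    if (length(obs)) {
      grp[w] <- sum(obs) / length(obs)
      win_sd[w] <- brute_pop_sd(obs)
    }
  }
  sd_diff <- numeric(I)                       # Eq. 5
  g_sd <- brute_pop_sd(grp)
  for (i in seq_len(I)) sd_diff[i] <- brute_pop_sd(indiv[, i]) - g_sd
  list(individual = indiv, group = grp, group_sd = g_sd,
       sd_diff = sd_diff, window_sd = win_sd,
       sd_of_sd = brute_pop_sd(win_sd))       # Eq. 7
}

# batch-means Monte-Carlo standard error of the SD of an autocorrelated series
batch_se_of_sd <- function(x, n_batches = 20L) {
  n <- length(x) %/% n_batches * n_batches
  batches <- matrix(x[seq_len(n)], ncol = n_batches)
  stats::sd(apply(batches, 2, stats::sd)) / sqrt(n_batches)
}

# long coupled simulation of a single tapper's asynchrony series
simulate_async_series <- function(alpha, beta, sigma_t = 10, sigma_m = 10,
                                  n = 1e5, seed = 1, burn = 500) {
  cfg <- trial_config(alpha = alpha, n_tones = n + burn)
  tp <- tapper_params(beta = beta, sigma_timekeeper = sigma_t,
                      sigma_motor = sigma_m)
  tr <- run_trial(cfg, tp, seed = seed, first_tap_tone = 1)
  tr$tap_rel[-seq_len(burn), 1]
}
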