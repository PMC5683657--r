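test_that("rate profile follows the tuning and adaptation model", {
  cfg <- population_config(n_neurons = 3, n_trials = 2, bf_jitter = 0,
                           spontaneous_range = c(4, 4), seed = 1)
  prof <- build_rate_profile(cfg)
  # neuron 1's best frequency sits at the lowest tone (no jitter)
  bf_stim <- which.min(abs(log2(prof$best_frequency[1] / cfg$stimuli$frequency)))
  # late sustained epoch at the best frequency: spontaneous + sustained rate
  k <- which(prof$t == 480)
  expect_equal(prof$rate[1, bf_stim, k], 4 + cfg$sustained_rate,
               tolerance = 0.01)
  # far-off stimulus with narrow tuning stays at spontaneous
  cfg2 <- population_config(n_neurons = 3, bf_jitter = 0,
                            spontaneous_range = c(4, 4),
                            tuning_width_onset = 0.3,
                            tuning_width_sustained = 0.3, seed = 1)
  prof2 <- build_rate_profile(cfg2)
  far_stim <- which.max(abs(log2(prof2$best_frequency[1] /
                                   cfg2$stimuli$frequency)))
  expect_equal(prof2$rate[1, far_stim, which(prof2$t == 30)], 4,
               tolerance = 0.02)
  # pre-onset and post-response rates are spontaneous
  expect_true(all(prof$rate[, , prof$t < 20] == 4))
  expect_true(all(prof$rate[, , prof$t >= 521] == 4))
})

test_that("population-mean rate peaks at onset and declines afterwards", {
  prof <- build_rate_profile(population_config(n_neurons = 50, seed = 3))
  mean_rate <- apply(prof$rate, 3, mean)
  bins <- sliding_windows(c(0, 500), 15, 15)
  bin_mean <- vapply(bins$start, function(s)
    mean(mean_rate[prof$t >= s & prof$t < s + 15]), numeric(1))
  expect_lte(bins$start[which.max(bin_mean)], 50)
  # monotone decline after the peak (coarse bins, exact for the model)
  after <- bin_mean[bins$start >= 30]
  expect_true(all(diff(after) <= 1e-9))
})

test_that("inhomogeneous Poisson sampling matches its rate profile", {
  # zero rate everywhere -> no spikes
  cfg0 <- population_config(n_neurons = 2, n_trials = 3,
                            spontaneous_range = c(0, 0),
                            onset_peak_rate = 0, sustained_rate = 0, seed = 1)
  expect_equal(nrow(simulate_population(cfg0, seed = 1)$spikes), 0)
  # constant 100 spikes/s: count in 500 ms is Poisson(50)
  cfgc <- population_config(n_neurons = 1, n_trials = 400,
                            stimuli = stimulus_set(frequency = 1000),
                            spontaneous_range = c(100, 100),
                            onset_peak_rate = 0, sustained_rate = 0,
                            record_span = c(0, 500), seed = 2)
  pop <- simulate_population(cfgc, seed = 3)
  counts <- count_tensor(pop, time_window(0, 500))[1, 1, ]
  se <- sqrt(50 / 400)
  expect_lt(abs(mean(counts) - 50), 3 * se)
  # Poisson dispersion: Fano within 3 SE of 1
  fano <- var(counts) / mean(counts)
  expect_lt(abs(fano - 1), 3 * sqrt(2 / (400 - 1)))
})

test_that("spike sampling is reproducible under a fixed seed", {
  cfg <- population_config(n_neurons = 5, seed = 9)
  a <- simulate_population(cfg, seed = 21)
  b <- simulate_population(cfg, seed = 21)
  expect_identical(a$spikes, b$spikes)
  c <- simulate_population(cfg, seed = 22)
  expect_false(identical(a$spikes, c$spikes))
})

test_that("count simulation draws Poisson counts with mean k_r r k_T T", {
  r <- matrix(c(0, 50, 100, 200), 2)
  expect_true(all(simulate_count_population(r * 0, T = 1, n_trials = 5,
                                            seed = 1) == 0))
  # k_r k_T product invariance of the expected count
  n <- 4000
  a <- simulate_count_population(r, k_r = 0.5, k_T = 2, T = 0.01,
                                 n_trials = n, seed = 2)
  b <- simulate_count_population(r, k_r = 1, k_T = 1, T = 0.01,
                                 n_trials = n, seed = 3)
  for (i in 1:2) for (j in 1:2) {
    mu <- r[i, j] * 0.01
    if (mu == 0) next
    se <- sqrt(mu / n)
    expect_lt(abs(mean(a[i, j, ]) - mu), 4 * se)
    expect_lt(abs(mean(a[i, j, ]) - mean(b[i, j, ])), 4 * sqrt(2) * se)
  }
  # closed-form mean check: 100 spikes/s for 8.8 ms -> 0.88
  x <- simulate_count_population(matrix(100), T = 0.0088, n_trials = 1e4,
                                 seed = 4)
  expect_lt(abs(mean(x) - 0.88), 3 * sqrt(0.88 / 1e4))
  expect_error(simulate_count_population(matrix(-1), T = 1), "non-negative")
})

test_that("generated populations show the onset/sustained structure", {
  pop <- small_population(n_neurons = 50, profile_seed = 3, spike_seed = 5)
  # (a) mean population rate maximal early, lower late
  rate_in <- function(s, l) mean(count_tensor(pop, time_window(s, l))) / (l / 1000)
  onset_max <- max(vapply(seq(0, 35, 5), rate_in, numeric(1), l = 15))
  sustained <- mean(vapply(seq(200, 485, 15), rate_in, numeric(1), l = 15))
  expect_gt(onset_max, 2 * sustained)
  # (b) more effective stimuli at onset than sustained (population mean)
  profs <- selectivity_profiles(pop, neurons = seq(1, 50, 2))
  eff_on <- vapply(profs, function(p)
    max(p$effective_count[p$time >= 0 & p$time < 200]), numeric(1))
  eff_su <- vapply(profs, function(p)
    max(p$effective_count[p$time >= 200 & p$time <= 450]), numeric(1))
  expect_gt(mean(eff_on), mean(eff_su))
  # (c) windowed counts look Poisson: GOF pass rate >= 95%
  set.seed(8)
  cells <- expand.grid(n = seq(1, 50, 3), s = 1:6, w = c(30, 120, 300))
  pvals <- apply(cells, 1, function(row) {
    cnt <- count_tensor(pop, time_window(row[["w"]], 15))[row[["n"]],
                                                          row[["s"]], ]
    poisson_gof_test(cnt)
  })
  expect_gte(mean(pvals > 0.05), 0.95)
})
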