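test_that("count_spikes uses half-open window semantics", {
  expect_identical(count_spikes(numeric(0), time_window(0, 100)), 0L)
  # start included, end excluded
  expect_identical(count_spikes(c(10, 20, 35), time_window(10, 15)), 2L)
  # brute-force oracle on a dense train
  train <- as.numeric(0:499)
  w <- time_window(0, 15)
  expect_identical(count_spikes(train, w), sum(train >= 0 & train < 15))
  expect_identical(count_spikes(train, w), 15L)
})

test_that("adjacent windows partition spike counts exactly", {
  set.seed(42)
  for (i in 1:20) {
    train <- sort(runif(200, -300, 1200))
    cuts <- sort(runif(3, -300, 1200))
    a <- cuts[1]; b <- cuts[2]; c <- cuts[3]
    expect_identical(
      count_spikes(train, time_window(a, b - a)) +
        count_spikes(train, time_window(b, c - b)),
      count_spikes(train, time_window(a, c - a)))
  }
})

test_that("rate_in_window converts counts to spikes/s", {
  expect_equal(rate_in_window(c(1, 5, 9), time_window(0, 15)), 200)
  expect_equal(rate_in_window(numeric(0), time_window(0, 15)), 0)
  set.seed(1)
  train <- sort(runif(40, 0, 50))
  w <- time_window(0, 50)
  expect_equal(rate_in_window(train, w), count_spikes(train, w) / 0.05)
  expect_error(time_window(0, 0), "positive")
})

test_that("sliding_windows enumerates starts while the window fits", {
  w <- sliding_windows(c(0, 500), 15, 5)
  expect_equal(nrow(w), 98)
  expect_equal(w$start[1], 0)
  expect_equal(w$start[98], 485)
  expect_equal(nrow(sliding_windows(c(0, 15), 15, 5)), 1)
  expect_equal(nrow(sliding_windows(c(0, 10), 15, 5)), 0)
  # count formula property
  set.seed(7)
  for (i in 1:20) {
    span <- sort(runif(2, -300, 1200))
    len <- runif(1, 1, 100)
    step <- runif(1, 0.5, 20)
    n <- nrow(sliding_windows(span, len, step))
    expect_equal(n, max(0, floor((diff(span) - len) / step) + 1))
  }
})

test_that("spike_count_window grows to the target pooled count", {
  # 100 spikes, one per ms at integer times 0..99
  df <- data.frame(neuron = 1, stimulus = 1, trial = 1, time = as.numeric(0:99))
  d <- manual_set(df, n_trials = 1, n_stim = 1)
  w <- spike_count_window(d, 0, 100)
  expect_equal(w$length, 100)
  expect_gte(count_spikes(get_train(d, 1, 1, 1), w), 100)
  # target 1, spike exactly at the left edge
  expect_equal(spike_count_window(d, 50, 1)$length, 1)
  # unreachable target errors and carries the achieved count
  err <- tryCatch(spike_count_window(d, 0, 500), condition = identity)
  expect_s3_class(err, "popcode_insufficient_spikes")
  expect_equal(err$achieved, 100)
})

test_that("doubling spike density never lengthens a count window", {
  set.seed(11)
  base <- poisson_spike_table(1, 1, 1:5, rate = 60, span = c(0, 1000))
  d1 <- manual_set(base, n_trials = 5, n_stim = 1, record_span = c(0, 1000))
  dbl <- rbind(base, transform(base, time = pmin(time + 0.25, 1000)))
  d2 <- manual_set(dbl, n_trials = 5, n_stim = 1, record_span = c(0, 1000))
  for (target in c(10, 40, 80)) {
    expect_lte(spike_count_window(d2, 0, target)$length,
               spike_count_window(d1, 0, target)$length)
  }
})

test_that("population_response extracts single-trial rate vectors", {
  df <- data.frame(neuron = c(1, 1, 1),
                   stimulus = 1, trial = 1, time = c(1, 5, 9))
  d <- manual_set(df, n_trials = 1, n_stim = 1, neurons = 1:2)
  pr <- population_response(d, time_window(0, 15))
  expect_equal(dim(pr$rates), c(1, 2))
  expect_equal(pr$rates[1, ], c(200, 0))
  # all-silent population gives the zero vector
  silent <- manual_set(data.frame(neuron = integer(0), stimulus = integer(0),
                                  trial = integer(0), time = numeric(0)),
                       n_trials = 2, n_stim = 2, neurons = 1:3)
  expect_true(all(population_response(silent, time_window(0, 50))$rates == 0))
})

test_that("count_tensor matches per-train counting elementwise", {
  pop <- small_population(n_neurons = 5)
  w <- time_window(20, 25)
  cnt <- count_tensor(pop, w)
  pr <- population_response(pop, w)
  for (n in 1:5) {
    for (s in 1:6) {
      for (tr in c(1, 7, 20)) {
        ref <- count_spikes(get_train(pop, n, s, tr), w)
        expect_identical(cnt[n, s, tr], ref)
        row <- which(pr$stimulus == s & pr$trial == tr)
        expect_equal(pr$rates[row, n], ref / (w$length / 1000))
      }
    }
  }
})

test_that("spike data round-trips through CSV + JSON manifest", {
  pop <- small_population(n_neurons = 20)
  csv <- tempfile(fileext = ".csv")
  write_spike_data(pop, csv)
  back <- read_spike_data(csv)
  expect_equal(back$neurons, pop$neurons)
  expect_equal(back$n_trials, pop$n_trials)
  expect_equal(back$record_span, pop$record_span)
  expect_equal(back$stimuli$frequency, pop$stimuli$frequency)
  expect_equal(nrow(back$spikes), nrow(pop$spikes))
  # identical spike times to 0.001 ms, same keys
  expect_identical(back$key, pop$key)
  expect_true(all(abs(back$spikes$time - pop$spikes$time) <= 5e-4 + 1e-9))
  unlink(c(csv, sub("csv$", "json", csv)))
})

test_that("malformed spike files are rejected with the offending record", {
  pop <- small_population(n_neurons = 3)
  csv <- tempfile(fileext = ".csv")
  write_spike_data(pop, csv)
  df <- read.csv(csv)
  bad <- df[, c("neuron_id", "stimulus_id", "spike_time_ms")]  # drop trial
  csv2 <- tempfile(fileext = ".csv")
  write.csv(bad, csv2, row.names = FALSE)
  file.copy(sub("csv$", "json", csv), sub("csv$", "json", csv2))
  expect_error(read_spike_data(csv2), "trial")
  # unsorted times within a trial block
  df2 <- df
  df2$spike_time_ms[1:2] <- rev(df2$spike_time_ms[1:2])
  csv3 <- tempfile(fileext = ".csv")
  write.csv(df2, csv3, row.names = FALSE)
  file.copy(sub("csv$", "json", csv), sub("csv$", "json", csv3))
  if (df$neuron_id[1] == df$neuron_id[2] && df$trial[1] == df$trial[2] &&
      df$stimulus_id[1] == df$stimulus_id[2] &&
      df$spike_time_ms[1] != df$spike_time_ms[2]) {
    expect_error(read_spike_data(csv3), "unsorted")
  }
  unlink(c(csv, csv2, csv3, sub("csv$", "json", csv),
           sub("csv$", "json", csv2), sub("csv$", "json", csv3)))
})

test_that("spike_train_set validates its invariants", {
  df <- data.frame(neuron = 1, stimulus = 1, trial = 1, time = 5000)
  expect_error(manual_set(df, n_trials = 1, n_stim = 1), "record_span")
  df2 <- data.frame(neuron = 1, stimulus = 9, trial = 1, time = 50)
  expect_error(manual_set(df2, n_trials = 1, n_stim = 2), "stimulus")
  expect_error(stimulus_set(frequency = c(2000, 1000)), "increasing")
})
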