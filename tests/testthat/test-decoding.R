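test_that("templates are per-stimulus means of training responses", {
  x <- rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8))
  y <- c(1, 1, 2, 2)
  m <- fit_template(x, y)
  expect_equal(m$templates, rbind(c(2, 3), c(6, 7)))
  # single trial per stimulus: template equals the trial
  m1 <- fit_template(x[c(1, 3), ], c(1, 2))
  expect_equal(m1$templates, x[c(1, 3), ])
  # (v, -v) averages to the zero template
  m0 <- fit_template(rbind(c(2, -1), c(-2, 1)), c(1, 1))
  expect_equal(m0$templates, matrix(0, 1, 2))
  # elementwise oracle on a random fixture
  set.seed(13)
  xr <- matrix(rnorm(60), 12)
  yr <- rep(1:3, each = 4)
  mr <- fit_template(xr, yr)
  for (cl in 1:3)
    expect_equal(mr$templates[cl, ], apply(xr[yr == cl, ], 2, mean))
})

test_that("classification picks the nearest template under each metric", {
  m <- fit_template(rbind(c(1, 0), c(0, 1)), c(1, 2))
  expect_equal(classify(m, c(1, 0)), 1)               # exact match, d = 0
  # hand computation: (0.9, 0.1) is closer to (1,0)
  expect_equal(classify(m, c(0.9, 0.1)), 1)
  d1 <- sqrt(0.01 + 0.01)
  d2 <- sqrt(0.81 + 0.81)
  expect_equal(d1, 0.1414214, tolerance = 1e-6)
  expect_gt(d2, d1)
  # angular metric is scale-invariant
  mc <- fit_template(rbind(c(1, 0), c(0, 1)), c(1, 2), metric = "angular")
  expect_equal(classify(mc, 10 * c(1, 0)), 1)
  expect_equal(classify(mc, 0.01 * c(0, 1)), 2)
  # zero-norm test vector resolves to the first class
  expect_equal(classify(mc, c(0, 0)), 1)
  # ties break to the lowest stimulus index
  expect_equal(classify(m, c(0.5, 0.5)), 1)
})

test_that("PCA+LDA decoder separates what is separable", {
  sep <- separable_responses(sep = 50, noise = 1, seed = 2)
  r <- decode_cv(sep$x, sep$y, sep$trial, "LDA")
  expect_equal(r$accuracy, 1.0)
  # identical class distributions decode at chance
  set.seed(3)
  x0 <- matrix(rnorm(120 * 8), 120)
  y0 <- rep(1:6, each = 20)
  tr0 <- rep(1:20, times = 6)
  acc0 <- decode_cv(x0, y0, tr0, "LDA")$accuracy
  expect_lt(abs(acc0 - 1 / 6), 3 * sqrt(1 / 6 * 5 / 6 / 120))
  # collinear data keep exactly one principal component
  set.seed(4)
  tvec <- rnorm(40)
  xl <- cbind(tvec, 2 * tvec, -tvec) +
    rep(c(0, 10), each = 20)
  ml <- fit_lda(xl, rep(1:2, each = 20))
  expect_equal(ml$n_components, 1)
})

test_that("our LDA agrees with an independent reference implementation", {
  set.seed(7)
  n <- 30
  x <- rbind(matrix(rnorm(n * 4, 0), n),
             matrix(rnorm(n * 4, 2), n),
             matrix(rnorm(n * 4, c(2, -2, 0, 1)), n))
  y <- rep(1:3, each = n)
  ours <- classify(fit_lda(x, y, var_retained = 0.9999), x)
  ref <- as.integer(predict(MASS::lda(x, grouping = y), x)$class)
  expect_gt(mean(ours == ref), 0.95)
})

test_that("cross-validated decoding matches the brute-force oracle", {
  set.seed(5)
  for (i in 1:100) {
    n_classes <- sample(3:6, 1)
    n_trials <- 8
    x <- matrix(rnorm(n_classes * n_trials * 5,
                      mean = rep(rnorm(n_classes, sd = 1.2),
                                 each = n_trials)),
                n_classes * n_trials, 5)
    y <- rep(seq_len(n_classes), each = n_trials)
    trial <- rep(seq_len(n_trials), times = n_classes)
    fold <- (trial - 1) %/% 2 + 1          # 4 folds of 2 trials
    for (f in 1:4) {
      te <- fold == f
      m <- fit_template(x[!te, , drop = FALSE], y[!te])
      expect_equal(classify(m, x[te, , drop = FALSE]),
                   oracle_nearest_template(x[!te, , drop = FALSE], y[!te],
                                           x[te, , drop = FALSE]))
    }
  }
})

test_that("all decoders are perfect on separated data, chance on shuffled", {
  sep <- separable_responses(sep = 50, noise = 1, seed = 11)
  set.seed(12)
  ysh <- sample(sep$y)
  for (m in c("LDA", "TMPEUC", "TMPCOS")) {
    expect_equal(decode_cv(sep$x, sep$y, sep$trial, m)$accuracy, 1.0)
    accs <- decode_cv(sep$x, ysh, sep$trial, m)$accuracy
    expect_lt(abs(accs - 1 / 6), 3 * sqrt(1 / 6 * 5 / 6 / 120))
  }
})

test_that("decoder invariances hold", {
  set.seed(21)
  x <- matrix(abs(rnorm(120 * 6, mean = rep(1:6, each = 20))), 120)
  y <- rep(1:6, each = 20)
  trial <- rep(1:20, times = 6)
  # TMPEUC is invariant under a common translation
  shift <- matrix(rep(rnorm(6), each = 120), 120)
  a1 <- decode_cv(x, y, trial, "TMPEUC")
  a2 <- decode_cv(x + shift, y, trial, "TMPEUC")
  expect_identical(a1$accuracy, a2$accuracy)
  expect_identical(a1$confusion, a2$confusion)
  # TMPCOS predictions are invariant under positive per-test-trial rescaling
  m <- fit_template(x[trial <= 15, ], y[trial <= 15], "angular")
  xte <- x[trial > 15, ]
  scl <- runif(nrow(xte), 0.2, 5)
  expect_identical(classify(m, xte * scl), classify(m, xte))
})

test_that("fold bookkeeping is valid and honest", {
  sep <- separable_responses(sep = 0.5, noise = 1, seed = 31)
  r <- decode_cv(sep$x, sep$y, sep$trial, "TMPEUC")
  expect_equal(sum(r$confusion), 120)
  expect_true(all(rowSums(r$confusion) == 20))
  expect_equal(r$accuracy, mean(r$fold_accuracy))
  expect_equal(r$accuracy, sum(diag(r$confusion)) / sum(r$confusion))
  expect_error(decode_cv(sep$x, sep$y, sep$trial, "TMPEUC", n_folds = 7),
               "divisible")
})

test_that("random-split accuracy quantifies split uncertainty", {
  pop <- small_population(n_neurons = 15)
  w <- time_window(20, 15)
  r1 <- random_split_accuracy(pop, w, "TMPEUC", n_runs = 50, seed = 5)
  r2 <- random_split_accuracy(pop, w, "TMPEUC", n_runs = 50, seed = 5)
  expect_identical(r1$accuracies, r2$accuracies)
  expect_gt(r1$sd, 0)
  # chance-level window: run-mean within 3 dataset-level binomial SE of 1/6
  r0 <- random_split_accuracy(pop, time_window(-250, 15), "TMPEUC",
                              n_runs = 200, seed = 9)
  expect_lt(abs(r0$mean - 1 / 6), 3 * sqrt(1 / 6 * 5 / 6 / 120))
  # per-run accuracies scatter like a 30-trial binomial around chance
  expect_lt(abs(r0$sd - sqrt(1 / 6 * 5 / 6 / 30)), 0.05)
})

test_that("single-neuron decoding works on scalar rates", {
  # disjoint count ranges per stimulus decode perfectly
  rows <- do.call(rbind, lapply(1:6, function(s)
    do.call(rbind, lapply(1:20, function(tr)
      data.frame(neuron = 1, stimulus = s, trial = tr,
                 time = seq(5, 5 + (s - 1) * 60, by = 10))))))
  d <- manual_set(rows, n_trials = 20)
  expect_equal(single_neuron_accuracy(d, 1, time_window(0, 400))$accuracy, 1.0)
  # untuned neuron decodes at chance
  pop <- small_population(n_neurons = 8)
  acc <- single_neuron_accuracy(pop, 3, time_window(-250, 15))$accuracy
  expect_lt(abs(acc - 1 / 6), 3 * sqrt(1 / 6 * 5 / 6 / 120))
  # equivalence with the population machinery restricted to one neuron
  w <- time_window(20, 15)
  pr <- population_response(pop, w)
  ref <- decode_cv(pr$rates[, 3, drop = FALSE], pr$stimulus, pr$trial,
                   "TMPEUC")
  expect_equal(single_neuron_accuracy(pop, 3, w)$accuracy, ref$accuracy)
})
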