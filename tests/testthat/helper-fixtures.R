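# Shared fixtures and independent oracles for the test suite.

.pop_cache <- new.env(parent = emptyenv())

# the default 171-neuron study-structure population, built once per run
default_population <- function() {
  if (is.null(.pop_cache$pop))
    .pop_cache$pop <- simulate_population(population_config(seed = 7),
                                          seed = 11)
  .pop_cache$pop
}

small_population <- function(n_neurons = 30, profile_seed = 7,
                             spike_seed = 11, ...) {
  simulate_population(population_config(n_neurons = n_neurons,
                                        seed = profile_seed, ...),
                      seed = spike_seed)
}

# hand-built spike_train_set from an explicit spike table
manual_set <- function(df, n_trials, n_stim = max(df$stimulus),
                       record_span = c(-300, 1200), neurons = NULL) {
  spike_train_set(df,
                  stimuli = stimulus_set(frequency = 1000 * 2^(seq_len(n_stim) - 1)),
                  n_trials = n_trials, record_span = record_span,
                  neurons = neurons)
}

# homogeneous-Poisson spike table: one row per spike, rate in spikes/s
poisson_spike_table <- function(neuron, stimulus, trials, rate, span) {
  len_s <- diff(span) / 1000
  out <- list()
  for (tr in trials) {
    k <- rpois(1, rate * len_s)
    if (k > 0)
      out[[length(out) + 1L]] <- data.frame(
        neuron = neuron, stimulus = stimulus, trial = tr,
        time = sort(runif(k, span[1], span[2])))
  }
  if (!length(out))
    return(data.frame(neuron = integer(0), stimulus = integer(0),
                      trial = integer(0), time = numeric(0)))
  do.call(rbind, out)
}

# independent brute-force nearest-mean-template classifier (Euclidean);
# deliberately written as plain loops, sharing no code with the package
oracle_nearest_template <- function(xtr, ytr, xte) {
  classes <- sort(unique(ytr))
  templates <- list()
  for (cl in classes)
    templates[[as.character(cl)]] <- colMeans(xtr[ytr == cl, , drop = FALSE])
  preds <- numeric(nrow(xte))
  for (i in seq_len(nrow(xte))) {
    best <- Inf
    bestc <- NA
    for (cl in classes) {
      d <- sqrt(sum((templates[[as.character(cl)]] - xte[i, ])^2))
      if (d < best - 1e-12) {
        best <- d
        bestc <- cl
      }
    }
    preds[i] <- bestc
  }
  preds
}

# analytic entropy (bits) of a Poisson(lambda) distribution by direct summation
poisson_entropy_bits <- function(lambda, kmax = 200) {
  p <- dpois(0:kmax, lambda)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# well-separated 6-class Gaussian response fixture
separable_responses <- function(n_classes = 6, n_trials = 20, n_dims = 10,
                                sep = 50, noise = 1, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(n_classes * n_dims), n_classes) * sep
  x <- centers[rep(seq_len(n_classes), each = n_trials), ] +
    matrix(rnorm(n_classes * n_trials * n_dims, 0, noise),
           n_classes * n_trials)
  list(x = x, y = rep(seq_len(n_classes), each = n_trials),
       trial = rep(seq_len(n_trials), times = n_classes))
}
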