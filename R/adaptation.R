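#' Derive base rates for the adaptation simulations
#'
#' Fixes the window start (default 30 ms after sound onset), grows the
#' window until it holds `target_count` pooled spikes (default 2,000 across
#' all neurons, trials and stimuli), and returns each (neuron, stimulus)
#' cell's mean spiking rate over trials in that window. These rates seed the
#' pure-Poisson count simulations.
#'
#' @param data A [spike_train_set()].
#' @param start Window start in ms.
#' @param target_count Pooled spike-count target.
#' @return List with `rates` (matrix neurons x stimuli, spikes/s) and
#'   `window` (the grown [time_window()]).
#' @export
derive_base_rates <- function(data, start = 30, target_count = 2000) {
  w <- spike_count_window(data, start, target_count)
  cnt <- count_tensor(data, w)
  rates <- apply(cnt, c(1, 2), mean) / (w$length / 1000)
  list(rates = rates, window = w)
}

#' Decoding accuracy of uniformly adapted Poisson populations
#'
#' Simulates, for each rate scaling factor `k_r`, a Poisson-spiking
#' population whose (neuron, stimulus) mean counts are
#' `k_r * r * k_T * T`, and decodes stimulus identity from the single-trial
#' count vectors with cross-validation. Under the `"reciprocal"` rule
#' `k_T = 1/k_r`, so expected counts -- and hence the entire count
#' distribution -- are identical at every `k_r`: decoding accuracy must stay
#' flat. Under the `"unity"` rule `k_T = 1`, so larger `k_r` means more
#' expected spikes and accuracy rises with the rate magnitude.
#'
#' @param base_rates Matrix (neurons x stimuli) of base rates, spikes/s;
#'   see [derive_base_rates()].
#' @param T Read-out window length in seconds.
#' @param k_r Rate scaling factors.
#' @param rule `"reciprocal"` (`k_T = 1/k_r`) or `"unity"` (`k_T = 1`).
#' @param n_trials Simulated trials per cell.
#' @param n_replicates Independent simulations per `k_r`, to furnish
#'   standard errors.
#' @param methods Decoder methods.
#' @param n_folds Cross-validation folds.
#' @param seed Seed for the whole experiment.
#' @return Data frame with columns `k_r`, `k_T`, `replicate`, `method`,
#'   `accuracy`.
#' @export
run_uniform_adaptation <- function(base_rates, T,
                                   k_r = seq(0.1, 1, by = 0.1),
                                   rule = c("reciprocal", "unity"),
                                   n_trials = 20, n_replicates = 20,
                                   methods = c("LDA", "TMPEUC", "TMPCOS"),
                                   n_folds = 4, seed = 1L) {
  rule <- match.arg(rule)
  base_rates <- as.matrix(base_rates)
  stopifnot(all(k_r > 0), T > 0)
  set.seed(seed)
  ns <- ncol(base_rates)
  out <- list()
  for (kr in k_r) {
    kT <- if (rule == "reciprocal") 1 / kr else 1
    for (rep_i in seq_len(n_replicates)) {
      cnt <- simulate_count_population(base_rates, k_r = kr, k_T = kT, T = T,
                                       n_trials = n_trials)
      x <- matrix(aperm(cnt, c(3, 2, 1)), nrow = ns * n_trials)
      y <- rep(seq_len(ns), each = n_trials)
      trial <- rep(seq_len(n_trials), times = ns)
      out[[length(out) + 1L]] <- data.frame(
        k_r = kr, k_T = kT, replicate = rep_i, method = methods,
        accuracy = vapply(methods, function(m)
          decode_cv(x, y, trial, m, n_folds)$accuracy, numeric(1)))
    }
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}
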