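#' Configure a synthetic tone-responsive population
#'
#' Parameters of the inhomogeneous-Poisson population generator. The default
#' configuration mirrors the structure of the study population this package
#' was designed around: 171 neurons, six 500-ms tones from 1 to 32 kHz spaced
#' one octave apart at 85 dB SPL, 20 trials each, recorded from 300 ms before
#' onset to 700 ms after offset. Each neuron has a best frequency (assigned
#' log-uniformly over the stimulus range so that every tone drives part of
#' the population), Gaussian log-frequency tuning, a high onset transient
#' decaying exponentially to a sparser sustained rate, and -- in the default
#' `"differential"` adaptation mode -- tuning that narrows over the same time
#' constant, so that off-preferred responses decay back to spontaneous
#' activity and the population grows more selective as the response evolves.
#' The `"uniform"` mode keeps the tuning width fixed at `tuning_width_onset`
#' so that all responses adapt by a common factor instead.
#'
#' @param n_neurons Number of neurons.
#' @param stimuli A [stimulus_set()].
#' @param n_trials Trials per (neuron, stimulus).
#' @param record_span Recorded interval in ms relative to sound onset.
#' @param spontaneous_range Range (spikes/s) of the per-neuron spontaneous
#'   rate, drawn uniformly.
#' @param onset_peak_rate Peak evoked rate at the best frequency (spikes/s),
#'   added to the spontaneous rate at the response latency.
#' @param sustained_rate Evoked rate at the best frequency (spikes/s) after
#'   adaptation has settled; must not exceed `onset_peak_rate`.
#' @param response_latency Latency from sound onset to response start (ms).
#' @param adaptation_tau Exponential adaptation time constant (ms).
#' @param tuning_width_onset,tuning_width_sustained Gaussian tuning SD in
#'   octaves at response start and after adaptation; the onset width must be
#'   at least the sustained width (broad early tuning that sharpens).
#' @param adaptation `"differential"` (tuning narrows over time) or
#'   `"uniform"` (fixed tuning, rates scale down together).
#' @param bf_jitter SD (octaves) of seeded jitter around the log-uniform
#'   best-frequency grid.
#' @param seed Seed used by [build_rate_profile()] for per-neuron draws.
#' @return An object of class `population_config`.
#' @export
population_config <- function(n_neurons = 171,
                              stimuli = stimulus_set(),
                              n_trials = 20,
                              record_span = c(-300, 1200),
                              spontaneous_range = c(1, 10),
                              onset_peak_rate = 150,
                              sustained_rate = 12,
                              response_latency = 20,
                              adaptation_tau = 60,
                              tuning_width_onset = 1.5,
                              tuning_width_sustained = 0.7,
                              adaptation = c("differential", "uniform"),
                              bf_jitter = 0.25,
                              seed = 1L) {
  adaptation <- match.arg(adaptation)
  stopifnot(n_neurons >= 1, n_trials >= 1,
            length(spontaneous_range) == 2,
            all(spontaneous_range >= 0), diff(spontaneous_range) >= 0)
  if (!(is.finite(onset_peak_rate) && is.finite(sustained_rate) &&
        onset_peak_rate >= sustained_rate && sustained_rate >= 0))
    stop("need onset_peak_rate >= sustained_rate >= 0, both finite")
  if (tuning_width_onset < tuning_width_sustained)
    stop("tuning_width_onset must be >= tuning_width_sustained")
  structure(
    list(n_neurons = as.integer(n_neurons), stimuli = stimuli,
         n_trials = as.integer(n_trials),
         record_span = as.numeric(record_span),
         spontaneous_range = spontaneous_range,
         onset_peak_rate = onset_peak_rate, sustained_rate = sustained_rate,
         response_latency = response_latency, adaptation_tau = adaptation_tau,
         tuning_width_onset = tuning_width_onset,
         tuning_width_sustained = tuning_width_sustained,
         adaptation = adaptation, bf_jitter = bf_jitter,
         seed = as.integer(seed)),
    class = "population_config")
}

#' Intended instantaneous rate profile of a configured population
#'
#' Evaluates, on a 1-ms grid over the record span, the intended rate
#' `r(neuron, stimulus, t) = spontaneous + G(d_oct; width(t)) * A(t)`, where
#' `d_oct = |log2(f_stim / f_best)|`, `G` is a Gaussian tuning factor, and
#' the drive `A(t)` is zero before `latency`, jumps to `onset_peak_rate` at
#' `latency`, decays exponentially with `adaptation_tau` towards
#' `sustained_rate`, and returns to zero at `duration + latency` (response
#' offset lags sound offset by the latency). In differential mode the width
#' interpolates from the onset to the sustained value with the same time
#' constant; in uniform mode it stays at the onset value.
#'
#' @param config A [population_config()].
#' @return An object of class `rate_profile`: a list with `rate` (array
#'   neurons x stimuli x time bins, spikes/s; bin `i` covers `[t_i, t_i+1)`),
#'   `t` (bin left edges, ms), `spontaneous`, `best_frequency`, `config`.
#' @export
build_rate_profile <- function(config) {
  stopifnot(inherits(config, "population_config"))
  set.seed(config$seed)
  fr <- config$stimuli$frequency
  lf <- log2(fr)
  bf_grid <- seq(min(lf), max(lf), length.out = config$n_neurons)
  bf <- bf_grid + rnorm(config$n_neurons, 0, config$bf_jitter)
  spont <- runif(config$n_neurons, config$spontaneous_range[1],
                 config$spontaneous_range[2])

  t0 <- config$record_span[1]
  t1 <- config$record_span[2]
  tt <- seq(t0, t1 - 1)                      # 1-ms bin left edges
  nt <- length(tt)
  lat <- config$response_latency
  dur <- config$stimuli$duration
  tau <- config$adaptation_tau

  drive <- numeric(nt)
  on <- tt >= lat & tt < dur + lat
  drive[on] <- config$sustained_rate +
    (config$onset_peak_rate - config$sustained_rate) *
    exp(-(tt[on] - lat) / tau)
  width <- rep(config$tuning_width_onset, nt)
  if (config$adaptation == "differential") {
    width[on] <- config$tuning_width_sustained +
      (config$tuning_width_onset - config$tuning_width_sustained) *
      exp(-(tt[on] - lat) / tau)
  }

  ns <- length(fr)
  rate <- array(0, dim = c(config$n_neurons, ns, nt))
  doct <- abs(outer(bf, lf, "-"))            # neurons x stimuli, octaves
  for (k in seq_len(nt)) {
    if (drive[k] > 0) {
      g <- exp(-doct^2 / (2 * width[k]^2))
      rate[, , k] <- spont + g * drive[k]
    } else {
      rate[, , k] <- spont
    }
  }
  structure(list(rate = rate, t = tt, spontaneous = spont,
                 best_frequency = 2^bf, config = config),
            class = "rate_profile")
}

#' Draw spike trains from a rate profile
#'
#' Samples an inhomogeneous Poisson process by per-ms binning: each 1-ms bin
#' contributes a Poisson count with mean `rate / 1000` and spike times are
#' jittered uniformly within the bin. Expected counts therefore match the
#' profile exactly in every window aligned to the ms grid.
#'
#' @param profile A [build_rate_profile()] result.
#' @param n_trials Trials per (neuron, stimulus); defaults to the config.
#' @param seed Integer seed; identical profile + seed reproduces the draw.
#' @return A [spike_train_set()].
#' @export
sample_spike_trains <- function(profile, n_trials = NULL, seed = 1L) {
  stopifnot(inherits(profile, "rate_profile"))
  cfg <- profile$config
  if (is.null(n_trials)) n_trials <- cfg$n_trials
  set.seed(seed)
  ns <- dim(profile$rate)[2]
  nt <- dim(profile$rate)[3]
  out <- vector("list", cfg$n_neurons)
  for (n in seq_len(cfg$n_neurons)) {
    lam <- matrix(profile$rate[n, , ], nrow = ns)   # stimuli x time
    lam_rep <- rep(as.vector(t(lam)) / 1000, times = n_trials)
    counts <- rpois(length(lam_rep), lam_rep)
    pos <- which(counts > 0L)
    if (!length(pos)) next
    k <- counts[pos]
    bin <- (pos - 1L) %% nt + 1L
    stim <- ((pos - 1L) %/% nt) %% ns + 1L
    trial <- (pos - 1L) %/% (nt * ns) + 1L
    times <- rep(profile$t[bin], k) + runif(sum(k))
    out[[n]] <- data.frame(neuron = n, stimulus = rep(stim, k),
                           trial = rep(trial, k), time = times)
  }
  spikes <- do.call(rbind, out)
  if (is.null(spikes))
    spikes <- data.frame(neuron = integer(0), stimulus = integer(0),
                         trial = integer(0), time = numeric(0))
  spike_train_set(spikes, cfg$stimuli, n_trials,
                  record_span = cfg$record_span,
                  neurons = seq_len(cfg$n_neurons))
}

#' Simulate a population in one call
#'
#' Convenience wrapper: builds the rate profile from `config` (using
#' `config$seed` for the per-neuron draws) and samples spike trains with
#' `seed` for the Poisson draws.
#'
#' @param config A [population_config()].
#' @param seed Seed for the spike draws.
#' @return A [spike_train_set()].
#' @export
simulate_population <- function(config = population_config(), seed = 1L) {
  sample_spike_trains(build_rate_profile(config), seed = seed)
}

#' Poisson spike-count simulation from base rates
#'
#' Draws trial spike counts for every (neuron, stimulus) cell from a Poisson
#' distribution with mean `k_r * r * k_T * T`, where `r` are base rates in
#' spikes/s, `T` is the read-out window length in seconds and `k_r`, `k_T`
#' uniformly scale the rates and the window. Used for the uniform-adaptation
#' experiments, where `k_T = 1/k_r` keeps the expected count constant.
#'
#' @param base_rates Numeric matrix (neurons x stimuli) of rates, spikes/s.
#' @param k_r Rate scaling factor, `> 0`.
#' @param k_T Window scaling factor, `> 0`.
#' @param T Window length in seconds, `> 0`.
#' @param n_trials Trials to draw per cell.
#' @param seed Optional seed.
#' @return Integer array (neurons x stimuli x trials) of simulated counts.
#' @export
simulate_count_population <- function(base_rates, k_r = 1, k_T = 1, T,
                                      n_trials = 20, seed = NULL) {
  base_rates <- as.matrix(base_rates)
  if (any(base_rates < 0)) stop("base rates must be non-negative")
  stopifnot(k_r > 0, k_T > 0, T > 0, n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  mu <- k_r * base_rates * k_T * T
  counts <- rpois(length(mu) * n_trials, rep(as.vector(mu), times = n_trials))
  array(counts, dim = c(nrow(base_rates), ncol(base_rates), n_trials))
}
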