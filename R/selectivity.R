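#' Poisson conditional test for a rate increase
#'
#' One-sided exact test of H0: `rate_test <= rate_ref` for two Poisson counts
#' observed over known exposures. Conditioning on the total count
#' `n = count_test + count_ref`, the test count is Binomial(n, e) with
#' `e = exposure_test / (exposure_test + exposure_ref)` under H0 at equality;
#' the p-value is `P(X >= count_test)`. All arguments are vectorised.
#'
#' @param count_test,count_ref Non-negative integer spike counts.
#' @param exposure_test,exposure_ref Positive exposures in seconds
#'   (window length x number of pooled trials).
#' @return One-sided p-value(s) in `[0, 1]`; `1` when both counts are zero.
#' @examples
#' poisson_conditional_test(10, 1, 0, 1) # 0.5^10
#' @export
poisson_conditional_test <- function(count_test, exposure_test,
                                     count_ref, exposure_ref) {
  if (any(exposure_test <= 0) || any(exposure_ref <= 0))
    stop("exposures must be positive")
  if (any(count_test < 0) || any(count_ref < 0))
    stop("counts must be non-negative")
  n <- count_test + count_ref
  e <- exposure_test / (exposure_test + exposure_ref)
  pbinom(count_test - 1, n, e, lower.tail = FALSE)
}

#' Number of effective stimuli over time for one neuron
#'
#' Slides a test window through the recording and, at each position, counts
#' the stimuli whose spiking rate significantly exceeds the neuron's
#' spontaneous rate (Poisson conditional test, Bonferroni-corrected). The
#' spontaneous reference pools the neuron's spikes over all stimuli and
#' trials in the pre-onset baseline. The count of effective stimuli is
#' inversely related to selectivity.
#'
#' @param data A [spike_train_set()].
#' @param neuron Neuron id.
#' @param alpha Significance level after correction.
#' @param window_length Test window length in ms.
#' @param step Displacement between adjacent windows in ms.
#' @param family Bonferroni family: `"whole"` corrects over all tested
#'   windows x stimuli for the neuron; `"per_window"` over stimuli only.
#' @param baseline_span Pre-onset interval (ms) defining the spontaneous
#'   reference.
#' @return An object of class `selectivity_profile`: a list with `neuron`,
#'   `time` (window start, ms), `effective_count` (integer per window),
#'   `window_length`, `alpha`, `family`.
#' @export
effective_stimulus_profile <- function(data, neuron, alpha = 0.05,
                                       window_length = 50, step = 1,
                                       family = c("whole", "per_window"),
                                       baseline_span = c(-300, 0)) {
  stopifnot(inherits(data, "spike_train_set"))
  family <- match.arg(family)
  ni <- match(neuron, data$neurons)
  if (is.na(ni)) stop("unknown neuron id: ", neuron)
  ns <- n_stimuli(data)
  sp <- data$spikes[data$spikes$neuron == ni, ]

  in_base <- sp$time >= baseline_span[1] & sp$time < baseline_span[2]
  count_ref <- sum(in_base)
  exposure_ref <- diff(baseline_span) / 1000 * data$n_trials * ns

  win <- sliding_windows(data$record_span, window_length, step)
  starts <- win$start
  nw <- length(starts)
  exposure_test <- window_length / 1000 * data$n_trials

  m <- if (family == "whole") nw * ns else ns
  eff <- integer(nw)
  for (s in seq_len(ns)) {
    tt <- sort(sp$time[sp$stimulus == s])
    cnt <- .n_below(starts + window_length, tt) - .n_below(starts, tt)
    p <- poisson_conditional_test(cnt, exposure_test, count_ref, exposure_ref)
    eff <- eff + as.integer(pmin(1, p * m) < alpha)
  }
  structure(list(neuron = neuron, time = starts, effective_count = eff,
                 window_length = window_length, alpha = alpha,
                 family = family),
            class = "selectivity_profile")
}

#' @export
print.selectivity_profile <- function(x, ...) {
  cat(sprintf("<selectivity_profile> neuron %s, %d windows of %g ms, max %d effective stimuli\n",
              format(x$neuron), length(x$time), x$window_length,
              max(x$effective_count)))
  invisible(x)
}

#' Selectivity profiles for many neurons
#'
#' @inheritParams effective_stimulus_profile
#' @param neurons Neuron ids; default all.
#' @return Named list of [effective_stimulus_profile()] results.
#' @export
selectivity_profiles <- function(data, neurons = data$neurons, ...) {
  out <- lapply(neurons, function(n)
    effective_stimulus_profile(data, n, ...))
  names(out) <- as.character(neurons)
  out
}

#' Select neurons with broad onset tuning that stays responsive
#'
#' Partitions the population using two criteria on each neuron's
#' effective-stimulus profile over the 500-ms sound: (1) the maximum number
#' of effective stimuli with window starts in the first 200 ms after onset
#' exceeds the maximum over the last 300 ms of the sound, and (2) the median
#' number over the last 300 ms is at least 1. Neurons satisfying both mimic
#' narrow-tuning neurons driven by finely spaced tones.
#'
#' @param profiles List of `selectivity_profile` objects
#'   (see [selectivity_profiles()]) covering at least `[0, 500]` ms.
#' @param sound_duration Sound duration in ms.
#' @return List with `subset` and `complement` vectors of neuron ids
#'   (disjoint, union = all profiled neurons).
#' @export
select_broad_tuning_subset <- function(profiles, sound_duration = 500) {
  onset_max <- function(p) {
    i <- p$time >= 0 & p$time < 200
    if (!any(i)) stop("profile does not cover the onset epoch")
    max(p$effective_count[i])
  }
  late <- function(p) {
    i <- p$time >= sound_duration - 300 &
      p$time <= sound_duration - p$window_length
    if (!any(i)) stop("profile does not cover the late sound epoch")
    p$effective_count[i]
  }
  keep <- vapply(profiles, function(p) {
    lt <- late(p)
    onset_max(p) > max(lt) && median(lt) >= 1
  }, logical(1))
  ids <- vapply(profiles, function(p) p$neuron, profiles[[1]]$neuron)
  list(subset = ids[keep], complement = ids[!keep])
}
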