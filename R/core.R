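#' Define a pure-tone stimulus set
#'
#' Describes the tones used in one experiment: frequencies (strictly
#' increasing), a common sound level, duration and on/off ramp. Stimulus
#' onset defines time zero throughout the package.
#'
#' @param frequency Tone frequencies in Hz, strictly increasing. Default: six
#'   tones from 1 to 32 kHz spaced one octave apart.
#' @param level Sound level in dB SPL, shared by all tones.
#' @param duration Tone duration in ms, shared by all tones.
#' @param ramp Linear on/off ramp duration in ms.
#' @return An object of class `stimulus_set`.
#' @examples
#' stim <- stimulus_set()
#' n_stimuli(stim)
#' @export
stimulus_set <- function(frequency = 1000 * 2^(0:5), level = 85,
                         duration = 500, ramp = 5) {
  if (length(frequency) < 1 || any(!is.finite(frequency)) || any(frequency <= 0))
    stop("'frequency' must be positive and finite")
  if (is.unsorted(frequency, strictly = TRUE))
    stop("'frequency' must be strictly increasing")
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0)
    stop("'duration' must be a single positive number (ms)")
  structure(
    list(frequency = as.numeric(frequency), level = level,
         duration = duration, ramp = ramp, onset_time = 0),
    class = "stimulus_set")
}

#' @rdname stimulus_set
#' @param x A `stimulus_set` or an object carrying one.
#' @export
n_stimuli <- function(x) {
  if (inherits(x, "spike_train_set")) x <- x$stimuli
  length(x$frequency)
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set> %d tones, %.3g-%.3g kHz, %g ms at %g dB SPL\n",
              length(x$frequency), min(x$frequency) / 1000,
              max(x$frequency) / 1000, x$duration, x$level))
  invisible(x)
}

#' Create a read-out window
#'
#' A window is the half-open interval `[start, start + length)` in ms. The
#' half-open convention makes adjacent windows partition time exactly.
#'
#' @param start Window start in ms relative to sound onset.
#' @param length Window length in ms, strictly positive.
#' @return An object of class `time_window` with fields `start` and `length`.
#' @export
time_window <- function(start, length) {
  if (!is.numeric(start) || length(start) != 1 || !is.finite(start))
    stop("'start' must be a single finite number (ms)")
  if (!is.numeric(length) || length(length) != 1 || !is.finite(length) ||
      length <= 0)
    stop("window 'length' must be a single positive number (ms)")
  structure(list(start = as.numeric(start), length = as.numeric(length)),
            class = "time_window")
}

#' @export
print.time_window <- function(x, ...) {
  cat(sprintf("<time_window> [%g, %g) ms (length %g ms)\n",
              x$start, x$start + x$length, x$length))
  invisible(x)
}

#' Trial-aligned spike-train container
#'
#' Holds sorted spike times (ms relative to sound onset) for every
#' (neuron, stimulus, trial) combination of one experiment. Every
#' (neuron, stimulus) pair must have exactly `n_trials` trials and all spike
#' times must fall inside `record_span`.
#'
#' @param spikes A data frame with columns `neuron`, `stimulus`, `trial`,
#'   `time`: `neuron` is an id in `neurons`, `stimulus` a 1-based index into
#'   `stimuli`, `trial` a 1-based trial number in `1:n_trials`, `time` the
#'   spike time in ms. Rows for silent trials may simply be absent.
#' @param stimuli A [stimulus_set()].
#' @param n_trials Number of trials per (neuron, stimulus) pair.
#' @param record_span Recorded interval `c(t_min, t_max)` in ms; the default
#'   spans 300 ms before onset to 700 ms after a 500-ms tone's offset.
#' @param neurons Vector of neuron ids; defaults to those present in `spikes`.
#' @return An object of class `spike_train_set`.
#' @seealso [simulate_population()], [read_spike_data()]
#' @export
spike_train_set <- function(spikes, stimuli, n_trials,
                            record_span = c(-300, 1200), neurons = NULL) {
  stopifnot(is.data.frame(spikes))
  need <- c("neuron", "stimulus", "trial", "time")
  miss <- setdiff(need, names(spikes))
  if (length(miss))
    stop("'spikes' is missing column(s): ", paste(miss, collapse = ", "))
  if (!inherits(stimuli, "stimulus_set")) stop("'stimuli' must be a stimulus_set")
  n_trials <- as.integer(n_trials)
  if (n_trials < 1) stop("'n_trials' must be >= 1")
  if (length(record_span) != 2 || diff(record_span) <= 0)
    stop("'record_span' must be c(t_min, t_max) with t_max > t_min")

  if (is.null(neurons)) neurons <- sort(unique(spikes$neuron))
  ns <- n_stimuli(stimuli)

  ni <- match(spikes$neuron, neurons)
  if (anyNA(ni)) stop("spike rows reference neurons not in 'neurons'")
  si <- as.integer(spikes$stimulus)
  if (any(si < 1 | si > ns)) stop("'stimulus' indices must be in 1..", ns)
  ti <- as.integer(spikes$trial)
  if (any(ti < 1 | ti > n_trials)) stop("'trial' must be in 1..", n_trials)
  tm <- as.numeric(spikes$time)
  if (anyNA(tm)) stop("non-numeric spike time at row ", which(is.na(tm))[1])
  bad <- which(tm < record_span[1] | tm > record_span[2])
  if (length(bad))
    stop("spike time outside record_span at row ", bad[1],
         " (t = ", tm[bad[1]], " ms)")

  key <- ((ni - 1L) * ns + (si - 1L)) * n_trials + ti
  ord <- order(key, tm)
  structure(
    list(neurons = neurons, stimuli = stimuli, n_trials = n_trials,
         record_span = as.numeric(record_span),
         spikes = data.frame(neuron = ni[ord], stimulus = si[ord],
                             trial = ti[ord], time = tm[ord]),
         key = key[ord],
         sorted_times = sort(tm)),
    class = "spike_train_set")
}

#' @rdname spike_train_set
#' @param x A `spike_train_set`.
#' @export
n_neurons <- function(x) length(x$neurons)

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf(paste0("<spike_train_set> %d neurons x %d stimuli x %d trials, ",
                     "%d spikes, span [%g, %g] ms\n"),
              n_neurons(x), n_stimuli(x), x$n_trials, nrow(x$spikes),
              x$record_span[1], x$record_span[2]))
  invisible(x)
}

#' Retrieve one spike train
#'
#' @param data A [spike_train_set()].
#' @param neuron Neuron id (as in `data$neurons`).
#' @param stimulus 1-based stimulus index.
#' @param trial 1-based trial number.
#' @return Sorted numeric vector of spike times (ms).
#' @export
get_train <- function(data, neuron, stimulus, trial) {
  ni <- match(neuron, data$neurons)
  if (is.na(ni)) stop("unknown neuron id: ", neuron)
  ns <- n_stimuli(data)
  key <- ((ni - 1L) * ns + (as.integer(stimulus) - 1L)) * data$n_trials +
    as.integer(trial)
  data$spikes$time[data$key == key]
}

# number of elements of sorted vector tt strictly below x (vectorised over x)
.n_below <- function(x, tt) findInterval(x, tt, left.open = TRUE)

#' Count spikes inside a window
#'
#' Counts spike times `t` with `start <= t < start + length` (half-open
#' convention), so adjacent windows partition the spikes exactly.
#'
#' @param train Sorted numeric vector of spike times (ms).
#' @param window A [time_window()].
#' @return Integer spike count.
#' @examples
#' count_spikes(c(10, 20, 35), time_window(10, 15)) # 2
#' @export
count_spikes <- function(train, window) {
  stopifnot(inherits(window, "time_window"))
  if (!length(train)) return(0L)
  a <- window$start
  b <- window$start + window$length
  .n_below(b, train) - .n_below(a, train)
}

#' Spiking rate in a window
#'
#' @inheritParams count_spikes
#' @return Rate in spikes/s (`count / (length / 1000)`).
#' @export
rate_in_window <- function(train, window) {
  count_spikes(train, window) / (window$length / 1000)
}

#' Enumerate sliding windows over a span
#'
#' Window starts are `t0, t0 + step, ...` for as long as the window fits
#' inside the span (`start + length <= t1`).
#'
#' @param span `c(t0, t1)` in ms.
#' @param length Window length in ms.
#' @param step Displacement between adjacent window starts in ms.
#' @return Data frame with columns `start` and `length`; zero rows when the
#'   span is shorter than the window.
#' @examples
#' nrow(sliding_windows(c(0, 500), 15, 5)) # 98
#' @export
sliding_windows <- function(span, length, step) {
  stopifnot(length(span) == 2, step > 0, length > 0)
  if (diff(span) < length)
    return(data.frame(start = numeric(0), length = numeric(0)))
  starts <- seq(span[1], span[2] - length, by = step)
  data.frame(start = starts, length = length)
}

#' Grow a window to hold a target pooled spike count
#'
#' Starting from a fixed left edge the window is elongated rightward in 1-ms
#' increments until the pooled spike count -- the total number of spikes
#' across all neurons, all trials and all stimuli falling in the window --
#' reaches or exceeds `target_count`.
#'
#' @param data A [spike_train_set()].
#' @param left_edge Fixed window start in ms (inside the record span).
#' @param target_count Required pooled spike count, a positive integer.
#' @return A [time_window()] whose pooled count is `>= target_count`.
#'   Signals an error of class `popcode_insufficient_spikes` (carrying the
#'   achieved count in field `achieved`) when the target cannot be reached
#'   inside the record span.
#' @export
spike_count_window <- function(data, left_edge, target_count) {
  stopifnot(inherits(data, "spike_train_set"))
  target_count <- as.integer(target_count)
  if (target_count < 1) stop("'target_count' must be a positive integer")
  if (left_edge < data$record_span[1] || left_edge >= data$record_span[2])
    stop("'left_edge' must lie inside the record span")
  tt <- data$sorted_times
  tt <- tt[tt >= left_edge]
  fail <- function(achieved) {
    cond <- structure(
      class = c("popcode_insufficient_spikes", "error", "condition"),
      list(message = sprintf(
             "insufficient spikes after %g ms: achieved %d of target %d",
             left_edge, achieved, target_count),
           call = sys.call(-1), achieved = achieved))
    stop(cond)
  }
  if (length(tt) < target_count) fail(length(tt))
  len <- floor(tt[target_count] - left_edge) + 1
  if (left_edge + len > data$record_span[2])
    fail(.n_below(data$record_span[2], tt))
  time_window(left_edge, len)
}

#' Spike-count tensor for one window
#'
#' @param data A [spike_train_set()].
#' @param window A [time_window()].
#' @return Integer array of dimension (neurons, stimuli, trials) of spike
#'   counts in the window.
#' @export
count_tensor <- function(data, window) {
  stopifnot(inherits(data, "spike_train_set"), inherits(window, "time_window"))
  a <- window$start
  b <- window$start + window$length
  tm <- data$spikes$time
  sel <- tm >= a & tm < b
  nbin <- n_neurons(data) * n_stimuli(data) * data$n_trials
  counts <- tabulate(data$key[sel], nbins = nbin)
  # key = ((neuron-1)*S + (stim-1))*T + trial, so trial varies fastest
  array(counts, dim = c(data$n_trials, n_stimuli(data), n_neurons(data)),
        dimnames = NULL) |> aperm(c(3, 2, 1))
}

#' Single-trial population response vectors
#'
#' For each selected (stimulus, trial) pair, extracts one vector of
#' single-trial spiking rates (spikes/s) with one dimension per neuron --
#' the unit of work of the population decoders.
#'
#' @param data A [spike_train_set()].
#' @param window A [time_window()].
#' @param trials Trials to include (1-based); default all.
#' @return An object of class `population_response`: a list with `rates`
#'   (matrix, rows = trials nested in stimuli, cols = neurons), `stimulus`
#'   and `trial` label vectors, and the `window`.
#' @export
population_response <- function(data, window, trials = NULL) {
  cnt <- count_tensor(data, window)          # neuron x stim x trial
  if (is.null(trials)) trials <- seq_len(data$n_trials)
  cnt <- cnt[, , trials, drop = FALSE]
  ns <- n_stimuli(data)
  nt <- length(trials)
  # column-major flatten of (trial, stim, neuron) gives rows ordered
  # stimulus-major with trials nested: (s1,t1), (s1,t2), ..., (s2,t1), ...
  rates <- matrix(aperm(cnt, c(3, 2, 1)), nrow = ns * nt,
                  ncol = n_neurons(data))
  rates <- rates / (window$length / 1000)
  structure(
    list(rates = rates,
         stimulus = rep(seq_len(ns), each = nt),
         trial = rep(trials, times = ns),
         window = window),
    class = "population_response")
}

#' @export
print.population_response <- function(x, ...) {
  cat(sprintf("<population_response> %d trials x %d neurons, window [%g, %g) ms\n",
              nrow(x$rates), ncol(x$rates), x$window$start,
              x$window$start + x$window$length))
  invisible(x)
}
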