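#' Decoding accuracy as a function of window position
#'
#' Runs cross-validated population decoding in fixed-length windows slid
#' through the recording.
#'
#' @param data A [spike_train_set()].
#' @param methods Decoder methods to evaluate.
#' @param window_length Window length in ms.
#' @param step Displacement between adjacent window starts in ms.
#' @param span Interval to cover, `c(t0, t1)`; default the record span.
#' @param n_folds Cross-validation folds.
#' @return An accuracy curve: data frame with columns `x` (window start,
#'   ms), `method`, `accuracy`, plus columns `window_length`; attribute
#'   `x_type = "start"`.
#' @export
accuracy_timecourse <- function(data, methods = c("LDA", "TMPEUC", "TMPCOS"),
                                window_length = 15, step = 5, span = NULL,
                                n_folds = 4) {
  stopifnot(inherits(data, "spike_train_set"))
  if (is.null(span)) span <- data$record_span
  win <- sliding_windows(span, window_length, step)
  out <- lapply(seq_len(nrow(win)), function(w) {
    pr <- population_response(data, time_window(win$start[w], window_length))
    data.frame(x = win$start[w], method = methods,
               accuracy = vapply(methods, function(m)
                 decode_cv(pr$rates, pr$stimulus, pr$trial, m,
                           n_folds)$accuracy, numeric(1)),
               window_length = window_length)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, x_type = "start")
}

#' Decoding accuracy as a function of window length
#'
#' Windows share a fixed beginning time and are extended rightward to each
#' requested length.
#'
#' @inheritParams accuracy_timecourse
#' @param start Common window start in ms.
#' @param lengths Window lengths in ms (e.g. `seq(2, 150, by = 2)`).
#' @return Accuracy curve with `x` = window length (ms); attribute
#'   `x_type = "length"`.
#' @export
accuracy_vs_length <- function(data, methods = c("LDA", "TMPEUC", "TMPCOS"),
                               start, lengths, n_folds = 4) {
  stopifnot(inherits(data, "spike_train_set"))
  if (start + max(lengths) > data$record_span[2])
    stop("longest window exceeds the record span")
  out <- lapply(lengths, function(len) {
    pr <- population_response(data, time_window(start, len))
    data.frame(x = len, method = methods,
               accuracy = vapply(methods, function(m)
                 decode_cv(pr$rates, pr$stimulus, pr$trial, m,
                           n_folds)$accuracy, numeric(1)),
               window_start = start)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, x_type = "length")
}

#' Saturation accuracy of a window-length sweep
#'
#' The arithmetic mean of the accuracies at all tested window lengths
#' falling in `range` (inclusive), per decoder method.
#'
#' @param curve Result of [accuracy_vs_length()].
#' @param range Length interval in ms over which accuracy is averaged.
#' @return Named numeric vector, one saturation accuracy per method.
#' @export
saturation_accuracy <- function(curve, range = c(150, 200)) {
  sel <- curve$x >= range[1] & curve$x <= range[2]
  if (!any(sel))
    stop("curve has no window lengths inside [", range[1], ", ", range[2], "] ms")
  vapply(split(curve$accuracy[sel], curve$method[sel]), mean, numeric(1))
}

#' Minimum window length reaching a fraction of saturation accuracy
#'
#' @param curve Result of [accuracy_vs_length()] for a single method (or
#'   subset the data frame by method first).
#' @param saturation Saturation accuracy (scalar, `> 0`).
#' @param frac Required fraction of saturation.
#' @return Smallest tested length (ms) whose accuracy is
#'   `>= frac * saturation`, or `NA` (with a message) when never reached.
#' @export
minimum_window_length <- function(curve, saturation, frac = 0.8) {
  stopifnot(saturation > 0)
  if (length(unique(curve$method)) > 1)
    stop("subset the curve to a single method first")
  ok <- curve$accuracy >= frac * saturation
  if (!any(ok)) {
    message("accuracy never reaches ", frac, " x saturation")
    return(NA_real_)
  }
  min(curve$x[ok])
}

#' Decoding accuracy in constant-spike-count windows over time
#'
#' For each left edge, the read-out window is grown rightward until it holds
#' `target` pooled spikes (see [spike_count_window()]), and cross-validated
#' decoding is run in that window. Under the constant spike count
#' hypothesis these curves are flat during the stimulus while fixed-length
#' windows track the population rate.
#'
#' @inheritParams accuracy_timecourse
#' @param targets Pooled spike-count targets (one curve per target).
#' @param edges Left edges in ms; default every `step` ms from sound onset
#'   to 450 ms.
#' @return Data frame with columns `x` (left edge, ms), `target`, `method`,
#'   `accuracy`, `window_length` (the grown length, ms).
#' @export
constant_spike_count_timecourse <- function(data, targets,
                                            methods = c("LDA", "TMPEUC", "TMPCOS"),
                                            step = 5, edges = NULL,
                                            n_folds = 4) {
  stopifnot(inherits(data, "spike_train_set"))
  if (is.null(edges)) edges <- seq(0, 450, by = step)
  out <- list()
  for (tg in targets) {
    for (e in edges) {
      w <- tryCatch(spike_count_window(data, e, tg),
                    popcode_insufficient_spikes = function(cond) {
                      stop("cannot reach ", tg, " pooled spikes at left edge ",
                           e, " ms: ", conditionMessage(cond), call. = FALSE)
                    })
      pr <- population_response(data, w)
      out[[length(out) + 1L]] <- data.frame(
        x = e, target = tg, method = methods,
        accuracy = vapply(methods, function(m)
          decode_cv(pr$rates, pr$stimulus, pr$trial, m, n_folds)$accuracy,
          numeric(1)),
        window_length = w$length)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, x_type = "start")
}

#' Self-normalise an accuracy time course
#'
#' Divides the accuracies by their standard deviation over the interval from
#' 200 ms before to 100 ms after sound onset, then subtracts an offset so
#' the mean over the 200 ms before onset is exactly zero. Puts curves from
#' experiments with different chance levels on a common scale; the result is
#' invariant under affine transforms of the input.
#'
#' @param curve An accuracy curve over window starts covering
#'   `[-200, 100]` ms, single method.
#' @return The curve with `accuracy` replaced by its normalised value.
#' @export
normalize_accuracy_curve <- function(curve) {
  if (length(unique(curve$method)) > 1)
    stop("subset the curve to a single method first")
  ref <- curve$x >= -200 & curve$x <= 100
  base <- curve$x >= -200 & curve$x < 0
  if (!any(ref) || !any(base))
    stop("curve must cover [-200, 100] ms around sound onset")
  s <- sd(curve$accuracy[ref])
  if (s == 0) stop("zero accuracy variance in the normalisation interval")
  y <- curve$accuracy / s
  curve$accuracy <- y - mean(y[base])
  curve
}
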