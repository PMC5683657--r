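#' Trial-averaged population response matrix for trajectory analysis
#'
#' Bins each neuron-stimulus pair's responses into nonoverlapping windows,
#' averages the rate across trials, and concatenates the stimuli along
#' columns: the result has one row per neuron and `n_stimuli * n_bins`
#' columns (with the default 171-neuron, 6-stimulus experiment and the
#' `[-30, 500]` ms span in 10-ms bins: 171 x 318). Each column is one time
#' point of one stimulus's mean population response.
#'
#' @param data A [spike_train_set()].
#' @param bin Bin length in ms.
#' @param span Interval `c(t0, t1)` in ms; its length must be a multiple of
#'   `bin`.
#' @return Numeric matrix (neurons x stimuli*bins, spikes/s) with attributes
#'   `bin_centers` (ms) and `stimulus` (column labels).
#' @export
build_trajectory_matrix <- function(data, bin = 10, span = c(-30, 500)) {
  stopifnot(inherits(data, "spike_train_set"))
  width <- diff(span)
  if (abs(width %% bin) > 1e-9)
    stop("span length (", width, " ms) is not a multiple of the bin (",
         bin, " ms)")
  n_bins <- as.integer(round(width / bin))
  starts <- span[1] + bin * (seq_len(n_bins) - 1)
  nn <- n_neurons(data)
  ns <- n_stimuli(data)
  mat <- matrix(0, nn, ns * n_bins)
  for (b in seq_len(n_bins)) {
    cnt <- count_tensor(data, time_window(starts[b], bin))
    mr <- apply(cnt, c(1, 2), mean) / (bin / 1000)    # neurons x stimuli
    mat[, (seq_len(ns) - 1) * n_bins + b] <- mr
  }
  structure(mat,
            bin_centers = rep(starts + bin / 2, times = ns),
            stimulus = rep(seq_len(ns), each = n_bins))
}

# centered moving average with a shrinking window at the sequence ends
.smooth_running <- function(x, k) {
  if (k <= 1) return(x)
  half <- (k - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Project population responses onto principal components
#'
#' PCA over the time-point columns of a trajectory matrix (each column is
#' one sample in neuron space, centred per neuron, unscaled since all
#' entries share units of spikes/s). The projections are split back into
#' per-stimulus trajectories and smoothed with a centred moving average
#' (shrinking at the sequence ends).
#'
#' @param mat Result of [build_trajectory_matrix()].
#' @param n_components Number of principal components to keep.
#' @param smooth Moving-average span in points; `1` disables smoothing.
#' @return An object of class `trajectory_set`: list with `points` (data
#'   frame: `stimulus`, `time`, `PC1..PCk`), `explained_variance` (full
#'   spectrum, fractions), `basis` (neurons x components), `n_components`.
#'   When fewer nonzero components exist than requested, the available ones
#'   are returned with a warning.
#' @export
project_trajectories <- function(mat, n_components = 3, smooth = 5) {
  stim <- attr(mat, "stimulus")
  tctr <- attr(mat, "bin_centers")
  if (is.null(stim) || is.null(tctr))
    stop("'mat' must come from build_trajectory_matrix()")
  pc <- prcomp(t(mat), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  share <- ev / sum(ev)
  nz <- sum(ev > max(ev) * 1e-12)
  k <- min(n_components, nz)
  if (k < n_components)
    warning("only ", k, " nonzero principal components available")
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (s in unique(stim)) {
    rows <- which(stim == s)
    for (j in seq_len(k))
      scores[rows, j] <- .smooth_running(scores[rows, j], smooth)
  }
  pts <- data.frame(stimulus = stim, time = tctr)
  for (j in seq_len(k)) pts[[paste0("PC", j)]] <- scores[, j]
  structure(list(points = pts, explained_variance = share,
                 basis = pc$rotation[, seq_len(k), drop = FALSE],
                 n_components = k),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d stimuli, %d points each, %d PCs (%.1f%% variance)\n",
              length(unique(x$points$stimulus)),
              sum(x$points$stimulus == x$points$stimulus[1]),
              x$n_components,
              100 * sum(x$explained_variance[seq_len(x$n_components)])))
  invisible(x)
}

#' Mean pairwise separation between stimulus trajectories
#'
#' Average over time of the mean pairwise Euclidean distance between the
#' per-stimulus trajectory points in PC space, within a time interval.
#' Quantifies whether stimulus responses are distinguishable in an epoch.
#'
#' @param traj A `trajectory_set`.
#' @param span Time interval `c(t0, t1)` in ms over bin centers.
#' @return Mean pairwise distance (spikes/s in PC coordinates).
#' @export
trajectory_separation <- function(traj, span) {
  pts <- traj$points
  sel <- pts$time >= span[1] & pts$time <= span[2]
  pts <- pts[sel, ]
  if (!nrow(pts)) stop("no trajectory points in the requested span")
  pcs <- as.matrix(pts[, grep("^PC", names(pts)), drop = FALSE])
  mean(vapply(split(seq_len(nrow(pts)), pts$time), function(rows) {
    if (length(rows) < 2) return(NA_real_)
    mean(dist(pcs[rows, , drop = FALSE]))
  }, numeric(1)), na.rm = TRUE)
}
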