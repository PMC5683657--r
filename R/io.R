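#' Read and write trial-aligned spike data
#'
#' The on-disk format is a long-form CSV with header
#' `neuron_id,stimulus_id,trial,spike_time_ms` (stimulus and trial ids
#' 0-based, one row per spike, times in ms to 0.001-ms precision) plus a JSON
#' manifest carrying the stimulus metadata, the neuron id list, the trial
#' count and the record span. A write followed by a read reproduces the
#' spike-train set exactly (times to 0.001 ms).
#'
#' @param data A [spike_train_set()].
#' @param path Path of the CSV file; the manifest defaults to the same path
#'   with extension `.json`.
#' @param manifest Path of the JSON manifest.
#' @return `write_spike_data()` returns `path` invisibly; `read_spike_data()`
#'   returns a [spike_train_set()].
#' @export
write_spike_data <- function(data, path,
                             manifest = paste0(tools::file_path_sans_ext(path),
                                               ".json")) {
  stopifnot(inherits(data, "spike_train_set"))
  df <- data.frame(
    neuron_id = data$neurons[data$spikes$neuron],
    stimulus_id = data$spikes$stimulus - 1L,
    trial = data$spikes$trial - 1L,
    spike_time_ms = sprintf("%.3f", data$spikes$time))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(
    neurons = data$neurons,
    n_trials = data$n_trials,
    record_span = data$record_span,
    stimuli = list(frequency = data$stimuli$frequency,
                   level = data$stimuli$level,
                   duration = data$stimuli$duration,
                   ramp = data$stimuli$ramp))
  jsonlite::write_json(meta, manifest, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spike_data
#' @export
read_spike_data <- function(path,
                            manifest = paste0(tools::file_path_sans_ext(path),
                                              ".json")) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(manifest)) stop("no such manifest: ", manifest)
  meta <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  for (f in c("neurons", "n_trials", "record_span", "stimuli"))
    if (is.null(meta[[f]])) stop("manifest is missing field '", f, "'")
  df <- read.csv(path)
  need <- c("neuron_id", "stimulus_id", "trial", "spike_time_ms")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("CSV is missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$spike_time_ms))
  if (length(bad))
    stop("malformed spike_time_ms at data row ", bad[1])
  # spike times must be sorted within each consecutive trial block
  same <- df$neuron_id[-1] == df$neuron_id[-nrow(df)] &
    df$stimulus_id[-1] == df$stimulus_id[-nrow(df)] &
    df$trial[-1] == df$trial[-nrow(df)]
  dec <- which(same & diff(df$spike_time_ms) < 0)
  if (length(dec))
    stop("unsorted spike times within a trial at data row ", dec[1] + 1L)
  spike_train_set(
    data.frame(neuron = df$neuron_id,
               stimulus = as.integer(df$stimulus_id) + 1L,
               trial = as.integer(df$trial) + 1L,
               time = as.numeric(df$spike_time_ms)),
    stimuli = stimulus_set(frequency = meta$stimuli$frequency,
                           level = meta$stimuli$level,
                           duration = meta$stimuli$duration,
                           ramp = meta$stimuli$ramp),
    n_trials = meta$n_trials,
    record_span = meta$record_span,
    neurons = meta$neurons)
}
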