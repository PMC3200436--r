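# Epoched sensor data container.

#' Construct epoched sensor data
#'
#' @param data numeric array (trials x channels x samples); Tesla for MEG,
#'   Volt for EEG.
#' @param fs sampling rate in Hz.
#' @param time_ms numeric vector of sample times in ms (uniform spacing
#'   `1000 / fs`).
#' @param trials `trial_table` (or data.frame) with one row per trial.
#' @param layout a `sensor_layout`.
#' @param artifacts optional list recording injected artifact metadata.
#' @param provenance optional list of processing records.
#' @return object of class `epoched_data`.
#' @export
epoched_data <- function(data, fs, time_ms, trials, layout,
                         artifacts = list(), provenance = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  d <- dim(data)
  if (nrow(trials) != d[1]) stop_("trial metadata (%d rows) does not match %d trials",
                                  nrow(trials), d[1])
  if (length(layout$channel_ids) != d[2]) {
    stop_("layout has %d channels but data has %d", length(layout$channel_ids), d[2])
  }
  if (length(time_ms) != d[3]) stop_("time axis length != number of samples")
  dt <- diff(time_ms)
  if (any(dt <= 0) || max(abs(dt - 1000 / fs)) > 1e-6) {
    stop_("time axis must increase uniformly with spacing 1000/fs")
  }
  out <- list(data = data, fs = fs, time_ms = as.numeric(time_ms),
              trials = trials, layout = layout, artifacts = artifacts,
              provenance = provenance)
  class(out) <- "epoched_data"
  out
}

#' @export
print.epoched_data <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Epoched data: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  time: %.1f .. %.1f ms; %d processing steps recorded\n",
              x$time_ms[1], x$time_ms[length(x$time_ms)], length(x$provenance)))
  invisible(x)
}

#' Epoch time axis for a sampling rate
#'
#' Samples satisfying `t_start <= t < t_end` (half-open on the right) on the
#' grid `t_start + k * 1000/fs`.
#'
#' @param fs sampling rate (Hz).
#' @param t_start,t_end window in ms.
#' @return numeric vector of sample times (ms).
#' @export
epoch_time_axis <- function(fs, t_start = -160, t_end = 700) {
  dt <- 1000 / fs
  n <- ceiling((t_end - t_start) / dt - 1e-9)
  t_start + (seq_len(n) - 1) * dt
}

#' Select a subset of trials
#'
#' @param epochs `epoched_data`.
#' @param idx integer or logical trial index.
#' @return `epoched_data` with the selected trials and aligned metadata.
#' @export
subset_trials <- function(epochs, idx) {
  stopifnot(inherits(epochs, "epoched_data"))
  epochs$data <- epochs$data[idx, , , drop = FALSE]
  epochs$trials <- epochs$trials[idx, , drop = FALSE]
  epochs
}
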