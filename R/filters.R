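# Zero-phase Butterworth filtering and resampling of epoched data.
#
# Filtering is applied forward-backward (zero phase) with odd-reflection
# padding at the epoch edges; the IIR recursion runs in compiled code over
# all trial-channel series at once.

# Butterworth design via the signal package; a normalized to a[1] = 1.
butter_coef <- function(order, cutoff_hz, fs, type) {
  w <- cutoff_hz / (fs / 2)
  if (any(w <= 0) || any(w >= 1)) {
    stop_("cutoff %s Hz outside (0, fs/2) for fs = %g",
          paste(cutoff_hz, collapse = "-"), fs)
  }
  flt <- signal::butter(order, w, type)
  list(b = flt$b / flt$a[1], a = flt$a / flt$a[1])
}

# steady-state initial filter states for a unit constant input (direct form
# II transposed); multiplied by the first sample this removes the step
# transient of zero initial conditions
filter_zi <- function(coef) {
  b <- coef$b; a <- coef$a
  nz <- max(length(b), length(a)) - 1L
  bb <- c(b, rep(0, nz + 1L - length(b)))
  aa <- c(a, rep(0, nz + 1L - length(a)))
  companion <- rbind(-aa[-1], cbind(diag(1, nz - 1L), 0))
  rhs <- bb[-1] - aa[-1] * bb[1]
  solve(diag(nz) - t(companion), rhs)
}

# reflection padding length, as in common forward-backward implementations
filter_pad <- function(coef, n) {
  as.integer(min(n - 1, 3 * max(length(coef$b), length(coef$a))))
}

# zero-phase filtering of a (samples x series) matrix: odd-reflection
# padding plus steady-state initial conditions, forward and backward
zerophase_filter <- function(x, coef, pad = filter_pad(coef, nrow(x))) {
  zerophase_filter_cols(x, coef$b, coef$a, filter_zi(coef),
                        as.integer(min(pad, nrow(x) - 1L)))
}

# apply a zero-phase filter cascade along the sample axis of an epoched
# array, chunked over trials to bound memory
filter_epochs_array <- function(data, coefs) {
  d <- dim(data)
  chunk <- max(1L, floor(4e6 / (d[2] * d[3])) * 4L)
  for (i0 in seq(1L, d[1], by = chunk)) {
    idx <- i0:min(d[1], i0 + chunk - 1L)
    m <- aperm(data[idx, , , drop = FALSE], c(3, 1, 2))
    dim(m) <- c(d[3], length(idx) * d[2])
    for (coef in coefs) m <- zerophase_filter(m, coef)
    dim(m) <- c(d[3], length(idx), d[2])
    data[idx, , ] <- aperm(m, c(2, 3, 1))
  }
  data
}

# fused resample + band-pass over an epoched array: one pass through the
# trial chunks, keeping each chunk in (samples x series) form throughout
resample_bandpass_array <- function(data, time_ms, fs, fs_new, band, order = 4L) {
  d <- dim(data)
  do_resample <- !is.null(fs_new) && fs_new < fs
  if (do_resample) {
    coef_aa <- butter_coef(8L, 0.45 * fs_new, fs, "low")
    dt_new <- 1000 / fs_new
    m_new <- floor((time_ms[d[3]] - time_ms[1]) / dt_new + 1e-9) + 1
    t_new <- time_ms[1] + (seq_len(m_new) - 1) * dt_new
    pos <- (t_new - time_ms[1]) / (1000 / fs) + 1
    i0 <- pmin(floor(pos), d[3] - 1)
    wgt <- pos - i0
    fs2 <- fs_new
  } else {
    t_new <- time_ms
    fs2 <- fs
    m_new <- d[3]
  }
  coefs2 <- list(butter_coef(order, band[2], fs2, "low"))
  if (band[1] > 0) {
    coefs2 <- c(list(butter_coef(order, band[1], fs2, "high")), coefs2)
  }
  out <- array(0, c(d[1], d[2], m_new))
  chunk <- max(1L, floor(4e6 / (d[2] * d[3])) * 4L)
  for (c0 in seq(1L, d[1], by = chunk)) {
    idx <- c0:min(d[1], c0 + chunk - 1L)
    m <- aperm(data[idx, , , drop = FALSE], c(3, 1, 2))
    dim(m) <- c(d[3], length(idx) * d[2])
    if (do_resample) {
      m <- zerophase_filter(m, coef_aa)
      m <- (1 - wgt) * m[i0, , drop = FALSE] + wgt * m[i0 + 1, , drop = FALSE]
    }
    for (coef in coefs2) m <- zerophase_filter(m, coef)
    dim(m) <- c(m_new, length(idx), d[2])
    out[idx, , ] <- aperm(m, c(2, 3, 1))
  }
  list(data = out, time_ms = t_new, fs = fs2)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a forward-backward (zero-phase) Butterworth filter per channel.
#' The band-pass is realized as a high-pass / low-pass cascade of the given
#' order, which is numerically robust for very low high-pass edges.  With
#' `low = 0` only the low-pass is applied.
#'
#' @param epochs `epoched_data`.
#' @param low,high band edges in Hz; `0 <= low < high < fs/2`.
#' @param order Butterworth design order per section (default 4).
#' @return filtered `epoched_data`.
#' @export
bandpass <- function(epochs, low, high, order = 4L) {
  stopifnot(inherits(epochs, "epoched_data"))
  if (!(low >= 0 && low < high && high < epochs$fs / 2)) {
    stop_("band edges must satisfy 0 <= low < high < fs/2 (got %g-%g at fs %g)",
          low, high, epochs$fs)
  }
  coefs <- list(butter_coef(order, high, epochs$fs, "low"))
  if (low > 0) coefs <- c(list(butter_coef(order, low, epochs$fs, "high")), coefs)
  epochs$data <- filter_epochs_array(epochs$data, coefs)
  add_provenance(epochs, "bandpass", list(low = low, high = high, order = order))
}

#' Zero-phase low-pass filter
#'
#' @param epochs `epoched_data`.
#' @param high cutoff in Hz.
#' @param order Butterworth order.
#' @return filtered `epoched_data`.
#' @export
lowpass <- function(epochs, high, order = 4L) {
  bandpass(epochs, 0, high, order)
}

# squared magnitude response of a zero-phase (forward-backward) cascade
zerophase_response <- function(coefs, f_hz, fs) {
  w <- 2 * pi * f_hz / fs
  h <- rep(1 + 0i, length(w))
  for (coef in coefs) {
    z <- exp(-1i * w)
    num <- vapply(z, function(zz) sum(coef$b * zz^(seq_along(coef$b) - 1)), complex(1))
    den <- vapply(z, function(zz) sum(coef$a * zz^(seq_along(coef$a) - 1)), complex(1))
    h <- h * num / den
  }
  Mod(h)^2 # forward-backward pass squares the magnitude
}

#' Resample epoched data to a lower rate
#'
#' Anti-alias low-pass filtering (zero-phase Butterworth, cutoff
#' `0.45 * fs_new`) followed by linear interpolation onto the new sample
#' grid, which starts at the same first sample.  When `fs / fs_new` is an
#' integer the interpolation reduces to exact decimation.
#'
#' @param epochs `epoched_data`.
#' @param fs_new target sampling rate in Hz; must be `< fs`.
#' @return resampled `epoched_data`.
#' @export
resample_epochs <- function(epochs, fs_new) {
  stopifnot(inherits(epochs, "epoched_data"))
  if (fs_new >= epochs$fs) stop_("fs_new (%g) must be below fs (%g)", fs_new, epochs$fs)
  coef <- butter_coef(8L, 0.45 * fs_new, epochs$fs, "low")
  data <- filter_epochs_array(epochs$data, list(coef))

  t_old <- epochs$time_ms
  dt_new <- 1000 / fs_new
  m <- floor((t_old[length(t_old)] - t_old[1]) / dt_new + 1e-9) + 1
  t_new <- t_old[1] + (seq_len(m) - 1) * dt_new
  pos <- (t_new - t_old[1]) / (1000 / epochs$fs) + 1
  i0 <- pmin(floor(pos), length(t_old) - 1)
  wgt <- pos - i0
  new_data <- (1 - rep(wgt, each = prod(dim(data)[1:2]))) *
    data[, , i0, drop = FALSE] +
    rep(wgt, each = prod(dim(data)[1:2])) * data[, , i0 + 1, drop = FALSE]

  out <- epoched_data(new_data, fs_new, t_new, epochs$trials, epochs$layout,
                      artifacts = epochs$artifacts, provenance = epochs$provenance)
  add_provenance(out, "resample", list(fs_new = fs_new))
}
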