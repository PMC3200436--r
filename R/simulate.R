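# Synthetic evoked sensor data: component superposition, 1/f + white noise,
# blink and high-amplitude artifacts.

#' Noise and artifact specification
#'
#' @param white_sd white-noise SD per sample (Tesla or Volt).
#' @param pink_sd SD of the 1/f ("pink") noise floor.
#' @param pink_exponent spectral exponent alpha of the `1/f^alpha` power
#'   spectrum (1 = pink).
#' @param blink_rate per-trial probability of an eye-blink artifact.
#' @param blink_amplitude peak blink amplitude at the most affected channel.
#' @param jump_rate per-trial probability of a high-amplitude channel jump.
#' @param jump_amplitude guaranteed exceedance level of injected jumps.
#' @param seed integer seed for all noise and artifact draws.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(white_sd = 5e-13, pink_sd = 5e-13, pink_exponent = 1,
                       blink_rate = 0.08, blink_amplitude = 4e-12,
                       jump_rate = 0.01, jump_amplitude = 5e-10, seed = 1L) {
  if (blink_rate < 0 || blink_rate > 1 || jump_rate < 0 || jump_rate > 1) {
    stop_("artifact rates must lie in [0, 1]")
  }
  if (white_sd < 0 || pink_sd < 0 || blink_amplitude < 0 || jump_amplitude < 0) {
    stop_("noise amplitudes must be >= 0")
  }
  out <- list(white_sd = white_sd, pink_sd = pink_sd,
              pink_exponent = pink_exponent, blink_rate = blink_rate,
              blink_amplitude = blink_amplitude, jump_rate = jump_rate,
              jump_amplitude = jump_amplitude, seed = as.integer(seed))
  class(out) <- "noise_spec"
  out
}

# 1/f^alpha noise, unit variance, by spectral synthesis: white Gaussian
# noise is shaped in the frequency domain with amplitude f^(-alpha/2),
# normalized analytically so the output SD equals 1.  Real and imaginary
# parts of one complex white input give two independent series, halving
# the FFT work.
pink_noise_matrix <- function(n_samples, n_series, exponent = 1) {
  noise_field_matrix(n_samples, n_series, 0, 1, exponent)
}

# white + 1/f^alpha noise in one spectral synthesis: the sum of the two
# independent Gaussian fields equals one Gaussian field whose power
# spectrum is the sum of the component spectra
noise_field_matrix <- function(n_samples, n_series, white_sd, pink_sd,
                               exponent = 1) {
  if (pink_sd == 0 || exponent == 0) {
    sd_tot <- sqrt(white_sd^2 + pink_sd^2)
    return(matrix(sd_tot * stats::rnorm(n_samples * n_series),
                  n_samples, n_series))
  }
  half <- ceiling(n_series / 2)
  nfft <- stats::nextn(n_samples, c(2, 3, 5)) # FFT-smooth length, then crop
  w <- matrix(complex(real = stats::rnorm(nfft * half),
                      imaginary = stats::rnorm(nfft * half)),
              nfft, half)
  k <- seq_len(nfft) - 1
  f <- pmin(k, nfft - k)               # symmetric FFT frequency index
  ampP <- c(0, f[-1]^(-exponent / 2))  # pink amplitude, zero at DC
  ampP <- ampP / sqrt(mean(ampP^2))
  amp <- sqrt(white_sd^2 + pink_sd^2 * ampP^2)
  x <- stats::mvfft(stats::mvfft(w) * amp, inverse = TRUE) / nfft
  x <- x[seq_len(n_samples), , drop = FALSE]
  cbind(Re(x), Im(x))[, seq_len(n_series), drop = FALSE]
}

#' Simulate evoked epochs from component specifications
#'
#' Each trial's clean signal is the superposition over components of
#' `amplitude * g(valence, P) * topography (x) Gaussian(peak, sd)`, to which
#' white and `1/f` noise are added.  Identical seeds give identical output.
#'
#' @param trials a `trial_table`.
#' @param components list of [erf_component()].
#' @param layout a `sensor_layout`.
#' @param noise a [noise_spec()]; use `noise_spec(white_sd = 0, pink_sd = 0)`
#'   for noise-free templates.
#' @param fs sampling rate (Hz).
#' @param t_start,t_end epoch window in ms (half-open on the right).
#' @param gain_scale scalar multiplier on all component amplitudes (e.g. a
#'   per-subject gain).
#' @return `epoched_data`.
#' @export
simulate_evoked <- function(trials, components, layout, noise = noise_spec(),
                            fs = 600, t_start = -160, t_end = 700,
                            gain_scale = 1) {
  if (!is_scalar_num(fs) || fs <= 0) stop_("fs must be a positive number")
  time_ms <- epoch_time_axis(fs, t_start, t_end)
  n <- nrow(trials); C <- length(layout$channel_ids); S <- length(time_ms)

  # clean signal assembled from per-condition templates: every trial in the
  # same (valence, P) cell shares one channels x samples template
  cell <- paste(trials$outcome_valence, trials$outcome_prob)
  ucell <- unique(cell)
  uval <- sub(" .*", "", ucell)
  uprob <- as.numeric(sub(".* ", "", ucell))
  templates <- array(0, c(length(ucell), C, S))
  for (comp in components) {
    if (comp$peak_ms < time_ms[1] || comp$peak_ms > time_ms[S]) {
      stop_("component '%s' peaks at %g ms, outside the epoch window",
            comp$name, comp$peak_ms)
    }
    topo <- component_topography(comp, layout)
    kernel <- exp(-(time_ms - comp$peak_ms)^2 / (2 * comp$sd_ms^2))
    g <- gain_scale * comp$amplitude * comp$gain(uval, uprob)
    templates <- templates + outer(g, topo %o% kernel)
  }
  data <- templates[match(cell, ucell), , , drop = FALSE]

  if (noise$white_sd > 0 || noise$pink_sd > 0) {
    set.seed(derive_seed(noise$seed, "noise"))
    # generate along the time axis in trial chunks to bound memory
    chunk <- max(1L, floor(2e6 / (C * S)) * 4L)
    for (i0 in seq(1L, n, by = chunk)) {
      idx <- i0:min(n, i0 + chunk - 1L)
      p <- noise_field_matrix(S, length(idx) * C, noise$white_sd,
                              noise$pink_sd, noise$pink_exponent)
      dim(p) <- c(S, length(idx), C)
      data[idx, , ] <- data[idx, , , drop = FALSE] + aperm(p, c(2, 3, 1))
    }
  }

  ep <- epoched_data(data, fs, time_ms, trials, layout)
  add_provenance(ep, "simulate_evoked",
                 list(fs = fs, n_components = length(components),
                      white_sd = noise$white_sd, pink_sd = noise$pink_sd,
                      seed = noise$seed))
}

# canonical blink spatial pattern: proximity falloff from the eyes
blink_topography <- function(layout, eye_m = c(0, 0.10, -0.01), sigma_m = 0.05) {
  d2 <- rowSums(sweep(layout$positions_3d, 2, eye_m)^2)
  w <- exp(-d2 / (2 * sigma_m^2))
  w / max(w)
}

#' Inject blink and high-amplitude artifacts
#'
#' Blink events add a fixed rank-1 spatial pattern (a proximity falloff from
#' the eyes) with a stereotyped Gaussian time course at a random latency.
#' Jump events add a brief spike on one random channel whose polarity
#' follows the underlying sample, guaranteeing `|sample| > jump_amplitude`.
#' Affected trial indices are recorded in `$artifacts`.
#'
#' @param epochs `epoched_data`.
#' @param noise a [noise_spec()] providing rates, amplitudes and the seed.
#' @return `epoched_data` with artifacts added and metadata recorded.
#' @export
inject_artifacts <- function(epochs, noise) {
  stopifnot(inherits(epochs, "epoched_data"))
  if (!all(is.finite(epochs$data))) stop_("epochs must be finite")
  d <- dim(epochs$data); n <- d[1]; S <- d[3]
  t <- epochs$time_ms
  set.seed(derive_seed(noise$seed, "artifacts"))

  blink_trials <- integer(0); jump_trials <- integer(0); jump_channels <- integer(0)
  if (noise$blink_rate > 0) {
    blink_trials <- which(stats::runif(n) < noise$blink_rate)
    topo <- noise$blink_amplitude * blink_topography(epochs$layout)
    onsets <- stats::runif(length(blink_trials), t[1] + 100, t[S] - 100)
    for (i in seq_along(blink_trials)) {
      course <- exp(-(t - onsets[i])^2 / (2 * 50^2))
      epochs$data[blink_trials[i], , ] <-
        epochs$data[blink_trials[i], , ] + topo %o% course
    }
    epochs$artifacts$blink_topography <- topo
    epochs$artifacts$blink_onsets <- onsets
  }
  if (noise$jump_rate > 0) {
    jump_trials <- which(stats::runif(n) < noise$jump_rate)
    jump_channels <- sample.int(d[2], length(jump_trials), replace = TRUE)
    for (i in seq_along(jump_trials)) {
      # sustained baseline step from a random onset (SQUID-jump-like),
      # polarity matching the underlying sample so the exceedance holds
      at <- sample.int(S - 4L, 1L)
      seg <- at:S
      x <- epochs$data[jump_trials[i], jump_channels[i], seg]
      epochs$data[jump_trials[i], jump_channels[i], seg] <-
        x + ifelse(x[1] >= 0, 1, -1) * noise$jump_amplitude
    }
  }
  epochs$artifacts$blink_trials <- blink_trials
  epochs$artifacts$jump_trials <- jump_trials
  epochs$artifacts$jump_channels <- jump_channels
  add_provenance(epochs, "inject_artifacts",
                 list(n_blinks = length(blink_trials),
                      n_jumps = length(jump_trials), seed = noise$seed))
}

#' Simulate a complete session
#'
#' Convenience wrapper: [build_session_design()] (unless a design is given),
#' [simulate_evoked()], then [inject_artifacts()].
#'
#' @param design optional `trial_table`; built with defaults otherwise.
#' @param components,layout,noise,fs,gain_scale passed to [simulate_evoked()].
#' @param seed session seed; overrides `noise$seed`.
#' @return `epoched_data`.
#' @export
simulate_session <- function(design = NULL, components = default_components(),
                             layout = meg_sensor_layout(), noise = noise_spec(),
                             fs = 600, seed = 1L, gain_scale = 1) {
  noise$seed <- as.integer(seed)
  if (is.null(design)) design <- build_session_design(seed = seed)
  ep <- simulate_evoked(design, components, layout, noise, fs,
                        gain_scale = gain_scale)
  inject_artifacts(ep, noise)
}
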