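# Evoked-component specifications: Gaussian time course x sensor topography
# x condition-dependent gain.

#' Define an evoked component
#'
#' A component is a Gaussian time course (peak latency, temporal SD) with a
#' fixed sensor topography and a gain `g(valence, P)` that scales it per
#' trial as a function of outcome valence and realized-outcome probability.
#'
#' @param name label.
#' @param peak_ms peak latency in ms relative to outcome onset.
#' @param sd_ms temporal Gaussian SD in ms.
#' @param topography per-channel weight vector (length = channels), or a
#'   function of a `sensor_layout` returning one.
#' @param gain function `g(valence, p)` returning a dimensionless amplitude
#'   multiplier; must be vectorized over its arguments.
#' @param amplitude physical scale of the component at gain 1 (Tesla for MEG,
#'   Volt for EEG).
#' @return an object of class `erf_component`.
#' @export
erf_component <- function(name, peak_ms, sd_ms, topography, gain,
                          amplitude = 1e-13) {
  stopifnot(is_scalar_num(peak_ms), is_scalar_num(sd_ms), sd_ms > 0,
            is.function(gain), is_scalar_num(amplitude))
  out <- list(name = name, peak_ms = peak_ms, sd_ms = sd_ms,
              topography = topography, gain = gain, amplitude = amplitude)
  class(out) <- "erf_component"
  out
}

#' Prediction-error component
#'
#' Gain follows the axiomatic prediction-error pattern: `+beta * (1 - P)` for
#' wins, `-beta * (1 - P)` for losses, and exactly zero for fully predicted
#' outcomes (P = 1).  Largest for the least likely outcomes, opposite in
#' sign for wins and losses.
#'
#' @param beta slope of the gain in `(1 - P)`.
#' @param peak_ms,sd_ms,topography,amplitude see [erf_component()].
#' @export
pe_component <- function(beta = 1, peak_ms = 320, sd_ms = 35,
                         topography = function(l) dipole_topography(l, c(-0.01, 0.01, 0.05), c(1, 1, 0)),
                         amplitude = 1.5e-13) {
  erf_component("prediction_error", peak_ms, sd_ms, topography,
                gain = function(valence, p) {
                  ifelse(valence == "win", beta * (1 - p), -beta * (1 - p))
                },
                amplitude = amplitude)
}

#' Outcome-valence component
#'
#' Gain depends only on valence (`gain_win` for wins, `gain_loss` for
#' losses), independent of probability; emulates the early valence response.
#'
#' @param gain_win,gain_loss gains for win and loss trials.
#' @param peak_ms,sd_ms,topography,amplitude see [erf_component()].
#' @export
valence_component <- function(gain_win = 1, gain_loss = -1, peak_ms = 200,
                              sd_ms = 30,
                              topography = function(l) dipole_topography(l, c(0.04, 0.01, 0.04), c(0, 1, 0)),
                              amplitude = 1.2e-13) {
  erf_component("valence", peak_ms, sd_ms, topography,
                gain = function(valence, p) {
                  ifelse(valence == "win", gain_win, gain_loss)
                },
                amplitude = amplitude)
}

#' Outcome-probability component
#'
#' Gain is an affine function of realized-outcome probability, identical for
#' wins and losses; emulates the later P300-like probability response.
#'
#' @param slope,intercept gain = `intercept + slope * P`.
#' @param peak_ms,sd_ms,topography,amplitude see [erf_component()].
#' @export
probability_component <- function(slope = -1, intercept = 1, peak_ms = 340,
                                  sd_ms = 40,
                                  topography = function(l) dipole_topography(l, c(0.01, -0.05, 0.04), c(1, 0, 0)),
                                  amplitude = 1.2e-13) {
  erf_component("probability", peak_ms, sd_ms, topography,
                gain = function(valence, p) intercept + slope * p,
                amplitude = amplitude)
}

#' Component set reproducing the FRN-like scalp-potential pattern
#'
#' A single fronto-central component at 270 ms whose gain increases with
#' outcome probability for *both* valences (win: `2 + 1.5 P`; loss:
#' `0.5 + 3 P`), with wins and losses equal at P = 1.  The loss - win
#' difference then shrinks linearly to zero as P grows -- a robust
#' difference-wave FRN -- while the separate win and loss signals share the
#' same slope sign, violating the bidirectional (axiom-2) requirement.
#'
#' @param layout a `sensor_layout`; the topography peaks at Cz when the
#'   default EEG montage is used.
#' @param amplitude physical scale (Volt).
#' @return list with one `erf_component`.
#' @export
eeg_frn_components <- function(layout = eeg_sensor_layout(), amplitude = 7e-6) {
  # source just posterior of the vertex: Cz sits on the positive extremum
  topo <- dipole_topography(layout, c(0, -0.03, 0.05), c(1, 0, 0))
  list(erf_component("frn_like", peak_ms = 270, sd_ms = 40, topography = topo,
                     gain = function(valence, p) {
                       ifelse(valence == "win", 2 + 1.5 * p, 0.5 + 3 * p)
                     },
                     amplitude = amplitude))
}

#' Default MEG component set
#'
#' Early valence (200 ms), probability (340 ms) and prediction-error
#' (320 ms) components with dipolar topographies at distinct sources.
#'
#' @param beta prediction-error gain slope.
#' @return list of `erf_component`.
#' @export
default_components <- function(beta = 1) {
  list(valence_component(), probability_component(), pe_component(beta = beta))
}

# resolve a component's topography against a concrete layout
component_topography <- function(component, layout) {
  topo <- component$topography
  if (is.function(topo)) topo <- topo(layout)
  if (length(topo) != length(layout$channel_ids)) {
    stop_("component '%s': topography has %d weights but layout has %d channels",
          component$name, length(topo), length(layout$channel_ids))
  }
  as.numeric(topo)
}
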