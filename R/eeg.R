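# EEG study arm: scalp-potential sessions on the 11-electrode montage,
# mastoid re-referencing, 2-30 Hz filtering, robust averaging, and the
# electrode-level condition waveforms for FRN / axiom analyses.

#' Default EEG noise specification
#'
#' Single-trial scalp-potential noise (Volt scale): 8 uV white and 1/f
#' floors (a clean laboratory recording), ~100 uV blinks; no channel jumps
#' (EEG amplifiers do not exhibit SQUID-style baseline jumps, and artifact
#' handling is delegated to the robust averager).
#'
#' @param seed integer seed.
#' @return `noise_spec`.
#' @export
eeg_noise_spec <- function(seed = 1L) {
  noise_spec(white_sd = 8e-6, pink_sd = 8e-6, pink_exponent = 1,
             blink_rate = 0.08, blink_amplitude = 1e-4,
             jump_rate = 0, jump_amplitude = 0, seed = seed)
}

#' Simulate the EEG study arm and extract electrode waveforms
#'
#' For each subject: a full gambling session on the 11-electrode montage
#' with the FRN-like component set ([eeg_frn_components()]: both win and
#' loss amplitudes increase with outcome probability, equal at P = 1),
#' re-referenced to the mastoid mean, resampled to 200 Hz, band-passed
#' 2-30 Hz, baseline-corrected, and robust-averaged per condition with a
#' 30 Hz post-average low-pass.  Returns the per-subject condition
#' waveforms at one electrode, ready for [frn_difference()] and
#' [window_average()] / [axiom_compliance()].
#'
#' @param n_subjects number of subjects (default 17).
#' @param seed study seed.
#' @param electrode electrode to extract (default `"Cz"`).
#' @param components component list; defaults to [eeg_frn_components()].
#' @param noise `noise_spec`; defaults to [eeg_noise_spec()].
#' @param fs acquisition sampling rate in Hz (default 480).
#' @param subject_gain_sd lognormal SD of the per-subject amplitude gain.
#' @param counts_per_win_prob,n_blocks session design (defaults as in
#'   [build_session_design()]).
#' @return `condition_waveforms` (subjects x 2 x 4 x samples) at the
#'   electrode, with the 200 Hz epoch time axis.
#' @export
simulate_eeg_study <- function(n_subjects = 17L, seed = 1L, electrode = "Cz",
                               components = NULL, noise = NULL, fs = 480,
                               subject_gain_sd = 0.1,
                               counts_per_win_prob = c("0" = 45, "0.25" = 180,
                                                       "0.5" = 90, "0.75" = 180,
                                                       "1" = 45),
                               n_blocks = 9L) {
  layout <- eeg_sensor_layout()
  if (is.null(components)) components <- eeg_frn_components(layout)
  ich <- match(electrode, layout$channel_ids)
  if (is.na(ich)) stop_("electrode '%s' not in the EEG montage", electrode)

  waves <- NULL
  cond <- canonical_conditions()
  for (s in seq_len(n_subjects)) {
    seed_s <- derive_seed(seed, paste0("eeg_subject", s))
    ns <- if (is.null(noise)) eeg_noise_spec(seed_s) else { noise$seed <- seed_s; noise }
    design <- build_session_design(counts_per_win_prob, n_blocks, seed = seed_s)
    set.seed(derive_seed(seed, paste0("eeg_gain", s)))
    gain <- exp(stats::rnorm(1, 0, subject_gain_sd))
    ep <- simulate_evoked(design, components, layout, ns, fs, gain_scale = gain)
    ep <- inject_artifacts(ep, ns)
    ep <- rereference(ep, c("M1", "M2"))
    rb <- resample_bandpass_array(ep$data, ep$time_ms, ep$fs, 200, c(2, 30))
    ep <- epoched_data(rb$data, rb$fs, rb$time_ms, ep$trials, ep$layout,
                       artifacts = ep$artifacts, provenance = ep$provenance)
    ep <- baseline_correct(ep)
    ev <- average_conditions(ep, method = "robust", lowpass_hz = 30)
    if (is.null(waves)) {
      waves <- array(NA_real_, c(n_subjects, 2, 4, length(ev$time_ms)))
      time_ms <- ev$time_ms
    }
    for (i in seq_len(nrow(cond))) {
      v <- if (cond$outcome_valence[i] == "win") 1L else 2L
      p <- match(cond$outcome_prob[i], c(0.25, 0.5, 0.75, 1))
      waves[s, v, p, ] <- ev$data[i, ich, ]
    }
  }
  condition_waveforms(waves, time_ms)
}
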