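# Configuration handling and the end-to-end pipeline driver.

#' Default pipeline configuration
#'
#' The defaults encode the study conditions the package emulates: a
#' 540-trial session per subject (45 gambles at P = 0 and 1, 90 at .50,
#' 180 at .25 and .75, in 9 blocks), 17 subjects, 275 axial gradiometers,
#' acquisition at 600 Hz; preprocessing resamples to 200 Hz, band-passes
#' 0.5-30 Hz, rejects trials above 1.5e-10 T and projects out 4 blink
#' components; images are 64 x 64 pixels of 3 mm smoothed with an
#' 8 mm/8 mm/8 ms FWHM kernel and masked to 100-600 ms; the ANCOVA uses a
#' peak threshold of 0.005 with cluster extent 100 and a P = 1 equivalence
#' mask at 0.05; the axiom battery averages 295-345 ms.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    n_subjects = 17L,
    n_channels = 275L,
    fs = 600,
    subject_gain_sd = 0.1,
    design = list(
      counts_per_win_prob = c("0" = 45, "0.25" = 180, "0.5" = 90,
                              "0.75" = 180, "1" = 45),
      n_blocks = 9L
    ),
    components = list(
      pe_beta = 1,
      pe_amplitude = 1.5e-13,
      include_valence = TRUE,
      include_probability = TRUE
    ),
    noise = list(
      white_sd = 5e-13, pink_sd = 5e-13, pink_exponent = 1,
      blink_rate = 0.08, blink_amplitude = 4e-12,
      jump_rate = 0.01, jump_amplitude = 5e-10
    ),
    preprocess = list(
      fs_target = 200, band = c(0.5, 30), reject_threshold = 1.5e-10,
      ssp_k = 4L, average = "mean"
    ),
    map = list(
      grid_n = 64L, pixel_mm = 3, fwhm = c(8, 8, 8), window = c(100, 600)
    ),
    glm = list(
      alpha_peak = 0.005, extent_min = 100L, mask_alpha = 0.05,
      connectivity = 26L, subject_effects = TRUE
    ),
    axioms = list(window = c(295, 345), alpha = 0.05),
    frn = list(window = c(0, 600))
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(defaults)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop_("unknown configuration key(s): %s",
          paste0(path, unknown, collapse = ", "))
  }
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
                           k != "counts_per_win_prob") {
      merge_config(defaults[[k]], user[[k]], paste0(path, k, "."))
    } else {
      user[[k]]
    }
  }
  defaults
}

#' Read and validate a pipeline configuration file
#'
#' YAML (or JSON) file whose keys mirror [default_config()]; unknown keys
#' are rejected, missing ones take their defaults.
#'
#' @param path configuration file.
#' @return a validated configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (!is.null(user$design$counts_per_win_prob)) {
    user$design$counts_per_win_prob <- unlist(user$design$counts_per_win_prob)
  }
  merge_config(default_config(), user)
}

config_components <- function(config) {
  comps <- list()
  if (isTRUE(config$components$include_valence)) {
    comps <- c(comps, list(valence_component()))
  }
  if (isTRUE(config$components$include_probability)) {
    comps <- c(comps, list(probability_component()))
  }
  if (config$components$pe_beta != 0) {
    comps <- c(comps, list(pe_component(beta = config$components$pe_beta,
                                        amplitude = config$components$pe_amplitude)))
  }
  comps
}

config_noise <- function(config, seed) {
  do.call(noise_spec, c(config$noise, list(seed = seed)))
}

# simulate + preprocess + image one subject; returns the list of per-
# condition scalp images (canonical condition order)
simulate_subject_images <- function(config, subject, components, layout,
                                    interpolator) {
  seed_s <- derive_seed(config$seed, paste0("subject", subject))
  design <- build_session_design(config$design$counts_per_win_prob,
                                 config$design$n_blocks, seed = seed_s)
  set.seed(derive_seed(config$seed, paste0("gain", subject)))
  gain <- exp(stats::rnorm(1, 0, config$subject_gain_sd))
  noise <- config_noise(config, seed_s)
  ep <- simulate_evoked(design, components, layout, noise, config$fs,
                        gain_scale = gain)
  ep <- inject_artifacts(ep, noise)
  pp <- preprocess(ep,
                   fs_target = config$preprocess$fs_target,
                   band = config$preprocess$band,
                   reject_threshold = config$preprocess$reject_threshold,
                   ssp_k = config$preprocess$ssp_k,
                   average = config$preprocess$average)
  sensor_maps(pp$evoked, grid_n = config$map$grid_n,
              pixel_mm = config$map$pixel_mm, fwhm = config$map$fwhm,
              window = config$map$window, interpolator = interpolator)
}

#' Run the full analysis pipeline on synthetic sessions
#'
#' Executes the canonical stage order for every subject -- session design,
#' evoked simulation with artifacts, preprocessing (resample, band-pass,
#' baseline, rejection, blink projection), condition averaging, scalp-image
#' construction -- then the group ANCOVA with the valence, probability and
#' interaction F contrasts, cluster thresholding, the P = 1 equivalence
#' mask on the interaction, and finally the axiom battery and FRN-style
#' difference-wave analysis at the interaction peak voxel.  Fully
#' reproducible from `(config, seed)`.
#'
#' @param config configuration list from [default_config()] or
#'   [read_config()].
#' @param seed overrides `config$seed` if given.
#' @param progress print per-stage progress to stderr.
#' @param keep_images also return the per-(subject, condition) scalp images
#'   (`$images`), e.g. for cluster-averaged signal extraction.
#' @return object of class `axiomerf_report`: cluster tables for the three
#'   contrasts, the equivalence mask summary, `axioms` (`axiom_report` or
#'   NULL if no interaction cluster survived), `frn` (`frn_result` or
#'   NULL), `peak` (interaction peak voxel and time), `condition_means`,
#'   `config`.
#' @export
run_pipeline <- function(config = default_config(), seed = NULL,
                         progress = FALSE, keep_images = FALSE) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  config <- merge_config(default_config(), config)
  say <- function(...) if (progress) message(sprintf(...))

  components <- config_components(config)
  layout <- meg_sensor_layout(config$n_channels)
  pos <- project_sensors(layout)
  interpolator <- build_interpolator(pos, config$map$grid_n, config$map$pixel_mm)

  S <- config$n_subjects
  all_images <- vector("list", 8L * S)
  for (s in seq_len(S)) {
    say("subject %d / %d", s, S)
    imgs <- simulate_subject_images(config, s, components, layout, interpolator)
    all_images[(s - 1L) * 8L + seq_len(8L)] <- imgs
  }
  conditions <- canonical_conditions()

  say("group ANCOVA")
  design <- build_design(S, config$glm$subject_effects)
  maps <- list(
    valence = fit_and_contrast(all_images, design, c(1, -1, 0, 0)),
    probability = fit_and_contrast(all_images, design, c(0, 0, 1, 1)),
    interaction = fit_and_contrast(all_images, design, c(0, 0, 1, -1))
  )
  win_p1 <- all_images[(seq_len(S) - 1L) * 8L + 4L]
  loss_p1 <- all_images[(seq_len(S) - 1L) * 8L + 8L]
  eq_mask <- equivalence_mask(win_p1, loss_p1, config$glm$mask_alpha)

  clusters <- list(
    valence = threshold_and_cluster(maps$valence, config$glm$alpha_peak,
                                    config$glm$extent_min,
                                    config$glm$connectivity),
    probability = threshold_and_cluster(maps$probability, config$glm$alpha_peak,
                                        config$glm$extent_min,
                                        config$glm$connectivity),
    interaction = threshold_and_cluster(maps$interaction, config$glm$alpha_peak,
                                        config$glm$extent_min,
                                        config$glm$connectivity,
                                        mask = eq_mask)
  )

  axioms <- NULL; frn <- NULL; peak <- NULL; cond_means <- NULL
  if (nrow(clusters$interaction) > 0) {
    pk <- clusters$interaction[1, ]
    ref <- all_images[[1]]
    ix <- which.min(abs(ref$coords_mm - pk$x_mm))
    iy <- which.min(abs(ref$coords_mm - pk$y_mm))
    waves <- extract_condition_waveforms(all_images, S, ix, iy)
    cond_means <- window_average(waves, config$axioms$window)
    axioms <- axiom_compliance(cond_means, config$axioms$alpha)
    frn <- frn_difference(waves, config$frn$window)
    peak <- list(ix = ix, iy = iy, x_mm = pk$x_mm, y_mm = pk$y_mm,
                 t_ms = pk$t_ms)
  }

  structure(list(clusters = clusters, equivalence_mask_summary = list(
    alpha = eq_mask$alpha, excluded_fraction = eq_mask$excluded_fraction),
    axioms = axioms, frn = frn, peak = peak,
    condition_means = cond_means, df = maps$interaction$df,
    F_crit = attr(clusters$interaction, "F_crit"),
    images = if (keep_images) all_images else NULL,
    config = config),
    class = "axiomerf_report")
}

#' Extract per-subject condition waveforms at one or more pixels
#'
#' With a single pixel, returns the waveforms at that pixel; with pixel
#' vectors (e.g. a cluster's spatial footprint), the waveform is the mean
#' over the pixels at every frame.
#'
#' @param images flat list of per-(subject, condition) `scalp_image` in
#'   subject-major canonical condition order.
#' @param n_subjects number of subjects.
#' @param ix,iy pixel index vectors (paired).
#' @return `condition_waveforms` (subjects x 2 x 4 x frames).
#' @export
extract_condition_waveforms <- function(images, n_subjects, ix, iy) {
  g <- dim(images[[1]]$values)[1]
  T_ <- dim(images[[1]]$values)[3]
  pix <- unique(cbind(ix, iy))
  lin <- pix[, 1] + (pix[, 2] - 1L) * g
  arr <- array(NA_real_, c(n_subjects, 2, 4, T_))
  for (s in seq_len(n_subjects)) {
    for (c_ in 1:8) {
      img <- images[[(s - 1L) * 8L + c_]]
      flat <- matrix(img$values, g * g, T_)
      v <- if (c_ <= 4) 1L else 2L
      p <- ((c_ - 1L) %% 4L) + 1L
      arr[s, v, p, ] <- colMeans(flat[lin, , drop = FALSE])
    }
  }
  condition_waveforms(arr, images[[1]]$time_ms)
}

#' Noise-free template condition means at a pixel
#'
#' Runs a single noiseless, artifact-free subject through the identical
#' preprocessing and imaging chain and returns its condition means at the
#' given pixel -- the injected-signal template against which recovered
#' slopes can be compared.
#'
#' @param config pipeline configuration.
#' @param ix,iy pixel indices (e.g. the recovered interaction peak).
#' @return `condition_means` (1 x 2 x 4).
#' @export
template_condition_means <- function(config, ix, iy) {
  config <- merge_config(default_config(), config)
  components <- config_components(config)
  layout <- meg_sensor_layout(config$n_channels)
  interpolator <- build_interpolator(project_sensors(layout),
                                     config$map$grid_n, config$map$pixel_mm)
  design <- build_session_design(config$design$counts_per_win_prob,
                                 config$design$n_blocks,
                                 seed = derive_seed(config$seed, "template"))
  quiet <- noise_spec(white_sd = 0, pink_sd = 0, blink_rate = 0, jump_rate = 0)
  ep <- simulate_evoked(design, components, layout, quiet, config$fs)
  pp <- preprocess(ep, fs_target = config$preprocess$fs_target,
                   band = config$preprocess$band,
                   reject_threshold = NULL, ssp_k = 0L)
  imgs <- sensor_maps(pp$evoked, grid_n = config$map$grid_n,
                      pixel_mm = config$map$pixel_mm, fwhm = config$map$fwhm,
                      window = config$map$window, interpolator = interpolator)
  waves <- extract_condition_waveforms(imgs, 1L, ix, iy)
  window_average(waves, config$axioms$window)
}

#' @export
print.axiomerf_report <- function(x, ...) {
  cat("==== Axiomatic prediction-error pipeline report ====\n")
  cat(sprintf("subjects: %d; ANCOVA df = (%g, %g); F_crit = %.2f\n",
              x$config$n_subjects, x$df[1], x$df[2], x$F_crit))
  for (nm in names(x$clusters)) {
    cat(sprintf("\n-- %s contrast --\n", nm))
    print(x$clusters[[nm]])
  }
  cat(sprintf("\nP=1 equivalence mask: %.1f%% of voxels excluded (alpha = %g)\n",
              100 * x$equivalence_mask_summary$excluded_fraction,
              x$equivalence_mask_summary$alpha))
  if (!is.null(x$peak)) {
    cat(sprintf("\ninteraction peak: x = %g mm, y = %g mm, t = %g ms\n",
                x$peak$x_mm, x$peak$y_mm, x$peak$t_ms))
  }
  if (!is.null(x$axioms)) { cat("\n"); print(x$axioms) }
  if (!is.null(x$frn)) { cat("\n"); print(x$frn) }
  invisible(x)
}

#' Export a pipeline report to JSON and TSV
#'
#' Writes `report.json` plus one TSV cluster table per contrast into `dir`.
#' Identical reports produce byte-identical files.
#'
#' @param report `axiomerf_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_report <- function(report, dir) {
  stopifnot(inherits(report, "axiomerf_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(
    clusters = lapply(report$clusters, function(tb) as.data.frame(tb)),
    equivalence_mask = report$equivalence_mask_summary,
    df = report$df, F_crit = report$F_crit,
    peak = report$peak,
    axioms = if (!is.null(report$axioms)) list(
      overall = report$axioms$overall,
      axiom1_pass = report$axioms$axiom1$pass,
      axiom2_pass = report$axioms$axiom2$pass,
      axiom3_pass = report$axioms$axiom3$pass,
      win_slope = report$axioms$axiom2$win_slope,
      loss_slope = report$axioms$axiom2$loss_slope),
    frn = if (!is.null(report$frn)) list(
      probability_F = report$frn$probability_F,
      probability_p = report$frn$probability_p,
      linear_trend_F = report$frn$linear_trend_F,
      linear_trend_p = report$frn$linear_trend_p),
    seed = report$config$seed
  )
  jsonlite::write_json(out, file.path(dir, "report.json"), digits = NA,
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  for (nm in names(report$clusters)) {
    utils::write.table(as.data.frame(report$clusters[[nm]]),
                       file.path(dir, sprintf("clusters_%s.tsv", nm)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  writeLines(utils::capture.output(print(report)), file.path(dir, "report.txt"))
  invisible(dir)
}
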