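# Sensor layouts: whole-head MEG gradiometer array and a small EEG montage.

#' Construct a sensor layout
#'
#' @param channel_ids character vector of unique channel labels.
#' @param positions_3d numeric matrix (channels x 3), metres, head-centred.
#' @param channel_type `"axial_gradiometer"` or `"eeg"` (recycled).
#' @return an object of class `sensor_layout`.
#' @export
sensor_layout <- function(channel_ids, positions_3d,
                          channel_type = "axial_gradiometer") {
  positions_3d <- as.matrix(positions_3d)
  if (nrow(positions_3d) != length(channel_ids) || ncol(positions_3d) != 3L) {
    stop_("positions_3d must be a (channels x 3) matrix matching channel_ids")
  }
  if (anyDuplicated(channel_ids)) stop_("channel labels must be unique")
  if (anyDuplicated(round(positions_3d, 12))) stop_("sensor positions must be unique")
  radii <- sqrt(rowSums(positions_3d^2))
  if (any(radii <= 0)) stop_("all sensor radii must be > 0")
  out <- list(channel_ids = as.character(channel_ids),
              positions_3d = positions_3d,
              channel_type = rep_len(channel_type, length(channel_ids)))
  class(out) <- "sensor_layout"
  out
}

#' @export
print.sensor_layout <- function(x, ...) {
  cat(sprintf("Sensor layout: %d channels (%s)\n", length(x$channel_ids),
              paste(unique(x$channel_type), collapse = ", ")))
  invisible(x)
}

#' Whole-head axial-gradiometer layout
#'
#' A quasi-uniform Fibonacci-spiral arrangement of axial gradiometers on a
#' spherical cap, emulating a 275-channel whole-head MEG array.  The spiral
#' avoids the exact regularities (cocircular quadruples) of latitude grids,
#' which keeps the scalp-map triangulation well conditioned.
#'
#' @param n_channels number of sensors.
#' @param radius_m helmet radius in metres.
#' @param cap_deg angular extent of the cap from the vertex, degrees.
#' @return a `sensor_layout`.
#' @export
meg_sensor_layout <- function(n_channels = 275L, radius_m = 0.11, cap_deg = 110) {
  i <- seq_len(n_channels)
  golden <- (1 + sqrt(5)) / 2
  # area-uniform in cos(theta) over the cap, golden-angle azimuths
  cmin <- cos(cap_deg * pi / 180)
  costh <- 1 - (i - 0.5) / n_channels * (1 - cmin)
  theta <- acos(costh)
  phi <- 2 * pi * (i / golden) %% (2 * pi)
  pos <- radius_m * cbind(sin(theta) * cos(phi),
                          sin(theta) * sin(phi),
                          costh)
  sensor_layout(sprintf("MEG%03d", i), pos, "axial_gradiometer")
}

#' Eleven-electrode EEG montage
#'
#' Standard 10-20 positions for AF7/AF8, AFz, Fz, Cz, Pz, P3/P4 and the two
#' mastoids (M1/M2), plus a vertical EOG channel below the left eye, on a
#' 9 cm head sphere.
#'
#' @return a `sensor_layout` with `channel_type = "eeg"`.
#' @export
eeg_sensor_layout <- function() {
  # (theta from vertex, phi from +x/right, counterclockwise seen from above)
  ang <- rbind(
    AF7 = c(72, 140), AF8 = c(72, 40), AFz = c(54, 90), Fz = c(36, 90),
    Cz = c(0, 0), Pz = c(36, 270), P3 = c(54, 230), P4 = c(54, 310),
    M1 = c(100, 175), M2 = c(100, 5), VEOG = c(115, 105)
  )
  th <- ang[, 1] * pi / 180; ph <- ang[, 2] * pi / 180
  pos <- 0.09 * cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  sensor_layout(rownames(ang), pos, "eeg")
}

#' Ideal dipolar field topography sampled at the sensors
#'
#' Radial component of the magnetic field of a current-dipole element inside
#' the head sphere, evaluated at each sensor and normalized to unit maximum
#' magnitude.  For axial gradiometers this produces the classic bilateral
#' dipolar (+/-) pattern whose source lies between the extrema.
#'
#' @param layout a `sensor_layout`.
#' @param origin_m numeric length-3, dipole position (metres).
#' @param moment numeric length-3, dipole moment direction.
#' @return numeric vector of per-channel weights, max |weight| = 1.
#' @export
dipole_topography <- function(layout, origin_m = c(0, 0.02, 0.05),
                              moment = c(1, 0, 0)) {
  stopifnot(inherits(layout, "sensor_layout"))
  r <- layout$positions_3d
  d <- sweep(r, 2, origin_m)          # sensor - source
  dist3 <- pmax(sqrt(rowSums(d^2)), 1e-6)^3
  m_cross_d <- cbind(moment[2] * d[, 3] - moment[3] * d[, 2],
                     moment[3] * d[, 1] - moment[1] * d[, 3],
                     moment[1] * d[, 2] - moment[2] * d[, 1])
  rhat <- r / sqrt(rowSums(r^2))
  b <- rowSums(m_cross_d * rhat) / dist3
  if (max(abs(b)) == 0) stop_("degenerate dipole: zero field at all sensors")
  b / max(abs(b))
}
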