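# Sensor-to-image mapping: 2D projection, triangulation-based linear
# interpolation onto a 64 x 64 pixel grid, Gaussian space-time smoothing,
# temporal masking.

#' Project 3D sensor positions onto the scalp plane
#'
#' Azimuthal-equidistant projection about the vertex (radius proportional to
#' the great-circle arc from the vertex), rescaled so the outermost sensor
#' lies at `extent_mm`; the vertex maps to the origin.  An orthographic
#' alternative is available.
#'
#' @param layout `sensor_layout`.
#' @param method `"azimuthal"` (equidistant, default) or `"orthographic"`.
#' @param extent_mm radius assigned to the outermost sensor; the default
#'   90 mm keeps the whole array inside a 64-pixel grid of 3 mm pixels.
#' @return numeric matrix (channels x 2) of x/y positions in mm, with the
#'   applied radial scale factor in `attr(, "scale")`.
#' @export
project_sensors <- function(layout, method = c("azimuthal", "orthographic"),
                            extent_mm = 90) {
  stopifnot(inherits(layout, "sensor_layout"))
  method <- match.arg(method)
  p <- layout$positions_3d
  r <- sqrt(rowSums(p^2))
  theta <- acos(pmin(1, pmax(-1, p[, 3] / r)))
  phi <- atan2(p[, 2], p[, 1])
  rho <- switch(method, azimuthal = theta, orthographic = sin(theta))
  xy <- cbind(rho * cos(phi), rho * sin(phi))
  # vertex sensors (theta == 0) have undefined phi; they map to the origin
  xy[theta < 1e-12, ] <- 0
  sv <- svd(scale(xy, scale = FALSE))$d
  if (nrow(xy) < 3 || sv[2] < 1e-9 * max(sv[1], 1e-300)) {
    stop_("degenerate (collinear) sensor layout cannot be projected")
  }
  scl <- extent_mm / max(sqrt(rowSums(xy^2)))
  out <- xy * scl
  colnames(out) <- c("x_mm", "y_mm")
  rownames(out) <- layout$channel_ids
  attr(out, "scale") <- scl
  out
}

# --- Delaunay triangulation (Bowyer-Watson), for the interpolation mesh ---

tri_circumcircle <- function(p, tri) {
  a <- p[tri[, 1], , drop = FALSE]; b <- p[tri[, 2], , drop = FALSE]
  c_ <- p[tri[, 3], , drop = FALSE]
  d <- 2 * (a[, 1] * (b[, 2] - c_[, 2]) + b[, 1] * (c_[, 2] - a[, 2]) +
              c_[, 1] * (a[, 2] - b[, 2]))
  a2 <- rowSums(a^2); b2 <- rowSums(b^2); c2 <- rowSums(c_^2)
  ux <- (a2 * (b[, 2] - c_[, 2]) + b2 * (c_[, 2] - a[, 2]) +
           c2 * (a[, 2] - b[, 2])) / d
  uy <- (a2 * (c_[, 1] - b[, 1]) + b2 * (a[, 1] - c_[, 1]) +
           c2 * (b[, 1] - a[, 1])) / d
  cbind(ux, uy, (ux - a[, 1])^2 + (uy - a[, 2])^2)
}

# Delaunay triangulation of 2D points; returns an (m x 3) index matrix.
# A deterministic sub-micrometre jitter guards against exactly cocircular
# quadruples without affecting interpolation beyond ~1e-7 relative error.
delaunay_triangulate <- function(pts) {
  n <- nrow(pts)
  if (n < 3) stop_("triangulation needs at least 3 points")
  span <- max(apply(pts, 2, function(v) diff(range(v))), 1e-12)
  jit <- ((seq_len(n) * 2654435761) %% 1000003) / 1000003 - 0.5
  jit2 <- ((seq_len(n) * 1013904223) %% 1000033) / 1000033 - 0.5
  p <- pts + 1e-7 * span * cbind(jit, jit2)
  ctr <- colMeans(p)
  rad <- 20 * max(sqrt(rowSums(sweep(p, 2, ctr)^2)), span)
  super <- rbind(ctr + rad * c(0, 2), ctr + rad * c(-1.8, -1),
                 ctr + rad * c(1.8, -1))
  p <- rbind(p, super)
  tri <- matrix(n + 1:3, 1, 3)
  cc <- tri_circumcircle(p, tri)
  for (i in seq_len(n)) {
    inside <- (p[i, 1] - cc[, 1])^2 + (p[i, 2] - cc[, 2])^2 <= cc[, 3] * (1 + 1e-12)
    bad <- tri[inside, , drop = FALSE]
    edges <- rbind(bad[, c(1, 2)], bad[, c(2, 3)], bad[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    boundary <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    new_tri <- cbind(boundary, i)
    tri <- rbind(tri[!inside, , drop = FALSE], new_tri)
    cc <- rbind(cc[!inside, , drop = FALSE], tri_circumcircle(p, new_tri))
  }
  keep <- apply(tri <= n, 1, all)
  tri[keep, , drop = FALSE]
}

#' Build a linear sensor-to-pixel interpolator
#'
#' Delaunay-triangulates the projected sensor positions and precomputes
#' barycentric interpolation weights for every pixel centre of an
#' `grid_n x grid_n` grid of `pixel_mm` pixels centred on the projection
#' origin.  Pixels outside the sensor convex hull are marked invalid.
#' Because the interpolation is piecewise linear with sensor-vertex nodes,
#' constant and affine sensor fields are reproduced exactly.
#'
#' @param positions_2d (channels x 2) matrix in mm, from [project_sensors()].
#' @param grid_n grid size (default 64).
#' @param pixel_mm pixel size in mm (default 3).
#' @return list of class `scalp_interpolator`: `weights` (pixels x
#'   channels), `mask` (grid_n x grid_n logical), `coords_mm`, `grid_n`,
#'   `pixel_mm`.
#' @export
build_interpolator <- function(positions_2d, grid_n = 64L, pixel_mm = 3) {
  pos <- as.matrix(positions_2d)
  if (nrow(pos) < 3) stop_("interpolation needs at least 3 sensors")
  sv <- svd(scale(pos, scale = FALSE))$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-300)) stop_("sensors are collinear")
  tri <- delaunay_triangulate(pos)
  ax <- (seq_len(grid_n) - (grid_n + 1) / 2) * pixel_mm
  px <- rep(ax, times = grid_n); py <- rep(ax, each = grid_n)
  npix <- grid_n^2
  W <- matrix(0, npix, nrow(pos))
  assigned <- rep(FALSE, npix)
  for (k in seq_len(nrow(tri))) {
    a <- pos[tri[k, 1], ]; b <- pos[tri[k, 2], ]; c_ <- pos[tri[k, 3], ]
    det <- (b[1] - a[1]) * (c_[2] - a[2]) - (c_[1] - a[1]) * (b[2] - a[2])
    if (abs(det) < 1e-12) next
    l1 <- ((b[2] - c_[2]) * (px - c_[1]) + (c_[1] - b[1]) * (py - c_[2])) / det
    l2 <- ((c_[2] - a[2]) * (px - c_[1]) + (a[1] - c_[1]) * (py - c_[2])) / det
    l3 <- 1 - l1 - l2
    hit <- !assigned & l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    if (any(hit)) {
      W[hit, tri[k, 1]] <- l1[hit]
      W[hit, tri[k, 2]] <- l2[hit]
      W[hit, tri[k, 3]] <- l3[hit]
      assigned[hit] <- TRUE
    }
  }
  structure(list(weights = W, mask = matrix(assigned, grid_n, grid_n),
                 coords_mm = ax, grid_n = as.integer(grid_n),
                 pixel_mm = pixel_mm, triangles = tri),
            class = "scalp_interpolator")
}

#' Construct a scalp image volume
#'
#' @param values numeric array (grid_n x grid_n x T); NA outside the mask.
#' @param mask logical (grid_n x grid_n), constant over time.
#' @param coords_mm pixel-centre coordinates along each spatial axis (mm).
#' @param time_ms frame times (ms).
#' @param pixel_mm pixel size (mm).
#' @return object of class `scalp_image`.
#' @export
scalp_image <- function(values, mask, coords_mm, time_ms, pixel_mm = 3) {
  stopifnot(length(dim(values)) == 3L, dim(values)[3] == length(time_ms),
            all(dim(values)[1:2] == dim(mask)))
  if (any(!is.finite(values[array(mask, dim(values))]))) {
    stop_("scalp image contains non-finite values inside the mask")
  }
  structure(list(values = values, mask = mask, coords_mm = coords_mm,
                 time_ms = as.numeric(time_ms), pixel_mm = pixel_mm,
                 time_step = if (length(time_ms) > 1) diff(time_ms[1:2]) else NA_real_),
            class = "scalp_image")
}

#' @export
print.scalp_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Scalp image: %d x %d px (%g mm) x %d frames; %d valid pixels\n",
              d[1], d[2], x$pixel_mm, d[3], sum(x$mask)))
  invisible(x)
}

#' Rasterize sensor values onto the pixel grid
#'
#' @param values_at_sensors numeric vector (channels) or matrix
#'   (channels x frames).
#' @param interpolator from [build_interpolator()].
#' @param time_ms frame times; defaults to frame index.
#' @return a `scalp_image` (single- or multi-frame).
#' @export
rasterize <- function(values_at_sensors, interpolator, time_ms = NULL) {
  stopifnot(inherits(interpolator, "scalp_interpolator"))
  v <- if (is.matrix(values_at_sensors)) values_at_sensors else
    matrix(values_at_sensors, ncol = 1L)
  if (nrow(v) != ncol(interpolator$weights)) {
    stop_("got %d sensor values for %d channels", nrow(v),
          ncol(interpolator$weights))
  }
  img <- interpolator$weights %*% v
  img[!interpolator$mask, ] <- NA_real_
  g <- interpolator$grid_n
  if (is.null(time_ms)) time_ms <- seq_len(ncol(v))
  scalp_image(array(img, c(g, g, ncol(v))), interpolator$mask,
              interpolator$coords_mm, time_ms, interpolator$pixel_mm)
}

gauss_kernel_matrix <- function(coords, sd) {
  if (sd <= 0) stop_("smoothing FWHM must be positive")
  K <- exp(-outer(coords, coords, "-")^2 / (2 * sd^2))
  K[K < exp(-8)] <- 0 # truncate at 4 SD
  K
}

#' Gaussian space-time smoothing of a scalp image
#'
#' Separable Gaussian smoothing with `SD = FWHM / 2.3548` per axis.  At the
#' sensor-hull boundary (and the first/last frames) the kernel is
#' renormalized over valid pixels, so constant images are left unchanged.
#'
#' @param image `scalp_image`.
#' @param fwhm length-3: spatial FWHM (mm, x and y) and temporal FWHM (ms).
#' @return smoothed `scalp_image`.
#' @export
smooth_scalp <- function(image, fwhm = c(8, 8, 8)) {
  stopifnot(inherits(image, "scalp_image"))
  if (any(fwhm <= 0)) stop_("smoothing FWHM must be positive")
  sds <- fwhm / (2 * sqrt(2 * log(2)))
  g <- dim(image$values)[1]; T_ <- dim(image$values)[3]
  Kx <- gauss_kernel_matrix(image$coords_mm, sds[1])
  Ky <- gauss_kernel_matrix(image$coords_mm, sds[2])
  m <- image$mask * 1
  vals <- image$values
  vals[is.na(vals)] <- 0
  vals <- vals * array(m, dim(vals))
  norm_sp <- Kx %*% m %*% Ky # same for all frames
  # separable spatial pass over all frames at once
  dim(vals) <- c(g, g * T_)
  vals <- Kx %*% vals
  dim(vals) <- c(g, g, T_)
  vals <- aperm(vals, c(2, 1, 3))
  dim(vals) <- c(g, g * T_)
  vals <- Ky %*% vals # Ky symmetric
  dim(vals) <- c(g, g, T_)
  out <- aperm(vals, c(2, 1, 3)) / array(norm_sp, c(g, g, T_))
  if (T_ > 1) {
    Kt <- gauss_kernel_matrix(image$time_ms, sds[3])
    norm_t <- colSums(Kt)
    flat <- matrix(out, g * g, T_)
    flat <- sweep(flat %*% Kt, 2, norm_t, "/")
    out <- array(flat, dim(vals))
  }
  out[!array(image$mask, dim(out))] <- NA_real_
  scalp_image(out, image$mask, image$coords_mm, image$time_ms, image$pixel_mm)
}

#' Restrict a scalp image to a time window
#'
#' @param image `scalp_image`.
#' @param window length-2 window `(t_min, t_max)` in ms, inclusive.
#' @return `scalp_image` containing only frames inside the window.
#' @export
temporal_mask <- function(image, window = c(100, 600)) {
  stopifnot(inherits(image, "scalp_image"))
  if (window[1] > window[2]) stop_("empty time window [%g, %g]", window[1], window[2])
  keep <- image$time_ms >= window[1] - 1e-9 & image$time_ms <= window[2] + 1e-9
  if (!any(keep)) stop_("no frames inside [%g, %g] ms", window[1], window[2])
  scalp_image(image$values[, , keep, drop = FALSE], image$mask,
              image$coords_mm, image$time_ms[keep], image$pixel_mm)
}

#' Scalp image volumes for every condition of an evoked set
#'
#' Projects the layout, builds the interpolator once, rasterizes every
#' frame of every condition average, smooths, and applies the temporal mask.
#'
#' @param evoked an `evoked_set` from [average_conditions()].
#' @param grid_n,pixel_mm grid geometry.
#' @param fwhm space-time smoothing FWHM (mm, mm, ms); `NULL` skips.
#' @param window temporal mask in ms; `NULL` skips.
#' @param interpolator optional precomputed [build_interpolator()] result.
#' @return list of `scalp_image`, one per condition row of
#'   `evoked$conditions`, with the conditions table as attribute
#'   `"conditions"`.
#' @export
sensor_maps <- function(evoked, grid_n = 64L, pixel_mm = 3, fwhm = c(8, 8, 8),
                        window = c(100, 600), interpolator = NULL) {
  stopifnot(inherits(evoked, "evoked_set"))
  if (is.null(interpolator)) {
    pos <- project_sensors(evoked$layout)
    interpolator <- build_interpolator(pos, grid_n, pixel_mm)
  }
  imgs <- vector("list", nrow(evoked$conditions))
  for (i in seq_along(imgs)) {
    img <- rasterize(matrix(evoked$data[i, , ], dim(evoked$data)[2]),
                     interpolator, evoked$time_ms)
    if (!is.null(fwhm)) img <- smooth_scalp(img, fwhm)
    if (!is.null(window)) img <- temporal_mask(img, window)
    imgs[[i]] <- img
  }
  names(imgs) <- condition_key(evoked$conditions$outcome_valence,
                               evoked$conditions$outcome_prob)
  attr(imgs, "conditions") <- evoked$conditions
  imgs
}
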