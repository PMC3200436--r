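test_that("sensor projection fixes the vertex and preserves symmetries", {
  # explicit sphere: vertex, two mirror-symmetric points, two equal-polar
  ang <- rbind(c(0, 0), c(50, 30), c(50, 150), c(70, 10), c(70, 200),
               c(30, 260), c(80, 90))
  th <- ang[, 1] * pi / 180; ph <- ang[, 2] * pi / 180
  pos <- 0.1 * cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  lay <- sensor_layout(sprintf("S%d", 1:7), pos)
  xy <- project_sensors(lay)
  expect_equal(unname(xy[1, ]), c(0, 0))
  # mirror pair (equal theta, phi and 180 - phi): x flips, y matches
  expect_equal(xy[2, "y_mm"], xy[3, "y_mm"], tolerance = 1e-9)
  expect_equal(xy[2, "x_mm"], -xy[3, "x_mm"], tolerance = 1e-9)
  # equal polar angle -> equal radius (azimuthal-equidistant property)
  r <- sqrt(rowSums(xy^2))
  expect_equal(unname(r[4]), unname(r[5]), tolerance = 1e-9)
  expect_lt(r[6], r[2]) # smaller polar angle, smaller radius
  expect_equal(max(r), 90) # outermost sensor scaled to the grid extent
})

test_that("collinear layouts cannot be projected or rasterized", {
  pos <- cbind(seq(0.01, 0.05, length.out = 5), 0, 0.09)
  lay <- sensor_layout(sprintf("S%d", 1:5), pos)
  expect_error(project_sensors(lay), "collinear")
  xy <- cbind(1:5, 2 * (1:5))
  expect_error(build_interpolator(xy), "collinear")
  expect_error(build_interpolator(xy[1:2, ]), "at least 3")
})

test_that("rasterization reproduces constant and affine sensor fields", {
  lay <- small_layout(60)
  pos <- project_sensors(lay)
  itp <- build_interpolator(pos)
  # constant field
  img <- rasterize(rep(2.5, 60), itp)
  expect_equal(max(abs(img$values[, , 1] - 2.5), na.rm = TRUE), 0,
               tolerance = 1e-9)
  expect_true(all(is.na(img$values[, , 1][!itp$mask])))
  # affine field a*x + b*y + c
  v <- 0.7 * pos[, 1] - 1.3 * pos[, 2] + 4
  img2 <- rasterize(v, itp)
  truth <- outer(0.7 * itp$coords_mm, -1.3 * itp$coords_mm, "+") + 4
  err <- abs(img2$values[, , 1] - truth)
  expect_lt(max(err[itp$mask], na.rm = TRUE), 1e-4)
  # a pixel whose centre is close to a sensor takes a nearby value
  set.seed(10)
  f <- rnorm(60)
  img3 <- rasterize(f, itp)
  ix <- which.min(abs(itp$coords_mm - pos[1, 1]))
  iy <- which.min(abs(itp$coords_mm - pos[1, 2]))
  expect_lt(abs(img3$values[ix, iy, 1] - f[1]), max(abs(diff(range(f)))) * 0.5)
})

test_that("smoothing preserves constants, mass, and the nominal FWHM", {
  lay <- small_layout(80)
  itp <- build_interpolator(project_sensors(lay))
  tms <- seq(0, 100, by = 5)
  # constant volume unchanged (mask-renormalized kernel)
  cimg <- rasterize(matrix(3, 80, length(tms)), itp, tms)
  expect_equal(max(abs(smooth_scalp(cimg)$values - 3), na.rm = TRUE), 0,
               tolerance = 1e-9)
  # interior impulse: measure FWHM by interpolated half-maximum crossings
  v <- array(0, c(64, 64, length(tms)))
  v[array(!itp$mask, dim(v))] <- NA
  v[32, 32, 11] <- 1
  im <- scalp_image(v, itp$mask, itp$coords_mm, tms)
  sm <- smooth_scalp(im, c(8, 8, 8))
  fwhm_of <- function(prof, step) {
    prof[is.na(prof)] <- 0
    hm <- max(prof) / 2
    i <- which.max(prof)
    left <- max(which(prof[1:i] <= hm))
    right <- i - 1 + min(which(prof[i:length(prof)] <= hm))
    xl <- left + (hm - prof[left]) / (prof[left + 1] - prof[left])
    xr <- right - 1 + (hm - prof[right - 1]) / (prof[right] - prof[right - 1])
    (xr - xl) * step
  }
  expect_equal(fwhm_of(sm$values[, 32, 11], 3), 8, tolerance = 0.5 * 3 / 8)
  expect_equal(fwhm_of(sm$values[32, , 11], 3), 8, tolerance = 0.5 * 3 / 8)
  expect_equal(fwhm_of(sm$values[32, 32, ], 5), 8, tolerance = 0.5 * 5 / 8)
  # mass conservation away from the mask edge
  expect_equal(sum(sm$values[20:44, 20:44, 8:14], na.rm = TRUE), 1,
               tolerance = 0.01)
  # linearity: scaling and constant shifts commute with smoothing
  set.seed(11)
  f <- matrix(rnorm(80 * 3), 80, 3)
  a <- smooth_scalp(rasterize(f, itp, 1:3))$values
  b <- smooth_scalp(rasterize(3 * f + 2, itp, 1:3))$values
  expect_equal(b, 3 * a + 2, tolerance = 1e-9)
  expect_error(smooth_scalp(cimg, c(0, 8, 8)), "positive")
})

test_that("the temporal mask keeps exactly the in-window frames", {
  lay <- small_layout(30)
  itp <- build_interpolator(project_sensors(lay))
  tms <- epoch_time_axis(200, -160, 700)
  img <- rasterize(matrix(rnorm(30 * length(tms)), 30), itp, tms)
  masked <- temporal_mask(img, c(100, 600))
  expect_equal(dim(masked$values)[3], 101L)
  expect_equal(range(masked$time_ms), c(100, 600))
  full <- temporal_mask(img, range(tms))
  expect_equal(full$values, img$values)
  expect_error(temporal_mask(img, c(700, 100)), "empty")
  expect_error(temporal_mask(img, c(900, 950)), "no frames")
})

test_that("the sensor-to-image chain is deterministic", {
  lay <- small_layout(50)
  d <- build_session_design(c("0" = 4, "0.25" = 8, "0.5" = 4, "0.75" = 8,
                              "1" = 4), n_blocks = 1, seed = 2)
  ns <- noise_spec(white_sd = 2e-13, seed = 3)
  ep <- simulate_evoked(d, default_components(), lay, ns, 200)
  ev <- average_conditions(ep)
  m1 <- sensor_maps(ev, fwhm = c(8, 8, 8), window = c(100, 600))
  m2 <- sensor_maps(ev, fwhm = c(8, 8, 8), window = c(100, 600))
  expect_identical(m1[[1]]$values, m2[[1]]$values)
})
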