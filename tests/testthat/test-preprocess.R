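test_that("amplitude rejection removes exactly the offending trials", {
  lay <- small_layout(6)
  set.seed(3)
  x <- array(rnorm(10 * 6 * 50, sd = 1e-13), c(10, 6, 50))
  ep <- make_epochs(x, 200, 0, lay)
  res <- reject_amplitude(ep, 1.5e-10)
  expect_equal(sum(res$rejected), 0L)
  x2 <- x; x2[4, 2, 10] <- 3e-10
  res2 <- reject_amplitude(make_epochs(x2, 200, 0, lay), 1.5e-10)
  expect_equal(which(res2$rejected), 4L)
  expect_equal(dim(res2$epochs$data)[1], 9L)
  expect_equal(nrow(res2$epochs$trials), 9L)
  expect_error(reject_amplitude(make_epochs(x2 * 1e5, 200, 0, lay), 1.5e-10),
               "review")
})

test_that("injected jumps are flagged and rejected at the same fraction", {
  lay <- small_layout(25)
  d <- build_session_design(c("0.5" = 200), n_blocks = 1, seed = 8)
  ns <- noise_spec(white_sd = 1e-13, pink_sd = 0, blink_rate = 0,
                   jump_rate = 0.05, jump_amplitude = 3e-10, seed = 8)
  ep <- inject_artifacts(simulate_evoked(d, list(), lay, ns, 200), ns)
  res <- reject_amplitude(ep, 1.5e-10) # jumps sit at 2x the threshold
  expect_setequal(which(res$rejected), ep$artifacts$jump_trials)
})

test_that("blink projector recovers the injected spatial pattern", {
  lay <- small_layout(30)
  d <- build_session_design(c("0.5" = 150), n_blocks = 1, seed = 9)
  ns <- noise_spec(white_sd = 3e-14, pink_sd = 0, blink_rate = 0.25,
                   blink_amplitude = 3e-11, jump_rate = 0, seed = 9)
  ep <- inject_artifacts(
    simulate_evoked(d, list(valence_component(gain_win = 1, gain_loss = 0.6,
                                              amplitude = 1e-12)), lay, ns, 200),
    ns)
  w <- axiomerf:::blink_topography(lay)
  bc <- lay$channel_ids[which.max(w)]
  op <- fit_blink_projector(ep, bc, k = 1L)
  cosine <- abs(sum(op$basis[, 1] * w) / sqrt(sum(w^2)))
  expect_gt(cosine, 0.99)
  # blink-locked signal strongly suppressed, evoked response preserved
  proj <- apply_projection(ep, op)
  bt <- ep$artifacts$blink_trials
  rms <- function(a) sqrt(mean(a^2))
  blink_part <- function(e) {
    colMeans(e$data[bt, , , drop = FALSE], dims = 1) -
      colMeans(e$data[-bt, , , drop = FALSE], dims = 1)
  }
  expect_lt(rms(blink_part(proj)) / rms(blink_part(ep)), 0.1)
  clean_before <- colMeans(ep$data[-bt, , , drop = FALSE], dims = 1)
  clean_after <- colMeans(proj$data[-bt, , , drop = FALSE], dims = 1)
  expect_lt(rms(clean_after - clean_before) / rms(clean_before), 0.1)
})

test_that("projection operators behave like orthogonal projections", {
  lay <- small_layout(12)
  set.seed(4)
  B <- qr.Q(qr(matrix(rnorm(12 * 2), 12, 2)))
  op <- structure(list(basis = B, k = 2L, channel_ids = lay$channel_ids,
                       n_blinks = 5L), class = "projection_operator")
  # data orthogonal to the basis is untouched
  v <- rnorm(12); v <- v - B %*% (t(B) %*% v)
  x <- array(rep(v, times = 20), c(1, 12, 20))
  x <- aperm(array(rep(v, 20), c(12, 20, 1)), c(3, 1, 2))
  ep <- make_epochs(x, 200, 0, lay)
  expect_equal(apply_projection(ep, op)$data, ep$data, tolerance = 1e-12)
  # data inside the basis is zeroed
  xb <- aperm(array(rep(B[, 1], 20), c(12, 20, 1)), c(3, 1, 2))
  epb <- make_epochs(xb, 200, 0, lay)
  expect_equal(max(abs(apply_projection(epb, op)$data)), 0, tolerance = 1e-12)
  # idempotence on arbitrary data
  set.seed(5)
  er <- make_epochs(array(rnorm(3 * 12 * 20), c(3, 12, 20)), 200, 0, lay)
  once <- apply_projection(er, op)
  twice <- apply_projection(once, op)
  expect_equal(twice$data, once$data, tolerance = 1e-12)
  # k = 0 gives the identity; blink-free data gives a detection error
  op0 <- fit_blink_projector(er, lay$channel_ids[1], k = 0L)
  expect_equal(apply_projection(er, op0)$data, er$data)
  const <- make_epochs(array(0, c(3, 12, 400)), 200, 0, lay)
  expect_error(fit_blink_projector(const, lay$channel_ids[1], k = 4L),
               "blink")
})

test_that("re-referencing subtracts the reference mean", {
  lay <- eeg_sensor_layout()
  n_ch <- length(lay$channel_ids)
  set.seed(6)
  x <- array(rnorm(4 * n_ch * 30), c(4, n_ch, 30))
  tr <- build_session_design(c("1" = 4), 1, 1)
  ep <- epoched_data(x, 200, (0:29) * 5, tr, lay)
  rr <- rereference(ep, c("M1", "M2"))
  im <- match(c("M1", "M2"), lay$channel_ids)
  ref_after <- apply(rr$data[, im, ], c(1, 3), mean)
  expect_equal(max(abs(ref_after)), 0, tolerance = 1e-12)
  # zero reference channels leave everything unchanged
  x0 <- x; x0[, im, ] <- 0
  ep0 <- epoched_data(x0, 200, (0:29) * 5, tr, lay)
  expect_equal(rereference(ep0, c("M1", "M2"))$data, x0)
  # single constant reference shifts all channels by its value
  x1 <- x; x1[, im[1], ] <- 1
  ep1 <- epoched_data(x1, 200, (0:29) * 5, tr, lay)
  expect_equal(rereference(ep1, "M1")$data, x1 - 1)
  expect_error(rereference(ep, "Oz"), "not in layout")
})

test_that("robust averaging equals the arithmetic mean on clean data", {
  set.seed(7)
  x <- matrix(rnorm(50 * 20), 50, 20)
  ra <- robust_average(x)
  am <- colMeans(x)
  sem <- apply(x, 2, sd) / sqrt(50)
  expect_lt(max(abs(ra$average - am) / sem), 0.1)
  expect_true(all(ra$weights >= 0 & ra$weights <= 1))
  # identical trials: average equals the trial, all weights 1
  xi <- matrix(rep(sin(1:100), each = 5), 5, 100)
  ri <- robust_average(xi)
  expect_equal(ri$average, sin(1:100))
  expect_true(all(ri$weights == 1))
  # unit-weight mode reproduces the arithmetic mean exactly
  expect_identical(robust_average(x, force_unit_weights = TRUE)$average,
                   colMeans(x))
})

test_that("robust averaging down-weights a localized burst", {
  set.seed(8)
  n <- 40; S <- 120
  x <- array(rnorm(n * 1 * S), c(n, 1, S))
  burst <- 61:70
  x[7, 1, burst] <- x[7, 1, burst] + 20 # 20-SD burst on 10 samples
  ra <- robust_average(x)
  expect_lt(max(ra$weights[7, 1, burst]), 0.2)
  expect_gt(mean(ra$weights[7, 1, setdiff(1:S, 55:75)]), 0.8)
  # the burst barely moves the robust average
  expect_lt(max(abs(ra$average[1, burst])), 1.5)
})

test_that("robust location agrees with the Huber M-estimator", {
  set.seed(9)
  y <- c(rnorm(30), 8, 9) # two gross outliers
  ra <- robust_average(matrix(y, ncol = 1), method = "huber",
                       huber_k = 1.345, tol = 1e-9)
  hub <- MASS::huber(y, k = 1.345)
  expect_lt(abs(ra$average - hub$mu), 0.05)
  # and both sit well below the outlier-dragged arithmetic mean
  expect_lt(abs(ra$average - hub$mu), abs(mean(y) - hub$mu))
})

test_that("MAD = 0 with outliers falls back to a usable scale", {
  x <- matrix(c(rep(1, 9), 50), ncol = 1) # majority identical, one outlier
  ra <- suppressWarnings(robust_average(x))
  expect_lt(ra$weights[10, 1], 0.2)
  expect_lt(abs(ra$average - 1), 1.5)
})
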