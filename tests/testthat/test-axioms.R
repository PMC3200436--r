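test_that("window averaging behaves on constants, points, and ramps", {
  tms <- seq(0, 500, by = 5)
  arr <- array(7, c(3, 2, 4, length(tms)))
  w <- window_average(condition_waveforms(arr, tms), c(100, 300))
  expect_true(all(w == 7))
  # single-sample window returns that sample
  arr2 <- arr
  arr2[1, 1, 1, ] <- seq_along(tms)
  w2 <- window_average(condition_waveforms(arr2, tms), c(250, 250))
  expect_equal(w2[1, 1, 1], which(tms == 250))
  # linear ramp 0..100 over 0-500 ms: 200-300 ms window mean = 50
  ramp <- array(rep(seq(0, 100, length.out = length(tms)),
                    each = 3 * 2 * 4), c(3, 2, 4, length(tms)))
  w3 <- window_average(condition_waveforms(ramp, tms), c(200, 300))
  expect_equal(unname(w3[1, 1, 1]), 50, tolerance = 1e-9)
  expect_error(window_average(condition_waveforms(arr, tms), c(300, 100)),
               "empty")
})

test_that("repeated-measures ANOVA matches the sums-of-squares oracle", {
  # 3-subject toy table with all effects present
  means <- array(c(
    2.0, 2.5, 1.8,  1.0, 1.2, 0.9,   # win .25 | loss .25
    1.5, 2.0, 1.4,  1.1, 1.4, 1.0,   # win .50 | loss .50
    1.1, 1.5, 1.0,  1.2, 1.5, 1.1,   # win .75 | loss .75
    0.9, 1.2, 0.8,  0.9, 1.3, 0.8),  # win 1   | loss 1
    c(3, 2, 4))
  class(means) <- "condition_means"
  fit <- rm_anova_2x4(means)
  orc <- oracle_rm_anova(unclass(means))
  expect_equal(fit$valence$F, orc$valence, tolerance = 1e-10)
  expect_equal(fit$probability$F, orc$probability, tolerance = 1e-10)
  expect_equal(fit$interaction$F, orc$interaction, tolerance = 1e-10)
  expect_equal(fit$valence$df, c(1, 2))
  expect_equal(fit$interaction$df, c(3, 6))
})

test_that("degenerate condition-mean tables are handled gracefully", {
  flat <- array(3, c(4, 2, 4))
  class(flat) <- "condition_means"
  fit <- rm_anova_2x4(flat)
  expect_equal(fit$valence$F, 0)
  expect_equal(fit$interaction$F, 0)
  expect_equal(fit$linear_trend$F, 0)
  # pure valence effect without noise: interaction zero, valence degenerate
  pv <- pattern_means(4, function(p) rep(1, 4), function(p) rep(-1, 4))
  fit2 <- rm_anova_2x4(pv)
  expect_equal(fit2$interaction$F, 0)
  expect_true(is.infinite(fit2$valence$F) && fit2$valence$degenerate)
  expect_equal(fit2$valence$p, 0)
})

test_that("ANOVA F is shift-invariant and p-values scale-invariant", {
  set.seed(16)
  m <- pattern_means(6, function(p) 1 - p, function(p) p - 1, noise_sd = 0.3)
  f0 <- rm_anova_2x4(m)
  m_shift <- m + 11.3
  class(m_shift) <- "condition_means"
  f1 <- rm_anova_2x4(m_shift)
  expect_equal(f1$valence$F, f0$valence$F, tolerance = 1e-8)
  expect_equal(f1$interaction$F, f0$interaction$F, tolerance = 1e-8)
  m_scale <- m * 7.7
  class(m_scale) <- "condition_means"
  f2 <- rm_anova_2x4(m_scale)
  expect_equal(f2$interaction$p, f0$interaction$p, tolerance = 1e-8)
  expect_equal(f2$linear_trend$p, f0$linear_trend$p, tolerance = 1e-8)
})

test_that("prediction-error-patterned means are graded compliant", {
  # gains +/- beta (1 - P): opposite slopes, zero at P = 1
  for (beta in c(0.5, 2)) {
    for (sd_n in c(0.01, 0.05)) {
      m <- pattern_means(17, function(p) beta * (1 - p),
                         function(p) -beta * (1 - p),
                         noise_sd = sd_n * beta, seed = 100 + beta * 10 + sd_n)
      rep_ <- axiom_compliance(m)
      expect_equal(rep_$overall, "compliant")
      expect_lt(rep_$axiom2$win_slope, 0)  # decreasing in probability
      expect_gt(rep_$axiom2$loss_slope, 0)
      expect_true(rep_$axiom2$sign_opposition)
    }
  }
})

test_that("same-signed probability slopes violate axiom 2", {
  # both valences increase with probability, equal at P = 1 (the scalp-
  # potential pattern); the difference wave still shrinks with P
  m <- pattern_means(17, function(p) 2 + 1.5 * p, function(p) 0.5 + 3 * p,
                     noise_sd = 0.05, seed = 21)
  rep_ <- axiom_compliance(m)
  expect_false(rep_$axiom2$sign_opposition)
  expect_false(rep_$axiom2$pass)
  expect_equal(rep_$overall, "violated")
  # identical means everywhere: axiom 1 fails, overall violated
  flat <- array(1, c(17, 2, 4))
  class(flat) <- "condition_means"
  rep_flat <- axiom_compliance(flat)
  expect_false(rep_flat$axiom1$pass)
  expect_equal(rep_flat$overall, "violated")
})

test_that("a strong P = 1 difference fails the equivalence axiom", {
  m <- pattern_means(17, function(p) 1 - p + 2, function(p) p - 1,
                     noise_sd = 0.02, seed = 22) # constant +2 offset for wins
  rep_ <- axiom_compliance(m)
  expect_false(rep_$axiom3$pass)
  expect_equal(rep_$overall, "violated")
  # the optional equivalence bound tightens axiom 3
  m2 <- pattern_means(17, function(p) 1 - p, function(p) p - 1,
                      noise_sd = 0.02, seed = 23)
  r_wide <- axiom_compliance(m2, equivalence_bound = 0.5)
  expect_true(r_wide$axiom3$pass)
  r_narrow <- axiom_compliance(m2, equivalence_bound = 1e-4)
  expect_false(r_narrow$axiom3$pass)
})

test_that("FRN difference waves localize injected negativities", {
  tms <- seq(-100, 695, by = 5)
  S <- 6
  arr <- array(0, c(S, 2, 4, length(tms)))
  # loss-only negativity at 270 ms scaling with 1 - P
  kern <- -exp(-(tms - 270)^2 / (2 * 30^2))
  for (s in seq_len(S)) for (p in 1:4) {
    arr[s, 2, p, ] <- kern * (1 - c(.25, .5, .75, 1)[p])
  }
  fr <- frn_difference(condition_waveforms(arr, tms), c(0, 600))
  expect_true(all(abs(fr$latency_ms[, 1:3] - 270) <= 5))
  expect_equal(unname(fr$amplitude[1, ]), c(-0.75, -0.5, -0.25, 0),
               tolerance = 1e-6)
  # loss == win gives an identically zero FRN
  z <- array(1, c(S, 2, 4, length(tms)))
  fz <- frn_difference(condition_waveforms(z, tms))
  expect_true(all(fz$amplitude == 0))
  # antisymmetry: swapping win and loss negates the difference wave
  set.seed(24)
  r <- array(rnorm(S * 2 * 4 * length(tms)), c(S, 2, 4, length(tms)))
  fr1 <- frn_difference(condition_waveforms(r, tms))
  r_sw <- r[, 2:1, , , drop = FALSE]
  fr2 <- frn_difference(condition_waveforms(r_sw, tms))
  # min of -d equals -max of d; at least the extreme magnitudes agree
  d <- r[1, 2, 1, tms >= 0 & tms <= 600] - r[1, 1, 1, tms >= 0 & tms <= 600]
  expect_equal(fr1$amplitude[1, 1], min(d))
  expect_equal(fr2$amplitude[1, 1], -max(d))
})

test_that("FRN magnitude shrinks with probability under a PE pattern", {
  tms <- seq(-100, 695, by = 5)
  S <- 17
  set.seed(25)
  kern <- exp(-(tms - 300)^2 / (2 * 40^2))
  arr <- array(rnorm(S * 2 * 4 * length(tms), sd = 0.15),
               c(S, 2, 4, length(tms)))
  for (s in seq_len(S)) for (p in 1:4) {
    pe <- (1 - c(.25, .5, .75, 1)[p])
    arr[s, 1, p, ] <- arr[s, 1, p, ] + pe * kern   # win positive
    arr[s, 2, p, ] <- arr[s, 2, p, ] - pe * kern   # loss negative
  }
  fr <- frn_difference(condition_waveforms(arr, tms), c(0, 600))
  mag <- colMeans(fr$amplitude)
  expect_true(all(diff(mag) > 0)) # strictly less negative as P grows
  expect_lt(fr$linear_trend_p, 0.05)
  expect_lt(fr$probability_p, 0.05)
})

test_that("sphericity correction and Holm adjustment behave as options", {
  set.seed(30)
  m <- pattern_means(10, function(p) 1 - p, function(p) p - 1, noise_sd = 0.3)
  f <- rm_anova_2x4(m, gg_correction = TRUE)
  # epsilon bounded by 1/(K-1) and 1 for a 4-level factor
  expect_gte(f$gg$interaction$epsilon, 1 / 3)
  expect_lte(f$gg$interaction$epsilon, 1)
  # for a clearly significant effect the corrected p is no smaller
  expect_gte(f$gg$interaction$p, f$interaction$p - 1e-12)
  raw <- axiom_compliance(m)
  holm <- axiom_compliance(m, p_adjust = "holm")
  expect_true(all(holm$axiom1$tests[, "p"] >= raw$axiom1$tests[, "p"] - 1e-12))
  expect_true(all(holm$adjacent_tests[, "p"] >= raw$adjacent_tests[, "p"] - 1e-12))
})
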