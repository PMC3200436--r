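test_that("the ANCOVA design encodes centred probability modulators", {
  des <- build_design(17)
  expect_equal(nrow(des$X), 136L)
  win_rows <- des$rows$outcome_valence == "win"
  # centred win modulator over win rows: [1.5, .5, -.5, -1.5] per subject
  expect_equal(unname(des$X[win_rows, "win_prob"][1:4]),
               c(1.5, 0.5, -0.5, -1.5))
  expect_equal(sum(des$X[, "win_prob"]), 0)
  expect_equal(sum(des$X[, "loss_prob"]), 0)
  # modulators vanish off their own condition rows
  expect_true(all(des$X[!win_rows, "win_prob"] == 0))
  # win/loss indicators are disjoint
  expect_true(all(des$X[, "win"] * des$X[, "loss"] == 0))
  expect_equal(des$modulator_codes[1:4], c(4, 3, 2, 1))
})

test_that("identical win and loss images give a zero valence contrast", {
  S <- 5
  des <- build_design(S)
  set.seed(12)
  base <- matrix(rnorm(S * 30), S, 30)
  Y <- base[rep(seq_len(S), each = 8), ] # same image for all 8 conditions
  sm <- fit_and_contrast(Y, des, c(1, -1, 0, 0))
  expect_lt(max(sm$F), 1e-18)
  sm_i <- fit_and_contrast(Y, des, c(0, 0, 1, -1))
  expect_lt(max(sm_i$F), 1e-18)
})

test_that("F statistics match the projection-matrix oracle", {
  set.seed(13)
  for (rep_i in 1:20) {
    S <- sample(4:7, 1)
    des <- build_design(S)
    Y <- matrix(rnorm(8 * S * 48), 8 * S, 48) # 4 x 4 x 3 voxel volume
    for (con in list(c(1, -1, 0, 0), c(0, 0, 1, 1), c(0, 0, 1, -1))) {
      sm <- fit_and_contrast(Y, des, con)
      orc <- oracle_F(Y, des$X, con)
      expect_lt(max(abs(sm$F - orc$F) / pmax(orc$F, 0.01)), 1e-8)
      expect_equal(sm$df, orc$df)
    }
  }
})

test_that("rank-deficient designs are rejected with the offending columns", {
  X <- cbind(a = rep(1, 8), b = rep(1:2, 4), c = rep(1, 8))
  expect_error(fit_and_contrast(matrix(rnorm(8 * 4), 8), X, c(1, 0, 0)),
               "rank deficient")
})

test_that("row permutations leave the F map unchanged", {
  S <- 6
  des <- build_design(S)
  set.seed(14)
  Y <- matrix(rnorm(8 * S * 20), 8 * S, 20)
  perm <- sample(nrow(Y))
  des_p <- des
  des_p$X <- des$X[perm, , drop = FALSE]
  f1 <- fit_and_contrast(Y, des, c(0, 0, 1, -1))$F
  f2 <- fit_and_contrast(Y[perm, , drop = FALSE], des_p, c(0, 0, 1, -1))$F
  expect_equal(f1, f2, tolerance = 1e-9)
})

# minimal stat_map wrapper for clustering tests
toy_statmap <- function(Fvol, df = c(1, 20), coords = NULL, tms = NULL) {
  d <- dim(Fvol)
  structure(list(F = Fvol, df = df, contrast = matrix(1, 1, 1),
                 coords_mm = coords %||% ((seq_len(d[1]) - (d[1] + 1) / 2) * 3),
                 time_ms = tms %||% (seq_len(d[3]) * 5),
                 pixel_mm = 3),
            class = "stat_map")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("thresholding and clustering find constructed blobs", {
  vol <- array(0, c(20, 20, 10))
  tab0 <- threshold_and_cluster(toy_statmap(vol), 0.005, extent_min = 5)
  expect_equal(nrow(tab0), 0L)
  # one 150-voxel blob: 5 x 5 x 6 region
  vol[6:10, 6:10, 3:8] <- 50
  vol[8, 7, 5] <- 80
  tab <- threshold_and_cluster(toy_statmap(vol), 0.005, extent_min = 100)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$extent, 150L)
  expect_equal(tab$peak_F, 80)
  sm <- toy_statmap(vol)
  expect_equal(tab$x_mm, sm$coords_mm[8])
  expect_equal(tab$t_ms, sm$time_ms[5])
  # the same blob is dropped when the extent threshold exceeds its size
  expect_equal(nrow(threshold_and_cluster(toy_statmap(vol), 0.005,
                                          extent_min = 151)), 0L)
  # two diagonal-touching voxels connect under 26- but not 6-connectivity
  v2 <- array(0, c(6, 6, 3))
  v2[2, 2, 1] <- 50; v2[3, 3, 2] <- 50
  t26 <- threshold_and_cluster(toy_statmap(v2), 0.005, extent_min = 2,
                               connectivity = 26)
  t6 <- threshold_and_cluster(toy_statmap(v2), 0.005, extent_min = 2,
                              connectivity = 6)
  expect_equal(nrow(t26), 1L)
  expect_equal(nrow(t6), 0L)
})

# build a list of single-frame scalp images from a subjects x voxels matrix
image_list <- function(M, g = 8) {
  mask <- matrix(TRUE, g, g)
  lapply(seq_len(nrow(M)), function(i) {
    scalp_image(array(M[i, ], c(g, g, 1)), mask,
                (seq_len(g) - (g + 1) / 2) * 3, 0)
  })
}

test_that("the P = 1 equivalence mask excludes only truly different regions", {
  S <- 8; g <- 8
  set.seed(15)
  W <- matrix(rnorm(S * g * g), S)
  # identical win/loss: all-true mask, F = 0
  m_id <- equivalence_mask(image_list(W), image_list(W))
  expect_true(all(m_id$mask))
  expect_equal(max(m_id$F, na.rm = TRUE), 0)
  # a strong localized difference is excluded
  L <- W
  hot <- 1:5 # first five voxels (column-major corner)
  L[, hot] <- L[, hot] + 10
  m_hot <- equivalence_mask(image_list(W), image_list(L))
  expect_true(all(!m_hot$mask[, , 1][hot]))
  expect_true(mean(m_hot$mask[, , 1][-hot]) > 0.8)
  expect_error(equivalence_mask(image_list(W), image_list(W)[1:3]), "matched")
})

test_that("masking the interaction contrast can only prune clusters", {
  vol <- array(0, c(20, 20, 6))
  vol[3:8, 3:8, 2:5] <- 40
  vol[12:17, 12:17, 2:5] <- 40
  sm <- toy_statmap(vol)
  full <- threshold_and_cluster(sm, 0.005, extent_min = 50)
  mask <- array(TRUE, dim(vol))
  mask[12:17, 12:17, ] <- FALSE
  masked <- threshold_and_cluster(sm, 0.005, extent_min = 50, mask = mask)
  expect_equal(nrow(full), 2L)
  expect_equal(nrow(masked), 1L)
  expect_lte(sum(masked$extent), sum(full$extent))
})
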