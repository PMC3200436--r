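# Second-level mass-univariate ANCOVA over condition images: design with
# parametric probability modulators, F contrasts, peak/extent thresholding,
# and the fully-predicted-outcome equivalence mask.

#' Build the 2 x 4 ANCOVA design matrix
#'
#' One row per (subject, condition) image in canonical order (per subject:
#' win P = .25, .50, .75, 1, then loss).  Columns: win and loss indicators,
#' win- and loss-probability parametric modulators coded 4, 3, 2, 1 for
#' P = .25 .. 1 and mean-centred within their own condition rows, and
#' (optionally) subject block regressors, treatment-coded to keep the
#' design full rank.
#'
#' @param subjects number of subjects (>= 1).
#' @param include_subject_effects add subject block regressors (default TRUE).
#' @return list of class `glm_design`: `X`, `task_columns` (names of the 4
#'   task regressors), `rows` (data.frame subject/valence/probability),
#'   `modulator_codes` (raw values before centring).
#' @export
build_design <- function(subjects, include_subject_effects = TRUE) {
  stopifnot(subjects >= 1)
  cond <- canonical_conditions()
  rows <- do.call(rbind, lapply(seq_len(subjects), function(s) {
    cbind(subject = s, cond)
  }))
  win <- as.numeric(rows$outcome_valence == "win")
  loss <- as.numeric(rows$outcome_valence == "loss")
  codes <- 5 - rows$outcome_prob * 4 # .25 -> 4, .50 -> 3, .75 -> 2, 1 -> 1
  win_mod <- win * (codes - mean(codes[win == 1]))
  loss_mod <- loss * (codes - mean(codes[loss == 1]))
  X <- cbind(win = win, loss = loss, win_prob = win_mod, loss_prob = loss_mod)
  if (include_subject_effects && subjects > 1) {
    S <- stats::model.matrix(~ factor(rows$subject))[, -1, drop = FALSE]
    colnames(S) <- sprintf("subject%d", 2:subjects)
    X <- cbind(X, S)
  }
  structure(list(X = X, task_columns = c("win", "loss", "win_prob", "loss_prob"),
                 rows = rows, modulator_codes = codes),
            class = "glm_design")
}

# stack a list of scalp images into a rows x voxels matrix (valid voxels)
images_to_matrix <- function(images) {
  ref <- images[[1]]
  stopifnot(inherits(ref, "scalp_image"))
  voxmask <- array(ref$mask, dim(ref$values))
  Y <- t(vapply(images, function(im) {
    if (!identical(dim(im$values), dim(ref$values))) {
      stop_("scalp images have inconsistent dimensions")
    }
    im$values[voxmask]
  }, numeric(sum(voxmask))))
  list(Y = Y, ref = ref, voxmask = voxmask)
}

# place per-voxel statistics back into a (g x g x T) volume
vector_to_volume <- function(v, ref, voxmask) {
  vol <- array(NA_real_, dim(ref$values))
  vol[voxmask] <- v
  vol
}

#' Fit the mass-univariate GLM and compute an F contrast
#'
#' Ordinary least squares per voxel; the F statistic for the contrast is
#' computed in the standard extra-sum-of-squares form
#' `F = (Cb)' [C (X'X)^-1 C']^-1 (Cb) / (q * sigma^2)`.
#'
#' @param images list of `scalp_image`, one per design row (or a numeric
#'   matrix rows x voxels, in which case a plain matrix of F values is
#'   returned).
#' @param design a `glm_design` (or a plain design matrix).
#' @param contrast numeric contrast weights over the task columns (length 4
#'   for a `glm_design`; zero-padded over subject regressors), or a matrix
#'   with one contrast row each for multi-row F tests.
#' @return object of class `stat_map`: `F` volume (g x g x T, NA outside the
#'   sensor hull), `df`, `contrast`, `beta` (task-column estimates per
#'   voxel), plus grid/time metadata.
#' @export
fit_and_contrast <- function(images, design, contrast) {
  X <- if (inherits(design, "glm_design")) design$X else as.matrix(design)
  C_ <- if (is.matrix(contrast)) contrast else matrix(contrast, nrow = 1)
  if (ncol(C_) < ncol(X)) {
    C_ <- cbind(C_, matrix(0, nrow(C_), ncol(X) - ncol(C_)))
  }
  if (ncol(C_) != ncol(X)) stop_("contrast length exceeds design columns")

  plain_matrix <- is.matrix(images)
  if (plain_matrix) {
    Y <- images
    stack <- NULL
  } else {
    stack <- images_to_matrix(images)
    Y <- stack$Y
  }
  n <- nrow(Y); p <- ncol(X)
  if (n != nrow(X)) stop_("%d images for %d design rows", n, nrow(X))
  qrX <- qr(X)
  if (qrX$rank < p) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop_("design matrix is rank deficient; dependent column(s): %s",
          paste(dep, collapse = ", "))
  }
  XtX_inv <- chol2inv(chol(crossprod(X)))
  beta <- XtX_inv %*% crossprod(X, Y)
  res <- Y - X %*% beta
  df2 <- n - p
  CB <- C_ %*% beta
  M <- C_ %*% XtX_inv %*% t(C_)
  q <- nrow(C_)
  ssh <- colSums(CB * solve(M, CB)) # extra sum of squares for the contrast
  rss <- colSums(res^2)
  Fv <- (ssh / q) / (rss / df2)
  # numerically-zero numerators or denominators (relative to the data scale)
  eps <- 1e-12 * (colSums(Y^2) + .Machine$double.xmin)
  Fv[ssh < eps] <- 0
  Fv[rss < eps & ssh >= eps] <- Inf

  task_idx <- if (inherits(design, "glm_design")) {
    match(design$task_columns, colnames(X))
  } else seq_len(min(4, p))
  if (plain_matrix) {
    return(structure(list(F = Fv, df = c(q, df2), contrast = C_,
                          beta = beta[task_idx, , drop = FALSE]),
                     class = "stat_map"))
  }
  structure(list(F = vector_to_volume(Fv, stack$ref, stack$voxmask),
                 df = c(q, df2), contrast = C_,
                 beta = beta[task_idx, , drop = FALSE],
                 voxmask = stack$voxmask, mask = stack$ref$mask,
                 coords_mm = stack$ref$coords_mm,
                 time_ms = stack$ref$time_ms,
                 pixel_mm = stack$ref$pixel_mm),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("Mass-univariate F map: df = (%g, %g), max F = %.2f\n",
              x$df[1], x$df[2], suppressWarnings(max(x$F, na.rm = TRUE))))
  invisible(x)
}

neighbour_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dt = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  off <- switch(as.character(connectivity),
                "6" = off[rowSums(abs(off)) == 1, , drop = FALSE],
                "18" = off[rowSums(abs(off)) <= 2, , drop = FALSE],
                "26" = off,
                stop_("connectivity must be 6, 18 or 26"))
  # half the offsets suffice for pairwise unions
  off[off[, 3] > 0 | (off[, 3] == 0 & (off[, 2] > 0 | (off[, 2] == 0 & off[, 1] > 0))), ,
      drop = FALSE]
}

label_connected <- function(supra, connectivity = 26) {
  d <- dim(supra)
  idx <- which(supra)
  if (length(idx) == 0) return(list(labels = integer(0), idx = idx))
  lab_of <- array(0L, d)
  lab_of[idx] <- seq_along(idx)
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ai <- arrayInd(idx, d)
  for (k in seq_len(nrow(off <- neighbour_offsets(connectivity)))) {
    ni <- ai[, 1] + off[k, 1]; nj <- ai[, 2] + off[k, 2]; nt <- ai[, 3] + off[k, 3]
    ok <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2] & nt >= 1 & nt <= d[3]
    if (!any(ok)) next
    nlin <- ni[ok] + (nj[ok] - 1L) * d[1] + (nt[ok] - 1L) * d[1] * d[2]
    nb <- lab_of[nlin]
    src <- which(ok)[nb > 0L]
    nb <- nb[nb > 0L]
    for (m in seq_along(src)) {
      ra <- find(src[m]); rb <- find(nb[m])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  list(labels = match(roots, unique(roots)), idx = idx)
}

#' Threshold an F map and extract clusters
#'
#' Retains voxels whose F statistic exceeds the upper `alpha_peak` quantile
#' of the F(df) distribution, finds connected components in the
#' (x, y, t) volume, drops clusters below `extent_min` voxels, and reports
#' each surviving cluster's extent and peak (F, Z-equivalent, mm/ms
#' coordinates).
#'
#' @param statmap `stat_map` from [fit_and_contrast()].
#' @param alpha_peak peak-level threshold (default 0.005).
#' @param extent_min minimum cluster extent in voxels (default 100).
#' @param connectivity 6, 18 or 26 (default).
#' @param mask optional inclusive mask (logical volume or
#'   `equivalence_mask` result): voxels outside it are ignored.
#' @return `data.frame` of class `cluster_table` with columns `cluster_id`,
#'   `extent`, `peak_F`, `peak_Z`, `x_mm`, `y_mm`, `t_ms`; threshold
#'   metadata in attributes `alpha_peak`, `F_crit`, `extent_min`, `df`.
#'   An empty suprathreshold set gives a zero-row table.
#' @export
threshold_and_cluster <- function(statmap, alpha_peak = 0.005, extent_min = 100,
                                  connectivity = 26, mask = NULL) {
  stopifnot(inherits(statmap, "stat_map"))
  if (is.null(dim(statmap$F))) stop_("clustering needs a volume-valued stat map")
  F_crit <- stats::qf(1 - alpha_peak, statmap$df[1], statmap$df[2])
  supra <- !is.na(statmap$F) & statmap$F > F_crit
  if (!is.null(mask)) {
    mvol <- if (inherits(mask, "equivalence_mask")) mask$mask else mask
    if (!identical(dim(mvol), dim(supra))) stop_("inclusive mask dimensions differ")
    supra <- supra & mvol
  }
  lab <- label_connected(supra, connectivity)
  empty <- data.frame(cluster_id = integer(0), extent = integer(0),
                      peak_F = numeric(0), peak_Z = numeric(0),
                      x_mm = numeric(0), y_mm = numeric(0), t_ms = numeric(0))
  tab <- empty
  voxlist <- list()
  if (length(lab$idx) > 0) {
    ext <- tabulate(lab$labels)
    keep <- which(ext >= extent_min)
    if (length(keep) > 0) {
      d <- dim(statmap$F)
      voxl <- vector("list", length(keep))
      rowsl <- lapply(seq_along(keep), function(j) {
        vox <- lab$idx[lab$labels == keep[j]]
        voxl[[j]] <<- arrayInd(vox, d)
        Fv <- statmap$F[vox]
        pk <- vox[which.max(Fv)]
        ac <- arrayInd(pk, d)
        pF <- max(Fv)
        pZ <- stats::qnorm(stats::pf(pF, statmap$df[1], statmap$df[2],
                                     lower.tail = FALSE),
                           lower.tail = FALSE)
        data.frame(cluster_id = j, extent = ext[keep[j]], peak_F = pF,
                   peak_Z = pZ, x_mm = statmap$coords_mm[ac[1]],
                   y_mm = statmap$coords_mm[ac[2]],
                   t_ms = statmap$time_ms[ac[3]])
      })
      tab <- do.call(rbind, rowsl)
      ord <- order(-tab$extent)
      tab <- tab[ord, , drop = FALSE]
      voxlist <- voxl[ord]
      tab$cluster_id <- seq_len(nrow(tab))
      rownames(tab) <- NULL
    }
  }
  attr(tab, "cluster_voxels") <- voxlist
  attr(tab, "alpha_peak") <- alpha_peak
  attr(tab, "F_crit") <- F_crit
  attr(tab, "extent_min") <- extent_min
  attr(tab, "df") <- statmap$df
  class(tab) <- c("cluster_table", "data.frame")
  tab
}

#' @export
print.cluster_table <- function(x, ...) {
  cat(sprintf("Clusters at p < %g (F > %.2f), extent >= %d, df = (%g, %g):\n",
              attr(x, "alpha_peak"), attr(x, "F_crit"), attr(x, "extent_min"),
              attr(x, "df")[1], attr(x, "df")[2]))
  if (nrow(x) == 0) cat("  (none)\n") else print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Inclusive mask from fully-predicted outcomes
#'
#' Voxelwise paired F test (win vs loss at P = 1) at a lenient threshold;
#' the returned mask is the *complement* of the significant voxels, i.e. it
#' retains only locations where fully-predicted wins and losses do not
#' differ, for use as an inclusive mask on the interaction contrast.
#'
#' @param images_win_p1,images_loss_p1 lists of `scalp_image`, one per
#'   subject, in matching subject order.
#' @param alpha significance level of the sensitivity map (default 0.05).
#' @return object of class `equivalence_mask`: `mask` (logical volume, TRUE
#'   where retained), `F` volume, `df`, `alpha`, `excluded_fraction`.
#' @export
equivalence_mask <- function(images_win_p1, images_loss_p1, alpha = 0.05) {
  if (length(images_win_p1) != length(images_loss_p1)) {
    stop_("win and loss image lists must have matched subjects")
  }
  S <- length(images_win_p1)
  if (S < 2) stop_("at least 2 subjects required")
  w <- images_to_matrix(images_win_p1)
  l <- images_to_matrix(images_loss_p1)
  D <- w$Y - l$Y
  mbar <- colMeans(D)
  sd_d <- sqrt(colSums((D - rep(mbar, each = S))^2) / (S - 1))
  tval <- ifelse(sd_d > 0, sqrt(S) * mbar / sd_d, ifelse(mbar == 0, 0, Inf))
  Fv <- tval^2
  F_crit <- stats::qf(1 - alpha, 1, S - 1)
  keepv <- Fv < F_crit
  vol <- vector_to_volume(as.numeric(keepv), w$ref, w$voxmask)
  mask <- !is.na(vol) & vol > 0
  structure(list(mask = mask, F = vector_to_volume(Fv, w$ref, w$voxmask),
                 df = c(1, S - 1), alpha = alpha, F_crit = F_crit,
                 excluded_fraction = mean(!keepv)),
            class = "equivalence_mask")
}

#' @export
print.equivalence_mask <- function(x, ...) {
  cat(sprintf("P=1 equivalence mask: alpha = %g, df = (%g, %g), %.1f%% of voxels excluded\n",
              x$alpha, x$df[1], x$df[2], 100 * x$excluded_fraction))
  invisible(x)
}
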