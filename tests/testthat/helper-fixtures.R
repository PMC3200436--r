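# Shared fixtures and independent oracles for the test suite.

# small MEG-like layout for fast tests
small_layout <- function(n = 40L) meg_sensor_layout(n_channels = n)

# quiet noise spec (no noise, no artifacts)
quiet_noise <- function(seed = 1L) {
  noise_spec(white_sd = 0, pink_sd = 0, blink_rate = 0, jump_rate = 0,
             seed = seed)
}

# epoched_data wrapper around a plain array with a matching dummy design
make_epochs <- function(data, fs, t_start = -160, layout = NULL) {
  d <- dim(data)
  if (is.null(layout)) layout <- small_layout(d[2])
  tr <- build_session_design(stats::setNames(d[1], "1"), 1L, seed = 1L)
  epoched_data(data, fs, t_start + (seq_len(d[3]) - 1) * 1000 / fs, tr, layout)
}

# --- GLM oracle: extra sum of squares via explicit model comparison -------
# Fits the full model and the model restricted to the null space of the
# contrast, entirely through projection matrices.  Independent of the
# package's (Cb)' [C (X'X)^-1 C']^-1 (Cb) route.
oracle_F <- function(Y, X, C_) {
  C_ <- if (is.matrix(C_)) C_ else matrix(C_, nrow = 1)
  if (ncol(C_) < ncol(X)) C_ <- cbind(C_, matrix(0, nrow(C_), ncol(X) - ncol(C_)))
  P_full <- X %*% solve(crossprod(X)) %*% t(X)
  # basis of the null space of C (parameters satisfying C beta = 0)
  N <- MASS::Null(t(C_))
  X0 <- X %*% N
  P_red <- X0 %*% solve(crossprod(X0)) %*% t(X0)
  n <- nrow(Y)
  rss_full <- colSums((Y - P_full %*% Y)^2)
  rss_red <- colSums((Y - P_red %*% Y)^2)
  q <- nrow(C_)
  df2 <- n - qr(X)$rank
  list(F = ((rss_red - rss_full) / q) / (rss_full / df2), df = c(q, df2))
}

# --- repeated-measures ANOVA oracle: explicit sums-of-squares partition ---
# means: subjects x 2 x 4
oracle_rm_anova <- function(means) {
  S <- dim(means)[1]
  gm <- mean(means)
  m_s <- apply(means, 1, mean)
  m_v <- apply(means, 2, mean)
  m_p <- apply(means, 3, mean)
  m_sv <- apply(means, c(1, 2), mean)
  m_sp <- apply(means, c(1, 3), mean)
  m_vp <- apply(means, c(2, 3), mean)
  ss_v <- 4 * S * sum((m_v - gm)^2)
  ss_p <- 2 * S * sum((m_p - gm)^2)
  ss_sv <- 4 * sum((m_sv - outer(m_s, m_v, "+") + gm)^2)
  ss_sp <- 2 * sum((m_sp - outer(m_s, m_p, "+") + gm)^2)
  ss_vp <- S * sum((m_vp - outer(m_v, m_p, "+") + gm)^2)
  resid <- means
  for (s in seq_len(S)) for (v in 1:2) for (p in 1:4) {
    resid[s, v, p] <- means[s, v, p] - m_sv[s, v] - m_sp[s, p] - m_vp[v, p] +
      m_s[s] + m_v[v] + m_p[p] - gm
  }
  ss_svp <- sum(resid^2)
  list(
    valence = (ss_v / 1) / (ss_sv / (S - 1)),
    probability = (ss_p / 3) / (ss_sp / (3 * (S - 1))),
    interaction = (ss_vp / 3) / (ss_svp / (3 * (S - 1)))
  )
}

# condition means following a given gain pattern with additive noise
pattern_means <- function(n_subjects, f_win, f_loss, noise_sd = 0, seed = 1) {
  set.seed(seed)
  probs <- c(0.25, 0.5, 0.75, 1)
  m <- array(NA_real_, c(n_subjects, 2, 4))
  for (s in seq_len(n_subjects)) {
    m[s, 1, ] <- f_win(probs) + stats::rnorm(4, 0, noise_sd)
    m[s, 2, ] <- f_loss(probs) + stats::rnorm(4, 0, noise_sd)
  }
  class(m) <- "condition_means"
  m
}

# squared-magnitude (zero-phase) response of the band-pass cascade
bandpass_response <- function(f_hz, low, high, fs, order = 4L) {
  coefs <- list(axiomerf:::butter_coef(order, high, fs, "low"))
  if (low > 0) {
    coefs <- c(list(axiomerf:::butter_coef(order, low, fs, "high")), coefs)
  }
  axiomerf:::zerophase_response(coefs, f_hz, fs)
}
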