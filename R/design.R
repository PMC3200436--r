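# Gambling-task session design: trial tables with exact-frequency outcomes.

#' Build a gambling-session trial table
#'
#' Constructs the per-trial design for a session of binary gambles.  Each
#' gamble has a stated win probability; its outcome is either a win of +1
#' currency unit or a loss of -1.  By default outcomes are realized by exact
#' stratified assignment: at win probability P with N gambles, exactly
#' `N * P` trials are wins, so realized frequencies match nominal
#' probabilities in every session.  An i.i.d. Bernoulli mode is available for
#' comparison.
#'
#' The default counts reproduce the 540-trial session used throughout the
#' package: 45 gambles at P = 0 and at P = 1, 90 at P = .50, and 180 at each
#' of P = .25 and P = .75, split over 9 blocks of 60 trials with equal
#' per-probability counts in every block.
#'
#' For analysis the trials are labelled on the 2 (outcome valence) x 4
#' (outcome probability) axes: `outcome_prob` is the probability of the
#' *realized* outcome, so a loss after a .25-win gamble is a P = .75 loss,
#' and certain gambles (P = 0 or 1) land in the P = 1 cells.
#'
#' @param counts_per_win_prob named numeric vector mapping win probability to
#'   gamble count.  Names are probabilities in `{0, .25, .5, .75, 1}`.
#' @param n_blocks number of blocks; every count must divide evenly.
#' @param seed integer seed controlling outcome assignment and trial order.
#' @param method `"exact"` (stratified, default) or `"bernoulli"`.
#' @param outcome_onset_ms outcome onset relative to epoch zero (ms).
#' @return a `data.frame` of class `trial_table` with columns `trial_id`,
#'   `block`, `target_win_prob`, `outcome_valence`, `outcome_prob`,
#'   `outcome_amount`, `outcome_onset`.
#' @examples
#' design <- build_session_design(seed = 1)
#' table(design$outcome_valence, design$outcome_prob)
#' @export
build_session_design <- function(counts_per_win_prob = c("0" = 45, "0.25" = 180,
                                                         "0.5" = 90, "0.75" = 180,
                                                         "1" = 45),
                                 n_blocks = 9L, seed = 1L,
                                 method = c("exact", "bernoulli"),
                                 outcome_onset_ms = 0) {
  method <- match.arg(method)
  probs <- as.numeric(names(counts_per_win_prob))
  counts <- as.numeric(counts_per_win_prob)
  if (anyNA(probs)) stop_("counts_per_win_prob must be named by win probability")
  if (!all(probs %in% c(0, 0.25, 0.5, 0.75, 1))) {
    stop_("win probabilities must lie in {0, .25, .50, .75, 1}")
  }
  if (any(counts <= 0) || any(counts != round(counts))) {
    stop_("gamble counts must be positive integers")
  }
  if (any(counts %% n_blocks != 0)) {
    bad <- probs[counts %% n_blocks != 0][1]
    stop_("count at P = %g is not divisible into %d blocks", bad, n_blocks)
  }
  n_wins <- counts * probs
  if (method == "exact" && any(abs(n_wins - round(n_wins)) > 1e-9)) {
    i <- which(abs(n_wins - round(n_wins)) > 1e-9)[1]
    stop_("expected win count is not an integer at (P = %g, N = %d)",
          probs[i], as.integer(counts[i]))
  }

  set.seed(derive_seed(seed, "design"))
  per_stratum <- vector("list", length(probs))
  for (i in seq_along(probs)) {
    p <- probs[i]; n <- counts[i]
    valence <- if (method == "exact") {
      sample(rep(c("win", "loss"), times = c(round(n * p), n - round(n * p))))
    } else {
      ifelse(stats::runif(n) < p, "win", "loss")
    }
    per_stratum[[i]] <- data.frame(
      block = rep(seq_len(n_blocks), each = n / n_blocks),
      target_win_prob = p,
      outcome_valence = valence,
      stringsAsFactors = FALSE
    )
  }
  trials <- do.call(rbind, per_stratum)
  # random order within each block
  ord <- order(trials$block, stats::runif(nrow(trials)))
  trials <- trials[ord, , drop = FALSE]
  trials$trial_id <- seq_len(nrow(trials))
  trials$outcome_prob <- ifelse(trials$outcome_valence == "win",
                                trials$target_win_prob,
                                1 - trials$target_win_prob)
  trials$outcome_amount <- ifelse(trials$outcome_valence == "win", 1, -1)
  trials$outcome_onset <- outcome_onset_ms
  rownames(trials) <- NULL
  trials <- trials[, c("trial_id", "block", "target_win_prob", "outcome_valence",
                       "outcome_prob", "outcome_amount", "outcome_onset")]
  class(trials) <- c("trial_table", "data.frame")
  trials
}

#' @export
print.trial_table <- function(x, ...) {
  cat(sprintf("Trial table: %d trials, %d blocks\n", nrow(x),
              length(unique(x$block))))
  tab <- table(x$outcome_valence, x$outcome_prob)
  print(tab)
  invisible(x)
}
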