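# Internal helpers shared across modules.

#' Derive a child seed from a session seed and a stage label
#'
#' All stochastic stages draw their own seed deterministically from one
#' session-level seed, so any stage can be re-run in isolation and reproduce
#' the full-pipeline result.  The scheme is a multiplicative hash of the
#' label folded into the seed, reduced modulo a prime below 2^31.
#'
#' @param seed integer session seed.
#' @param label character stage label (e.g. "design", "noise", "subject3").
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483629 # prime < 2^31
  h <- 0
  for (code in utf8ToInt(paste(label, collapse = "/"))) {
    h <- (h * 131 + code) %% m
  }
  # 69069: classic Marsaglia multiplier; products stay < 2^53 so exact in doubles
  as.integer(((abs(seed) %% m) * 69069 + h) %% m + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
canonical_conditions <- function() {
  data.frame(
    outcome_valence = rep(c("win", "loss"), each = 4L),
    outcome_prob    = rep(c(0.25, 0.50, 0.75, 1.00), 2L),
    stringsAsFactors = FALSE
  )
}

condition_key <- function(valence, prob) sprintf("%s_p%02d", valence, round(prob * 100))

# append an operation record to an epoched_data provenance list
add_provenance <- function(x, op, params = list()) {
  rec <- list(op = op, params = params)
  x$provenance <- c(x$provenance, list(rec))
  x
}
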