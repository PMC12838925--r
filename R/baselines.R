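#' Random keep/reset draw
#'
#' @param p_reset Per-step reset probability in `[0, 1]`.
#' @return `"reset"` with probability `p_reset`, else `"keep"`; draws are
#'   independent across calls.
#' @export
random_decide <- function(p_reset) {
  if (stats::runif(1) < p_reset) "reset" else "keep"
}

#' Calibrate the random policy's reset probability
#'
#' The random baseline is calibrated to the SSM agent's marginal reset
#' rate: total resets divided by total steps across a set of SSM runs.
#'
#' @param logs A list of run logs (see [run_sim()]).
#' @return The pooled reset rate in `[0, 1]`.
#' @export
calibrate_reset_prob <- function(logs) {
  if (inherits(logs, "run_log")) logs <- list(logs)
  if (length(logs) == 0L) stop("need at least one run log to calibrate")
  resets <- sum(vapply(logs, function(l) sum(l$records$action == "reset"),
                       numeric(1)))
  steps <- sum(vapply(logs, function(l) nrow(l$records), numeric(1)))
  resets / steps
}

#' Empirical good-frequency memory
#'
#' A mutable map signature -> (good_count, visit_count). The empirical
#' frequency of a signature is `good_count / visit_count`, defined as 0
#' when the signature has never been visited.
#'
#' @return An object of class `frequency_memory`.
#' @export
frequency_memory <- function() {
  structure(new.env(parent = emptyenv()), class = "frequency_memory")
}

#' @rdname frequency_memory
#' @param memory A `frequency_memory`.
#' @param sig An integer signature vector (or key string).
#' @return `good_frequency()`: the empirical good-frequency in `[0, 1]`.
#' @export
good_frequency <- function(memory, sig) {
  key <- if (is.character(sig)) sig else signature_key(sig)
  counts <- memory[[key]]
  if (is.null(counts) || counts[["visits"]] == 0L) return(0)
  counts[["good"]] / counts[["visits"]]
}

#' Frequency-rule decision
#'
#' Keep iff the signature's empirical good-frequency strictly exceeds
#' `freq_threshold`. The comparison is strict, so a cold-start frequency of
#' 0 (and an exact 0.5) resets — this is what makes the agent degenerate
#' into constant resetting under the reset-outcome = -1 convention.
#'
#' @param memory A [frequency_memory()].
#' @param sig An integer signature vector (or key string).
#' @param freq_threshold Keep threshold, default 0.5.
#' @return `"keep"` or `"reset"`.
#' @export
frequency_decide <- function(memory, sig, freq_threshold = 0.5) {
  if (good_frequency(memory, sig) > freq_threshold) "keep" else "reset"
}

#' Record an outcome in a frequency memory
#'
#' Increments the visit count of the pre-action signature and, for a good
#' outcome, its good count. Modifies `memory` in place.
#'
#' @inheritParams frequency_decide
#' @param outcome `+1` or `-1`.
#' @return The signature's updated `(good, visits)` counts, invisibly.
#' @export
frequency_update <- function(memory, sig, outcome) {
  stopifnot(outcome %in% c(-1L, 1L))
  key <- if (is.character(sig)) sig else signature_key(sig)
  counts <- memory[[key]]
  if (is.null(counts)) counts <- c(good = 0L, visits = 0L)
  counts[["visits"]] <- counts[["visits"]] + 1L
  if (outcome == 1L) counts[["good"]] <- counts[["good"]] + 1L
  memory[[key]] <- counts
  invisible(counts)
}

#' Tabular Q-learning configuration
#'
#' Hyperparameters of the minimal signature-level Q-learner. The reference
#' study leaves them unstated; the defaults here are the conventional
#' textbook values, and the comparison against this agent should be read
#' qualitatively.
#'
#' @param eta Learning rate in `(0, 1]`. Default 0.1.
#' @param gamma Discount factor in `[0, 1)`. Default 0.9.
#' @param epsilon Exploration probability of epsilon-greedy selection.
#'   Default 0.1.
#' @return An object of class `qlearning_config`.
#' @export
qlearning_config <- function(eta = 0.1, gamma = 0.9, epsilon = 0.1) {
  stopifnot(eta > 0, eta <= 1, gamma >= 0, gamma < 1,
            epsilon >= 0, epsilon <= 1)
  structure(list(eta = eta, gamma = gamma, epsilon = epsilon),
            class = "qlearning_config")
}

#' Q-table over (signature, action)
#'
#' A mutable map with default value 0 for any (signature, action) pair not
#' yet updated.
#'
#' @return An object of class `q_table`.
#' @export
q_table <- function() {
  structure(new.env(parent = emptyenv()), class = "q_table")
}

#' @rdname q_table
#' @param qtable A `q_table`.
#' @param sig An integer signature vector (or key string).
#' @return `q_values()`: a named numeric vector `c(keep = , reset = )`.
#' @export
q_values <- function(qtable, sig) {
  key <- if (is.character(sig)) sig else signature_key(sig)
  qs <- qtable[[key]]
  if (is.null(qs)) c(keep = 0, reset = 0) else qs
}

#' Epsilon-greedy action selection
#'
#' With probability `epsilon` a uniformly random action; otherwise the
#' argmax of the signature's Q-values, ties broken toward `keep`.
#'
#' @param qtable A [q_table()].
#' @param sig An integer signature vector (or key string).
#' @param config A [qlearning_config()].
#' @return `"keep"` or `"reset"`.
#' @export
q_decide <- function(qtable, sig, config = qlearning_config()) {
  if (stats::runif(1) < config$epsilon) {
    return(sample(c("keep", "reset"), 1L))
  }
  qs <- q_values(qtable, sig)
  if (qs[["reset"]] > qs[["keep"]]) "reset" else "keep"
}

#' One-step Q-learning update
#'
#' `Q(s, a) <- Q(s, a) + eta * (r + gamma * max_a' Q(s', a') - Q(s, a))`,
#' with the step outcome (+1/-1, including the forced -1 on reset) as the
#' reward. Modifies `qtable` in place.
#'
#' @param qtable A [q_table()].
#' @param sig Pre-action signature.
#' @param action The action taken (`"keep"` or `"reset"`).
#' @param reward The step outcome.
#' @param next_sig Post-action signature.
#' @param config A [qlearning_config()].
#' @return The updated Q-value.
#' @export
q_update <- function(qtable, sig, action, reward, next_sig,
                     config = qlearning_config()) {
  stopifnot(action %in% c("keep", "reset"))
  key <- if (is.character(sig)) sig else signature_key(sig)
  qs <- q_values(qtable, key)
  target <- reward + config$gamma * max(q_values(qtable, next_sig))
  qs[[action]] <- qs[[action]] + config$eta * (target - qs[[action]])
  qtable[[key]] <- qs
  qs[[action]]
}
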