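#' Agent constructors
#'
#' Four agents share the same environment, oracle and logging schema:
#'
#' * `ssm_agent()` — the synthetic somatic marker agent: one scalar valence
#'   per signature, clipped incremental updates, threshold keep/reset rule.
#' * `random_agent()` — memory-free policy that resets with fixed
#'   probability `p_reset` each step, normally calibrated to the SSM
#'   agent's marginal reset rate (see [calibrate_reset_prob()]).
#' * `frequency_agent()` — stores the empirical frequency of good outcomes
#'   per signature and keeps only when that frequency strictly exceeds
#'   `freq_threshold`; unseen signatures have frequency 0.
#' * `qlearning_agent()` — minimal tabular Q-learning over (signature,
#'   action) pairs with epsilon-greedy selection, ties broken toward keep.
#'
#' Each constructor returns an immutable recipe; the mutable per-run memory
#' is created fresh by the simulator at the start of every run, so runs are
#' independent.
#'
#' @param ssm An [ssm_config()].
#' @param policy An [agent_config()].
#' @return An object of class `pix_agent`.
#' @name agents
NULL

#' @rdname agents
#' @export
ssm_agent <- function(ssm = ssm_config(), policy = agent_config()) {
  structure(list(ssm = ssm, policy = policy),
            class = c("ssm_agent", "pix_agent"))
}

#' @rdname agents
#' @param p_reset Per-step reset probability in `[0, 1]`.
#' @export
random_agent <- function(p_reset) {
  stopifnot(is.numeric(p_reset), length(p_reset) == 1L,
            p_reset >= 0, p_reset <= 1)
  structure(list(p_reset = p_reset),
            class = c("random_agent", "pix_agent"))
}

#' @rdname agents
#' @param freq_threshold Keep only when the signature's empirical
#'   good-frequency strictly exceeds this value. Default 0.5.
#' @export
frequency_agent <- function(freq_threshold = 0.5) {
  stopifnot(is.numeric(freq_threshold), length(freq_threshold) == 1L)
  structure(list(freq_threshold = freq_threshold),
            class = c("frequency_agent", "pix_agent"))
}

#' @rdname agents
#' @param config A [qlearning_config()].
#' @export
qlearning_agent <- function(config = qlearning_config()) {
  structure(list(config = config),
            class = c("qlearning_agent", "pix_agent"))
}

#' @export
print.pix_agent <- function(x, ...) {
  cat(sprintf("<%s agent>\n", agent_type(x)))
  str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Short label for an agent
#'
#' @param agent A `pix_agent`.
#' @return One of `"ssm"`, `"random"`, `"freq"`, `"qlearn"`; recorded in
#'   run-log metadata.
#' @export
agent_type <- function(agent) UseMethod("agent_type")
#' @export
agent_type.ssm_agent <- function(agent) "ssm"
#' @export
agent_type.random_agent <- function(agent) "random"
#' @export
agent_type.frequency_agent <- function(agent) "freq"
#' @export
agent_type.qlearning_agent <- function(agent) "qlearn"

#' Fresh per-run agent memory
#'
#' @param agent A `pix_agent`.
#' @return The agent's mutable state for one run (a valence memory,
#'   frequency memory, Q-table, or nothing for the random policy).
#' @keywords internal
#' @export
agent_state <- function(agent) UseMethod("agent_state")
#' @export
agent_state.ssm_agent <- function(agent) valence_memory()
#' @export
agent_state.random_agent <- function(agent) NULL
#' @export
agent_state.frequency_agent <- function(agent) frequency_memory()
#' @export
agent_state.qlearning_agent <- function(agent) q_table()

#' Consult an agent for one decision
#'
#' Returns the chosen action together with the scalar the agent consulted
#' (logged as `valence_pre`): the signature's valence for the SSM agent,
#' its empirical good-frequency for the frequency agent, its greedy
#' Q-value for the Q-learner, and 0 for the memory-free random policy.
#'
#' @param agent A `pix_agent`.
#' @param state The agent's per-run memory from [agent_state()].
#' @param sig The current grid's signature.
#' @return A list with elements `action` (`"keep"`/`"reset"`) and
#'   `valence` (the consulted scalar).
#' @keywords internal
#' @export
agent_policy <- function(agent, state, sig) UseMethod("agent_policy")

#' @export
agent_policy.ssm_agent <- function(agent, state, sig) {
  v <- get_valence(state, sig)
  list(action = decide(v, agent$policy), valence = v)
}

#' @export
agent_policy.random_agent <- function(agent, state, sig) {
  action <- random_decide(agent$p_reset)
  list(action = action, valence = 0)
}

#' @export
agent_policy.frequency_agent <- function(agent, state, sig) {
  f <- good_frequency(state, sig)
  action <- frequency_decide(state, sig, agent$freq_threshold)
  list(action = action, valence = f)
}

#' @export
agent_policy.qlearning_agent <- function(agent, state, sig) {
  qs <- q_values(state, sig)
  list(action = q_decide(state, sig, agent$config), valence = max(qs))
}

#' Feed one outcome back into an agent's memory
#'
#' The update is keyed to the pre-action signature `sig` for every agent
#' (the Q-learner additionally uses the post-action signature `next_sig`
#' for its bootstrap term).
#'
#' @param agent A `pix_agent`.
#' @param state The agent's per-run memory; modified in place.
#' @param sig Signature of the pre-action grid.
#' @param action The action taken at this step.
#' @param outcome The oracle's `+1`/`-1` label for the step.
#' @param next_sig Signature of the post-action grid.
#' @return The updated evaluative scalar, or `NULL` for memory-free agents.
#' @keywords internal
#' @export
agent_learn <- function(agent, state, sig, action, outcome, next_sig) {
  UseMethod("agent_learn")
}

#' @export
agent_learn.ssm_agent <- function(agent, state, sig, action, outcome, next_sig) {
  update_valence(state, sig, outcome, agent$ssm)
}

#' @export
agent_learn.random_agent <- function(agent, state, sig, action, outcome, next_sig) {
  NULL
}

#' @export
agent_learn.frequency_agent <- function(agent, state, sig, action, outcome, next_sig) {
  frequency_update(state, sig, outcome)
}

#' @export
agent_learn.qlearning_agent <- function(agent, state, sig, action, outcome, next_sig) {
  q_update(state, sig, action, outcome, next_sig, agent$config)
}
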