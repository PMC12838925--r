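#' Experiment protocol configuration
#'
#' The reference protocol is 30 independent runs of 100 iterations each.
#' Per-run seeds are derived deterministically as `base_seed + run index`,
#' so runs are reproducible yet distinct, and agent memory is reinitialised
#' every run.
#'
#' @param steps Iterations per run (`T`). Default 100.
#' @param n_runs Number of independent runs. Default 30.
#' @param base_seed Integer from which per-run seeds are derived.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(steps = 100L, n_runs = 30L, base_seed = 1L) {
  steps <- as.integer(steps); n_runs <- as.integer(n_runs)
  base_seed <- as.integer(base_seed)
  stopifnot(steps >= 1L, n_runs >= 1L, !is.na(base_seed))
  seeds <- base_seed + seq_len(n_runs)
  if (anyDuplicated(seeds)) stop("derived per-run seeds are not distinct")
  structure(list(steps = steps, n_runs = n_runs, base_seed = base_seed,
                 seeds = seeds),
            class = "protocol_config")
}

#' Execute one interaction step
#'
#' The fixed per-step cycle: compress the current grid to its signature;
#' consult the agent; on `reset` draw a completely fresh random grid and
#' force the outcome to -1 (the cost of abandoning the trajectory); on
#' `keep` apply the stochastic transition and let the oracle classify the
#' new grid. The agent's memory is then updated, keyed to the *pre-action*
#' signature, and a step record carrying the pre-update valence is emitted.
#'
#' @param grid The current grid.
#' @param agent A `pix_agent` (see [agents]).
#' @param state The agent's per-run memory; updated in place.
#' @param config An [env_config()].
#' @param t Step index stored in the record.
#' @return A list with the new `grid` and the `record` (a one-row list with
#'   fields `t`, `signature`, `valence_pre`, `action`, `outcome`).
#' @export
sim_step <- function(grid, agent, state, config = env_config(), t = 1L) {
  sig <- compress(grid)
  choice <- agent_policy(agent, state, sig)
  if (choice$action == "reset") {
    new_grid <- random_grid(config)
    outcome <- -1L
  } else {
    new_grid <- transition(grid, config)
    outcome <- classify(new_grid)
  }
  agent_learn(agent, state, sig, choice$action, outcome, compress(new_grid))
  record <- list(t = as.integer(t), signature = signature_key(sig),
                 valence_pre = choice$valence, action = choice$action,
                 outcome = outcome)
  list(grid = new_grid, record = record)
}

#' Run one simulation
#'
#' Seeds the RNG, draws a random initial grid and an empty agent memory,
#' and executes `steps` interaction steps. Identical `(agent, config,
#' steps, seed)` give bit-identical logs.
#'
#' @param agent A `pix_agent` (see [agents]).
#' @param config An [env_config()].
#' @param steps Number of iterations (`T >= 1`).
#' @param seed Integer seed for this run's RNG stream.
#' @return An object of class `run_log`: a list with `records` (a data
#'   frame with columns `t`, `signature`, `valence_pre`, `action`,
#'   `outcome`), the `config`, the final agent `memory`, `seed` and
#'   `agent_type`.
#' @examples
#' log <- run_sim(ssm_agent(), steps = 20, seed = 1)
#' head(log$records)
#' @export
run_sim <- function(agent, config = env_config(), steps = 100L, seed = 1L) {
  steps <- as.integer(steps)
  stopifnot(steps >= 1L)
  set.seed(as.integer(seed))
  grid <- random_grid(config)
  state <- agent_state(agent)
  records <- vector("list", steps)
  for (t in seq_len(steps)) {
    out <- sim_step(grid, agent, state, config, t)
    grid <- out$grid
    records[[t]] <- out$record
  }
  records <- data.frame(
    t = vapply(records, `[[`, integer(1), "t"),
    signature = vapply(records, `[[`, character(1), "signature"),
    valence_pre = vapply(records, `[[`, numeric(1), "valence_pre"),
    action = vapply(records, `[[`, character(1), "action"),
    outcome = vapply(records, `[[`, integer(1), "outcome"),
    stringsAsFactors = FALSE
  )
  structure(list(records = records, config = config, agent = agent,
                 memory = state, seed = as.integer(seed),
                 agent_type = agent_type(agent)),
            class = "run_log")
}

#' @export
print.run_log <- function(x, ...) {
  cat(sprintf("<run_log: %s agent, %d steps, seed %d>\n",
              x$agent_type, nrow(x$records), x$seed))
  cat(sprintf("  resets: %d | good steps: %d\n",
              sum(x$records$action == "reset"),
              sum(x$records$outcome == 1L)))
  invisible(x)
}

#' Run a repeated-run experiment
#'
#' Executes `n_runs` independent runs with derived distinct seeds and a
#' fresh agent memory per run (no cross-run carryover, so across-run
#' standard deviations are meaningful).
#'
#' @param agent A `pix_agent` (see [agents]).
#' @param protocol A [protocol_config()].
#' @param config An [env_config()].
#' @return A list of [run_sim()] logs, of class `experiment_logs`.
#' @export
run_experiment <- function(agent, protocol = protocol_config(),
                           config = env_config()) {
  logs <- lapply(protocol$seeds, function(s) {
    run_sim(agent, config, protocol$steps, s)
  })
  structure(logs, class = c("experiment_logs", "list"),
            protocol = protocol)
}

#' @export
print.experiment_logs <- function(x, ...) {
  cat(sprintf("<experiment_logs: %d x %s runs of %d steps>\n",
              length(x), x[[1L]]$agent_type, nrow(x[[1L]]$records)))
  invisible(x)
}

#' Write / read a run log
#'
#' The step log is written as CSV with header
#' `t,signature,valence_pre,action,outcome` (signatures dash-joined, e.g.
#' `"2-0-3"`), plus a JSON sidecar `<path>.json` holding the config, seed
#' and agent type so a log can be audited without the R session.
#' `read_run_log()` inverts the pair; `read(write(x))` reproduces the
#' records, seed and agent type exactly.
#'
#' @param log A `run_log`.
#' @param path CSV file path; the sidecar goes to `paste0(path, ".json")`.
#' @return `write_run_log()`: `path`, invisibly. `read_run_log()`: a
#'   `run_log` (without the in-memory agent state).
#' @export
write_run_log <- function(log, path) {
  stopifnot(inherits(log, "run_log"))
  utils::write.csv(log$records, path, row.names = FALSE, quote = FALSE)
  meta <- list(agent_type = log$agent_type, seed = log$seed,
               n = log$config$n, flip_prob = log$config$flip_prob,
               steps = nrow(log$records))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_run_log
#' @export
read_run_log <- function(path) {
  expected <- c("t", "signature", "valence_pre", "action", "outcome")
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  if (!identical(header, expected)) {
    stop(sprintf("malformed log %s: header line 1 must be '%s'",
                 path, paste(expected, collapse = ",")))
  }
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = c(t = "integer",
                                            signature = "character",
                                            valence_pre = "numeric",
                                            action = "character",
                                            outcome = "integer"))
  bad <- which(!records$action %in% c("keep", "reset"))
  if (length(bad)) {
    stop(sprintf("malformed log %s: bad action on data line %d",
                 path, bad[1L]))
  }
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(records = records,
                 config = env_config(meta$n, meta$flip_prob),
                 agent = NULL, memory = NULL,
                 seed = as.integer(meta$seed),
                 agent_type = meta$agent_type),
            class = "run_log")
}
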