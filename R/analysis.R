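#' Summarise one run
#'
#' Reduces a step log to the repeated-run metrics: total resets, the
#' proportion of good steps, the `k` most frequently visited signatures,
#' and the average valence over those signatures.
#'
#' "Proportion of good states" is the fraction of steps whose *recorded
#' outcome* is +1. Reset steps carry the forced -1 outcome and therefore
#' count as not-good; this is the only reading under which the frequency
#' baseline's exact 0.00 is possible, since the grid drawn after a reset
#' would itself be good about a quarter of the time.
#'
#' The top-`k` valence metric supports three readings of "average valence
#' of the most visited signatures":
#' * `"final"` (default) — the end-of-run stored valence of each top-`k`
#'   signature, averaged over the `k` signatures. This is the value the
#'   valence has *stabilised* at after the run.
#' * `"visit"` — the visit-weighted mean of the logged pre-update valences
#'   over all steps whose signature is in the top-`k` set.
#' * `"unweighted"` — the per-signature mean of logged pre-update
#'   valences, averaged over the `k` signatures.
#'
#' For a log read back from disk (no stored memory), `"final"` uses the
#' last logged pre-update valence of each signature updated by that
#' signature's last outcome — identical to the stored value for the SSM
#' agent, whose memory the log replays exactly.
#'
#' Ties in visit counts are broken by lexicographic signature order, for
#' determinism.
#'
#' @param log A `run_log` from [run_sim()].
#' @param k Number of top signatures. Default 3.
#' @param weighting One of `"final"`, `"visit"`, `"unweighted"`.
#' @return A list of class `run_summary` with fields `total_resets`,
#'   `prop_good`, `top_signatures` (data frame of signature and visit
#'   count), `top_avg_valence`, `agent_type` and `seed`.
#' @export
summarize_run <- function(log, k = 3L,
                          weighting = c("final", "visit", "unweighted")) {
  weighting <- match.arg(weighting)
  k <- as.integer(k)
  if (k < 1L) stop("k must be at least 1")
  rec <- log$records
  if (nrow(rec) == 0L) stop("empty run log")

  counts <- table(rec$signature)
  ord <- order(-as.integer(counts), names(counts))
  top <- names(counts)[ord][seq_len(min(k, length(counts)))]

  top_val <- switch(weighting,
    visit = mean(rec$valence_pre[rec$signature %in% top]),
    unweighted = mean(vapply(top, function(s) {
      mean(rec$valence_pre[rec$signature == s])
    }, numeric(1))),
    final = mean(vapply(top, function(s) final_valence(log, s), numeric(1)))
  )

  structure(list(
    total_resets = sum(rec$action == "reset"),
    prop_good = mean(rec$outcome == 1L),
    top_signatures = data.frame(signature = top,
                                visits = as.integer(counts[top]),
                                row.names = NULL),
    top_avg_valence = top_val,
    agent_type = log$agent_type,
    seed = log$seed
  ), class = "run_summary")
}

# End-of-run evaluative value of one signature: the stored memory when the
# log still carries it, otherwise reconstructed from the last logged step.
final_valence <- function(log, key) {
  if (inherits(log$memory, "valence_memory")) {
    return(get_valence(log$memory, key))
  }
  rec <- log$records
  i <- max(which(rec$signature == key))
  a <- if (!is.null(log$agent) && inherits(log$agent, "ssm_agent")) {
    log$agent$ssm$alpha
  } else 0.1
  min(1, max(-1, rec$valence_pre[i] + a * rec$outcome[i]))
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("<run_summary: %s agent, seed %d>\n", x$agent_type, x$seed))
  cat(sprintf("  resets %d | prop_good %.2f | top-%d valence %.3f\n",
              x$total_resets, x$prop_good, nrow(x$top_signatures),
              x$top_avg_valence))
  invisible(x)
}

#' Summarise a repeated-run experiment
#'
#' Reduces per-run summaries to mean and sample standard deviation
#' (`n - 1` denominator) for each metric.
#'
#' @param logs An `experiment_logs` list (or plain list of `run_log`s) of
#'   at least 2 runs.
#' @inheritParams summarize_run
#' @return A list of class `experiment_summary` with a `metrics` data
#'   frame (columns `metric`, `mean`, `sd`), the `per_run` data frame,
#'   `n_runs` and `agent_type`.
#' @examples
#' logs <- run_experiment(ssm_agent(), protocol_config(steps = 50, n_runs = 5))
#' summarize_experiment(logs)
#' @export
summarize_experiment <- function(logs, k = 3L,
                                 weighting = c("final", "visit", "unweighted")) {
  weighting <- match.arg(weighting)
  if (length(logs) < 2L) stop("need at least 2 runs for a standard deviation")
  sums <- lapply(logs, summarize_run, k = k, weighting = weighting)
  per_run <- data.frame(
    seed = vapply(sums, `[[`, integer(1), "seed"),
    total_resets = vapply(sums, `[[`, integer(1), "total_resets"),
    prop_good = vapply(sums, `[[`, numeric(1), "prop_good"),
    top_avg_valence = vapply(sums, `[[`, numeric(1), "top_avg_valence")
  )
  metrics <- data.frame(
    metric = c("total_resets", "prop_good", "top_avg_valence"),
    mean = c(mean(per_run$total_resets), mean(per_run$prop_good),
             mean(per_run$top_avg_valence)),
    sd = c(stats::sd(per_run$total_resets), stats::sd(per_run$prop_good),
           stats::sd(per_run$top_avg_valence))
  )
  structure(list(metrics = metrics, per_run = per_run,
                 n_runs = length(logs),
                 agent_type = sums[[1L]]$agent_type),
            class = "experiment_summary")
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat(sprintf("<experiment_summary: %s agent, %d runs>\n",
              x$agent_type, x$n_runs))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-16s %6.2f ± %.2f\n", m$metric[i], m$mean[i], m$sd[i]))
  }
  invisible(x)
}

#' Sensitivity-sweep specification
#'
#' The default grid varies the learning rate, the decision threshold and
#' the flip probability around the reference setting, 27 cells in all.
#'
#' @param alpha_values Learning rates to sweep. Default `c(0.05, 0.1, 0.2)`.
#' @param theta_values Thresholds to sweep. Default `c(-0.3, -0.5, -0.7)`.
#' @param flip_values Flip probabilities to sweep.
#'   Default `c(0.20, 0.30, 0.40)`.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(alpha_values = c(0.05, 0.10, 0.20),
                       theta_values = c(-0.3, -0.5, -0.7),
                       flip_values = c(0.20, 0.30, 0.40)) {
  stopifnot(length(alpha_values) >= 1L, length(theta_values) >= 1L,
            length(flip_values) >= 1L)
  structure(list(alpha_values = unique(alpha_values),
                 theta_values = unique(theta_values),
                 flip_values = unique(flip_values)),
            class = "sweep_spec")
}

#' Run the parameter-sensitivity sweep
#'
#' One full repeated-run SSM experiment per cell of the
#' `alpha x theta x flip_prob` grid, reduced to the same summary metrics
#' as [summarize_experiment()] and returned as a tidy table keyed by the
#' three parameters.
#'
#' @param spec A [sweep_spec()].
#' @param protocol A [protocol_config()]; each cell reuses the same derived
#'   seeds, so cells differ only in parameters.
#' @param n Grid side length. Default 3.
#' @inheritParams summarize_run
#' @return A data frame with one row per cell: `alpha`, `theta`,
#'   `flip_prob`, and mean/sd columns for resets, prop_good and the top-3
#'   valence.
#' @export
run_sweep <- function(spec = sweep_spec(), protocol = protocol_config(),
                      n = 3L, k = 3L, weighting = "final") {
  cells <- expand.grid(alpha = spec$alpha_values,
                       theta = spec$theta_values,
                       flip_prob = spec$flip_values,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    agent <- ssm_agent(ssm_config(alpha = cells$alpha[i]),
                       agent_config(theta = cells$theta[i]))
    logs <- run_experiment(agent, protocol,
                           env_config(n = n, flip_prob = cells$flip_prob[i]))
    s <- summarize_experiment(logs, k = k, weighting = weighting)$metrics
    data.frame(alpha = cells$alpha[i], theta = cells$theta[i],
               flip_prob = cells$flip_prob[i],
               mean_resets = s$mean[1L], sd_resets = s$sd[1L],
               mean_prop_good = s$mean[2L], sd_prop_good = s$sd[2L],
               mean_top_valence = s$mean[3L], sd_top_valence = s$sd[3L])
  })
  do.call(rbind, rows)
}

#' Failure-mode diagnostics
#'
#' Screens a set of run logs for the three maladaptive regimes:
#'
#' * excess resetting — runs whose reset rate exceeds
#'   `reset_rate_threshold` are flagged;
#' * low-valence cycles — signatures whose logged pre-update valence
#'   stayed strictly below `theta` for at least `min_cycle_visits`
#'   consecutive visits (the agent keeps returning to a signature it can
#'   only reset);
#' * signature aliasing — per-signature variance of keep-step outcomes,
#'   grouped by the signature of the grid the oracle classified (the
#'   post-transition grid, i.e. the next step's signature). With the
#'   row-count compression and the active-count oracle the label is a
#'   function of that signature, so this score is identically 0; it is
#'   retained for alternative oracles or compressions, where a signature
#'   mixing good and bad grids yields noisy valence estimates.
#'
#' @param logs A list of `run_log`s.
#' @param reset_rate_threshold Flag runs whose reset fraction exceeds
#'   this. Default 0.5.
#' @param theta Threshold defining "low" valence. Default -0.5.
#' @param min_cycle_visits Consecutive below-threshold visits needed to
#'   call a cycle. Default 3.
#' @return A list of class `failure_diagnostics` with data frames
#'   `run_flags`, `low_valence_cycles` and `aliasing`.
#' @export
failure_diagnostics <- function(logs, reset_rate_threshold = 0.5,
                                theta = -0.5, min_cycle_visits = 3L) {
  if (inherits(logs, "run_log")) logs <- list(logs)
  if (length(logs) == 0L) stop("no run logs supplied")

  run_flags <- do.call(rbind, lapply(seq_along(logs), function(i) {
    rec <- logs[[i]]$records
    rate <- mean(rec$action == "reset")
    data.frame(run = i, seed = logs[[i]]$seed,
               reset_rate = rate,
               excess_resets = rate > reset_rate_threshold)
  }))

  cycles <- do.call(rbind, lapply(seq_along(logs), function(i) {
    rec <- logs[[i]]$records
    out <- lapply(unique(rec$signature), function(s) {
      below <- rec$valence_pre[rec$signature == s] < theta
      r <- rle(below)
      longest <- if (any(r$values)) max(r$lengths[r$values]) else 0L
      data.frame(run = i, signature = s,
                 max_consecutive_low = longest)
    })
    df <- do.call(rbind, out)
    df[df$max_consecutive_low >= min_cycle_visits, , drop = FALSE]
  }))

  # a keep step's outcome labels the post-transition grid, whose signature
  # is the next record's; the final step has no successor and is dropped
  keep_steps <- do.call(rbind, lapply(logs, function(l) {
    rec <- l$records
    i <- which(rec$action == "keep" & rec$t < nrow(rec))
    data.frame(signature = rec$signature[i + 1L], outcome = rec$outcome[i])
  }))
  aliasing <- if (nrow(keep_steps)) {
    agg <- stats::aggregate(outcome ~ signature, data = keep_steps,
                            FUN = function(x) {
                              c(n = length(x),
                                var = if (length(x) > 1L) stats::var(x) else 0)
                            })
    data.frame(signature = agg$signature,
               n_keep = agg$outcome[, "n"],
               outcome_var = agg$outcome[, "var"])
  } else {
    data.frame(signature = character(), n_keep = numeric(),
               outcome_var = numeric())
  }

  structure(list(run_flags = run_flags,
                 low_valence_cycles = cycles,
                 aliasing = aliasing),
            class = "failure_diagnostics")
}

#' @export
print.failure_diagnostics <- function(x, ...) {
  cat(sprintf("<failure_diagnostics: %d run(s)>\n", nrow(x$run_flags)))
  cat(sprintf("  excess-reset runs: %d\n", sum(x$run_flags$excess_resets)))
  cat(sprintf("  low-valence cycles: %d\n", nrow(x$low_valence_cycles)))
  cat(sprintf("  aliased signatures (var > 0): %d\n",
              sum(x$aliasing$outcome_var > 0)))
  invisible(x)
}

#' Render agent-comparison tables
#'
#' Lays out one row per agent with `mean ± SD` strings for resets,
#' proportion of good steps and the top-3 valence — the across-agent
#' comparison table of the repeated-run protocol.
#'
#' @param summaries A named list of `experiment_summary` objects (names
#'   are used as row labels; unnamed lists fall back to each summary's
#'   agent type).
#' @return A data frame with columns `agent`, `resets`, `prop_good`,
#'   `top_valence`.
#' @export
make_tables <- function(summaries) {
  if (inherits(summaries, "experiment_summary")) summaries <- list(summaries)
  if (length(summaries) == 0L) stop("no experiment summaries supplied")
  labels <- names(summaries)
  if (is.null(labels)) labels <- rep("", length(summaries))
  fmt <- function(m, s, digits = 2) {
    sprintf(paste0("%.", digits, "f ± %.", digits, "f"), m, s)
  }
  rows <- lapply(seq_along(summaries), function(i) {
    s <- summaries[[i]]
    if (!inherits(s, "experiment_summary")) {
      warning(sprintf("entry %d is not an experiment summary; omitted", i))
      return(NULL)
    }
    m <- s$metrics
    data.frame(
      agent = if (nzchar(labels[i])) labels[i] else s$agent_type,
      resets = fmt(m$mean[1L], m$sd[1L]),
      prop_good = fmt(m$mean[2L], m$sd[2L]),
      top_valence = fmt(m$mean[3L], m$sd[3L]),
      stringsAsFactors = FALSE
    )
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) stop("no valid experiment summaries supplied")
  do.call(rbind, rows)
}
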