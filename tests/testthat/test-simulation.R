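test_that("a step keeps on a fresh signature and resets below threshold", {
  cfg <- env_config()
  # fresh signature: valence 0 >= theta, so the agent keeps
  set.seed(51)
  agent <- ssm_agent()
  state <- agent_state(agent)
  g <- random_grid(cfg)
  out <- sim_step(g, agent, state, cfg)
  expect_identical(out$record$action, "keep")
  expect_identical(out$record$valence_pre, 0)

  # stored valence -0.6 < -0.5: reset, forced -1 outcome, valence -> -0.7
  state2 <- agent_state(agent)
  sig <- compress(g)
  state2[[signature_key(sig)]] <- -0.6
  out2 <- sim_step(g, agent, state2, cfg)
  expect_identical(out2$record$action, "reset")
  expect_identical(out2$record$outcome, -1L)
  expect_equal(out2$record$valence_pre, -0.6)
  expect_equal(get_valence(state2, sig), -0.7)
})

test_that("a frozen environment makes keep outcomes deterministic", {
  cfg <- env_config(flip_prob = 0)
  g <- matrix(0L, 3, 3); g[1, 1:2] <- 1L   # 2 active cells
  agent <- ssm_agent()
  state <- agent_state(agent)
  out <- sim_step(g, agent, state, cfg)
  expect_identical(out$record$action, "keep")
  expect_identical(out$record$outcome, 1L)
  expect_identical(out$grid, g)
})

test_that("runs are seed-deterministic and length-T", {
  a <- run_sim(ssm_agent(), steps = 100, seed = 7)
  b <- run_sim(ssm_agent(), steps = 100, seed = 7)
  expect_identical(a$records, b$records)
  expect_identical(nrow(a$records), 100L)
  expect_identical(a$records$t, 1:100)

  c <- run_sim(ssm_agent(), steps = 100, seed = 8)
  expect_false(identical(a$records, c$records))

  smoke <- run_sim(ssm_agent(), steps = 1, seed = 7)
  expect_identical(nrow(smoke$records), 1L)
  expect_identical(smoke$records$valence_pre, 0)
})

test_that("experiments use distinct derived seeds and fresh memory", {
  proto <- protocol_config(steps = 30, n_runs = 5, base_seed = 100)
  expect_identical(proto$seeds, 101:105)
  logs <- run_experiment(ssm_agent(), proto)
  expect_length(logs, 5L)
  expect_true(all(vapply(logs, function(l) l$agent_type, character(1)) == "ssm"))
  expect_identical(vapply(logs, function(l) l$seed, integer(1)), 101:105)
  # fresh memory per run: every run's first consulted valence is 0
  expect_true(all(vapply(logs, function(l) l$records$valence_pre[1], numeric(1)) == 0))
})

test_that("reset steps always carry the forced -1 outcome", {
  for (agent in list(ssm_agent(policy = agent_config(theta = -0.1)),
                     random_agent(0.5), frequency_agent())) {
    log <- run_sim(agent, steps = 80, seed = 52)
    r <- log$records
    expect_true(all(r$outcome[r$action == "reset"] == -1L))
  }
})

test_that("replaying logged outcomes reproduces the valence trajectory", {
  log <- run_sim(ssm_agent(), steps = 200, seed = 53)
  mem <- valence_memory()
  cfg <- ssm_config(alpha = 0.1)
  for (i in seq_len(nrow(log$records))) {
    expect_identical(get_valence(mem, log$records$signature[i]),
                     log$records$valence_pre[i])
    update_valence(mem, log$records$signature[i], log$records$outcome[i], cfg)
  }
  expect_identical(valence_table(mem), valence_table(log$memory))
})

test_that("run logs round-trip through CSV plus JSON sidecar", {
  log <- run_sim(ssm_agent(), steps = 50, seed = 54)
  path <- withr::local_tempfile(fileext = ".csv")
  write_run_log(log, path)
  back <- read_run_log(path)
  expect_equal(back$records, log$records)
  expect_identical(back$seed, log$seed)
  expect_identical(back$agent_type, log$agent_type)
  expect_identical(back$config$flip_prob, log$config$flip_prob)
  # serialized signature convention
  expect_match(log$records$signature[1], "^[0-3]-[0-3]-[0-3]$")
})

test_that("malformed logs are rejected with the offending location", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,signature,wrong,action,outcome", "1,0-0-0,0,keep,1"), path)
  jsonlite::write_json(list(agent_type = "ssm", seed = 1, n = 3,
                            flip_prob = 0.3, steps = 1),
                       paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_run_log(path), "header")

  writeLines(c("t,signature,valence_pre,action,outcome",
               "1,0-0-0,0,hold,1"), path)
  expect_error(read_run_log(path), "line 1")
})

test_that("protocol invariants are enforced", {
  expect_error(protocol_config(steps = 0))
  expect_error(protocol_config(n_runs = 0))
  expect_error(run_sim(ssm_agent(), steps = 0, seed = 1))
})
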