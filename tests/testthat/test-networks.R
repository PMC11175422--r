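# trained networks are cached by the experiment layer; reuse the same
# cache here so the suite trains each (gate, dropout, seed) only once
cached_net <- function(gate, p, s) pidnets:::.cached_mlp(gate, p, s)

test_that("feedforward nets learn the gates and evaluate deterministically", {
  net <- cached_net("XOR2", 0, 1)
  expect_true(net$converged)
  grid <- pidnets:::.gate_grid("XOR2")
  expect_equal(mlp_accuracy(net, list(inputs = grid,
                                      labels = gate_label("XOR2", grid))), 1)
  # dropout trained, dropout-free evaluation still perfect
  netd <- cached_net("COPY", 0.5, 1)
  expect_true(netd$converged)
  # evaluation has no stochastic component
  expect_identical(predict(netd, grid), predict(netd, grid))
  # training is deterministic given the seed
  d <- generate_logic_gate("XOR2", seed = 1)
  n1 <- train_mlp(mlp_spec(2), d, epochs = 50L, seed = 7)
  n2 <- train_mlp(mlp_spec(2), d, epochs = 50L, seed = 7)
  expect_identical(n1$W, n2$W)
  expect_error(mlp_spec(2, dropout_p = 1), "dropout")
})

test_that("activation records are frozen, aligned and nonnegative", {
  net <- cached_net("XOR2", 0, 2)
  grid <- pidnets:::.gate_grid("XOR2")
  rec <- sample_mlp_activations(net, grid)
  expect_length(rec$layers, 2L)
  expect_equal(dim(rec$layers[[1L]]), c(4L, 10L))
  expect_equal(dim(rec$layers[[2L]]), c(4L, 10L))
  expect_true(all(rec$layers[[1L]] >= 0))
  expect_equal(length(rec$outputs), 4L)
  # repeated sampling is bit-identical (weights frozen, no dropout)
  rec2 <- sample_mlp_activations(net, grid)
  expect_identical(rec$layers, rec2$layers)
})

test_that("lesioning zeroes outgoing activations and degrades gracefully", {
  net <- cached_net("XOR2", 0, 3)
  grid <- pidnets:::.gate_grid("XOR2")
  les <- lesion_neurons(net, 1L, c(2L, 5L))
  rec <- sample_mlp_activations(les, grid)
  expect_true(all(rec$layers[[1L]][, c(2, 5)] == 0))
  # removing everything forces a constant output: chance on balanced gates
  for (l in 1:2) les <- lesion_neurons(les, l, 1:10)
  expect_equal(mlp_accuracy(les, list(inputs = grid,
                                      labels = gate_label("XOR2", grid))),
               0.5)
  expect_error(lesion_neurons(net, 1L, 42L), "invalid")
})

test_that("recurrent nets solve single tasks and sampling aligns timesteps", {
  net <- train_rnn("DM1", total_steps = 6000L, seed = 1)
  acc <- rnn_accuracy(net, n_trials = 100L)
  expect_gt(acc[["DM1"]], 0.8)
  # determinism
  net2 <- train_rnn("DM1", total_steps = 500L, seed = 3)
  net3 <- train_rnn("DM1", total_steps = 500L, seed = 3)
  expect_equal(net2$weights, net3$weights, tolerance = 1e-12)
  rec <- sample_rnn_activations(net, n_trials = 20L, seed = 5)
  Tlen <- attr(net$timing, "total")
  expect_equal(nrow(rec$sources), 20L * (Tlen - 1L))
  expect_equal(ncol(rec$sources), 6L + 10L)
  expect_equal(ncol(rec$targets), 10L)
  # the source block at t+1 equals the target block at t within a trial
  h_src <- rec$sources[2:(Tlen - 1L), 7:16]
  h_tgt <- rec$targets[1:(Tlen - 2L), ]
  expect_equal(unname(h_src), unname(h_tgt), tolerance = 1e-12)
})

test_that("sequential training of an incongruent pair forgets the first task", {
  inter <- train_rnn(c("DM1", "DM2"), "interleaved", total_steps = 20000L,
                     seed = 2)
  seqn <- train_rnn(c("DM1", "DM2"), "sequential", total_steps = 20000L,
                    seed = 2)
  ai <- rnn_accuracy(inter, n_trials = 100L)
  as_ <- rnn_accuracy(seqn, n_trials = 100L)
  expect_gt(min(ai), 0.75)            # interleaving solves both tasks
  expect_gt(as_[["DM2"]], 0.75)       # the recently trained task is intact
  expect_lt(as_[["DM1"]], min(ai))    # the first task degrades
  expect_error(train_rnn(c("DM1", "DM2", "CtxDM1")), "two tasks")
})

test_that("decision-phase loss weighting speeds up decision learning", {
  # early in training, the scarce decision steps dominate the weighted
  # loss and decision accuracy runs ahead of the unweighted control
  weighted <- train_rnn("DM2", total_steps = 1000L, seed = 11)
  flat <- train_rnn("DM2", total_steps = 1000L, seed = 11,
                    decision_weight = 1)
  expect_gt(rnn_accuracy(weighted)[["DM2"]], rnn_accuracy(flat)[["DM2"]])
})

test_that("policy-gradient agents master the two-bit platform task", {
  env <- raycast_env("XOR2", 2L)
  res <- train_agent(new_agent(seed = 4), env, episodes = 6000L,
                     window = 200L, seed = 4)
  expect_true(res$reached_threshold)
  expect_equal(agent_success_rate(res$agent, env), 1)
  # curriculum produces one checkpoint per stage with success recorded
  run <- train_curriculum(list(raycast_env("XOR2", 2L),
                               raycast_env("XOR2", 10L)),
                          seed = 4, episodes_per_stage = 6000L,
                          window = 200L)
  expect_length(run, 2L)
  expect_true(all(vapply(run, function(st) inherits(st$agent, "pg_agent"),
                         TRUE)))
  expect_gte(run[[2L]]$success, 0.75)
  rec <- sample_agent_activations(run[[2L]]$agent,
                                  list(raycast_env("XOR2", 2L)))
  expect_equal(ncol(rec$inputs), 12L)
  expect_length(rec$layers, 2L)
  expect_true(all(rec$layers[[1L]] >= 0))
})
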