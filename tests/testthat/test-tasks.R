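test_that("logic-gate datasets are balanced and follow the label rules", {
  expect_equal(gate_label("XOR2", rbind(c(0, 1))), 1L)
  expect_equal(gate_label("COPY", rbind(c(0, 1))), 0L)
  expect_equal(gate_label("XOR3", rbind(c(0, 0, 1))), 1L)
  d <- generate_logic_gate("XOR2", 40, seed = 3)
  expect_equal(nrow(d$inputs), 40L)
  cfg <- table(apply(d$inputs, 1, paste, collapse = ""))
  expect_true(all(cfg == 10))
  expect_equal(d$labels, gate_label("XOR2", d$inputs))
  d3 <- generate_logic_gate("XOR3", seed = 1)
  expect_equal(nrow(d3$inputs), 8L)
  expect_error(generate_logic_gate("XOR2", 7), "multiple")
  # same seed reproduces the same shuffle
  expect_equal(generate_logic_gate("COPY", 16, seed = 9)$inputs,
               generate_logic_gate("COPY", 16, seed = 9)$inputs)
})

test_that("platform environment geometry, rewards and parity rule check out", {
  env <- raycast_env("XOR2", 2L)
  # exhaustive enumeration of all four configurations: output 0 pays
  # forward, output 1 pays backward
  for (b1 in 0:1) for (b2 in 0:1) {
    out <- (b1 + b2) %% 2
    st <- env_reset(env, bits = c(b1, b2))
    for (k in 1:2) st <- env_step(st, "forward")
    expect_true(st$done)
    expect_equal(st$reward, if (out == 0) 4 else -1)
    st <- env_reset(env, bits = c(b1, b2))
    for (k in 1:2) st <- env_step(st, "backward")
    expect_equal(st$reward, if (out == 1) 4 else -1)
  }
  # minimum path length equals the platform length
  env30 <- raycast_env("XOR2", 30L)
  st <- env_reset(env30, bits = c(0, 0))
  for (k in 1:29) {
    st <- env_step(st, "forward")
    expect_false(st$done)
  }
  st <- env_step(st, "forward")
  expect_true(st$done)
  expect_error(env_step(st, "forward"), "done")
})

test_that("observations encode the barrier bits and occlude the pits", {
  env <- raycast_env("XOR2", 2L)
  st <- env_reset(env, bits = c(1, 0))
  obs <- st$observation
  expect_equal(unname(obs["left_cardbox"]), 1)
  expect_equal(unname(obs["left_wall"]), 0)
  expect_equal(unname(obs["right_wall"]), 1)
  expect_equal(length(obs), 12L)
  # the observation carries no reward-side information beyond the bits:
  # two configurations with equal bits give identical observations
  st2 <- env_reset(env, bits = c(1, 0))
  expect_equal(st2$observation, obs)
  # three-bit variant exposes the front barrier bit
  env3 <- raycast_env("XOR3", 2L)
  st3 <- env_reset(env3, bits = c(0, 0, 1))
  expect_equal(unname(st3$observation["front_cardbox"]), 1)
  # distances normalized by the arena
  expect_true(all(obs[c("front_dist", "left_dist", "right_dist")] >= 0 &
                    obs[c("front_dist", "left_dist", "right_dist")] <= 1))
})

test_that("the oracle policy solves every configuration from step one", {
  for (env in list(raycast_env("XOR2", 2L), raycast_env("XOR3", 2L),
                   raycast_env("XOR2", 10L))) {
    grid <- as.matrix(expand.grid(rep(list(0:1), env$n_bits)))
    for (r in seq_len(nrow(grid))) {
      st <- env_reset(env, bits = grid[r, ])
      a <- env_oracle_action(st)
      while (!st$done) st <- env_step(st, a)
      expect_equal(st$reward, 4)
    }
  }
})

test_that("uniform configuration sampling covers all barrier patterns", {
  env <- raycast_env("XOR2", 2L)
  set.seed(77)
  cfg <- replicate(400, paste(env_reset(env)$bits, collapse = ""))
  freq <- table(cfg) / 400
  expect_equal(length(freq), 4L)
  expect_true(all(abs(freq - 0.25) < 0.1))
})

test_that("decision trials carry the stated stimulus and target structure", {
  timing <- dm_timing(3, 7, 3)
  b <- generate_dm_batch("DM1", 200, timing = timing, seed = 5)
  dec <- 10 + 1:3
  stim <- 3 + 1:7
  # target: fixate outside the decision phase, stronger stimulus inside
  expect_true(all(b$target[1:10, ] == 1L))
  expect_true(all(b$target[dec, ] %in% 2:3))
  stronger <- 1L + (b$strengths[, 1L] <= b$strengths[, 2L]) + 1L
  expect_equal(b$target[11L, ], ifelse(b$strengths[, 1L] > b$strengths[, 2L],
                                       2L, 3L))
  # attended modality mean amplitude reflects the strengths; the silent
  # modality is noisy-zero
  m1 <- apply(b$x[stim, c("mod1_a", "mod1_b"), ], 3L, colMeans)
  expect_gt(cor(m1[1L, ], b$strengths[, 1L]), 0.8)
  m2 <- b$x[stim, c("mod2_a", "mod2_b"), ]
  expect_lt(abs(mean(m2)), 0.05)
  expect_gt(stats::sd(m2), 0.1)
  # strengths respect the minimum gap
  expect_true(all(abs(b$strengths[, 1L] - b$strengths[, 2L]) >= 0.1))
  # balanced targets under symmetric sampling
  expect_lt(abs(mean(b$target[11L, ] == 2L) - 0.5), 0.15)
})

test_that("contextual distractors never affect the target", {
  b <- generate_dm_batch("CtxDM1", 300, seed = 6)
  stim <- 3 + 1:7
  distract_mean <- apply(b$x[stim, "mod2_a", ], 2L, mean)
  expect_gt(stats::sd(distract_mean), 0.1)  # distractors are present
  expect_equal(b$target[11L, ], ifelse(b$strengths[, 1L] > b$strengths[, 2L],
                                       2L, 3L))
  # distractor strength uncorrelated with the decision target
  expect_lt(abs(cor(distract_mean, as.numeric(b$target[11L, ]))), 0.15)
  # non-contextual DM2 leaves modality 1 silent
  b2 <- generate_dm_batch("DM2", 100, seed = 6)
  expect_lt(abs(mean(b2$x[stim, "mod1_a", ])), 0.05)
})

test_that("congruence matches the modality-sharing definition", {
  expect_equal(congruence("DM1", "CtxDM1"), "congruent")
  expect_equal(congruence("DM2", "CtxDM2"), "congruent")
  expect_equal(congruence("DM1", "DM2"), "incongruent")
  expect_equal(congruence("CtxDM1", "CtxDM2"), "incongruent")
  expect_equal(congruence("DM1", "CtxDM2"), "incongruent")
  expect_error(congruence("DM1", "DM1"), "distinct")
  pairs <- dm_task_pairs()
  expect_equal(nrow(pairs), 6L)
  expect_equal(sum(pairs$congruence == "congruent"), 2L)
})
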