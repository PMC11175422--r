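test_that("canonical gate decompositions match exact values", {
  # XOR: all synergy; COPY: all unique to source 1; identical under both
  # redundancy functions
  for (rf in c("mmi", "min")) {
    x <- pid_decompose(xor_dist(), rf)
    expect_equal(unname(c(x$redundancy, x$unique, x$synergy,
                          x$mutual_information)), c(0, 0, 0, 1, 1),
                 tolerance = 1e-9)
    cp <- pid_decompose(copy_dist(), rf)
    expect_equal(unname(c(cp$redundancy, cp$unique, cp$synergy,
                          cp$mutual_information)), c(0, 1, 0, 0, 1),
                 tolerance = 1e-9)
  }
  # AND gate: R_min = 3/4 log2(4/3) ~ 0.311278, S_min = 1/2, I = H(1/4)
  a <- pid_decompose(and_dist(), "min")
  expect_equal(a$redundancy, 0.75 * log2(4 / 3), tolerance = 1e-9)
  expect_equal(a$synergy, 0.5, tolerance = 1e-9)
  expect_equal(a$mutual_information, 2 - 0.75 * log2(3), tolerance = 1e-9)
  expect_equal(a$unique, c(0, 0), tolerance = 1e-9)
})

test_that("mutual information follows direct-summation oracle and contracts", {
  expect_equal(mutual_information(xor_dist(), 1L), 0, tolerance = 1e-12)
  expect_equal(mutual_information(xor_dist(), 1:2), 1, tolerance = 1e-12)
  # independent target: 4 uniform joint states, y independent of x
  g <- as.matrix(expand.grid(1:2, 1:2))
  ind <- joint_dist(cbind(g[, 1L], g[, 2L]), rep(0.25, 4))
  expect_equal(mutual_information(ind, 1L), 0, tolerance = 1e-12)
  expect_error(mutual_information(xor_dist(), integer(0)), "non-empty")
  expect_error(mutual_information(xor_dist(), 3L), "invalid")
})

test_that("specific information matches examples and averages to MI", {
  expect_equal(specific_information(copy_dist(), 1L, 1L), 1, tolerance = 1e-12)
  # AND gate, source 1, y = TRUE (code 2): posterior concentrates on x1 = 1
  expect_equal(specific_information(and_dist(), 1L, 2L), 1, tolerance = 1e-12)
  # independent source: specific information is 0 for every outcome
  g <- as.matrix(expand.grid(1:2, 1:2))
  ind <- joint_dist(cbind(g[, 1L], g[, 2L]), rep(0.25, 4))
  expect_equal(specific_information(ind, 1L, 2L), 0, tolerance = 1e-12)
  expect_error(specific_information(copy_dist(), 1L, 99L), "positive")
  # expectation over y recovers I(X_i; Y) on random distributions
  set.seed(5)
  for (rep in 1:20) {
    p <- random_joint_array()
    d <- array_to_joint(p)
    y <- pidnets:::.marginalize(d, d$M + 1L)
    for (i in 1:2) {
      ev <- sum(vapply(seq_along(y$p), function(k) {
        y$p[k] * specific_information(d, i, y$states[k, 1L])
      }, 0))
      expect_equal(ev, mutual_information(d, i), tolerance = 1e-9)
    }
  }
})

test_that("redundancy and synergy functions reproduce hand-derived cases", {
  expect_equal(redundancy_mmi(xor_dist()), 0, tolerance = 1e-12)
  expect_equal(redundancy_mmi(copy_dist()), 0, tolerance = 1e-12)
  dup <- joint_dist(cbind(c(1L, 2L), c(1L, 2L), c(1L, 2L)), c(0.5, 0.5))
  expect_equal(redundancy_mmi(dup), 1, tolerance = 1e-12)
  expect_equal(redundancy_min(dup), 1, tolerance = 1e-12)
  expect_equal(synergy_mmi(xor_dist()), 1, tolerance = 1e-12)
  expect_equal(synergy_mmi(copy_dist()), 0, tolerance = 1e-12)
  expect_equal(synergy_min(xor_dist()), 1, tolerance = 1e-12)
  expect_equal(synergy_min(and_dist()), 0.5, tolerance = 1e-9)
  expect_equal(synergy_min(copy_dist()), 0, tolerance = 1e-12)
  # three-source parity: fully synergistic at full order
  expect_equal(synergy_mmi(parity3_dist()), 1, tolerance = 1e-12)
  single <- joint_dist(cbind(c(1L, 2L), c(1L, 2L)), c(0.5, 0.5))
  expect_error(redundancy_mmi(single), "two sources")
})

test_that("two-source decomposition agrees with the brute-force oracle", {
  set.seed(11)
  for (rep in 1:100) {
    p <- random_joint_array()
    d <- array_to_joint(p)
    for (rf in c("mmi", "min")) {
      got <- pid_decompose(d, rf)
      want <- oracle_decompose(p, rf)
      expect_equal(c(got$redundancy, got$unique, got$synergy,
                     got$mutual_information),
                   unname(want), tolerance = 1e-9)
    }
  }
})

test_that("decomposition identity, nonnegativity and function ordering hold", {
  set.seed(21)
  for (rep in 1:200) {
    p <- random_joint_array()
    d <- array_to_joint(p)
    vals <- lapply(c("mmi", "min"), function(rf) pid_decompose(d, rf))
    for (v in vals) {
      expect_equal(v$redundancy + sum(v$unique) + v$synergy,
                   v$mutual_information, tolerance = 1e-9)
      expect_true(all(c(v$redundancy, v$unique, v$synergy) >= -1e-12))
    }
    expect_lte(vals[[2L]]$redundancy, vals[[1L]]$redundancy + 1e-9)
    expect_lte(vals[[2L]]$synergy, vals[[1L]]$synergy + 1e-9)
    # chain consistency and monotonicity of MI
    expect_gte(mutual_information(d, 1:2) + 1e-9,
               max(mutual_information(d, 1L), mutual_information(d, 2L)))
    hy <- target_entropy(d)
    expect_lte(mutual_information(d, 1:2), hy + 1e-9)
  }
})

test_that("normalized atoms sum to one when information is positive", {
  n <- pid_decompose(and_dist(), "min", normalize = TRUE)
  expect_equal(n$redundancy + sum(n$unique) + n$synergy, 1, tolerance = 1e-9)
  # zero-information distribution cannot be normalized
  g <- as.matrix(expand.grid(1:2, 1:2, 1:2))
  ind <- joint_dist(g, rep(0.125, 8))
  expect_error(pid_decompose(ind, normalize = TRUE), "normalize")
})

test_that("K-order averaging reduces correctly and sampling is unbiased", {
  codes <- cbind(c(1L, 1L, 2L, 2L), c(1L, 2L, 1L, 2L))
  tgt <- matrix(1L + (rowSums(codes) %% 2L))
  # M = 2, K = 2: single subset equals the full decomposition
  k2 <- korder_average(codes, tgt, K = 2)
  expect_equal(k2$n_subsets_evaluated, 1L)
  expect_equal(k2$synergy, 1, tolerance = 1e-12)
  expect_true(is.na(k2$subset_sampling_seed))
  # larger layer: exhaustive average vs capped-at-total sampling agree
  set.seed(3)
  src <- matrix(sample(1:3, 60 * 5, replace = TRUE), 60, 5)
  tg <- matrix(sample(1:2, 60, replace = TRUE))
  full <- korder_average(src, tg, K = 2, max_subsets = Inf)
  capped <- korder_average(src, tg, K = 2, max_subsets = 10L, seed = 42L)
  expect_equal(full$n_subsets_evaluated, 10L)
  expect_equal(capped$n_subsets_evaluated, 10L)
  expect_equal(capped$subset_sampling_seed, NA_integer_)
  expect_equal(capped$redundancy, full$redundancy, tolerance = 1e-12)
  expect_equal(capped$synergy, full$synergy, tolerance = 1e-12)
  # K = M: one subset, equal to direct full-order computation
  km <- korder_average(src, tg, K = 5)
  expect_equal(km$n_subsets_evaluated, 1L)
  d <- plug_in_joint(src, tg)
  expect_equal(km$redundancy, redundancy_mmi(d), tolerance = 1e-12)
  expect_equal(km$synergy, synergy_mmi(d), tolerance = 1e-12)
  expect_error(korder_average(src, tg, K = 1), "between 2")
  expect_error(korder_average(src, tg, K = 6), "between 2")
})

test_that("K-order subset sampling matches exhaustive enumeration in the mean", {
  set.seed(8)
  src <- matrix(sample(1:3, 40 * 6, replace = TRUE), 40, 6)
  tg <- matrix(sample(1:2, 40, replace = TRUE))
  full <- korder_average(src, tg, K = 2, max_subsets = Inf)
  samp <- korder_average(src, tg, K = 2, max_subsets = 8L, seed = 7L)
  expect_equal(samp$n_subsets_evaluated, 8L)
  expect_equal(samp$subset_sampling_seed, 7L)
  # a sampled average is within the spread of subset values
  expect_lt(abs(samp$synergy - full$synergy), 0.5)
})

test_that("per-neuron pairwise synergy honours symmetry and constants", {
  codes <- cbind(c(1L, 1L, 2L, 2L), c(1L, 2L, 1L, 2L))
  tgt <- matrix(1L + (rowSums(codes) %% 2L))
  # two-neuron layer: the statistic is the single pair's synergy
  expect_equal(pairwise_neuron_synergy(codes, tgt, 1L), 1, tolerance = 1e-12)
  expect_equal(pairwise_neuron_synergy(codes, tgt, 2L), 1, tolerance = 1e-12)
  # permuting neuron labels permutes the per-neuron values identically
  set.seed(13)
  src <- matrix(sample(1:3, 30 * 4, replace = TRUE), 30, 4)
  tg <- matrix(sample(1:2, 30, replace = TRUE))
  vals <- vapply(1:4, function(i) pairwise_neuron_synergy(src, tg, i), 0)
  perm <- c(3L, 1L, 4L, 2L)
  vals_p <- vapply(1:4, function(i) {
    pairwise_neuron_synergy(src[, perm], tg, i)
  }, 0)
  expect_equal(vals_p, vals[perm], tolerance = 1e-12)
  # a constant neuron contributes no marginal information of its own
  src_const <- cbind(src[, 1:3], 1L)
  v4 <- pairwise_neuron_synergy(src_const, tg, 4L)
  d_pair <- plug_in_joint(src_const[, c(4L, 1L)], tg)
  expect_equal(mutual_information(d_pair, 1L), 0, tolerance = 1e-12)
  expect_error(pairwise_neuron_synergy(src[, 1, drop = FALSE], tg, 1L),
               "two neurons")
})

test_that("joint_dist validates its invariants", {
  expect_error(joint_dist(cbind(1:2, 1:2), c(0.7, 0.4)), "sum to 1")
  expect_error(joint_dist(cbind(1:2, 1:2), c(1.2, -0.2)), "nonnegative")
  expect_error(joint_dist(cbind(0:1, 1:2), c(0.5, 0.5)), "1-based")
  expect_error(joint_dist(cbind(1:2, 1:2), c(0.5, 0.5), source_cards = 1L),
               "cardinality")
  # duplicate support rows are merged
  d <- joint_dist(rbind(c(1, 1), c(1, 1), c(2, 2)), c(0.25, 0.25, 0.5))
  expect_equal(nrow(d$states), 2L)
  expect_equal(sum(d$p), 1)
})
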