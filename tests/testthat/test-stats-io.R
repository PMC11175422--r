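test_that("t tests match closed-form values and degenerate limits", {
  # identical paired samples: the limit of the test is statistic 0, p 1
  r <- t_test(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # equal independent samples: statistic exactly 0
  r2 <- t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$statistic, 0)
  # hand-computed Welch case
  a <- c(1.1, 2.3, 0.8, 1.9, 1.5)
  b <- c(2.0, 2.8, 2.2, 3.1)
  se <- sqrt(var(a) / 5 + var(b) / 4)
  tstat <- (mean(a) - mean(b)) / se
  r3 <- t_test(a, b)
  expect_equal(r3$statistic, tstat, tolerance = 1e-12)
  expect_equal(r3$test, "independent_t")
  # one-sided halves the symmetric two-sided p in the positive direction
  r4 <- t_test(b, a, one_sided = TRUE)
  expect_equal(r4$p_value, r3$p_value / 2, tolerance = 1e-12)
  expect_error(t_test(1, c(1, 2)), "at least 2")
  expect_error(t_test(c(1, 2), c(1, 2, 3), paired = TRUE), "align")
})

test_that("BH correction reproduces the step-up procedure", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r$rejected))
  r2 <- bh_fdr(0.04, q = 0.05)
  expect_equal(r2$adjusted, 0.04)
  expect_true(r2$rejected)
  expect_false(any(bh_fdr(rep(1, 5))$rejected))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  # agreement with an independently coded step-up on random families
  set.seed(19)
  for (rep in 1:100) {
    p <- runif(sample(3:12, 1))
    got <- bh_fdr(p)$adjusted
    m <- length(p)
    o <- order(p)
    ref <- numeric(m)
    prev <- 1
    for (i in m:1) {
      prev <- min(prev, p[o[i]] * m / i)
      ref[o[i]] <- prev
    }
    expect_equal(got, ref, tolerance = 1e-12)
    expect_true(all(got >= p - 1e-12))
  }
})

test_that("experiment results round-trip through CSV/JSON", {
  metrics <- data.frame(gate = "XOR2", dropout_p = c(0, 0.5), seed = 1L,
                        hidden_R = c(0.21, 0.43), stringsAsFactors = FALSE)
  tests <- t_test(rnorm(5) + 1, rnorm(5), label = "demo")
  tests <- pidnets:::.adjust_tests(tests)
  res <- pidnets:::.experiment_result("dropout", metrics, tests,
                                      config = list(gate = "XOR2",
                                                    seeds = 1L))
  dir <- withr::local_tempdir()
  paths <- write_experiment_result(res, dir)
  expect_true(all(file.exists(paths)))
  back <- read_experiment_result(dir, "dropout")
  expect_equal(back$metrics$hidden_R, metrics$hidden_R)
  expect_equal(back$tests$p_value, tests$p_value)
  expect_equal(back$config$gate, "XOR2")
  # rerunning the writer yields identical bytes
  first <- readLines(paths["metrics"])
  write_experiment_result(res, dir)
  expect_identical(readLines(paths["metrics"]), first)
})

test_that("run_experiment dispatches YAML configs and validates fields", {
  dir <- withr::local_tempdir()
  cfg <- file.path(dir, "exp.yaml")
  writeLines(c("experiment: lesion", "gate: XOR2", "dropout_p: 0.0",
               "seeds: [1, 2]", "k_values: [3]"), cfg)
  res <- run_experiment(cfg, output_dir = dir)
  expect_s3_class(res, "experiment_result")
  expect_true(file.exists(file.path(dir, "lesion_metrics.csv")))
  rep <- report_results(dir)
  expect_named(rep, "lesion")
  expect_true("p_value" %in% names(rep$lesion))
  expect_error(run_experiment(list(experiment = "lesion", bogus = 1)),
               "bogus")
  expect_error(run_experiment(list(gate = "XOR2")), "experiment")
  expect_error(run_experiment(file.path(dir, "missing.yaml")), "not found")
})

test_that("the canonical PID table prints the exact gate atoms", {
  tab <- pid_canonical_table()
  expect_equal(nrow(tab), 6L)
  xor_mmi <- tab[tab$gate == "XOR" & tab$redundancy_function == "mmi", ]
  expect_equal(xor_mmi$S, 1, tolerance = 1e-12)
  and_min <- tab[tab$gate == "AND" & tab$redundancy_function == "min", ]
  expect_equal(and_min$R, 0.3112781, tolerance = 1e-6)
  expect_equal(and_min$S, 0.5, tolerance = 1e-9)
})
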