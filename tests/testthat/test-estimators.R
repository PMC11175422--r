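test_that("even-frequency edges put the median split where expected", {
  e <- iqr_even_frequency_edges(1:8, 2)
  expect_equal(e[2L], 4.5)
  expect_equal(length(e), 3L)
  # nonnegative clipping for rectifier-style samples
  x <- c(rep(0, 3), 0.5, 1, 2, 4, 8)
  e2 <- iqr_even_frequency_edges(x, 3)
  expect_gte(e2[1L], 0)
  # the full bin-count sweep used in the robustness analyses
  set.seed(2)
  s <- rexp(500)
  for (nb in c(3, 4, 5, 10)) {
    e <- iqr_even_frequency_edges(s, nb)
    expect_equal(length(e), nb + 1L)
    expect_true(all(diff(e) > 0))
  }
  expect_error(iqr_even_frequency_edges(rep(2, 50), 3), "degenerate")
})

test_that("even-frequency binning balances counts for distinct samples", {
  set.seed(4)
  x <- rnorm(300)
  for (nb in c(3, 5)) {
    e <- iqr_even_frequency_edges(x, nb)
    cm <- discretize(matrix(x[x >= e[1] & x <= e[nb + 1]]), e)
    counts <- tabulate(cm$codes, nb)
    expect_lte(max(counts) - min(counts), ceiling(length(x) * 0.01) + 1)
  }
})

test_that("fixed-range edges are equal width and validated", {
  expect_equal(fixed_range_edges(3, 0, 5), c(0, 5 / 3, 10 / 3, 5))
  expect_equal(fixed_range_edges(3, 0, 1), c(0, 1, 2, 3) / 3)
  expect_equal(length(fixed_range_edges(5, 0, 40)), 6L)
  expect_error(fixed_range_edges(3, 2, 2), "range")
  expect_error(fixed_range_edges(1, 0, 1), "n_bins")
})

test_that("discretize follows the boundary and clipping conventions", {
  e <- c(0, 1, 2, 3)
  cm <- discretize(matrix(c(-5, 0.5, 1, 1.5, 2, 2.5, 99)), e)
  # below range -> first bin; interior edge -> lower bin; above -> last
  expect_equal(as.vector(cm$codes), c(1L, 1L, 1L, 2L, 2L, 3L, 3L))
  expect_equal(cm$cardinalities, 3L)
  expect_error(discretize(matrix(c(1, NA)), e), "finite")
  expect_error(discretize(matrix(1:3), c(0, 0, 1)), "increasing")
  # constant column keeps a single code
  cc <- discretize(matrix(rep(0.5, 10)), e)
  expect_equal(length(unique(cc$codes)), 1L)
})

test_that("plug-in distribution reproduces exact frequencies and groupings", {
  codes <- cbind(c(1L, 1L, 2L, 2L), c(1L, 2L, 1L, 2L))
  tgt <- matrix(1L + (rowSums(codes) %% 2L))
  d <- plug_in_joint(codes, tgt)
  expect_equal(synergy_mmi(d), 1, tolerance = 1e-12)
  expect_equal(sort(d$p), rep(0.25, 4))
  # duplicated sample block leaves the distribution unchanged
  d2 <- plug_in_joint(codes[rep(1:4, 3), ], tgt[rep(1:4, 3), , drop = FALSE])
  expect_equal(d2$p, d$p)
  expect_equal(d2$states, d$states)
  # grouping fuses one-hot columns into a single source
  onehot <- cbind(c(1L, 2L, 1L, 2L), c(2L, 1L, 2L, 1L))  # complementary
  d3 <- plug_in_joint(cbind(onehot, codes[, 2L]), tgt,
                      source_grouping = list(1:2, 3L))
  expect_equal(d3$M, 2L)
  expect_equal(d3$source_cards[1L], 2L)  # two observed fused states
  expect_error(plug_in_joint(codes[0, ], tgt[0, , drop = FALSE]), "zero")
})

test_that("plug-in + exact MI equals the histogram mutual information", {
  set.seed(9)
  x <- sample(1:3, 200, replace = TRUE)
  y <- sample(1:2, 200, replace = TRUE)
  d <- plug_in_joint(matrix(x), matrix(y))
  tab <- table(x, y) / 200
  px <- rowSums(tab); py <- colSums(tab)
  ref <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (tab[i, j] > 0) ref <- ref + tab[i, j] * log2(tab[i, j] / (px[i] * py[j]))
  }
  expect_equal(mutual_information(d, 1L), as.numeric(ref), tolerance = 1e-12)
})

test_that("copula MI matches the Gaussian closed form and is rank-invariant", {
  set.seed(31)
  n <- 5000
  for (rho in c(0, 0.5, 0.9)) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    expect_lt(abs(gcmi_mutual_information(x, y) + 0.5 * log2(1 - rho^2)),
              0.03)
  }
  x <- rnorm(n); y <- x + rnorm(n)
  expect_equal(gcmi_mutual_information(exp(x), y),
               gcmi_mutual_information(x, y), tolerance = 1e-9)
  expect_error(gcmi_mutual_information(rep(1, 100), rnorm(100)), "constant")
  expect_error(gcmi_mutual_information(rnorm(5), rnorm(5)), "10 samples")
})

test_that("copula pair decomposition behaves on constructed cases", {
  set.seed(33)
  n <- 10000
  x1 <- rnorm(n); x2 <- rnorm(n)
  # additive target: joint information strictly exceeds either marginal
  p <- gcmi_pair_synergy(x1, x2, x1 + x2)
  expect_gt(p$synergy, 0.2)
  # target equals one source: all information unique to it
  q <- gcmi_pair_synergy(x1, x2, x1)
  expect_lt(abs(q$synergy), 0.05)
  expect_gt(q$unique[1L], 1)
  expect_lt(q$redundancy, 0.05)
  # identical sources: no unique information
  r <- gcmi_pair_synergy(x1, x1, x1 + rnorm(n))
  expect_equal(r$unique, c(0, 0), tolerance = 1e-9)
})
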