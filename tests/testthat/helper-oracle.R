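# Independent brute-force PID oracle on dense probability arrays.
# Deliberately a separate code path from the package: distributions are
# full multidimensional arrays and every quantity is computed by direct
# loops over all cells, with no marginalization machinery shared with the
# implementation under test.

# p: array with dim = c(card_1, ..., card_M, card_Y)
oracle_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# marginal over the given dims (kept), by explicit summation
oracle_marginal <- function(p, keep) {
  apply(p, keep, sum)
}

# I(X_A; Y) with A a set of source dims
oracle_mi <- function(p, A) {
  M <- length(dim(p)) - 1L
  ycol <- M + 1L
  pj <- oracle_marginal(p, c(A, ycol))
  pa <- oracle_marginal(p, A)
  py <- oracle_marginal(p, ycol)
  oracle_entropy(pa) + oracle_entropy(py) - oracle_entropy(pj)
}

# specific information I(X_A; Y = y)
oracle_specific <- function(p, A, y) {
  M <- length(dim(p)) - 1L
  pj <- oracle_marginal(p, c(A, M + 1L))
  # collapse pj to matrix (states of A) x (y)
  pj <- matrix(pj, ncol = dim(p)[M + 1L])
  pa <- as.vector(oracle_marginal(p, A))
  py <- colSums(pj)
  if (py[y] <= 0) stop("p(y) = 0")
  tot <- 0
  for (a in seq_along(pa)) {
    pay <- pj[a, y]
    if (pay > 0) {
      tot <- tot + (pay / py[y]) * log2((pay / pa[a]) / py[y])
    }
  }
  tot
}

oracle_rmmi <- function(p) {
  M <- length(dim(p)) - 1L
  min(sapply(seq_len(M), function(i) oracle_mi(p, i)))
}

oracle_smmi <- function(p) {
  M <- length(dim(p)) - 1L
  full <- oracle_mi(p, seq_len(M))
  full - max(sapply(seq_len(M), function(d) oracle_mi(p, setdiff(seq_len(M), d))))
}

oracle_rmin <- function(p) {
  M <- length(dim(p)) - 1L
  py <- oracle_marginal(p, M + 1L)
  tot <- 0
  for (y in seq_along(py)) {
    if (py[y] > 0) {
      tot <- tot + py[y] *
        min(sapply(seq_len(M), function(i) oracle_specific(p, i, y)))
    }
  }
  tot
}

oracle_smin <- function(p) {
  M <- length(dim(p)) - 1L
  full <- oracle_mi(p, seq_len(M))
  py <- oracle_marginal(p, M + 1L)
  imax <- 0
  for (y in seq_along(py)) {
    if (py[y] > 0) {
      imax <- imax + py[y] * max(sapply(seq_len(M), function(d) {
        oracle_specific(p, setdiff(seq_len(M), d), y)
      }))
    }
  }
  full - imax
}

# full two-source decomposition from the oracle primitives
oracle_decompose <- function(p, redundancy = c("mmi", "min")) {
  redundancy <- match.arg(redundancy)
  i1 <- oracle_mi(p, 1L)
  i2 <- oracle_mi(p, 2L)
  i12 <- oracle_mi(p, 1:2)
  r <- if (redundancy == "mmi") oracle_rmmi(p) else oracle_rmin(p)
  c(R = r, U1 = i1 - r, U2 = i2 - r, S = i12 - i1 - i2 + r, I = i12)
}

# convert a dense array to the package's sparse joint_dist
array_to_joint <- function(p) {
  d <- dim(p)
  states <- as.matrix(expand.grid(lapply(d, seq_len)))
  joint_dist(states[p > 0, , drop = FALSE], p[p > 0],
             source_cards = d[-length(d)], target_card = d[length(d)])
}

# random two-source distribution: cardinalities 2-4, Dirichlet(1) pmf
random_joint_array <- function(M = 2L, max_card = 4L) {
  d <- c(sample(2:max_card, M, replace = TRUE), sample(2:max_card, 1L))
  g <- stats::rgamma(prod(d), 1)
  array(g / sum(g), dim = d)
}

# canonical gates as dense arrays (uniform inputs)
oracle_gate_array <- function(gate = c("XOR", "COPY", "AND")) {
  gate <- match.arg(gate)
  p <- array(0, dim = c(2, 2, 2))
  for (x1 in 0:1) for (x2 in 0:1) {
    y <- switch(gate, XOR = (x1 + x2) %% 2, COPY = x1, AND = x1 * x2)
    p[x1 + 1, x2 + 1, y + 1] <- 0.25
  }
  p
}
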