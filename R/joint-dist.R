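#' Discrete joint source-target distribution
#'
#' A sparse probability mass function over joint states of `M` discrete
#' sources \eqn{X_1,\dots,X_M} and one discrete target \eqn{Y}. This is the
#' substrate of all discrete information decomposition in the package:
#' mutual information, specific information and the redundancy/synergy
#' functions all operate on it. States are 1-based integer codes; only the
#' support needs to be listed (joint target states of a whole network layer
#' can have huge nominal cardinality but tiny observed support).
#'
#' @param states integer matrix, one row per support point, `M + 1` columns:
#'   the `M` source symbols followed by the target symbol.
#' @param prob numeric vector of probabilities, one per row of `states`.
#'   Must be nonnegative and sum to 1 (tolerance `1e-12` after
#'   renormalization guard of `1e-8`).
#' @param source_cards integer vector of source cardinalities. Defaults to
#'   the observed maxima.
#' @param target_card integer target cardinality. Defaults to the observed
#'   maximum.
#'
#' @return An object of class `joint_dist` with elements `states`, `p`,
#'   `M`, `source_cards`, `target_card`.
#' @examples
#' d <- xor_dist()
#' mutual_information(d, 1:2)
#' @export
joint_dist <- function(states, prob, source_cards = NULL, target_card = NULL) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (ncol(states) < 2L) stop("need at least one source and one target column")
  if (nrow(states) != length(prob)) stop("states/prob length mismatch")
  if (any(!is.finite(prob)) || any(prob < -1e-15)) {
    stop("probabilities must be finite and nonnegative")
  }
  prob <- pmax(prob, 0)
  s <- sum(prob)
  if (abs(s - 1) > 1e-8) stop("probabilities must sum to 1 (got ", format(s), ")")
  prob <- prob / s
  M <- ncol(states) - 1L
  if (any(states < 1L)) stop("state codes are 1-based positive integers")
  obs_cards <- apply(states, 2L, max)
  if (is.null(source_cards)) source_cards <- obs_cards[seq_len(M)]
  if (is.null(target_card)) target_card <- obs_cards[M + 1L]
  source_cards <- as.integer(source_cards)
  target_card <- as.integer(target_card)
  if (length(source_cards) != M) stop("source_cards length must equal M")
  if (any(obs_cards > c(source_cards, target_card))) {
    stop("observed state exceeds declared cardinality")
  }
  # merge duplicated support rows
  key <- .state_key(states)
  if (anyDuplicated(key)) {
    p <- rowsum(prob, key, reorder = TRUE)   # rows sorted by key
    st <- states[!duplicated(key), , drop = FALSE]
    st <- st[order(.state_key(st)), , drop = FALSE]
    states <- st
    prob <- as.vector(p)
  }
  keep <- prob > 0
  structure(
    list(states = states[keep, , drop = FALSE], p = prob[keep], M = M,
         source_cards = source_cards, target_card = target_card),
    class = "joint_dist"
  )
}

# collapse a state matrix row-wise into a sortable character key
.state_key <- function(m) {
  if (ncol(m) == 1L) return(sprintf("%09d", m[, 1L]))
  do.call(paste, c(lapply(seq_len(ncol(m)), function(j) sprintf("%09d", m[, j])),
                   sep = "."))
}

#' @export
print.joint_dist <- function(x, ...) {
  cat("Discrete joint distribution:", x$M, "source(s), cardinalities [",
      paste(x$source_cards, collapse = ", "), "], target cardinality ",
      x$target_card, "\n", sep = "")
  cat("Support size:", nrow(x$states), "\n")
  invisible(x)
}

# marginal pmf over a set of columns (source indices and/or M+1 for target);
# returns list(states, p) with duplicate rows merged
.marginalize <- function(dist, cols) {
  sub <- dist$states[, cols, drop = FALSE]
  key <- .state_key(sub)
  p <- rowsum(dist$p, key, reorder = TRUE)
  first <- !duplicated(key)
  st <- sub[first, , drop = FALSE]
  st <- st[order(.state_key(st)), , drop = FALSE]
  list(states = st, p = as.vector(p))
}

#' Empirical plug-in distribution from discretized codes
#'
#' Counts occurrences of each joint sources-target state across samples and
#' normalizes (the plug-in estimator). Target columns are always merged into
#' a single joint target symbol; optionally, groups of source columns are
#' merged into single source variables (e.g. one symbol per raycast block).
#'
#' @param source_codes integer matrix (samples x source variables), 1-based
#'   codes, or a `code_matrix`.
#' @param target_codes integer matrix (samples x target variables); all
#'   columns are fused into one joint target symbol.
#' @param source_grouping optional list of integer vectors; each element
#'   names the source columns merged into one source variable. Defaults to
#'   one source per column.
#' @return a [joint_dist()].
#' @export
plug_in_joint <- function(source_codes, target_codes, source_grouping = NULL) {
  source_codes <- .as_code_matrix(source_codes)
  target_codes <- .as_code_matrix(target_codes)
  n <- nrow(source_codes)
  if (n == 0L) stop("zero samples")
  if (nrow(target_codes) != n) stop("source/target sample counts differ")
  if (is.null(source_grouping)) {
    source_grouping <- as.list(seq_len(ncol(source_codes)))
  }
  src <- vapply(source_grouping, function(cols) {
    .fuse_codes(source_codes[, cols, drop = FALSE])
  }, integer(n))
  if (n == 1L) src <- matrix(src, nrow = 1L)
  tgt <- .fuse_codes(target_codes)
  states <- cbind(src, tgt)
  key <- .state_key(states)
  p <- rowsum(rep.int(1 / n, n), key, reorder = TRUE)
  first <- !duplicated(key)
  st <- states[first, , drop = FALSE]
  st <- st[order(.state_key(st)), , drop = FALSE]
  joint_dist(st, as.vector(p))
}

# fuse several 1-based code columns into one 1-based symbol (dense relabel
# of the observed combinations, order-stable)
.fuse_codes <- function(m) {
  if (ncol(m) == 1L) {
    v <- m[, 1L]
  } else {
    key <- .state_key(m)
    v <- match(key, sort(unique(key)))
  }
  as.integer(match(v, sort(unique(v))))
}

.as_code_matrix <- function(x) {
  if (inherits(x, "code_matrix")) x <- x$codes
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("codes must be integer-valued")
  storage.mode(x) <- "integer"
  if (any(x < 1L)) stop("codes are 1-based")
  x
}

#' Shannon entropy of the target marginal, in bits
#' @param dist a [joint_dist()]
#' @export
target_entropy <- function(dist) {
  m <- .marginalize(dist, dist$M + 1L)
  -sum(m$p * log2(m$p))
}

#' Mutual information between a subset of sources and the target
#'
#' Computes \eqn{I(X_A; Y)} in bits by direct summation over the joint
#' support, with the convention \eqn{0 \log 0 = 0}.
#'
#' @param dist a [joint_dist()]
#' @param subset integer vector of source indices (the subset is treated as
#'   one joint variable)
#' @return mutual information in bits (nonnegative)
#' @export
mutual_information <- function(dist, subset) {
  subset <- as.integer(subset)
  if (length(subset) == 0L) stop("subset must be non-empty")
  if (any(subset < 1L | subset > dist$M)) stop("invalid source index")
  ycol <- dist$M + 1L
  j <- .marginalize(dist, c(subset, ycol))
  a <- .marginalize(dist, subset)
  y <- .marginalize(dist, ycol)
  pa <- a$p[match(.state_key(j$states[, seq_along(subset), drop = FALSE]),
                  .state_key(a$states))]
  py <- y$p[match(j$states[, length(subset) + 1L], y$states[, 1L])]
  mi <- sum(j$p * log2(j$p / (pa * py)))
  max(mi, 0)
}

#' Specific information of a source (set) about one target outcome
#'
#' \eqn{I(X_A; Y = y) = \sum_a p(a \mid y) \log_2 \frac{p(y \mid a)}{p(y)}},
#' the Kullback-Leibler divergence between the posterior and prior over the
#' source states given the outcome. Its expectation over \eqn{y} recovers
#' \eqn{I(X_A; Y)}.
#'
#' @param dist a [joint_dist()]
#' @param subset integer vector of source indices treated jointly
#' @param y target symbol (1-based) with positive probability
#' @return specific information in bits (nonnegative)
#' @export
specific_information <- function(dist, subset, y) {
  subset <- as.integer(subset)
  if (length(subset) == 0L) stop("subset must be non-empty")
  if (any(subset < 1L | subset > dist$M)) stop("invalid source index")
  ycol <- dist$M + 1L
  ymarg <- .marginalize(dist, ycol)
  iy <- match(as.integer(y), ymarg$states[, 1L])
  if (is.na(iy) || ymarg$p[iy] <= 0) stop("p(y) must be positive")
  py <- ymarg$p[iy]
  j <- .marginalize(dist, c(subset, ycol))
  sel <- j$states[, length(subset) + 1L] == as.integer(y)
  js <- j$states[sel, seq_along(subset), drop = FALSE]
  pjy <- j$p[sel]                       # p(a, y)
  a <- .marginalize(dist, subset)
  pa <- a$p[match(.state_key(js), .state_key(a$states))]
  # p(a|y) log2( p(y|a) / p(y) )
  max(sum((pjy / py) * log2((pjy / pa) / py)), 0)
}
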