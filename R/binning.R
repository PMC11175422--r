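#' Even-frequency bin edges with interquartile-range truncation
#'
#' Builds discretization edges for a vector of sampled activations. The
#' binned range is first truncated to `[max(Q1 - 1.5 IQR, 0), Q3 + 1.5 IQR]`
#' (the lower bound floored at zero because rectifier activations are
#' nonnegative; set `clip_nonnegative = FALSE` to allow negative ranges),
#' then interior edges are placed at equal-frequency quantiles of the
#' in-range samples: the median for 2 bins, quartiles for 4, and so on.
#' Samples outside the truncated range are later assigned to the extreme
#' bins by [discretize()]. Quantiles use linear interpolation of the
#' empirical distribution (type 7).
#'
#' @param samples numeric vector of observed values
#' @param n_bins number of bins (at least 2)
#' @param clip_nonnegative floor the lower range bound at 0
#' @return strictly increasing numeric vector of `n_bins + 1` edges; the
#'   outer edges are the truncated range bounds
#' @export
iqr_even_frequency_edges <- function(samples, n_bins, clip_nonnegative = TRUE) {
  samples <- samples[is.finite(samples)]
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be at least 2")
  if (length(unique(samples)) < n_bins) {
    stop("degenerate binning: fewer than n_bins distinct finite samples")
  }
  q <- stats::quantile(samples, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2L] - q[1L]
  hi <- q[2L] + 1.5 * iqr
  lo <- q[1L] - 1.5 * iqr
  if (clip_nonnegative) lo <- max(lo, 0)
  if (hi <= lo) stop("degenerate binning: empty truncated range")
  inside <- samples[samples >= lo & samples <= hi]
  probs <- seq_len(n_bins - 1L) / n_bins
  interior <- stats::quantile(inside, probs, names = FALSE, type = 7)
  edges <- c(lo, interior, hi)
  if (any(diff(edges) <= 0)) {
    # duplicate quantiles (heavy ties, e.g. rectifier zeros): nudge to a
    # strictly increasing grid while preserving the range
    edges <- lo + (hi - lo) * .monotonize((edges - lo) / (hi - lo))
  }
  edges
}

.monotonize <- function(u) {
  for (i in seq_along(u)[-1L]) {
    if (u[i] <= u[i - 1L]) u[i] <- u[i - 1L] + 1e-9
  }
  u / max(u)
}

#' Equal-width bin edges over a fixed range
#'
#' The fixed-range strategy used for logic-gate layer activations (3 bins on
#' `[0, 5]`), normalized raycast distances (3 bins on `[0, 1]`) and global
#' position (5 bins on `[0, 40]`). Out-of-range values are assigned to the
#' extreme bins by [discretize()].
#'
#' @param n_bins number of bins (at least 2)
#' @param range_low,range_high range bounds, `range_low < range_high`
#' @return numeric vector of `n_bins + 1` equally spaced edges
#' @export
fixed_range_edges <- function(n_bins, range_low, range_high) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be at least 2")
  if (!is.finite(range_low) || !is.finite(range_high) ||
      range_low >= range_high) {
    stop("invalid range")
  }
  seq(range_low, range_high, length.out = n_bins + 1L)
}

#' Discretize continuous samples into integer codes
#'
#' Maps each value to a 1-based bin index given per-variable edge vectors.
#' Bins are left-closed and right-open with the last bin closed; a value
#' exactly on an interior edge falls in the lower bin, and values outside
#' the outer edges are clipped to the extreme bins.
#'
#' @param values numeric matrix (samples x variables) or vector
#' @param edges a numeric vector of edges (recycled across variables) or a
#'   list with one edge vector per variable
#' @return an object of class `code_matrix`: list with `codes`
#'   (integer matrix) and `cardinalities` (bins per variable)
#' @export
discretize <- function(values, edges) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("values must be finite")
  if (!is.list(edges)) edges <- rep(list(edges), ncol(values))
  if (length(edges) != ncol(values)) stop("one edge vector per variable needed")
  codes <- matrix(0L, nrow(values), ncol(values))
  cards <- integer(ncol(values))
  for (j in seq_len(ncol(values))) {
    e <- edges[[j]]
    if (any(diff(e) <= 0)) stop("edges must be strictly increasing")
    nb <- length(e) - 1L
    # right-closed lower assignment on interior edges: value <= edge -> lower
    idx <- findInterval(values[, j], e, left.open = TRUE, rightmost.closed = FALSE)
    idx[idx < 1L] <- 1L        # at or below the lower bound -> first bin
    idx[idx > nb] <- nb        # above the upper bound -> last bin
    codes[, j] <- as.integer(idx)
    cards[j] <- nb
  }
  structure(list(codes = codes, cardinalities = cards), class = "code_matrix")
}

#' @export
print.code_matrix <- function(x, ...) {
  cat("Code matrix:", nrow(x$codes), "samples x", ncol(x$codes),
      "variables; cardinalities [", paste(x$cardinalities, collapse = ", "),
      "]\n")
  invisible(x)
}
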