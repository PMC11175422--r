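#' Two-sample t test wrapped as a tidy outcome row
#'
#' Independent-samples t test (Welch) for comparing different models,
#' paired-samples t test for comparing the same models at different
#' training points. Two-sided by default; `one_sided = TRUE` tests the
#' directional hypothesis `mean(a) > mean(b)`.
#'
#' @param a,b numeric samples (equal length when `paired`)
#' @param paired paired test
#' @param one_sided test `greater` instead of `two.sided`
#' @param label optional comparison label
#' @return one-row data frame of class `test_outcome`: `label`, `test`,
#'   `statistic`, `df`, `p_value`, `n_a`, `n_b`, `mean_a`, `mean_b`,
#'   `one_sided`
#' @export
t_test <- function(a, b, paired = FALSE, one_sided = FALSE, label = "") {
  if (length(a) < 2L || length(b) < 2L) stop("need at least 2 values per group")
  if (paired && length(a) != length(b)) stop("paired samples must align")
  alt <- if (one_sided) "greater" else "two.sided"
  # zero-variance degenerate case (e.g. identical paired samples): report
  # the limit of the test rather than failing or returning NaN
  degenerate <- function() {
    md <- mean(a) - mean(b)
    stat <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else if (one_sided) as.numeric(md < 0) else 0
    list(statistic = c(t = stat), parameter = c(df = NA_real_), p.value = p)
  }
  ht <- tryCatch(
    stats::t.test(a, b, paired = paired, alternative = alt,
                  var.equal = FALSE),
    error = function(e) degenerate())
  if (!is.finite(ht$p.value)) ht <- degenerate()
  out <- data.frame(
    label = label,
    test = if (paired) "paired_t" else "independent_t",
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value, n_a = length(a), n_b = length(b),
    mean_a = mean(a), mean_b = mean(b), one_sided = one_sided,
    stringsAsFactors = FALSE
  )
  class(out) <- c("test_outcome", "data.frame")
  out
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjustment of a family of p values at level `q`. Adjusted
#' p values are monotone non-decreasing in the rank of the raw p values and
#' never smaller than them.
#'
#' @param p_values numeric vector of p values in `[0, 1]`
#' @param q FDR level
#' @return list with `adjusted` (BH-adjusted p values) and `rejected`
#'   (logical flags at level `q`)
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adj, rejected = adj <= q)
}

# apply BH within a family of test_outcome rows
.adjust_tests <- function(tests, q = 0.05) {
  if (nrow(tests) == 0L) return(tests)
  r <- bh_fdr(tests$p_value, q)
  tests$adjusted_p <- r$adjusted
  tests$rejected <- r$rejected
  tests
}
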