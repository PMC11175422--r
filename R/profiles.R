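#' Averaged second-order decomposition between two code sets
#'
#' Decomposes every pair of (grouped) sources against the joint target
#' symbol, and averages both the raw atoms (bits) and the
#' mutual-information-normalized shares. Pairs whose joint mutual
#' information is below `eps` are excluded from the normalized averages
#' (their shares are undefined).
#'
#' @param source_codes,target_codes integer code matrices (or
#'   `code_matrix`)
#' @param redundancy `"mmi"` or `"min"`
#' @param source_grouping optional source grouping (see [plug_in_joint()])
#' @param max_pairs cap on pairs (uniformly sampled with `seed` beyond it)
#' @param seed pair-sampling seed
#' @param eps mutual-information floor for normalization
#' @param pairs optional explicit list of source-index pairs (into the
#'   grouped sources) to evaluate instead of all combinations
#' @return list with `n_pairs`, raw means `R`, `U1`, `U2`, `S`, `I`, and
#'   normalized means `R_norm`, `U1_norm`, `U2_norm`, `S_norm` (`NA` when
#'   no pair clears `eps`)
#' @export
pair_profile <- function(source_codes, target_codes,
                         redundancy = c("mmi", "min"),
                         source_grouping = NULL, max_pairs = Inf,
                         seed = 1L, eps = 1e-10, pairs = NULL) {
  redundancy <- match.arg(redundancy)
  source_codes <- .as_code_matrix(source_codes)
  target_codes <- .as_code_matrix(target_codes)
  if (is.null(source_grouping)) {
    source_grouping <- as.list(seq_len(ncol(source_codes)))
  }
  M <- length(source_grouping)
  if (M < 2L) stop("need at least two sources")
  if (is.null(pairs)) pairs <- utils::combn(M, 2L, simplify = FALSE)
  if (length(pairs) > max_pairs) {
    rng <- .isolated_rng(seed)
    pairs <- pairs[rng$sample_int(length(pairs), max_pairs)]
  }
  vals <- t(vapply(pairs, function(pr) {
    d <- plug_in_joint(source_codes, target_codes,
                       source_grouping = source_grouping[pr])
    p <- pid_decompose(d, redundancy)
    c(R = p$redundancy, U1 = p$unique[1L], U2 = p$unique[2L],
      S = p$synergy, I = p$mutual_information)
  }, numeric(5)))
  ok <- vals[, "I"] > eps
  norm <- if (any(ok)) {
    colMeans(vals[ok, c("R", "U1", "U2", "S"), drop = FALSE] /
               vals[ok, "I"])
  } else c(R = NA_real_, U1 = NA_real_, U2 = NA_real_, S = NA_real_)
  c(list(n_pairs = length(pairs)),
    as.list(colMeans(vals)),
    stats::setNames(as.list(norm), c("R_norm", "U1_norm", "U2_norm", "S_norm")))
}

# discretize one activation layer with either strategy
.layer_codes <- function(mat, strategy = c("fixed", "iqr"), n_bins = 3L,
                         range = c(0, 5)) {
  strategy <- match.arg(strategy)
  if (strategy == "fixed") {
    discretize(mat, fixed_range_edges(n_bins, range[1L], range[2L]))
  } else {
    edges <- lapply(seq_len(ncol(mat)), function(j) {
      col <- mat[, j]
      # near-constant units (or units whose IQR-truncated range collapses,
      # e.g. mostly-silent rectifier units) fall back to an equal-width
      # grid over their observed range
      fallback <- function() {
        lo <- min(col); hi <- max(col)
        if (hi - lo == 0) hi <- lo + 1e-6
        fixed_range_edges(n_bins, lo - 1e-9, hi + 1e-9)
      }
      if (length(unique(col)) < n_bins) fallback() else
        tryCatch(iqr_even_frequency_edges(col, n_bins),
                 error = function(e) fallback())
    })
    discretize(mat, edges)
  }
}

#' Layer-transition PID profile of an activation record
#'
#' Computes second-order (and optionally K-order) redundancy/synergy for
#' every layer transition of a sampled network: input to first layer,
#' between hidden layers, and last hidden layer to output when the record
#' carries outputs. Sources are discretized per the record's task type
#' (logic-gate inputs are already binary; platform observations use the
#' raycast/position grouping of [env_input_spec()]; layer activations use
#' the requested strategy with edges computed per layer within this
#' record), and the downstream layer is always fused into one joint target
#' symbol.
#'
#' @param record an `activation_record` from [sample_mlp_activations()] or
#'   [sample_agent_activations()]
#' @param redundancy `"mmi"` or `"min"`
#' @param n_bins bins per activation unit
#' @param layer_strategy `"fixed"` (equal width over `layer_range`, the
#'   logic-gate setting) or `"iqr"` (even-frequency with IQR truncation,
#'   the platform setting)
#' @param layer_range range for the fixed strategy
#' @param K additionally compute a K-order average per transition (e.g.
#'   `K = 10` for the full-order profile of a ten-unit layer); `NULL`
#'   skips it
#' @param max_pairs,seed pair sampling controls passed to [pair_profile()]
#' @return object of class `layer_pid_profile`: list of per-transition
#'   profiles (`input`, `hidden1`, `hidden2` as available), each a
#'   [pair_profile()] result plus optional `korder`
#' @export
layer_pid_profile <- function(record, redundancy = c("mmi", "min"),
                              n_bins = 3L,
                              layer_strategy = c("fixed", "iqr"),
                              layer_range = c(0, 5), K = NULL,
                              max_pairs = Inf, seed = 1L) {
  redundancy <- match.arg(redundancy)
  layer_strategy <- match.arg(layer_strategy)
  layers <- lapply(record$layers, .layer_codes, strategy = layer_strategy,
                   n_bins = n_bins, range = layer_range)
  # input sources
  if (record$meta$kind == "agent") {
    spec <- env_input_spec(n_dist_bins = n_bins)
    in_codes <- discretize(record$inputs[, spec$columns, drop = FALSE],
                           spec$edges)
    in_grouping <- spec$grouping
  } else {
    in_codes <- discretize(record$inputs,
                           fixed_range_edges(2L, -0.5, 1.5))
    in_grouping <- NULL
  }
  transitions <- list()
  if (record$meta$kind == "agent") {
    # raycast pairs are the headline input profile; raycast x position
    # pairs are reported as a separate transition
    rc <- in_grouping[c("front", "left", "right")]
    transitions$input <- list(src = in_codes, tgt = layers[[1L]],
                              grouping = rc)
    transitions$input_position <- list(src = in_codes, tgt = layers[[1L]],
                                       grouping = in_grouping,
                                       pairs = lapply(1:3, function(i) c(i, 4L)))
  } else {
    transitions$input <- list(src = in_codes, tgt = layers[[1L]],
                              grouping = in_grouping)
  }
  if (length(layers) >= 2L) {
    transitions$hidden1 <- list(src = layers[[1L]], tgt = layers[[2L]],
                                grouping = NULL)
  }
  if (!is.null(record$outputs)) {
    out_codes <- matrix(as.integer(record$outputs > 0.5) + 1L, ncol = 1L)
    transitions$hidden2 <- list(src = layers[[length(layers)]],
                                tgt = out_codes, grouping = NULL)
  }
  out <- lapply(transitions, function(tr) {
    prof <- pair_profile(tr$src, tr$tgt, redundancy = redundancy,
                         source_grouping = tr$grouping,
                         max_pairs = max_pairs, seed = seed,
                         pairs = tr$pairs)
    if (!is.null(K)) {
      M <- if (is.null(tr$grouping)) ncol(.as_code_matrix(tr$src)) else
        length(tr$grouping)
      if (K >= 2L && K <= M) {
        prof$korder <- korder_average(tr$src, tr$tgt, K = K,
                                      redundancy = redundancy,
                                      source_grouping = tr$grouping,
                                      seed = seed)
      }
    }
    prof
  })
  structure(list(transitions = out, redundancy_function = redundancy,
                 n_bins = n_bins, layer_strategy = layer_strategy,
                 meta = record$meta),
            class = "layer_pid_profile")
}

#' @export
print.layer_pid_profile <- function(x, digits = 3, ...) {
  cat(sprintf("Layer PID profile (%s, %d bins, %s layer binning)\n",
              toupper(x$redundancy_function), x$n_bins, x$layer_strategy))
  for (nm in names(x$transitions)) {
    tr <- x$transitions[[nm]]
    cat(sprintf("  %-8s R=%.*f U1=%.*f U2=%.*f S=%.*f I=%.*f (%d pairs)\n",
                nm, digits, tr$R, digits, tr$U1, digits, tr$U2, digits,
                tr$S, digits, tr$I, tr$n_pairs))
  }
  invisible(x)
}
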