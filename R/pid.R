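#' Redundancy and synergy functions
#'
#' Two closed-form redundancy functions drive all decompositions in the
#' package. The minimum-mutual-information function takes the minimum over
#' sources of the whole-variable mutual information,
#' \deqn{R_{MMI}(X;Y) = \min_i I(X_i;Y),}
#' and its synergy is the least information lost by deleting one source,
#' \deqn{S_{MMI}(X;Y) = I(X;Y) - \max_{|A|=M-1} I(A;Y).}
#' The Williams-Beer style function replaces whole-variable mutual
#' information by its target-outcome-wise expectation of specific
#' information,
#' \deqn{R_{min}(X;Y) = \sum_j p(y_j)\,\min_i I(X_i; Y=y_j),}
#' \deqn{S_{min}(X;Y) = I(X;Y) - \sum_j p(y_j)\max_{|A|=M-1} I(A; Y=y_j),}
#' where for more than two sources the maximum runs over joint
#' (M-1)-subsets, mirroring the subset structure of the MMI synergy; for
#' two sources it reduces to a maximum over the single sources. Both
#' satisfy \eqn{R_{min} \le R_{MMI}} and \eqn{S_{min} \le S_{MMI}}.
#'
#' @param dist a [joint_dist()] with at least two sources
#' @return bits
#' @name redundancy-functions
NULL

#' @rdname redundancy-functions
#' @export
redundancy_mmi <- function(dist) {
  .check_multisource(dist)
  min(vapply(seq_len(dist$M), function(i) mutual_information(dist, i), 0))
}

#' @rdname redundancy-functions
#' @export
synergy_mmi <- function(dist) {
  .check_multisource(dist)
  full <- mutual_information(dist, seq_len(dist$M))
  best <- max(vapply(seq_len(dist$M), function(drop) {
    mutual_information(dist, setdiff(seq_len(dist$M), drop))
  }, 0))
  max(full - best, 0)
}

#' @rdname redundancy-functions
#' @export
redundancy_min <- function(dist) {
  .check_multisource(dist)
  y <- .marginalize(dist, dist$M + 1L)
  sum(vapply(seq_along(y$p), function(k) {
    yj <- y$states[k, 1L]
    y$p[k] * min(vapply(seq_len(dist$M),
                        function(i) specific_information(dist, i, yj), 0))
  }, 0))
}

#' @rdname redundancy-functions
#' @export
synergy_min <- function(dist) {
  .check_multisource(dist)
  full <- mutual_information(dist, seq_len(dist$M))
  y <- .marginalize(dist, dist$M + 1L)
  imax <- sum(vapply(seq_along(y$p), function(k) {
    yj <- y$states[k, 1L]
    y$p[k] * max(vapply(seq_len(dist$M), function(drop) {
      specific_information(dist, setdiff(seq_len(dist$M), drop), yj)
    }, 0))
  }, 0))
  max(full - imax, 0)
}

.check_multisource <- function(dist) {
  if (!inherits(dist, "joint_dist")) stop("expected a joint_dist")
  if (dist$M < 2L) stop("needs at least two sources")
  invisible(dist)
}

#' Two-source partial information decomposition
#'
#' Splits \eqn{I(X_1,X_2;Y)} into redundancy, two unique atoms and synergy:
#' \eqn{U_i = I(X_i;Y) - R} and
#' \eqn{S = I(X_1,X_2;Y) - R - U_1 - U_2}, so the decomposition identity
#' holds by construction and `S` coincides with [synergy_mmi()] /
#' [synergy_min()] analytically. Atoms are nonnegative for both redundancy
#' functions; values below `-1e-12` raise an internal consistency error.
#'
#' @param dist a [joint_dist()] with exactly two sources
#' @param redundancy `"mmi"` or `"min"`
#' @param normalize if `TRUE`, atoms are divided by the joint mutual
#'   information (an error if that is zero)
#' @return an object of class `pid` with fields `redundancy`, `unique`
#'   (length 2), `synergy`, `mutual_information`, `redundancy_function`,
#'   `normalized`
#' @examples
#' pid_decompose(xor_dist())             # purely synergistic
#' pid_decompose(and_dist(), "min")      # mixed profile
#' @export
pid_decompose <- function(dist, redundancy = c("mmi", "min"),
                          normalize = FALSE) {
  redundancy <- match.arg(redundancy)
  if (dist$M != 2L) stop("two-source decomposition needs exactly M = 2")
  i1 <- mutual_information(dist, 1L)
  i2 <- mutual_information(dist, 2L)
  i12 <- mutual_information(dist, 1:2)
  r <- if (redundancy == "mmi") redundancy_mmi(dist) else redundancy_min(dist)
  u <- c(i1 - r, i2 - r)
  s <- i12 - r - u[1L] - u[2L]
  atoms <- c(r, u, s)
  if (any(atoms < -1e-12)) {
    stop("internal consistency error: negative PID atom (",
         paste(format(atoms), collapse = ", "), ")")
  }
  atoms <- pmax(atoms, 0)
  if (normalize) {
    if (i12 <= 0) stop("cannot normalize: joint mutual information is zero")
    atoms <- atoms / i12
  }
  structure(
    list(redundancy = atoms[1L], unique = atoms[2:3], synergy = atoms[4L],
         mutual_information = i12, redundancy_function = redundancy,
         order = 2L, normalized = normalize),
    class = "pid"
  )
}

#' @export
print.pid <- function(x, digits = 4, ...) {
  unit <- if (x$normalized) "share of I" else "bits"
  cat(sprintf("Two-source PID (%s redundancy, %s)\n",
              toupper(x$redundancy_function), unit))
  v <- c(R = x$redundancy, U1 = x$unique[1L], U2 = x$unique[2L],
         S = x$synergy, I = x$mutual_information)
  print(round(v, digits))
  invisible(x)
}

#' @export
summary.pid <- function(object, ...) {
  out <- c(redundancy = object$redundancy, unique1 = object$unique[1L],
           unique2 = object$unique[2L], synergy = object$synergy,
           mutual_information = object$mutual_information)
  attr(out, "redundancy_function") <- object$redundancy_function
  out
}

#' @export
as.double.pid <- function(x, ...) {
  c(redundancy = x$redundancy, unique1 = x$unique[1L],
    unique2 = x$unique[2L], synergy = x$synergy)
}

#' K-order averaged redundancy and synergy
#'
#' Averages redundancy and synergy over all (or a uniform sample of)
#' size-`K` subsets of the source variables, each subset decomposed against
#' the joint target symbol. `K = 2` is the second-order profile used
#' throughout the analyses; `K = M` is the full-order decomposition (a
#' single subset). When the number of subsets exceeds `max_subsets`, that
#' many subsets are drawn uniformly without replacement using a dedicated
#' seeded generator, independent of any training randomness.
#'
#' @param source_codes integer code matrix (samples x sources) or
#'   `code_matrix`
#' @param target_codes integer code matrix (samples x target variables);
#'   columns fused into one joint target symbol
#' @param K subset size, between 2 and the number of sources
#' @param redundancy `"mmi"` or `"min"`
#' @param max_subsets cap on the number of subsets evaluated
#' @param seed integer seed for subset sampling (used only when sampling)
#' @param source_grouping optional grouping of source columns (see
#'   [plug_in_joint()]); subsets are drawn over grouped sources
#' @return an object of class `korder_pid`: `order`, `redundancy`,
#'   `synergy`, `mutual_information` (averages, bits), `n_subsets_evaluated`,
#'   `subset_sampling_seed` (NA when exhaustive)
#' @export
korder_average <- function(source_codes, target_codes, K,
                           redundancy = c("mmi", "min"),
                           max_subsets = Inf, seed = 1L,
                           source_grouping = NULL) {
  redundancy <- match.arg(redundancy)
  source_codes <- .as_code_matrix(source_codes)
  target_codes <- .as_code_matrix(target_codes)
  if (nrow(source_codes) != nrow(target_codes)) {
    stop("source/target sample counts differ")
  }
  if (is.null(source_grouping)) {
    source_grouping <- as.list(seq_len(ncol(source_codes)))
  }
  M <- length(source_grouping)
  K <- as.integer(K)
  if (K < 2L || K > M) stop("K must be between 2 and the number of sources")
  subsets <- utils::combn(M, K, simplify = FALSE)
  sampled <- length(subsets) > max_subsets
  if (sampled) {
    rng <- .isolated_rng(seed)
    subsets <- subsets[rng$sample_int(length(subsets), max_subsets)]
  }
  rfun <- if (redundancy == "mmi") redundancy_mmi else redundancy_min
  sfun <- if (redundancy == "mmi") synergy_mmi else synergy_min
  vals <- vapply(subsets, function(ss) {
    d <- plug_in_joint(source_codes, target_codes,
                       source_grouping = source_grouping[ss])
    c(rfun(d), sfun(d), mutual_information(d, seq_len(K)))
  }, numeric(3))
  structure(
    list(order = K, redundancy = mean(vals[1L, ]), synergy = mean(vals[2L, ]),
         mutual_information = mean(vals[3L, ]),
         redundancy_function = redundancy,
         n_subsets_evaluated = length(subsets),
         subset_sampling_seed = if (sampled) as.integer(seed) else NA_integer_),
    class = "korder_pid"
  )
}

#' @export
print.korder_pid <- function(x, digits = 4, ...) {
  cat(sprintf("K-order PID average (K = %d, %s, %d subset%s%s)\n", x$order,
              toupper(x$redundancy_function), x$n_subsets_evaluated,
              if (x$n_subsets_evaluated == 1L) "" else "s",
              if (is.na(x$subset_sampling_seed)) "" else ", sampled"))
  print(round(c(R = x$redundancy, S = x$synergy,
                I = x$mutual_information), digits))
  invisible(x)
}

#' Per-neuron average pairwise synergy
#'
#' The lesioning statistic: the mean second-order synergy over all source
#' pairs that contain the given neuron (with every other neuron in the same
#' layer), against the joint target symbol.
#'
#' @inheritParams korder_average
#' @param neuron_index column of `source_codes` to score
#' @return bits
#' @export
pairwise_neuron_synergy <- function(source_codes, target_codes, neuron_index,
                                    redundancy = c("mmi", "min")) {
  redundancy <- match.arg(redundancy)
  source_codes <- .as_code_matrix(source_codes)
  M <- ncol(source_codes)
  if (M < 2L) stop("layer must have at least two neurons")
  neuron_index <- as.integer(neuron_index)
  if (neuron_index < 1L || neuron_index > M) stop("invalid neuron index")
  sfun <- if (redundancy == "mmi") synergy_mmi else synergy_min
  partners <- setdiff(seq_len(M), neuron_index)
  mean(vapply(partners, function(j) {
    d <- plug_in_joint(source_codes[, c(neuron_index, j), drop = FALSE],
                       target_codes)
    sfun(d)
  }, 0))
}

# private RNG stream that never touches .Random.seed
.isolated_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  env$with <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    expr
  }
  env$sample_int <- function(n, k) env$with(sample.int(n, k))
  env
}
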