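#' Canonical two-source benchmark distributions
#'
#' Uniform two-bit input distributions with the classic gate targets:
#' `xor_dist()` (target = parity; purely synergistic, 1 bit),
#' `copy_dist()` (target = first input; purely unique),
#' `and_dist()` (target = conjunction; mixed redundancy/synergy profile),
#' and `parity3_dist()` (three uniform bits, target = 3-way parity).
#' Useful as ground truth for estimator checks.
#'
#' @return a [joint_dist()]
#' @name canonical-gates
NULL

#' @rdname canonical-gates
#' @export
xor_dist <- function() {
  g <- as.matrix(expand.grid(x1 = 1:2, x2 = 1:2))
  joint_dist(cbind(g, y = 1L + (g[, 1L] + g[, 2L]) %% 2L), rep(0.25, 4))
}

#' @rdname canonical-gates
#' @export
copy_dist <- function() {
  g <- as.matrix(expand.grid(x1 = 1:2, x2 = 1:2))
  joint_dist(cbind(g, y = g[, 1L]), rep(0.25, 4))
}

#' @rdname canonical-gates
#' @export
and_dist <- function() {
  g <- as.matrix(expand.grid(x1 = 1:2, x2 = 1:2))
  joint_dist(cbind(g, y = 1L + (g[, 1L] == 2L & g[, 2L] == 2L)), rep(0.25, 4))
}

#' @rdname canonical-gates
#' @export
parity3_dist <- function() {
  g <- as.matrix(expand.grid(x1 = 1:2, x2 = 1:2, x3 = 1:2))
  joint_dist(cbind(g, y = 1L + (g[, 1L] + g[, 2L] + g[, 3L]) %% 2L),
             rep(0.125, 8))
}

#' Exact PID table for the canonical gates
#'
#' Decomposes XOR, COPY and AND under both redundancy functions — a quick
#' smoke test that the arithmetic is wired correctly (XOR must be all
#' synergy, COPY all unique-to-source-1, AND a redundancy/synergy mix).
#'
#' @return data frame with columns `gate`, `redundancy_function`, `R`,
#'   `U1`, `U2`, `S`, `I` (bits)
#' @examples
#' pid_canonical_table()
#' @export
pid_canonical_table <- function() {
  gates <- list(XOR = xor_dist(), COPY = copy_dist(), AND = and_dist())
  rows <- lapply(names(gates), function(g) {
    do.call(rbind, lapply(c("mmi", "min"), function(rf) {
      p <- pid_decompose(gates[[g]], rf)
      data.frame(gate = g, redundancy_function = rf, R = p$redundancy,
                 U1 = p$unique[1L], U2 = p$unique[2L], S = p$synergy,
                 I = p$mutual_information, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
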