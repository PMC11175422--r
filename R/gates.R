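#' Generate a balanced logic-gate dataset
#'
#' Binary classification datasets with known information structure: COPY
#' (label = first input bit, purely unique information), two-bit XOR
#' (label = parity, purely synergistic) and three-bit XOR (parity of three
#' bits). Every input configuration appears equally often; row order is
#' shuffled with the given seed.
#'
#' @param gate `"COPY"`, `"XOR2"` or `"XOR3"`
#' @param n_samples total rows; must be a multiple of the number of input
#'   configurations (4 for two-bit gates, 8 for `XOR3`)
#' @param seed integer seed for the row shuffle
#' @return list of class `logic_gate_dataset` with `gate`, `inputs`
#'   (matrix of 0/1), `labels` (0/1 vector)
#' @examples
#' d <- generate_logic_gate("XOR2", 8)
#' table(d$labels)
#' @export
generate_logic_gate <- function(gate = c("COPY", "XOR2", "XOR3"),
                                n_samples = NULL, seed = 1L) {
  gate <- match.arg(gate)
  bits <- if (gate == "XOR3") 3L else 2L
  grid <- as.matrix(expand.grid(rep(list(0:1), bits)))
  colnames(grid) <- paste0("x", seq_len(bits))
  ncfg <- nrow(grid)
  if (is.null(n_samples)) n_samples <- ncfg
  if (n_samples %% ncfg != 0L) {
    stop("n_samples must be a multiple of ", ncfg, " configurations")
  }
  inputs <- grid[rep(seq_len(ncfg), n_samples / ncfg), , drop = FALSE]
  rng <- .isolated_rng(seed)
  ord <- rng$sample_int(nrow(inputs), nrow(inputs))
  inputs <- inputs[ord, , drop = FALSE]
  labels <- gate_label(gate, inputs)
  structure(list(gate = gate, inputs = inputs, labels = labels),
            class = "logic_gate_dataset")
}

#' Gate label rule
#'
#' @param gate gate name as in [generate_logic_gate()]
#' @param inputs 0/1 matrix with one configuration per row
#' @return 0/1 label vector (COPY: first bit; XOR: parity of all bits)
#' @export
gate_label <- function(gate, inputs) {
  inputs <- as.matrix(inputs)
  if (gate == "COPY") as.integer(inputs[, 1L]) else
    as.integer(rowSums(inputs) %% 2L)
}
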