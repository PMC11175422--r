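#' Feedforward network specification
#'
#' The analysis networks: two rectifier hidden layers of ten units by
#' default (a twenty-unit variant is available through `hidden`), a single
#' sigmoid output for binary gates, and optional dropout applied to the
#' hidden layers during training only — never at evaluation or lesioning.
#'
#' @param input_dim number of input dimensions
#' @param hidden integer vector of hidden layer widths
#' @param dropout_p dropout probability in `[0, 1)` (training only)
#' @return list of class `mlp_spec`
#' @export
mlp_spec <- function(input_dim, hidden = c(10L, 10L), dropout_p = 0) {
  if (dropout_p < 0 || dropout_p >= 1) stop("dropout_p must be in [0, 1)")
  structure(list(input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden), dropout_p = dropout_p),
            class = "mlp_spec")
}

# He-style initialization of one weight matrix
.init_w <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

#' Train a feedforward network on a logic-gate dataset
#'
#' Full-batch Adam on binary cross-entropy with inverted dropout masks
#' redrawn per sample per epoch. Deterministic given `seed` (training never
#' touches the session RNG). Convergence is assessed after training by a
#' dropout-free evaluation pass over every input configuration; a model
#' that misclassifies any row is flagged `converged = FALSE`.
#'
#' @param spec an [mlp_spec()]
#' @param data a dataset from [generate_logic_gate()], or a list with 0/1
#'   `inputs` matrix and `labels`
#' @param epochs training epochs (one Adam step per epoch)
#' @param lr Adam learning rate
#' @param batch_rep number of dropout-mask replicas of the configuration
#'   grid per batch (gives dropout a meaningful sample of masks)
#' @param seed integer seed controlling initialization and dropout masks
#' @return object of class `mlp_net`: weights `W` / `b` per layer, `spec`,
#'   `seed`, `lesion_masks`, `converged`, `final_loss`
#' @export
train_mlp <- function(spec, data, epochs = 2000L, lr = 0.01,
                      batch_rep = 32L, seed = 1L) {
  stopifnot(inherits(spec, "mlp_spec"))
  X0 <- unique(as.matrix(data$inputs))
  y0 <- gate_label(data$gate, X0)
  X <- X0[rep(seq_len(nrow(X0)), batch_rep), , drop = FALSE]
  y <- rep(y0, batch_rep)
  dims <- c(spec$input_dim, spec$hidden, 1L)
  nl <- length(dims) - 1L
  p <- spec$dropout_p
  rng <- .isolated_rng(seed)
  model <- rng$with({
    W <- lapply(seq_len(nl), function(l) .init_w(dims[l], dims[l + 1L]))
    b <- lapply(seq_len(nl), function(l) numeric(dims[l + 1L]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mB <- lapply(b, function(x) x * 0); vB <- mB
    n <- nrow(X)
    final_loss <- NA_real_
    for (ep in seq_len(epochs)) {
      # forward with per-sample dropout masks on hidden layers
      a <- X
      zs <- vector("list", nl); as_ <- vector("list", nl)
      masks <- vector("list", nl)
      for (l in seq_len(nl)) {
        z <- sweep(a %*% W[[l]], 2L, b[[l]], "+")
        zs[[l]] <- z
        if (l < nl) {
          h <- pmax(z, 0)
          if (p > 0) {
            m <- matrix(stats::rbinom(length(h), 1L, 1 - p), nrow(h)) / (1 - p)
            h <- h * m
            masks[[l]] <- m
          }
          a <- h
        } else {
          a <- 1 / (1 + exp(-z))
        }
        as_[[l]] <- a
      }
      prob <- as_[[nl]][, 1L]
      final_loss <- -mean(y * log(pmax(prob, 1e-12)) +
                          (1 - y) * log(pmax(1 - prob, 1e-12)))
      # backward
      delta <- matrix((prob - y) / n, ncol = 1L)
      gW <- vector("list", nl); gB <- vector("list", nl)
      for (l in rev(seq_len(nl))) {
        ain <- if (l == 1L) X else as_[[l - 1L]]
        gW[[l]] <- crossprod(ain, delta)
        gB[[l]] <- colSums(delta)
        if (l > 1L) {
          delta <- delta %*% t(W[[l]])
          if (p > 0) delta <- delta * masks[[l - 1L]]
          delta <- delta * (zs[[l - 1L]] > 0)
        }
      }
      for (l in seq_len(nl)) {
        mW[[l]] <- 0.9 * mW[[l]] + 0.1 * gW[[l]]
        vW[[l]] <- 0.999 * vW[[l]] + 0.001 * gW[[l]]^2
        mB[[l]] <- 0.9 * mB[[l]] + 0.1 * gB[[l]]
        vB[[l]] <- 0.999 * vB[[l]] + 0.001 * gB[[l]]^2
        c1 <- 1 - 0.9^ep; c2 <- 1 - 0.999^ep
        W[[l]] <- W[[l]] - lr * (mW[[l]] / c1) / (sqrt(vW[[l]] / c2) + 1e-8)
        b[[l]] <- b[[l]] - lr * (mB[[l]] / c1) / (sqrt(vB[[l]] / c2) + 1e-8)
      }
    }
    list(W = W, b = b, final_loss = final_loss)
  })
  net <- structure(
    list(W = model$W, b = model$b, spec = spec, seed = as.integer(seed),
         gate = data$gate,
         lesion_masks = lapply(spec$hidden, function(h) rep(TRUE, h)),
         final_loss = model$final_loss, converged = NA),
    class = "mlp_net"
  )
  net$converged <- mlp_accuracy(net, list(inputs = X0, labels = y0)) == 1
  net
}

#' Dropout-free forward pass
#'
#' Evaluates the network on raw inputs with dropout off and any lesion
#' masks applied (lesioned neurons have their outgoing activations forced
#' to zero).
#'
#' @param object an `mlp_net`
#' @param newdata input matrix
#' @param type `"prob"` (default), `"class"` (0/1 at threshold 0.5) or
#'   `"activations"` (list of hidden-layer activation matrices plus
#'   probabilities)
#' @param ... unused
#' @return see `type`
#' @export
predict.mlp_net <- function(object, newdata, type = c("prob", "class",
                                                      "activations"), ...) {
  type <- match.arg(type)
  a <- as.matrix(newdata)
  nl <- length(object$W)
  acts <- vector("list", nl - 1L)
  for (l in seq_len(nl)) {
    z <- sweep(a %*% object$W[[l]], 2L, object$b[[l]], "+")
    if (l < nl) {
      a <- pmax(z, 0)
      a <- sweep(a, 2L, as.numeric(object$lesion_masks[[l]]), "*")
      acts[[l]] <- a
    } else {
      a <- 1 / (1 + exp(-z))
    }
  }
  prob <- a[, 1L]
  switch(type,
         prob = prob,
         class = as.integer(prob > 0.5),
         activations = list(hidden = acts, prob = prob))
}

#' @export
print.mlp_net <- function(x, ...) {
  cat(sprintf("Feedforward net (%s): %d-%s-1, dropout %.1f, seed %d, %s\n",
              x$gate, x$spec$input_dim,
              paste(x$spec$hidden, collapse = "-"), x$spec$dropout_p,
              x$seed,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  nles <- sum(!unlist(x$lesion_masks))
  if (nles > 0) cat("Lesioned neurons:", nles, "\n")
  invisible(x)
}

#' Classification accuracy of a network on a gate dataset
#'
#' @param model an `mlp_net`
#' @param data list with `inputs` and `labels`
#' @return fraction of rows classified correctly (dropout-free evaluation)
#' @export
mlp_accuracy <- function(model, data) {
  mean(predict(model, data$inputs, type = "class") == data$labels)
}

#' Lesion neurons by zeroing their outgoing activations
#'
#' Returns a copy of the network whose given hidden-layer neurons are
#' permanently silenced at evaluation. Lesions accumulate.
#'
#' @param model an `mlp_net`
#' @param layer hidden layer index (1-based)
#' @param neurons neuron indices within that layer
#' @return lesioned `mlp_net`
#' @export
lesion_neurons <- function(model, layer, neurons) {
  mask <- model$lesion_masks[[layer]]
  if (any(neurons < 1L | neurons > length(mask))) stop("invalid neuron index")
  mask[neurons] <- FALSE
  model$lesion_masks[[layer]] <- mask
  model
}

#' Sample frozen-weight activations from a feedforward network
#'
#' Runs a dropout-free evaluation pass over the test inputs and records
#' every hidden layer together with aligned inputs and outputs. Rectifier
#' activations are elementwise nonnegative.
#'
#' @param model an `mlp_net`
#' @param inputs test input matrix; defaults to the unique gate
#'   configurations seen in training order
#' @return object of class `activation_record`: `inputs`, `layers` (list
#'   of matrices, samples x units), `outputs`, `meta`
#' @export
sample_mlp_activations <- function(model, inputs) {
  fw <- predict(model, inputs, type = "activations")
  structure(
    list(inputs = as.matrix(inputs), layers = fw$hidden, outputs = fw$prob,
         meta = list(kind = "mlp", gate = model$gate, seed = model$seed,
                     dropout_p = model$spec$dropout_p)),
    class = "activation_record"
  )
}

#' @export
print.activation_record <- function(x, ...) {
  cat("Activation record (", x$meta$kind, "): ", nrow(x$inputs),
      " samples, layers [", paste(vapply(x$layers, ncol, 0L), collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}
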