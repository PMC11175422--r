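#' Recurrent network specification
#'
#' A single leaky-ReLU recurrent layer of ten units reading the
#' decision-making trial inputs (fixation cue, two channels per modality,
#' task bit) and emitting three actions (fixate, choice 1, choice 2).
#'
#' @param input_dim input dimensions (6 for the DM trial encoding)
#' @param hidden hidden units
#' @param n_actions output actions
#' @param leak negative slope of the leaky rectifier
#' @return list of class `rnn_spec`
#' @export
rnn_spec <- function(input_dim = 6L, hidden = 10L, n_actions = 3L,
                     leak = 0.01) {
  structure(list(input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden),
                 n_actions = as.integer(n_actions), leak = leak),
            class = "rnn_spec")
}

.rnn_init <- function(spec) {
  H <- spec$hidden; D <- spec$input_dim; A <- spec$n_actions
  list(Win = matrix(stats::rnorm(H * D, 0, sqrt(1 / D)), H, D),
       Wrec = matrix(stats::rnorm(H * H, 0, sqrt(1 / H)), H, H),
       b = numeric(H),
       Wout = matrix(stats::rnorm(A * H, 0, sqrt(1 / H)), A, H),
       bout = numeric(A))
}

#' Train a recurrent network on one or two decision-making tasks
#'
#' Supervised cross-entropy over per-timestep actions, with decision-phase
#' steps weighted 20x relative to fixation steps (decisions are scarce in a
#' trial). One training step is one trial (backpropagation through time +
#' Adam). Two protocols are supported for task pairs: `"sequential"` trains
#' on task A for the first half of the steps then on task B (forgetting can
#' occur; no continual-learning regularizer is used), `"interleaved"` mixes
#' both tasks uniformly throughout. Deterministic given `seed`.
#'
#' @param tasks one or two DM-family task names
#' @param protocol `"interleaved"` or `"sequential"` (pairs only)
#' @param total_steps total training trials across tasks
#' @param spec an [rnn_spec()]
#' @param timing a [dm_timing()]
#' @param decision_weight loss weight of decision-phase steps
#' @param noise_sd stimulus observation noise used for training and,
#'   via the stored model, for evaluation and activation sampling
#' @param lr Adam learning rate
#' @param seed integer seed (weights, trial draws)
#' @return object of class `rnn_net`: `weights`, `spec`, `tasks`,
#'   `protocol`, `task_bits`, `timing`, `seed`, `mean_loss`
#' @export
train_rnn <- function(tasks, protocol = c("interleaved", "sequential"),
                      total_steps = 40000L, spec = rnn_spec(),
                      timing = dm_timing(), decision_weight = 20,
                      noise_sd = 0.4, lr = 0.002, seed = 1L) {
  protocol <- match.arg(protocol)
  if (length(tasks) > 2L) stop("at most two tasks are supported")
  if (length(tasks) == 1L) protocol <- "interleaved"  # degenerate single task
  task_bits <- stats::setNames(seq_along(tasks) - 1L, tasks)
  rng <- .isolated_rng(seed)
  weights <- rng$with(.rnn_init(spec))
  Tlen <- attr(timing, "total")
  dec_steps <- timing$fixation + timing$stimulus + seq_len(timing$decision)
  make_weight <- function(n) {
    w <- matrix(1, Tlen, n)
    w[dec_steps, ] <- decision_weight
    w
  }
  train_on <- function(weights, task_seq, n) {
    batch <- rng$with(
      generate_dm_batch(task_seq, n, timing = timing, task_bits = task_bits,
                        noise_sd = noise_sd))
    rnn_train_cpp(weights, batch$x, batch$target, make_weight(n), lr,
                  spec$leak, 1L)
  }
  if (length(tasks) == 2L && protocol == "sequential") {
    half <- as.integer(total_steps / 2L)
    weights <- train_on(weights, tasks[1L], half)
    weights <- train_on(weights, tasks[2L], half)
  } else {
    weights <- train_on(weights, tasks, as.integer(total_steps))
  }
  structure(
    list(weights = weights[c("Win", "Wrec", "b", "Wout", "bout")],
         spec = spec, tasks = tasks, protocol = protocol,
         task_bits = task_bits, timing = timing, noise_sd = noise_sd,
         seed = as.integer(seed), mean_loss = weights$mean_loss),
    class = "rnn_net"
  )
}

#' @export
print.rnn_net <- function(x, ...) {
  cat(sprintf("Recurrent net: tasks [%s], %s protocol, %d hidden, seed %d\n",
              paste(x$tasks, collapse = ", "), x$protocol, x$spec$hidden,
              x$seed))
  invisible(x)
}

# forward pass on a dm_batch; returns hidden [T,H,n] and logits [T,A,n]
.rnn_forward <- function(model, batch) {
  rnn_forward_cpp(model$weights, batch$x, model$spec$leak)
}

#' Per-task decision accuracy of a trained recurrent network
#'
#' A trial counts as correct when the action with the largest summed logit
#' over the decision phase equals the trial's correct choice.
#'
#' @param model an `rnn_net`
#' @param tasks tasks to evaluate (default: the training tasks)
#' @param n_trials test trials per task
#' @param seed seed for the test draw
#' @return named numeric vector of accuracies, one per task
#' @export
rnn_accuracy <- function(model, tasks = model$tasks, n_trials = 100L,
                         seed = 99L) {
  timing <- model$timing
  dec <- timing$fixation + timing$stimulus + seq_len(timing$decision)
  vapply(stats::setNames(tasks, tasks), function(task) {
    batch <- generate_dm_batch(task, n_trials, timing = timing,
                               task_bits = model$task_bits,
                               noise_sd = model$noise_sd, seed = seed)
    fw <- .rnn_forward(model, batch)
    correct <- vapply(seq_len(n_trials), function(i) {
      sc <- colSums(fw$logits[dec, , i, drop = FALSE][, , 1L, drop = TRUE])
      which.max(sc) == batch$target[dec[1L], i]
    }, TRUE)
    mean(correct)
  }, 0)
}

#' Sample per-timestep activations from a recurrent network
#'
#' Runs the frozen network over test trials (split evenly over its training
#' tasks) and aligns, for every timestep `t < T`, the inputs and hidden
#' state at `t` (sources) with the hidden state at `t + 1` (target).
#'
#' @param model an `rnn_net`
#' @param n_trials number of test trials
#' @param seed seed for the test draw
#' @return object of class `activation_record` with `sources`
#'   (samples x (input dims + hidden)), `targets` (samples x hidden),
#'   `source_names`, `meta`
#' @export
sample_rnn_activations <- function(model, n_trials = 100L, seed = 7L) {
  batch <- generate_dm_batch(rep_len(model$tasks, n_trials), n_trials,
                             timing = model$timing,
                             task_bits = model$task_bits,
                             noise_sd = model$noise_sd, seed = seed)
  fw <- .rnn_forward(model, batch)
  Tlen <- attr(model$timing, "total")
  H <- model$spec$hidden
  D <- model$spec$input_dim
  idx_t <- seq_len(Tlen - 1L)
  src <- do.call(rbind, lapply(seq_len(n_trials), function(i) {
    cbind(batch$x[idx_t, , i, drop = TRUE],
          fw$hidden[idx_t, , i, drop = TRUE])
  }))
  tgt <- do.call(rbind, lapply(seq_len(n_trials), function(i) {
    fw$hidden[idx_t + 1L, , i, drop = TRUE]
  }))
  colnames(src) <- c(dimnames(batch$x)[[2L]], paste0("h", seq_len(H)))
  structure(
    list(sources = src, targets = tgt,
         source_names = colnames(src),
         meta = list(kind = "rnn", tasks = model$tasks,
                     protocol = model$protocol, seed = model$seed,
                     n_trials = n_trials)),
    class = "activation_record"
  )
}

#' Average second-order synergy of a recurrent network
#'
#' The continuous-activation synergy statistic: Gaussian-copula
#' second-order synergy (minimum-mutual-information decomposition),
#' averaged over a fixed-seed uniform sample of source pairs, sources being
#' input dimensions plus hidden units at `t` and the target the joint
#' hidden state at `t + 1`. Constant source columns (e.g. a task bit in a
#' single-task record) are excluded before pairing; pairs are normalized by
#' their joint mutual information.
#'
#' @param record an `activation_record` from [sample_rnn_activations()]
#' @param n_pairs number of source pairs to average (default 45)
#' @param pair_seed seed of the dedicated pair-sampling stream
#' @param normalize divide each pair's synergy by its joint mutual
#'   information
#' @return mean synergy across pairs (share of mutual information when
#'   `normalize = TRUE`, bits otherwise)
#' @export
rnn_pair_synergy <- function(record, n_pairs = 45L, pair_seed = 1234L,
                             normalize = TRUE) {
  src <- record$sources
  keep <- apply(src, 2L, function(v) max(v) - min(v) > 0)
  src <- src[, keep, drop = FALSE]
  M <- ncol(src)
  pairs <- utils::combn(M, 2L, simplify = FALSE)
  if (length(pairs) > n_pairs) {
    rng <- .isolated_rng(pair_seed)
    pairs <- pairs[rng$sample_int(length(pairs), n_pairs)]
  }
  vals <- vapply(pairs, function(pr) {
    p <- gcmi_pair_synergy(src[, pr[1L]], src[, pr[2L]], record$targets,
                           normalize = normalize)
    p$synergy
  }, 0)
  mean(vals)
}
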