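#' Dropout sweep on a logic gate
#'
#' Trains an ensemble of networks per dropout level, profiles every
#' converged network at second order, and contrasts each nonzero level
#' against no dropout on the hidden-layer redundancy share (one-sided:
#' dropout increases redundancy), with BH correction across levels.
#' Hidden-layer redundancy pools the two transitions whose sources are
#' hidden layers (between the hidden layers, and last hidden layer to
#' output). Layer activations are discretized with even-frequency
#' IQR-truncated bins computed per layer and seed; an equal-width grid
#' over a fixed range is available via `layer_strategy = "fixed"` (see the
#' methods vignette for why the fixed grid can degenerate).
#' Non-convergent seeds are excluded and flagged in `excluded`.
#'
#' @param gate `"COPY"` or `"XOR2"`
#' @param dropout_levels subset of `c(0, 0.1, 0.3, 0.5)` including 0
#' @param seeds integer vector of model seeds
#' @param redundancy `"mmi"` or `"min"`
#' @param n_bins bins per activation unit
#' @param layer_strategy `"iqr"` or `"fixed"` layer discretization
#' @param layer_range range for the fixed strategy
#' @param epochs training epochs per network
#' @return object of class `experiment_result` with per-seed `metrics`
#'   (accuracy and normalized atoms per transition) and `tests`
#' @export
dropout_experiment <- function(gate = c("COPY", "XOR2"),
                               dropout_levels = c(0, 0.5), seeds = 1:10,
                               redundancy = c("mmi", "min"), n_bins = 3L,
                               layer_strategy = c("iqr", "fixed"),
                               layer_range = c(0, 5), epochs = 2000L) {
  gate <- match.arg(gate)
  redundancy <- match.arg(redundancy)
  layer_strategy <- match.arg(layer_strategy)
  if (!0 %in% dropout_levels) stop("dropout_levels must include 0")
  rows <- list(); excluded <- list()
  for (p in dropout_levels) {
    for (s in seeds) {
      net <- .cached_mlp(gate, p, s, epochs = epochs)
      if (!isTRUE(net$converged)) {
        excluded[[length(excluded) + 1L]] <-
          data.frame(gate = gate, dropout_p = p, seed = s)
        next
      }
      prof <- layer_pid_profile(sample_mlp_activations(net, .gate_grid(gate)),
                                redundancy = redundancy, n_bins = n_bins,
                                layer_strategy = layer_strategy,
                                layer_range = layer_range)
      hid <- prof$transitions[c("hidden1", "hidden2")]
      pool <- function(field) mean(vapply(hid, `[[`, 0, field), na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        gate = gate, dropout_p = p, seed = s,
        accuracy = mlp_accuracy(net, list(inputs = .gate_grid(gate),
                                          labels = gate_label(gate, .gate_grid(gate)))),
        input_R = prof$transitions$input$R_norm,
        input_S = prof$transitions$input$S_norm,
        hidden_R = pool("R_norm"),
        hidden_U = pool("U1_norm") + pool("U2_norm"),
        hidden_S = pool("S_norm"),
        stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, rows)
  base <- metrics$hidden_R[metrics$dropout_p == 0]
  tests <- do.call(rbind, lapply(setdiff(dropout_levels, 0), function(p) {
    t_test(metrics$hidden_R[metrics$dropout_p == p], base, one_sided = TRUE,
           label = sprintf("%s hidden redundancy: p=%.1f > p=0.0", gate, p))
  }))
  tests <- .adjust_tests(tests)
  .experiment_result("dropout", metrics, tests,
                     config = list(gate = gate, levels = dropout_levels,
                                   seeds = seeds, redundancy = redundancy,
                                   n_bins = n_bins, epochs = epochs),
                     excluded = if (length(excluded)) do.call(rbind, excluded))
}

.gate_grid <- function(gate) {
  bits <- if (gate == "XOR3") 3L else 2L
  as.matrix(expand.grid(rep(list(0:1), bits)))
}

# memoized trained networks, shared across experiments within a session
.mlp_cache <- new.env(parent = emptyenv())

.cached_mlp <- function(gate, dropout_p, seed, epochs = 2000L) {
  key <- sprintf("%s_%g_%d_%d", gate, dropout_p, seed, epochs)
  if (is.null(.mlp_cache[[key]])) {
    data <- generate_logic_gate(gate, seed = seed)
    spec <- mlp_spec(ncol(data$inputs), dropout_p = dropout_p)
    .mlp_cache[[key]] <- train_mlp(spec, data, epochs = epochs, seed = seed)
  }
  .mlp_cache[[key]]
}

#' Synergy-ranked lesion sweep of a trained network
#'
#' Scores every hidden neuron by its average pairwise synergy (with the
#' next layer as joint target), ranks neurons within each layer once on
#' the intact network, then removes `1, 2, ...` neurons per layer — most-
#' or least-synergistic first — re-evaluating dropout-free accuracy after
#' each step. Ties in the ranking break by neuron index.
#'
#' @param model a converged `mlp_net`
#' @param direction `"most_synergistic_first"` or
#'   `"least_synergistic_first"`
#' @param redundancy `"mmi"` or `"min"`
#' @param n_bins bins per activation unit
#' @param layer_strategy `"iqr"` or `"fixed"` layer discretization
#' @param layer_range range for the fixed strategy
#' @return object of class `lesion_curve`: `accuracy` (length
#'   `n_units + 1`, step 0 = intact), `ranking` (per-layer neuron order),
#'   `synergy` (per-layer per-neuron scores), `direction`
#' @export
lesion_sweep <- function(model,
                         direction = c("most_synergistic_first",
                                       "least_synergistic_first"),
                         redundancy = c("mmi", "min"), n_bins = 3L,
                         layer_strategy = c("iqr", "fixed"),
                         layer_range = c(0, 5)) {
  direction <- match.arg(direction)
  redundancy <- match.arg(redundancy)
  layer_strategy <- match.arg(layer_strategy)
  grid <- .gate_grid(model$gate)
  labels <- gate_label(model$gate, grid)
  rec <- sample_mlp_activations(model, grid)
  codes <- lapply(rec$layers, .layer_codes, strategy = layer_strategy,
                  n_bins = n_bins, range = layer_range)
  out_codes <- matrix(as.integer(rec$outputs > 0.5) + 1L, ncol = 1L)
  targets <- list(codes[[2L]], out_codes)
  synergy <- lapply(1:2, function(l) {
    vapply(seq_len(ncol(codes[[l]]$codes)), function(i) {
      pairwise_neuron_synergy(codes[[l]], targets[[l]], i,
                              redundancy = redundancy)
    }, 0)
  })
  ranking <- lapply(synergy, function(sv) {
    if (direction == "most_synergistic_first") {
      order(-sv, seq_along(sv))
    } else {
      order(sv, seq_along(sv))
    }
  })
  n_units <- length(synergy[[1L]])
  acc <- vapply(0:n_units, function(k) {
    les <- model
    if (k > 0) {
      for (l in 1:2) les <- lesion_neurons(les, l, ranking[[l]][seq_len(k)])
    }
    mlp_accuracy(les, list(inputs = grid, labels = labels))
  }, 0)
  structure(list(accuracy = acc, ranking = ranking, synergy = synergy,
                 direction = direction, gate = model$gate,
                 seed = model$seed, dropout_p = model$spec$dropout_p),
            class = "lesion_curve")
}

#' @export
print.lesion_curve <- function(x, ...) {
  cat(sprintf("Lesion curve (%s, %s, dropout %.1f):\n", x$gate,
              x$direction, x$dropout_p))
  cat("accuracy:", paste(format(x$accuracy, digits = 3), collapse = " "), "\n")
  invisible(x)
}

#' Lesioning experiment across an ensemble
#'
#' For each seed, runs most- and least-synergistic-first lesion sweeps on
#' the trained network and contrasts accuracy after removing `k` neurons
#' per layer (paired t tests across seeds, BH-corrected over `k`).
#'
#' @param gate gate name
#' @param dropout_p dropout used in training
#' @param seeds model seeds
#' @param k_values removal counts to test
#' @param ... passed to [lesion_sweep()]
#' @return `experiment_result` with per-seed accuracy curves in `metrics`
#'   and paired contrasts in `tests`
#' @export
lesion_experiment <- function(gate = "XOR2", dropout_p = 0, seeds = 1:10,
                              k_values = c(1L, 3L, 5L), ...) {
  rows <- list()
  for (s in seeds) {
    net <- .cached_mlp(gate, dropout_p, s)
    if (!isTRUE(net$converged)) next
    for (dir in c("most_synergistic_first", "least_synergistic_first")) {
      cv <- lesion_sweep(net, direction = dir, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        gate = gate, dropout_p = dropout_p, seed = s, direction = dir,
        k = seq_along(cv$accuracy) - 1L, accuracy = cv$accuracy,
        stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, rows)
  tests <- do.call(rbind, lapply(k_values, function(k) {
    most <- metrics$accuracy[metrics$direction == "most_synergistic_first" &
                               metrics$k == k]
    least <- metrics$accuracy[metrics$direction == "least_synergistic_first" &
                                metrics$k == k]
    t_test(least, most, paired = TRUE, one_sided = TRUE,
           label = sprintf("%s: least-first > most-first accuracy at k=%d",
                           gate, k))
  }))
  tests <- .adjust_tests(tests)
  .experiment_result("lesion", metrics, tests,
                     config = list(gate = gate, dropout_p = dropout_p,
                                   seeds = seeds, k_values = k_values))
}

#' Curriculum experiment on the platform environment
#'
#' Trains an ensemble of agents through a two-stage curriculum — either
#' two-bit XOR followed by three-bit XOR (a new information source) or
#' two-bit XOR followed by a longer-platform two-bit XOR (same sources,
#' longer action-reward delay) — snapshotting each agent at the end of
#' each stage. Each checkpoint is evaluated on all configurations of all
#' curriculum tasks and its normalized second-order raycast-pair synergy
#' (input to first actor layer) recorded; the stage contrast is a paired t
#' test across seeds.
#'
#' @param curriculum `"xor3"` (XOR2 then XOR3) or `"distance"` (XOR2 then
#'   platform length 10)
#' @param seeds agent seeds
#' @param episodes_per_stage episode cap per stage
#' @param redundancy `"mmi"` or `"min"`
#' @param n_bins bins for distances and layer activations
#' @param one_sided direction of the stage contrast (increase expected for
#'   `"xor3"`; defaults accordingly)
#' @param window trailing-reward window for the task-advance criterion
#' @param ... passed to [train_agent()]
#' @return `experiment_result`: per seed x checkpoint synergy and success
#'   rates, plus the paired stage contrast
#' @export
curriculum_experiment <- function(curriculum = c("xor3", "distance"),
                                  seeds = 1:10, episodes_per_stage = 6000L,
                                  redundancy = c("mmi", "min"), n_bins = 3L,
                                  one_sided = NULL, window = 200L, ...) {
  curriculum <- match.arg(curriculum)
  redundancy <- match.arg(redundancy)
  if (is.null(one_sided)) one_sided <- curriculum == "xor3"
  stages <- if (curriculum == "xor3") {
    list(raycast_env("XOR2", 2L), raycast_env("XOR3", 2L))
  } else {
    list(raycast_env("XOR2", 2L), raycast_env("XOR2", 10L))
  }
  rows <- list()
  for (s in seeds) {
    run <- train_curriculum(stages, seed = s,
                            episodes_per_stage = episodes_per_stage,
                            window = window, ...)
    for (ck in seq_along(run)) {
      rec <- sample_agent_activations(run[[ck]]$agent, stages)
      prof <- layer_pid_profile(rec, redundancy = redundancy,
                                n_bins = n_bins, layer_strategy = "iqr")
      rows[[length(rows) + 1L]] <- data.frame(
        curriculum = curriculum, seed = s, checkpoint = ck,
        stage_gate = stages[[ck]]$gate,
        platform_length = stages[[ck]]$platform_length,
        success = run[[ck]]$success,
        reached_threshold = run[[ck]]$reached_threshold,
        input_S = prof$transitions$input$S_norm,
        input_R = prof$transitions$input$R_norm,
        hidden_S = prof$transitions$hidden1$S_norm,
        stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, rows)
  s1 <- metrics$input_S[metrics$checkpoint == 1L]
  s2 <- metrics$input_S[metrics$checkpoint == 2L]
  tests <- t_test(s2, s1, paired = TRUE, one_sided = one_sided,
                  label = sprintf("%s curriculum: input synergy stage 2 vs 1",
                                  curriculum))
  .experiment_result("curriculum", metrics, tests,
                     config = list(curriculum = curriculum, seeds = seeds,
                                   episodes_per_stage = episodes_per_stage,
                                   redundancy = redundancy, n_bins = n_bins))
}

#' Congruence experiment on decision-making task pairs
#'
#' Trains recurrent networks on DM-family task pairs under sequential and
#' interleaved protocols, measures mean decision accuracy over both tasks
#' and normalized Gaussian-copula second-order synergy (45 sampled source
#' pairs), then tests: interleaved vs sequential synergy per pair
#' (BH-corrected family), the pooled contrast within each congruence
#' class, and interleaved incongruent vs interleaved congruent synergy.
#'
#' @param pairs data frame as from [dm_task_pairs()] (subset allowed)
#' @param seeds model seeds
#' @param total_steps training trials per network
#' @param n_test_trials activation-sampling trials
#' @param n_pairs source pairs for the synergy average
#' @param ... passed to [train_rnn()]
#' @return `experiment_result` with per seed x pair x protocol `metrics`
#'   and the contrast table in `tests`
#' @export
congruence_experiment <- function(pairs = dm_task_pairs(), seeds = 1:10,
                                  total_steps = 40000L,
                                  n_test_trials = 100L, n_pairs = 45L, ...) {
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    tasks <- c(pairs$task_a[i], pairs$task_b[i])
    for (proto in c("sequential", "interleaved")) {
      for (s in seeds) {
        net <- train_rnn(tasks, protocol = proto, total_steps = total_steps,
                         seed = s, ...)
        acc <- rnn_accuracy(net, n_trials = n_test_trials, seed = 1000L + s)
        rec <- sample_rnn_activations(net, n_trials = n_test_trials,
                                      seed = 2000L + s)
        syn <- rnn_pair_synergy(rec, n_pairs = n_pairs)
        rows[[length(rows) + 1L]] <- data.frame(
          pair = paste(tasks, collapse = "&"),
          congruence = pairs$congruence[i], protocol = proto, seed = s,
          accuracy = mean(acc), acc_task1 = acc[1L], acc_task2 = acc[2L],
          synergy = syn, stringsAsFactors = FALSE)
      }
    }
  }
  metrics <- do.call(rbind, rows)
  per_pair <- do.call(rbind, lapply(unique(metrics$pair), function(pr) {
    sub <- metrics[metrics$pair == pr, ]
    t_test(sub$synergy[sub$protocol == "interleaved"],
           sub$synergy[sub$protocol == "sequential"], one_sided = TRUE,
           label = sprintf("%s (%s): interleaved > sequential synergy", pr,
                           sub$congruence[1L]))
  }))
  per_pair <- .adjust_tests(per_pair)
  pooled <- do.call(rbind, lapply(c("incongruent", "congruent"), function(cg) {
    sub <- metrics[metrics$congruence == cg, ]
    t_test(sub$synergy[sub$protocol == "interleaved"],
           sub$synergy[sub$protocol == "sequential"], one_sided = TRUE,
           label = sprintf("pooled %s: interleaved > sequential synergy", cg))
  }))
  inter <- metrics[metrics$protocol == "interleaved", ]
  cls <- t_test(inter$synergy[inter$congruence == "incongruent"],
                inter$synergy[inter$congruence == "congruent"],
                one_sided = TRUE,
                label = "interleaved: incongruent > congruent synergy")
  tests <- rbind(per_pair,
                 cbind(pooled, adjusted_p = NA_real_, rejected = NA),
                 cbind(cls, adjusted_p = NA_real_, rejected = NA))
  .experiment_result("congruence", metrics, tests,
                     config = list(seeds = seeds, total_steps = total_steps,
                                   n_test_trials = n_test_trials,
                                   n_pairs = n_pairs))
}

.experiment_result <- function(id, metrics, tests, config, excluded = NULL) {
  structure(list(experiment = id, metrics = metrics, tests = tests,
                 config = config, excluded = excluded),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Experiment '%s': %d metric rows\n", x$experiment,
              nrow(x$metrics)))
  if (!is.null(x$excluded) && nrow(x$excluded)) {
    cat("Excluded (non-convergent):", nrow(x$excluded), "runs\n")
  }
  if (!is.null(x$tests)) {
    cat("Tests:\n")
    cols <- intersect(c("label", "statistic", "p_value", "adjusted_p"),
                      names(x$tests))
    print(x$tests[, cols], row.names = FALSE, digits = 3)
  }
  invisible(x)
}
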