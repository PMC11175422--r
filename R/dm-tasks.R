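#' Timing of a decision-making trial
#'
#' Fixed-length phase structure shared by all DM-family trials: a fixation
#' phase, a stimulus phase and a decision phase, in time steps.
#'
#' @param fixation,stimulus,decision phase lengths (positive integers)
#' @return list of class `dm_timing` with the three lengths and `total`
#' @export
dm_timing <- function(fixation = 3L, stimulus = 7L, decision = 3L) {
  v <- c(fixation = as.integer(fixation), stimulus = as.integer(stimulus),
         decision = as.integer(decision))
  if (any(v < 1L)) stop("phase lengths must be positive")
  structure(as.list(v), total = sum(v), class = "dm_timing")
}

.dm_tasks <- c("DM1", "DM2", "CtxDM1", "CtxDM2")

# modality a task attends to
dm_modality <- function(task) {
  task <- match.arg(task, .dm_tasks)
  if (task %in% c("DM1", "CtxDM1")) 1L else 2L
}

# contextual tasks present (to-be-ignored) distractors in the other modality
dm_contextual <- function(task) {
  match.arg(task, .dm_tasks) %in% c("CtxDM1", "CtxDM2")
}

#' Congruence of a pair of decision-making tasks
#'
#' Two distinct DM-family tasks are congruent when they attend the same
#' input modality (DM1 & CtxDM1; DM2 & CtxDM2) and incongruent when they
#' attend different modalities (the remaining four pairings).
#'
#' @param task_a,task_b distinct task names from
#'   `DM1, DM2, CtxDM1, CtxDM2`
#' @return `"congruent"` or `"incongruent"`
#' @examples
#' congruence("DM1", "CtxDM1")   # congruent
#' congruence("DM1", "DM2")      # incongruent
#' @export
congruence <- function(task_a, task_b) {
  task_a <- match.arg(task_a, .dm_tasks)
  task_b <- match.arg(task_b, .dm_tasks)
  if (task_a == task_b) stop("tasks must be distinct")
  if (dm_modality(task_a) == dm_modality(task_b)) "congruent" else "incongruent"
}

#' The six DM-family task pairs
#'
#' @return data frame with columns `task_a`, `task_b`, `congruence`
#' @export
dm_task_pairs <- function() {
  cmb <- utils::combn(.dm_tasks, 2L)
  data.frame(task_a = cmb[1L, ], task_b = cmb[2L, ],
             congruence = mapply(congruence, cmb[1L, ], cmb[2L, ],
                                 USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

# draw n strength pairs, uniform on [0,1] with a guaranteed gap >= 0.1
#
# All four stimulus channels carry i.i.d. Gaussian observation noise at
# every time step (as in the cognitive-task batteries these trials
# emulate): a silent modality is noisy-zero, not exactly zero, so
# networks experience pressure to suppress task-irrelevant channels
# rather than simply never receiving gradient through them.
.draw_strength_pairs <- function(n, min_gap = 0.1) {
  a <- numeric(n); b <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    a[need] <- stats::runif(length(need))
    b[need] <- stats::runif(length(need))
    need <- need[abs(a[need] - b[need]) < min_gap]
  }
  cbind(a, b)
}

#' Generate a batch of decision-making trials
#'
#' Produces per-timestep inputs and target actions for `n_trials` trials of
#' the given tasks (tasks are cycled over trials when more than one is
#' given). Input dimensions are: fixation cue; two channels of modality 1;
#' two channels of modality 2; a binary task-indicator bit. During the
#' stimulus phase the attended modality carries two stimulus strengths
#' drawn uniformly on `[0, 1]` with a minimum gap of 0.1; contextual tasks
#' also present an independent distractor pair in the other modality,
#' non-contextual tasks present no stimulus there. Every stimulus channel
#' additionally carries i.i.d. Gaussian observation noise at every time
#' step, so unattended channels are noisy-zero rather than exactly zero. The target action is `fixate` until the decision phase
#' and then the index of the stronger attended stimulus. The task bit is
#' the 0/1 position of the trial's task within `task_bits` (so a pair of
#' tasks shares one indicator).
#'
#' @param tasks character vector of task names (one or two, typically)
#' @param n_trials number of trials
#' @param timing a [dm_timing()]
#' @param noise_sd standard deviation of stimulus observation noise
#' @param task_bits named 0/1 vector assigning the indicator value per
#'   task; defaults to order of appearance in `tasks`
#' @param seed optional integer; when given the batch is drawn from a
#'   private RNG stream
#' @return list of class `dm_batch`: `x` array `[T, 6, n_trials]`, `target`
#'   integer matrix `[T, n_trials]` (1 = fixate, 2/3 = choice), `task`
#'   per-trial task names, `strengths` per-trial attended strengths, and
#'   `timing`
#' @export
generate_dm_batch <- function(tasks, n_trials, timing = dm_timing(),
                              noise_sd = 0.4, task_bits = NULL, seed = NULL) {
  tasks <- vapply(tasks, function(t) match.arg(t, .dm_tasks), "")
  if (is.null(task_bits)) {
    task_bits <- stats::setNames(seq_along(unique(tasks)) - 1L, unique(tasks))
  }
  build <- function() {
    Tlen <- attr(timing, "total")
    task_of <- rep_len(tasks, n_trials)
    x <- array(0, dim = c(Tlen, 6L, n_trials),
               dimnames = list(NULL, c("fixation", "mod1_a", "mod1_b",
                                       "mod2_a", "mod2_b", "task_bit"), NULL))
    tgt <- matrix(1L, Tlen, n_trials)
    fix_steps <- seq_len(timing$fixation + timing$stimulus)
    stim_steps <- timing$fixation + seq_len(timing$stimulus)
    dec_steps <- timing$fixation + timing$stimulus + seq_len(timing$decision)
    x[fix_steps, "fixation", ] <- 1
    chan <- c("mod1_a", "mod1_b", "mod2_a", "mod2_b")
    x[, chan, ] <- stats::rnorm(Tlen * 4L * n_trials, 0, noise_sd)
    strengths <- .draw_strength_pairs(n_trials)
    distract <- .draw_strength_pairs(n_trials)
    for (i in seq_len(n_trials)) {
      task <- task_of[i]
      att <- dm_modality(task)
      att_cols <- if (att == 1L) c("mod1_a", "mod1_b") else c("mod2_a", "mod2_b")
      oth_cols <- if (att == 1L) c("mod2_a", "mod2_b") else c("mod1_a", "mod1_b")
      x[stim_steps, att_cols[1L], i] <- x[stim_steps, att_cols[1L], i] + strengths[i, 1L]
      x[stim_steps, att_cols[2L], i] <- x[stim_steps, att_cols[2L], i] + strengths[i, 2L]
      if (dm_contextual(task)) {
        x[stim_steps, oth_cols[1L], i] <- x[stim_steps, oth_cols[1L], i] + distract[i, 1L]
        x[stim_steps, oth_cols[2L], i] <- x[stim_steps, oth_cols[2L], i] + distract[i, 2L]
      }
      x[, "task_bit", i] <- task_bits[[task]]
      tgt[dec_steps, i] <- 1L + if (strengths[i, 1L] > strengths[i, 2L]) 1L else 2L
    }
    structure(list(x = x, target = tgt, task = task_of, strengths = strengths,
                   timing = timing, task_bits = task_bits),
              class = "dm_batch")
  }
  if (is.null(seed)) build() else .isolated_rng(seed)$with(build())
}

#' Generate a single decision-making trial
#'
#' Convenience wrapper around [generate_dm_batch()] for one trial.
#'
#' @inheritParams generate_dm_batch
#' @param task task name
#' @return list with `x` (matrix `[T, 6]`), `target` (length-`T` integer
#'   vector), `task`, `strengths`
#' @export
generate_dm_trial <- function(task, timing = dm_timing(), noise_sd = 0.4,
                              seed = NULL) {
  b <- generate_dm_batch(task, 1L, timing = timing, noise_sd = noise_sd,
                         seed = seed)
  list(x = b$x[, , 1L], target = b$target[, 1L], task = task,
       strengths = b$strengths[1L, ])
}
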