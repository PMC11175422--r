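# Actor-critic policy-gradient agent for the platform environment.
# Two feedforward rectifier layers of ten units in each head, matching the
# feedforward nets used in the supervised experiments; the information
# analyses read the actor's hidden activations.

.agent_mlp_init <- function(dims, scale = 1) {
  nl <- length(dims) - 1L
  scale <- rep_len(scale, nl)
  list(W = lapply(seq_len(nl),
                  function(l) scale[l] * .init_w(dims[l], dims[l + 1L])),
       b = lapply(seq_len(nl), function(l) numeric(dims[l + 1L])))
}

# forward through a rectifier MLP head; returns activations per layer and
# final linear output (no nonlinearity on the last layer)
.agent_mlp_forward <- function(par, X) {
  nl <- length(par$W)
  acts <- vector("list", nl - 1L)
  zs <- vector("list", nl)
  a <- X
  for (l in seq_len(nl)) {
    z <- sweep(a %*% par$W[[l]], 2L, par$b[[l]], "+")
    zs[[l]] <- z
    if (l < nl) {
      a <- pmax(z, 0)
      acts[[l]] <- a
    } else a <- z
  }
  list(out = a, acts = acts, zs = zs, X = X)
}

# gradient of sum(dout * out) wrt weights, given a forward record
.agent_mlp_backward <- function(par, fw, dout) {
  nl <- length(par$W)
  gW <- vector("list", nl); gB <- vector("list", nl)
  delta <- dout
  for (l in rev(seq_len(nl))) {
    ain <- if (l == 1L) fw$X else fw$acts[[l - 1L]]
    gW[[l]] <- crossprod(ain, delta)
    gB[[l]] <- colSums(delta)
    if (l > 1L) delta <- (delta %*% t(par$W[[l]])) * (fw$zs[[l - 1L]] > 0)
  }
  list(W = gW, b = gB)
}

.adam_new <- function(par) rapply(par, function(x) list(m = x * 0, v = x * 0),
                                  how = "list")

.adam_step <- function(par, grad, state, lr, t, weight_decay = 0) {
  walk <- function(p, g, s) {
    if (is.numeric(p)) {
      s$m <- 0.9 * s$m + 0.1 * g
      s$v <- 0.999 * s$v + 0.001 * g^2
      p <- p * (1 - lr * weight_decay) -
        lr * (s$m / (1 - 0.9^t)) / (sqrt(s$v / (1 - 0.999^t)) + 1e-8)
      return(list(p = p, s = s))
    }
    for (k in seq_along(p)) {
      r <- walk(p[[k]], g[[k]], s[[k]])
      p[[k]] <- r$p
      s[[k]] <- r$s
    }
    list(p = p, s = s)
  }
  r <- walk(par, grad, state)
  list(par = r$p, state = r$s)
}

#' Create an untrained actor-critic agent
#'
#' @param input_dim observation dimensions (12 for the platform
#'   environment)
#' @param hidden hidden widths of both heads
#' @param n_actions number of actions (2: forward, backward)
#' @param arena_size used to scale the position input to `[0, 1]`
#' @param init_scale per-layer multiplier on the He initialization
#'   (recycled). The default shrinks only the input layer: weight columns
#'   of input dimensions a task never activates receive no gradient and
#'   stay at initialization, and a small first-layer scale keeps such
#'   untrained pathways below the resolution of the activation
#'   discretization — the information analyses then see what the agent
#'   learned rather than what its initialization happens to transmit.
#'   Later layers keep full scale so learning signals propagate.
#' @param seed integer seed for weight initialization
#' @return object of class `pg_agent`
#' @export
new_agent <- function(input_dim = 12L, hidden = c(10L, 10L), n_actions = 2L,
                      arena_size = 40, init_scale = c(0.1, 1, 1),
                      seed = 1L) {
  rng <- .isolated_rng(seed)
  par <- rng$with(list(
    actor = .agent_mlp_init(c(input_dim, hidden, n_actions), init_scale),
    critic = .agent_mlp_init(c(input_dim, hidden, 1L))
  ))
  structure(list(actor = par$actor, critic = par$critic,
                 input_dim = as.integer(input_dim), hidden = as.integer(hidden),
                 n_actions = as.integer(n_actions), arena_size = arena_size,
                 seed = as.integer(seed)),
            class = "pg_agent")
}

#' @export
print.pg_agent <- function(x, ...) {
  cat(sprintf("Actor-critic agent: %d-%s-%d, seed %d\n", x$input_dim,
              paste(x$hidden, collapse = "-"), x$n_actions, x$seed))
  invisible(x)
}

# scale raw observations for the network input
.agent_scale_obs <- function(agent, obs) {
  obs <- rbind(obs)
  obs[, 12L] <- obs[, 12L] / agent$arena_size
  obs
}

# action probabilities (rows) for a matrix of raw observations
.agent_probs <- function(agent, obs) {
  fw <- .agent_mlp_forward(agent$actor, .agent_scale_obs(agent, obs))
  z <- fw$out - apply(fw$out, 1L, max)
  e <- exp(z)
  list(probs = e / rowSums(e), fw = fw)
}

# run one episode; actions sampled from the policy (or greedy argmax)
.agent_episode <- function(agent, env, bits = NULL, greedy = FALSE,
                           record = FALSE) {
  st <- env_reset(env, bits = bits)
  obs <- list(); acts <- integer(); rews <- numeric()
  h1 <- list(); h2 <- list()
  while (!st$done) {
    o <- st$observation
    pr <- .agent_probs(agent, o)
    a <- if (greedy) which.max(pr$probs[1L, ]) else
      sample.int(agent$n_actions, 1L, prob = pr$probs[1L, ])
    obs[[length(obs) + 1L]] <- o
    if (record) {
      h1[[length(h1) + 1L]] <- pr$fw$acts[[1L]][1L, ]
      h2[[length(h2) + 1L]] <- pr$fw$acts[[2L]][1L, ]
    }
    acts <- c(acts, a)
    st <- env_step(st, if (a == 1L) "forward" else "backward")
    rews <- c(rews, st$reward)
  }
  out <- list(obs = do.call(rbind, obs), actions = acts, rewards = rews,
              total_reward = sum(rews), bits = st$bits)
  if (record) {
    out$h1 <- do.call(rbind, h1)
    out$h2 <- do.call(rbind, h2)
  }
  out
}

#' Train an agent on a platform task with policy gradients
#'
#' REINFORCE with a learned state-value baseline and an entropy bonus; one
#' Adam update per episode. Training stops early once the mean reward over
#' the last `window` episodes reaches `reward_threshold` (the task-advance
#' criterion), otherwise at the episode cap, in which case the agent is
#' flagged as not having reached threshold.
#'
#' @param agent a `pg_agent`
#' @param env a [raycast_env()]
#' @param episodes episode cap for this task
#' @param lr Adam learning rate
#' @param gamma discount factor
#' @param entropy_beta entropy bonus coefficient
#' @param weight_decay decoupled weight decay per update; shrinks weight
#'   pathways that receive no gradient (e.g. input dimensions silent in
#'   the current task), so information the task never used does not leak
#'   through initialization-scale weights into the analyzed activations
#' @param batch_episodes episodes per gradient update (round-robin over
#'   barrier configurations; advantages are standardized per batch)
#' @param reward_threshold mean-reward advance criterion
#' @param window trailing window (episodes) for the criterion
#' @param seed integer seed for action sampling and configuration draws
#' @return list with the trained `agent`, `reward_history`,
#'   `reached_threshold`, `episodes_run`
#' @export
train_agent <- function(agent, env, episodes = 3000L, lr = 0.01,
                        gamma = 0.99, entropy_beta = 0.01,
                        weight_decay = 0, batch_episodes = 8L,
                        reward_threshold = 3.5, window = 100L, seed = 1L) {
  rng <- .isolated_rng(seed)
  state <- .adam_new(list(actor = agent$actor, critic = agent$critic))
  hist <- numeric(0)
  reached <- FALSE
  t_adam <- 0L
  grid <- as.matrix(expand.grid(rep(list(0:1), env$n_bits)))
  ep <- 0L
  while (ep < episodes && !reached) {
    # one batch: episodes round-robin over the barrier configurations
    Xs <- list(); As <- integer(0); Gs <- numeric(0)
    for (bi in seq_len(min(batch_episodes, episodes - ep))) {
      bits <- grid[(ep %% nrow(grid)) + 1L, ]
      tr <- rng$with(.agent_episode(agent, env, bits = bits))
      Tn <- length(tr$actions)
      G <- numeric(Tn)
      acc <- 0
      for (k in rev(seq_len(Tn))) {
        acc <- tr$rewards[k] + gamma * acc
        G[k] <- acc
      }
      Xs[[bi]] <- tr$obs
      As <- c(As, tr$actions)
      Gs <- c(Gs, G)
      hist <- c(hist, tr$total_reward)
      ep <- ep + 1L
      if (ep >= window &&
          mean(hist[(ep - window + 1L):ep]) >= reward_threshold) {
        reached <- TRUE
      }
    }
    Tn <- length(As)
    X <- .agent_scale_obs(agent, do.call(rbind, Xs))
    afw <- .agent_mlp_forward(agent$actor, X)
    z <- afw$out - apply(afw$out, 1L, max)
    p <- exp(z) / rowSums(exp(z))
    cfw <- .agent_mlp_forward(agent$critic, X)
    v <- cfw$out[, 1L]
    adv <- Gs - v
    if (stats::sd(adv) > 1e-8) adv <- adv / stats::sd(adv)
    onehot <- matrix(0, Tn, agent$n_actions)
    onehot[cbind(seq_len(Tn), As)] <- 1
    logp <- log(pmax(p, 1e-12))
    Hent <- -rowSums(p * logp)
    dlogits <- (p - onehot) * adv / Tn +
      entropy_beta * p * (logp + Hent) / Tn
    ga <- .agent_mlp_backward(agent$actor, afw, dlogits)
    gc <- .agent_mlp_backward(agent$critic, cfw,
                              matrix((v - Gs) / Tn, ncol = 1L))
    t_adam <- t_adam + 1L
    res <- .adam_step(list(actor = agent$actor, critic = agent$critic),
                      list(actor = ga, critic = gc), state, lr, t_adam,
                      weight_decay = weight_decay)
    agent$actor <- res$par$actor
    agent$critic <- res$par$critic
    state <- res$state
  }
  list(agent = agent, reward_history = hist, reached_threshold = reached,
       episodes_run = length(hist))
}

#' Greedy success rate over all barrier configurations
#'
#' @param agent a `pg_agent`
#' @param env a [raycast_env()]
#' @return fraction of configurations whose greedy episode ends in the
#'   positive reward
#' @export
agent_success_rate <- function(agent, env) {
  grid <- as.matrix(expand.grid(rep(list(0:1), env$n_bits)))
  mean(apply(grid, 1L, function(bits) {
    tr <- .agent_episode(agent, env, bits = bits, greedy = TRUE)
    tr$total_reward >= env$reward_correct
  }))
}

#' Sample frozen actor activations over task configurations
#'
#' Runs test episodes for every barrier configuration of every supplied
#' environment (all configurations within the curriculum trained so far)
#' and records, per time step, the raw observation and both actor
#' hidden-layer activations. By default several stochastic-policy episodes
#' are rolled out per configuration (plus one greedy episode), so the
#' record covers a spread of positions and repeated visits rather than a
#' single deterministic trajectory — with only one greedy pass the joint
#' next-layer state can separate every distinct observation, which makes
#' input-side decompositions insensitive to what the network has learned.
#'
#' @param agent a `pg_agent`
#' @param envs a [raycast_env()] or list of them
#' @param n_episodes stochastic episodes per configuration
#' @param seed seed for the stochastic rollouts (private stream)
#' @return an `activation_record` with `inputs` (raw observations),
#'   `layers` (two matrices), and `meta`
#' @export
sample_agent_activations <- function(agent, envs, n_episodes = 5L,
                                     seed = 17L) {
  if (inherits(envs, "raycast_env")) envs <- list(envs)
  rng <- .isolated_rng(seed)
  obs <- list(); h1 <- list(); h2 <- list()
  for (env in envs) {
    grid <- as.matrix(expand.grid(rep(list(0:1), env$n_bits)))
    for (r in seq_len(nrow(grid))) {
      for (ep in seq_len(n_episodes + 1L)) {
        tr <- if (ep == 1L) {
          .agent_episode(agent, env, bits = grid[r, ], greedy = TRUE,
                         record = TRUE)
        } else {
          rng$with(.agent_episode(agent, env, bits = grid[r, ],
                                  greedy = FALSE, record = TRUE))
        }
        obs[[length(obs) + 1L]] <- tr$obs
        h1[[length(h1) + 1L]] <- tr$h1
        h2[[length(h2) + 1L]] <- tr$h2
      }
    }
  }
  structure(
    list(inputs = do.call(rbind, obs),
         layers = list(do.call(rbind, h1), do.call(rbind, h2)),
         outputs = NULL,
         meta = list(kind = "agent", seed = agent$seed,
                     gates = vapply(envs, function(e) e$gate, ""))),
    class = "activation_record"
  )
}

#' Train an agent through a curriculum of platform tasks
#'
#' Trains the same agent on each task in order, advancing on the reward
#' threshold or at the episode cap, and snapshots the agent at the end of
#' each task (checkpoint "at task threshold"). Agents that never reach
#' threshold advance at the cap and are flagged.
#'
#' @param stages list of [raycast_env()] tasks, in curriculum order
#' @param seed integer seed (weights and training randomness)
#' @param episodes_per_stage episode cap per task (recycled)
#' @param ... further arguments passed to [train_agent()]
#' @return list of class `curriculum_run`: per-stage list with `agent`
#'   (checkpoint), `reached_threshold`, `episodes_run`, `success`
#' @export
train_curriculum <- function(stages, seed = 1L, episodes_per_stage = 3000L,
                             ...) {
  episodes_per_stage <- rep_len(episodes_per_stage, length(stages))
  agent <- new_agent(seed = seed,
                     arena_size = stages[[1L]]$arena_size)
  out <- vector("list", length(stages))
  for (s in seq_along(stages)) {
    res <- train_agent(agent, stages[[s]], episodes = episodes_per_stage[s],
                       seed = seed + 1000L * s, ...)
    agent <- res$agent
    out[[s]] <- list(agent = agent, reached_threshold = res$reached_threshold,
                     episodes_run = res$episodes_run,
                     success = agent_success_rate(agent, stages[[s]]))
  }
  structure(out, class = "curriculum_run", names = paste0("stage", seq_along(stages)))
}
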