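#' One-dimensional delayed-reward platform environment
#'
#' An abstract stand-in for a 3D logic-gate arena: the agent stands at the
#' centre of a platform flanked by two pits, observes the object types of
#' the barriers around it through three raycast blocks (front, left,
#' right), and must walk forward or backward into the pit whose side is
#' selected by a logic gate applied to the barrier bits (wall = 0,
#' cardbox = 1; gate output 0 = forward pit, 1 = backward pit). The correct
#' pit pays `+4`, the wrong pit `-1`, and intermediate steps pay 0, so with
#' platform length `L` at least `L` consecutive same-direction steps
#' separate action from reward. Every piece of task information is present
#' in the first observation; pit contents are never observable.
#'
#' Each raycast block is a one-hot object-type vector (wall, cardbox) plus
#' a distance normalized by the arena size; the agent-state block carries
#' health (constant 1), signed unit velocity and global position in arena
#' units. For two-bit gates the front raycast sees the far arena wall; the
#' three-bit XOR adds a front barrier carrying the third input bit.
#'
#' @param gate `"XOR2"` or `"XOR3"` (reward-side rule = parity of the
#'   barrier bits)
#' @param platform_length half-length `L` of the platform in arena units;
#'   pits sit at positions `-L` and `+L` and the agent starts at 0
#' @param arena_size arena extent used to normalize distances and position
#' @param reward_correct,reward_wrong terminal rewards
#' @param max_episode_steps step cap before a zero-reward timeout
#' @return an object of class `raycast_env`
#' @examples
#' env <- raycast_env("XOR2", platform_length = 2)
#' st <- env_reset(env, bits = c(0, 1))
#' env_step(st, "backward")$reward
#' @export
raycast_env <- function(gate = c("XOR2", "XOR3"), platform_length = 2L,
                        arena_size = 40, reward_correct = 4,
                        reward_wrong = -1, max_episode_steps = NULL) {
  gate <- match.arg(gate)
  n_bits <- if (gate == "XOR3") 3L else 2L
  platform_length <- as.integer(platform_length)
  if (platform_length < 1L) stop("platform_length must be positive")
  if (is.null(max_episode_steps)) max_episode_steps <- 10L * platform_length + 20L
  structure(
    list(gate = gate, n_bits = n_bits, platform_length = platform_length,
         arena_size = arena_size, reward_correct = reward_correct,
         reward_wrong = reward_wrong,
         max_episode_steps = as.integer(max_episode_steps)),
    class = "raycast_env"
  )
}

#' Start a new episode
#'
#' Samples a barrier-bit configuration uniformly (or uses `bits` when
#' given), places the agent at the platform centre and returns the initial
#' state. The first observation already contains all barrier bits.
#'
#' @param env a [raycast_env()]
#' @param bits optional explicit 0/1 barrier bits (length 2 or 3)
#' @param seed optional integer; when given, the configuration draw uses a
#'   private RNG stream and leaves the session RNG untouched
#' @return episode state: list with `env`, `bits`, `output`, `pos`,
#'   `steps`, `done`, `last_action`, `observation`
#' @export
env_reset <- function(env, bits = NULL, seed = NULL) {
  if (is.null(bits)) {
    bits <- if (is.null(seed)) {
      stats::rbinom(env$n_bits, 1L, 0.5)
    } else {
      .isolated_rng(seed)$with(stats::rbinom(env$n_bits, 1L, 0.5))
    }
  }
  bits <- as.integer(bits)
  if (length(bits) != env$n_bits || any(!bits %in% 0:1)) {
    stop("bits must be 0/1 of length ", env$n_bits)
  }
  st <- list(env = env, bits = bits, output = sum(bits) %% 2L, pos = 0L,
             steps = 0L, done = FALSE, last_action = 0L)
  st$observation <- env_observation(st)
  st
}

#' Raw observation vector for an episode state
#'
#' Twelve named dimensions: three raycast blocks (one-hot wall/cardbox +
#' normalized distance) for front, left, right, then health, velocity and
#' global position.
#'
#' @param state episode state from [env_reset()] / [env_step()]
#' @return named numeric vector of length 12
#' @export
env_observation <- function(state) {
  env <- state$env
  L <- env$platform_length
  front_type <- if (env$n_bits == 3L) state$bits[3L] else 0L
  front_dist <- (L - state$pos + 1L) / env$arena_size
  side_dist <- 2 / env$arena_size
  block <- function(type, dist) c(1 - type, type, dist)
  obs <- c(block(front_type, front_dist),
           block(state$bits[1L], side_dist),
           block(state$bits[2L], side_dist),
           1.0,                                   # health
           as.numeric(state$last_action),         # signed unit velocity
           env$arena_size / 2 + state$pos)        # global position
  names(obs) <- c("front_wall", "front_cardbox", "front_dist",
                  "left_wall", "left_cardbox", "left_dist",
                  "right_wall", "right_cardbox", "right_dist",
                  "health", "velocity", "position")
  obs
}

#' Advance an episode by one action
#'
#' @param state episode state (not done)
#' @param action `"forward"` or `"backward"` (or `+1` / `-1`)
#' @return updated state with `reward` and `done` set; reaching the pit at
#'   `+L` ends the episode with the positive reward iff the gate output is
#'   0, the pit at `-L` iff it is 1
#' @export
env_step <- function(state, action) {
  if (state$done) stop("episode is done; call env_reset()")
  dir <- if (is.character(action)) {
    switch(match.arg(action, c("forward", "backward")), forward = 1L, backward = -1L)
  } else as.integer(sign(action))
  if (!dir %in% c(-1L, 1L)) stop("action must be forward or backward")
  env <- state$env
  state$pos <- state$pos + dir
  state$steps <- state$steps + 1L
  state$last_action <- dir
  L <- env$platform_length
  reward <- 0
  if (state$pos >= L) {
    reward <- if (state$output == 0L) env$reward_correct else env$reward_wrong
    state$done <- TRUE
  } else if (state$pos <= -L) {
    reward <- if (state$output == 1L) env$reward_correct else env$reward_wrong
    state$done <- TRUE
  } else if (state$steps >= env$max_episode_steps) {
    state$done <- TRUE
  }
  state$reward <- reward
  state$observation <- env_observation(state)
  state
}

#' Oracle action for an episode state
#'
#' Reads the barrier bits from the observation, computes the parity and
#' heads straight for the rewarded pit — certifies the environment solvable
#' from the first step.
#'
#' @param state episode state
#' @return `"forward"` or `"backward"`
#' @export
env_oracle_action <- function(state) {
  obs <- state$observation
  bits <- c(obs["left_cardbox"], obs["right_cardbox"])
  if (state$env$n_bits == 3L) bits <- c(bits, obs["front_cardbox"])
  if (sum(bits) %% 2 == 0) "forward" else "backward"
}

#' Source grouping and binning for environment observations
#'
#' The discretization scheme for platform-environment inputs: each raycast
#' block is one source (its one-hot type fused with the distance, binned
#' with 3 equal-width bins on `[0, 1]`) and global position is a fourth
#' source (5 equal-width bins on `[0, arena_size]`). Health and velocity
#' carry no task information and are excluded.
#'
#' @param arena_size arena extent (default 40)
#' @param n_dist_bins bins for normalized distances (default 3)
#' @param n_pos_bins bins for global position (default 5)
#' @return list with `columns` (observation columns used), `edges` (edge
#'   vector per column) and `grouping` (source grouping over those columns)
#' @export
env_input_spec <- function(arena_size = 40, n_dist_bins = 3L, n_pos_bins = 5L) {
  cols <- c(1:9, 12L)                    # raycast blocks + position
  dist_edges <- fixed_range_edges(n_dist_bins, 0, 1)
  onehot_edges <- fixed_range_edges(2L, -0.5, 1.5)  # 0/1 indicator
  pos_edges <- fixed_range_edges(n_pos_bins, 0, arena_size)
  edges <- c(rep(list(onehot_edges, onehot_edges, dist_edges), 3L),
             list(pos_edges))
  list(columns = cols, edges = edges,
       grouping = list(front = 1:3, left = 4:6, right = 7:9, position = 10L))
}
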