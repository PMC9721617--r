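#' Two-step task configuration
#'
#' Builds the environment definition for the deterministic two-step task:
#' two first-stage states ("spaceship pairs"), each offering two actions that
#' fly deterministically to one of two planets, whose point payouts follow
#' independent discretized Gaussian random walks bounded in `[-4, 5]`.
#'
#' The drift (the SD of the per-trial Gaussian increment on the latent walk)
#' changes over the session: `drift_levels` are laid out over contiguous
#' blocks of equal length, in the order given. Each trial starts in one of
#' the two first-stage states; the default sequence is a seeded Markov chain
#' in which the state repeats with probability `p_same_state`, giving equal
#' state frequencies in expectation.
#'
#' @param n_trials number of trials per session (default 200).
#' @param reward_bounds closed integer interval for delivered points,
#'   default `c(-4, 5)`.
#' @param drift_levels positive SDs of the latent walk increments; the
#'   default set is `c(0.5, 1, 2)`.
#' @param drift_schedule optional explicit per-trial drift assignment
#'   (length `n_trials`, values drawn from `drift_levels`); overrides the
#'   block layout.
#' @param transition_map 2x2 integer matrix, `transition_map[s, a]` = planet
#'   (1 = "red", 2 = "green") reached by action `a` in first-stage state `s`.
#'   Each row must contain both planets.
#' @param first_state_sequence optional explicit per-trial first-stage state
#'   labels (values 1/2); generated from `seed` when omitted.
#' @param p_same_state probability that consecutive trials share the
#'   first-stage state when the sequence is generated (default 0.5).
#' @param points_to_cents conversion of points to Eurocents (default 4).
#' @param seed integer seed for the generated first-state sequence.
#' @return an object of class `twostep_task_config`.
#' @export
task_config <- function(n_trials = 200L,
                        reward_bounds = c(-4L, 5L),
                        drift_levels = c(0.5, 1, 2),
                        drift_schedule = NULL,
                        transition_map = default_transition_map(),
                        first_state_sequence = NULL,
                        p_same_state = 0.5,
                        points_to_cents = 4,
                        seed = 1L) {
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) stop("n_trials must be a positive integer")
  if (length(reward_bounds) != 2L || reward_bounds[1] >= reward_bounds[2])
    stop("reward_bounds must be an interval c(lower, upper) with lower < upper")
  if (any(drift_levels < 0)) stop("drift_levels must be non-negative")
  if (!is.matrix(transition_map) || !identical(dim(transition_map), c(2L, 2L)))
    stop("transition_map must be a 2x2 matrix")
  if (!all(sort(transition_map[1, ]) == 1:2) ||
      !all(sort(transition_map[2, ]) == 1:2))
    stop("each first-stage state must offer one action per planet")

  if (is.null(drift_schedule)) {
    k <- length(drift_levels)
    block <- rep(seq_len(k), each = ceiling(n_trials / k))[seq_len(n_trials)]
    drift_schedule <- drift_levels[block]
  }
  if (length(drift_schedule) != n_trials)
    stop("drift_schedule length must equal n_trials")
  if (!all(drift_schedule %in% drift_levels))
    stop("every scheduled drift level must be one of drift_levels")

  if (is.null(first_state_sequence)) {
    first_state_sequence <- local({
      rng <- local_rng(seed)
      s <- integer(n_trials)
      s[1] <- sample(1:2, 1)
      if (n_trials > 1L)
        for (t in 2:n_trials)
          s[t] <- if (stats::runif(1) < p_same_state) s[t - 1] else 3L - s[t - 1]
      s
    })
  }
  first_state_sequence <- as.integer(first_state_sequence)
  if (length(first_state_sequence) != n_trials ||
      !all(first_state_sequence %in% 1:2))
    stop("first_state_sequence must be n_trials labels in {1, 2}")

  structure(
    list(n_trials = n_trials,
         reward_bounds = as.integer(reward_bounds),
         drift_levels = drift_levels,
         drift_schedule = drift_schedule,
         transition_map = transition_map,
         first_state_sequence = first_state_sequence,
         points_to_cents = points_to_cents),
    class = "twostep_task_config")
}

#' Default spaceship-to-planet transition map
#'
#' Action 1 in state 1 flies to the red planet (1), action 2 to the green
#' planet (2); state 2 reverses the assignment so that the response slot is
#' not confounded with the planet.
#' @return 2x2 integer matrix indexed `[first_state, action]`.
#' @export
default_transition_map <- function() {
  matrix(c(1L, 2L, 2L, 1L), nrow = 2, byrow = TRUE,
         dimnames = list(state = c("s1", "s2"), action = c("a1", "a2")))
}

#' Planet labels used in trial tables
#' @keywords internal
planet_labels <- c("red", "green")

#' Resolve a first-stage choice to its planet
#'
#' The transition structure is deterministic and trial-invariant: the planet
#' is a pure function of the first-stage state and the chosen action.
#'
#' @param config a [task_config()] object.
#' @param first_state first-stage state, 1 or 2 (vectorised).
#' @param action chosen action, 1 or 2 (vectorised).
#' @return integer planet labels (1 = red, 2 = green).
#' @export
resolve_transition <- function(config, first_state, action) {
  if (!all(first_state %in% 1:2)) stop("unknown first_state label")
  if (!all(action %in% 1:2)) stop("unknown action label")
  config$transition_map[cbind(first_state, action)]
}

#' Stimulus (spaceship) identity for a state/action pair
#' @keywords internal
stimulus_id <- function(first_state, action) 2L * (first_state - 1L) + action

#' Generate a bounded random-walk reward trajectory for one planet
#'
#' The latent trajectory starts uniformly inside the bounds and evolves by
#' Gaussian increments with the per-trial SD given by the drift schedule.
#' Excursions beyond a bound bounce back (reflection `x -> 2*bound - x`,
#' applied iteratively), keeping the latent value continuous; the delivered
#' reward is the latent value rounded to the nearest integer.
#'
#' @param config a [task_config()] object.
#' @param planet planet index (1 or 2); only used to label the result.
#' @param seed integer seed.
#' @param start optional latent starting value (default: uniform draw within
#'   the bounds).
#' @return a list of class `twostep_reward_walk` with integer `reward`,
#'   continuous `latent`, `planet` and `seed`.
#' @export
generate_reward_walk <- function(config, planet = 1L, seed = 1L, start = NULL) {
  lo <- config$reward_bounds[1]; hi <- config$reward_bounds[2]
  rng <- local_rng(seed)
  if (is.null(start)) start <- stats::runif(1, lo, hi)
  x <- numeric(config$n_trials)
  cur <- reflect_into(start, lo, hi)
  for (t in seq_len(config$n_trials)) {
    if (t > 1L)
      cur <- reflect_into(cur + stats::rnorm(1, 0, config$drift_schedule[t]),
                          lo, hi)
    x[t] <- cur
  }
  structure(list(reward = as.integer(round(x)), latent = x,
                 planet = planet, seed = seed),
            class = "twostep_reward_walk")
}

#' Reflect a value into a closed interval ("bouncing" boundaries)
#' @keywords internal
reflect_into <- function(x, lo, hi) {
  while (x < lo || x > hi) {
    if (x > hi) x <- 2 * hi - x
    if (x < lo) x <- 2 * lo - x
  }
  x
}

#' Generate one pair of independent planet reward walks
#'
#' @inheritParams generate_reward_walk
#' @param seed integer seed; the two planets use `seed` and `seed + 1L`.
#' @return list with elements `red` and `green` (class `twostep_reward_walk`).
#' @export
generate_walk_pair <- function(config, seed = 1L) {
  list(red = generate_reward_walk(config, 1L, seed),
       green = generate_reward_walk(config, 2L, seed + 1L))
}

walks_matrix <- function(walks, n_trials) {
  m <- cbind(walks$red$reward, walks$green$reward)
  if (nrow(m) != n_trials) stop("walk length does not match n_trials")
  m
}

#' Simulate one session of play under an arbitrary policy
#'
#' Composes a choice policy with the task environment. The policy is a
#' function `(trial_index, first_state, history)` returning an action in
#' `{1, 2}`; `history` is the data frame of completed trials. Model-driven
#' simulation is provided by [simulate_choices()], which tracks subjective
#' values internally.
#'
#' @param policy function of `(t, first_state, history)` returning 1 or 2.
#' @param config a [task_config()] object.
#' @param walks a walk pair from [generate_walk_pair()].
#' @param seed seed for any randomness inside the policy (the environment
#'   itself is deterministic given the walks).
#' @param subject_id,session labels stamped on the records.
#' @return data frame of trial records: `subject_id, session, trial,
#'   first_state, action, stimulus_id, planet, reward`.
#' @export
simulate_session <- function(policy, config, walks, seed = 1L,
                             subject_id = "s1", session = 1L) {
  n <- config$n_trials
  rw <- walks_matrix(walks, n)
  rng <- local_rng(seed)
  fs <- config$first_state_sequence
  action <- integer(n); planet <- integer(n); reward <- integer(n)
  hist <- NULL
  for (t in seq_len(n)) {
    a <- policy(t, fs[t], hist)
    if (!a %in% 1:2) stop("policy returned an invalid action at trial ", t)
    p <- resolve_transition(config, fs[t], a)
    action[t] <- a; planet[t] <- p; reward[t] <- rw[t, p]
    hist <- data.frame(trial = seq_len(t), first_state = fs[seq_len(t)],
                       action = action[seq_len(t)], planet = planet[seq_len(t)],
                       reward = reward[seq_len(t)])
  }
  data.frame(subject_id = subject_id, session = as.integer(session),
             trial = seq_len(n), first_state = fs, action = action,
             stimulus_id = stimulus_id(fs, action), planet = planet,
             reward = reward)
}

#' Code stay events from a session of trials
#'
#' A "stay" on trial t means choosing the first-stage option that flies to
#' the same planet as the choice on trial t-1; staying is defined on planets,
#' not on stimuli, so it is well defined whether or not consecutive trials
#' share the first-stage state.
#'
#' @param session data frame of trial records for one subject-session,
#'   ordered by trial.
#' @return data frame with one row per trial from the second onwards:
#'   `trial_index`, `same_first_state`, `prev_points`, `stayed` (all logical/
#'   integer). Empty (0 rows) for single-trial sessions.
#' @export
code_stay_events <- function(session) {
  n <- nrow(session)
  if (n < 2L)
    return(data.frame(trial_index = integer(0), same_first_state = logical(0),
                      prev_points = integer(0), stayed = logical(0)))
  idx <- 2:n
  data.frame(
    trial_index = session$trial[idx],
    same_first_state = session$first_state[idx] == session$first_state[idx - 1],
    prev_points = session$reward[idx - 1],
    stayed = session$planet[idx] == session$planet[idx - 1])
}

#' Convert total points to the monetary payout
#'
#' Each point is worth `points_to_cents` Eurocents (4 by default); the
#' payout may be negative.
#'
#' @param total_points integer point total (vectorised).
#' @param points_to_cents cents per point.
#' @return payout in Euros.
#' @export
points_to_payout <- function(total_points, points_to_cents = 4) {
  total_points * points_to_cents / 100
}
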