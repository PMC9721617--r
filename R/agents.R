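#' Parameters of the last-outcome learner (M1 / M1_sticky)
#'
#' `omega` mixes model-based and model-free action values, `gamma` is the
#' per-trial devaluation (forgetting) of model-free values of unchosen and
#' unencountered spaceships, and `eta` is the softmax inverse temperature.
#' Supplying `rho` (response stickiness) and `pi` (stimulus stickiness)
#' selects the sticky variant.
#'
#' @param omega model-based weight in `[0, 1]`.
#' @param gamma forgetting parameter in `[0, 1]`.
#' @param eta inverse temperature, `>= 0`.
#' @param rho,pi optional unbounded stickiness biases.
#' @return named numeric vector with attribute `model_id`.
#' @export
m1_params <- function(omega, gamma, eta, rho = NULL, pi = NULL) {
  stopifnot(omega >= 0, omega <= 1, gamma >= 0, gamma <= 1, eta >= 0)
  sticky <- !is.null(rho) || !is.null(pi)
  p <- if (sticky)
    c(omega = omega, gamma = gamma, eta = eta,
      rho = rho %||% 0, pi = pi %||% 0)
  else c(omega = omega, gamma = gamma, eta = eta)
  structure(p, model_id = if (sticky) "M1_sticky" else "M1")
}

#' Parameters of the dual-system TD learners (M2 / M3)
#'
#' @param omega model-based weight in `[0, 1]`.
#' @param eta inverse temperature, `>= 0`.
#' @param alpha1,alpha2 stage-1 and stage-2 learning rates in `[0, 1]`;
#'   passing `alpha2 = NULL` ties the rates (model M3).
#' @param lambda eligibility trace in `[0, 1]`.
#' @return named numeric vector with attribute `model_id`.
#' @export
rl_params <- function(omega, eta, alpha1, alpha2 = NULL, lambda = 0) {
  stopifnot(omega >= 0, omega <= 1, eta >= 0,
            alpha1 >= 0, alpha1 <= 1, lambda >= 0, lambda <= 1)
  if (is.null(alpha2))
    return(structure(c(omega = omega, eta = eta, alpha = alpha1,
                       lambda = lambda), model_id = "M3"))
  stopifnot(alpha2 >= 0, alpha2 <= 1)
  structure(c(omega = omega, eta = eta, alpha1 = alpha1, alpha2 = alpha2,
              lambda = lambda), model_id = "M2")
}

params_vector <- function(params, model_id) {
  info <- model_par_info(model_id)
  if (!is.null(names(params))) {
    miss <- setdiff(info$name, names(params))
    if (length(miss)) stop("missing parameters: ", paste(miss, collapse = ", "))
    unname(params[info$name])
  } else {
    stopifnot(length(params) == nrow(info))
    unname(params)
  }
}

#' Fresh subjective-value state
#'
#' All model-free and planet values start at zero (a symmetric start: the
#' first choice of a session is uniformly random under every model) and no
#' previous action/stimulus is recorded.
#' @return list with `QMF` (2x2, state x action), `Q2` (length 2, planet),
#'   `prev_action`, `prev_stim`.
#' @export
value_state_init <- function() {
  list(QMF = matrix(0, 2, 2), Q2 = c(0, 0),
       prev_action = NA_integer_, prev_stim = NA_integer_)
}

#' Mixed action values for one first-stage state
#'
#' `Q(a) = omega * QMB(a) + (1 - omega) * QMF(a)`, where the model-based
#' value of an action is the value of the planet it deterministically leads
#' to, `QMB(s, a) = Q2(transition_map[s, a])`. The sticky variant adds
#' `rho * resp(a) + pi * stim(a)`, with indicators of the action slot and
#' the spaceship chosen on the immediately preceding trial (zero on trial 1).
#'
#' @param params model parameters (see [m1_params()], [rl_params()]).
#' @param state a value state from [value_state_init()] / the update ops.
#' @param first_state first-stage state of the current trial.
#' @param transition_map the task's deterministic transition map.
#' @param model_id model identifier; defaults to the params attribute.
#' @return numeric length-2 vector of action values.
#' @export
mixed_value <- function(params, state, first_state,
                        transition_map = default_transition_map(),
                        model_id = attr(params, "model_id")) {
  omega <- params[["omega"]]
  planets <- transition_map[first_state, ]
  qmb <- state$Q2[planets]
  qmf <- state$QMF[first_state, ]
  q <- omega * qmb + (1 - omega) * qmf
  if (identical(model_id, "M1_sticky")) {
    if (!is.na(state$prev_action))
      q <- q + params[["rho"]] * (seq_len(2) == state$prev_action)
    if (!is.na(state$prev_stim))
      q <- q + params[["pi"]] *
        (stimulus_id(first_state, seq_len(2)) == state$prev_stim)
  }
  unname(q)
}

#' Softmax choice probabilities
#'
#' Numerically stable two-option softmax `P(a) = exp(eta Q(a)) / sum`.
#' `eta = 0` gives uniform choice; an infinite `eta` selects the argmax
#' (ties split 0.5/0.5).
#'
#' @param Q numeric length-2 action values.
#' @param eta inverse temperature, `>= 0`.
#' @return numeric length-2 probability vector summing to 1.
#' @export
choice_prob <- function(Q, eta) {
  if (eta < 0) stop("eta must be non-negative")
  stopifnot(length(Q) == 2L, all(is.finite(Q)))
  if (!is.finite(eta)) {
    if (Q[1] == Q[2]) return(c(0.5, 0.5))
    return(as.numeric(c(Q[1] > Q[2], Q[2] > Q[1])))
  }
  z <- eta * Q
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Value update of the last-outcome learner (M1)
#'
#' The model-free value of the chosen spaceship is set to the just-received
#' outcome; the three other (state, action) model-free entries shrink toward
#' zero by the factor `1 - gamma`. The planet value is set to the outcome,
#' which updates the model-based value of *both* spaceships flying there —
#' including the one in the unencountered first-stage state. Model-based
#' values of the other planet are left unchanged (no model-based decay).
#'
#' @param state value state before the trial's outcome.
#' @param trial one trial record (list/row with `first_state`, `action`,
#'   `planet`, `reward`).
#' @param gamma forgetting parameter.
#' @param transition_map task transition map.
#' @return updated value state.
#' @export
m1_update <- function(state, trial, gamma,
                      transition_map = default_transition_map()) {
  s <- trial$first_state; a <- trial$action; r <- trial$reward
  keep <- state$QMF[s, a]
  state$QMF <- state$QMF * (1 - gamma)
  state$QMF[s, a] <- r
  state$Q2[trial$planet] <- r
  state$prev_action <- a
  state$prev_stim <- stimulus_id(s, a)
  state
}

#' Temporal-difference value update (M2 / M3)
#'
#' Three steps, in order: (i) stage-1 TD step with
#' `delta1 = Q2(planet) - QMF(s1, a)` computed from the pre-update planet
#' value, `QMF(s1, a) += alpha1 * delta1`; (ii) stage-2 step
#' `delta2 = r - Q2(planet)`, `Q2(planet) += alpha2 * delta2`; (iii)
#' eligibility-trace step `QMF(s1, a) += lambda * alpha1 * delta2`. Only the
#' experienced state/action and reached planet change; model-based values
#' are always read off the planet values through the transition map.
#'
#' @inheritParams m1_update
#' @param alpha1,alpha2 stage learning rates.
#' @param lambda eligibility trace.
#' @return updated value state.
#' @export
td_update <- function(state, trial, alpha1, alpha2, lambda,
                      transition_map = default_transition_map()) {
  s <- trial$first_state; a <- trial$action; r <- trial$reward
  pl <- trial$planet
  delta1 <- state$Q2[pl] - state$QMF[s, a]
  state$QMF[s, a] <- state$QMF[s, a] + alpha1 * delta1
  delta2 <- r - state$Q2[pl]
  state$Q2[pl] <- state$Q2[pl] + alpha2 * delta2
  state$QMF[s, a] <- state$QMF[s, a] + lambda * alpha1 * delta2
  state$prev_action <- a
  state$prev_stim <- stimulus_id(s, a)
  state
}

apply_update <- function(state, trial, pv, model_id, transition_map) {
  switch(model_id,
    M1 = m1_update(state, trial, pv[2], transition_map),
    M1_sticky = m1_update(state, trial, pv[2], transition_map),
    M2 = td_update(state, trial, pv[3], pv[4], pv[5], transition_map),
    M3 = td_update(state, trial, pv[3], pv[3], pv[4], transition_map))
}

#' Sequential log-likelihood of one session
#'
#' Sum over trials of the log choice probability of the observed action
#' given the subjective values *before* that trial; values start at zero
#' and are updated after each choice. The compiled engine (default) and the
#' plain-R engine compose identical update rules and agree to numerical
#' precision; the R engine exists as a readable reference.
#'
#' @param params model parameters in native space.
#' @param model_id one of `"M1"`, `"M1_sticky"`, `"M2"`, `"M3"`.
#' @param session trial records of one subject-session, ordered by trial.
#' @param transition_map task transition map.
#' @param engine `"cpp"` (compiled) or `"r"` (reference).
#' @return total log-likelihood (scalar).
#' @export
session_loglik <- function(params, model_id = attr(params, "model_id"),
                           session,
                           transition_map = default_transition_map(),
                           engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  pv <- params_vector(params, model_id)
  if (engine == "cpp") {
    ll <- session_loglik_cpp(
      model_code(model_id), pv,
      as.integer(session$first_state), as.integer(session$action),
      as.integer(session$planet), as.numeric(session$reward),
      transition_map)
    if (!is.finite(ll)) stop("non-finite session log-likelihood")
    return(ll)
  }
  state <- value_state_init()
  eta <- pv[[which(model_par_info(model_id)$name == "eta")]]
  ll <- 0
  for (i in seq_len(nrow(session))) {
    tr <- session[i, ]
    q <- mixed_value(pv_named(pv, model_id), state, tr$first_state,
                     transition_map, model_id)
    pr <- choice_prob(q, eta)
    ll <- ll + log(pr[tr$action])
    if (!is.finite(ll)) stop("non-finite log-likelihood at trial ", i)
    state <- apply_update(state, tr, pv, model_id, transition_map)
  }
  ll
}

pv_named <- function(pv, model_id) {
  stats::setNames(pv, model_par_info(model_id)$name)
}

#' Per-trial log-likelihood decomposition of one session
#'
#' @inheritParams session_loglik
#' @return numeric vector, one log-probability per trial; its sum equals
#'   [session_loglik()].
#' @export
session_loglik_pointwise <- function(params,
                                     model_id = attr(params, "model_id"),
                                     session,
                                     transition_map = default_transition_map()) {
  pv <- params_vector(params, model_id)
  session_loglik_pointwise_cpp(
    model_code(model_id), pv,
    as.integer(session$first_state), as.integer(session$action),
    as.integer(session$planet), as.numeric(session$reward),
    transition_map)
}

#' Simulate choices of a model agent over one session
#'
#' Generative mirror of [session_loglik()]: at each trial the action is
#' sampled from the softmax over the current mixed values, the planet follows
#' deterministically, and the reward is read from the planet's walk.
#'
#' @inheritParams session_loglik
#' @param config a [task_config()] object.
#' @param walks a walk pair from [generate_walk_pair()].
#' @param seed integer seed for the sampled choices.
#' @param subject_id,session_label labels stamped on the records.
#' @return data frame of trial records (standard schema).
#' @export
simulate_choices <- function(params, model_id = attr(params, "model_id"),
                             config, walks, seed = 1L,
                             subject_id = "s1", session_label = 1L) {
  pv <- params_vector(params, model_id)
  info <- model_par_info(model_id)
  eta <- pv[[which(info$name == "eta")]]
  n <- config$n_trials
  rw <- walks_matrix(walks, n)
  fs <- config$first_state_sequence
  tm <- config$transition_map
  local_rng(seed)
  u <- stats::runif(n)
  state <- value_state_init()
  action <- integer(n); planet <- integer(n); reward <- numeric(n)
  for (t in seq_len(n)) {
    q <- mixed_value(pv_named(pv, model_id), state, fs[t], tm, model_id)
    pr <- choice_prob(q, eta)
    a <- if (u[t] < pr[1]) 1L else 2L
    p <- tm[fs[t], a]
    action[t] <- a; planet[t] <- p; reward[t] <- rw[t, p]
    state <- apply_update(state,
                          list(first_state = fs[t], action = a, planet = p,
                               reward = rw[t, p]),
                          pv, model_id, tm)
  }
  data.frame(subject_id = subject_id, session = as.integer(session_label),
             trial = seq_len(n), first_state = fs, action = action,
             stimulus_id = stimulus_id(fs, action), planet = planet,
             reward = as.integer(reward))
}
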