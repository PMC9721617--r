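# Shared fixtures: everything is generated in code at test time.

quick_config <- function(n_trials = 40L, seed = 1L, ...) {
  task_config(n_trials = n_trials, seed = seed, ...)
}

quick_walks <- function(config, seed = 2L) generate_walk_pair(config, seed)

# A small deterministic session for likelihood tests.
fixed_session <- function(n = 5L, seed = 3L) {
  cfg <- quick_config(n_trials = n, seed = seed)
  walks <- quick_walks(cfg, seed + 1L)
  simulate_choices(m1_params(0.6, 0.3, 1), "M1", cfg, walks, seed = seed + 2L)
}

quick_spec <- function(n_arm = 4L, n_trials = 60L, seed = 11L, ...) {
  cohort_spec(n_per_arm = c(placebo = n_arm, amisulpride = n_arm,
                            naltrexone = n_arm),
              n_trials = n_trials, master_seed = seed, ...)
}

# Stay table drawn from a known logistic model (not from the task), used for
# GLM recovery tests.
logistic_stay_table <- function(n_subj = 12L, n_per = 100L, slope = 0.4,
                                state_int = -0.2, seed = 1L,
                                permute_points = FALSE) {
  set.seed(seed)
  rows <- vector("list", n_subj * 2L)
  for (i in seq_len(n_subj)) {
    b0 <- stats::rnorm(1, 0.2, 0.5)
    for (sess in 1:2) {
      pts <- sample(-4:5, n_per, replace = TRUE)
      sdf <- stats::rbinom(n_per, 1, 0.5)
      eta <- b0 + slope * pts - 0.15 * sdf + state_int * pts * sdf
      stay <- stats::rbinom(n_per, 1, stats::plogis(eta))
      if (permute_points) pts <- sample(pts)
      rows[[2L * (i - 1L) + sess]] <- data.frame(
        subject_id = sprintf("s%02d", i), session = sess,
        trial_index = seq_len(n_per) + 1L, prev_points = pts,
        same_first_state = sdf == 0, stayed = stay,
        drug = c("placebo", "amisulpride", "naltrexone")[1L + (i %% 3L)],
        serum_group = NA_character_)
    }
  }
  do.call(rbind, rows)
}

# Independent step-by-step oracle for the session log-likelihood: a direct
# transcription of the value-update and softmax equations, sharing no code
# with the package implementation.
oracle_session_loglik <- function(model_id, pars, session, tm) {
  qmf <- matrix(0, 2, 2); q2 <- c(0, 0)
  prev_a <- NA; prev_stim <- NA
  ll <- 0
  for (t in seq_len(nrow(session))) {
    s <- session$first_state[t]; a <- session$action[t]
    pl <- session$planet[t]; r <- session$reward[t]
    qmb <- c(q2[tm[s, 1]], q2[tm[s, 2]])
    q <- pars$omega * qmb + (1 - pars$omega) * qmf[s, ]
    if (model_id == "M1_sticky") {
      if (!is.na(prev_a)) q[prev_a] <- q[prev_a] + pars$rho
      for (aa in 1:2)
        if (!is.na(prev_stim) && 2 * (s - 1) + aa == prev_stim)
          q[aa] <- q[aa] + pars$pi
    }
    z <- pars$eta * q
    ll <- ll + z[a] - (max(z) + log(sum(exp(z - max(z)))))
    if (model_id %in% c("M1", "M1_sticky")) {
      old <- qmf[s, a]
      qmf <- qmf * (1 - pars$gamma)
      qmf[s, a] <- r
      q2[pl] <- r
    } else {
      a1 <- pars$alpha1; a2 <- pars$alpha2; lam <- pars$lambda
      d1 <- q2[pl] - qmf[s, a]
      qmf[s, a] <- qmf[s, a] + a1 * d1
      d2 <- r - q2[pl]
      q2[pl] <- q2[pl] + a2 * d2
      qmf[s, a] <- qmf[s, a] + lam * a1 * d2
    }
    prev_a <- a; prev_stim <- 2 * (s - 1) + a
  }
  ll
}
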