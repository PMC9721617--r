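test_that("reward walks stay inside the bouncing boundaries", {
  cfg <- task_config(n_trials = 200, seed = 1)
  for (s in 1:25) {
    w <- generate_reward_walk(cfg, seed = s)
    expect_gte(min(w$reward), -4)
    expect_lte(max(w$reward), 5)
    expect_gte(min(w$latent), -4)
    expect_lte(max(w$latent), 5)
  }
})

test_that("zero drift gives a constant walk and reflection follows x -> 2b - x", {
  cfg <- task_config(n_trials = 20, drift_levels = 0,
                     drift_schedule = rep(0, 20), seed = 1)
  w <- generate_reward_walk(cfg, seed = 5, start = 3)
  expect_identical(w$reward, rep(3L, 20))
  expect_equal(w$latent, rep(3, 20))
  # latent 4.6 plus increment +1.0 exceeds the bound: 5.6 -> 4.4, rounds to 4
  expect_equal(twostepRL:::reflect_into(4.6 + 1.0, -4, 5), 4.4)
  expect_equal(round(twostepRL:::reflect_into(5.6, -4, 5)), 4)
  # reflection is applied iteratively for large excursions:
  # 23.5 -> -13.5 -> 5.5 -> 4.5
  expect_equal(twostepRL:::reflect_into(23.5, -4, 5), 4.5)
})

test_that("transitions are deterministic, trial-invariant, and cover both planets", {
  cfg <- quick_config()
  expect_identical(resolve_transition(cfg, 1L, 1L), 1L)  # red
  expect_identical(resolve_transition(cfg, 1L, 2L), 2L)  # green
  for (s in 1:2)
    expect_setequal(resolve_transition(cfg, c(s, s), c(1L, 2L)), 1:2)
  expect_identical(resolve_transition(cfg, 2L, 1L),
                   resolve_transition(cfg, 2L, 1L))
  expect_error(resolve_transition(cfg, 3L, 1L), "first_state")
  expect_error(resolve_transition(cfg, 1L, 0L), "action")
  expect_error(task_config(transition_map = matrix(c(1L, 1L, 2L, 2L), 2,
                                                   byrow = TRUE)),
               "one action per planet")
})

test_that("simulate_session composes policies with the environment", {
  cfg <- quick_config(n_trials = 30)
  walks <- quick_walks(cfg)
  ses <- simulate_session(function(t, s, h) 1L, cfg, walks)
  expect_identical(nrow(ses), 30L)
  expect_identical(ses$planet,
                   unname(cfg$transition_map[cbind(ses$first_state, 1L)]))
  expect_identical(ses$reward,
                   ifelse(ses$planet == 1, walks$red$reward,
                          walks$green$reward))
  pol <- function(t, s, h) sample(1:2, 1)
  a <- simulate_session(pol, cfg, walks, seed = 9)
  b <- simulate_session(pol, cfg, walks, seed = 9)
  expect_identical(a, b)
})

test_that("a model-based agent out-earns a random agent on average", {
  cfg <- quick_config(n_trials = 80, seed = 2)
  gains <- vapply(1:40, function(s) {
    walks <- generate_walk_pair(cfg, seed = s)
    mb <- simulate_choices(m1_params(1, 0, 20), "M1", cfg, walks, seed = 1000 + s)
    rnd <- simulate_choices(m1_params(0.5, 0, 0), "M1", cfg, walks, seed = 2000 + s)
    sum(mb$reward) - sum(rnd$reward)
  }, 0)
  expect_gt(mean(gains), 0)
})

test_that("stay events compare planets, with prev_points from the earlier trial", {
  # three-trial vignette: -1 point then switch planet; 2 points then stay
  ses <- data.frame(subject_id = "s", session = 1L, trial = 1:3,
                    first_state = c(1L, 1L, 2L), action = c(1L, 2L, 2L),
                    stimulus_id = c(1L, 2L, 4L), planet = c(1L, 2L, 2L),
                    reward = c(-1L, 2L, 0L))
  ev <- code_stay_events(ses)
  expect_identical(nrow(ev), 2L)
  expect_identical(ev$stayed, c(FALSE, TRUE))
  expect_identical(ev$prev_points, c(-1L, 2L))
  expect_identical(ev$same_first_state, c(TRUE, FALSE))

  # an agent repeating the same planet every trial always stays
  cfg <- quick_config(n_trials = 25)
  walks <- quick_walks(cfg)
  always_red <- simulate_session(function(t, s, h)
    which(cfg$transition_map[s, ] == 1L), cfg, walks)
  expect_true(all(code_stay_events(always_red)$stayed))

  expect_identical(nrow(code_stay_events(ses[1, ])), 0L)
})

test_that("stay coding is invariant to stimulus relabelling that preserves planets", {
  cfg <- quick_config(n_trials = 50, seed = 4)
  walks <- quick_walks(cfg)
  ses <- simulate_choices(m1_params(0.5, 0.2, 1), "M1", cfg, walks, seed = 5)
  relab <- ses
  relab$action <- 3L - ses$action  # swap action slots ...
  tm2 <- cfg$transition_map[, 2:1] # ... and the map columns with them
  relab$planet <- tm2[cbind(relab$first_state, relab$action)]
  expect_identical(relab$planet, ses$planet)
  expect_identical(code_stay_events(relab), code_stay_events(ses))
})

test_that("points convert to Euros at 4 cents per point", {
  expect_identical(points_to_payout(0), 0)
  expect_identical(points_to_payout(100), 4)
  expect_identical(points_to_payout(-25), -1)
})

test_that("configuration errors are caught", {
  expect_error(task_config(reward_bounds = c(5, -4)), "lower < upper")
  expect_error(task_config(n_trials = 10, drift_schedule = rep(1, 5)),
               "length")
  expect_error(task_config(n_trials = 10, drift_schedule = rep(3, 10)),
               "drift_levels")
})
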