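test_that("the stay table bookkeeping matches the trial structure", {
  co <- generate_cohort(quick_spec(n_arm = 1L, n_trials = 200,
                                   seed = 41L))
  co$trials <- co$trials[co$trials$subject_id %in%
                           unique(co$trials$subject_id)[1:2], ]
  tab <- build_stay_table(co$trials)
  expect_identical(nrow(tab), 2L * 2L * 199L)
  expect_true(all(tab$trial_index >= 2))
  expect_true(all(tapply(tab$drug, tab$subject_id,
                         function(x) length(unique(x))) == 1))
  # an always-same-planet agent produces an all-ones stayed column
  cfg <- quick_config(n_trials = 20)
  walks <- quick_walks(cfg)
  ses <- simulate_session(function(t, s, h) which(cfg$transition_map[s, ] == 1L),
                          cfg, walks)
  ses$drug <- "placebo"; ses$serum_group <- NA_character_
  expect_true(all(build_stay_table(ses)$stayed == 1))
  expect_error(build_stay_table(transform(ses, drug = "aspirin")),
               "unknown drug")
})

test_that("odds ratios reproduce the printed log-odds pairings", {
  expect_equal(odds_ratio(0), 1)
  expect_equal(odds_ratio(0.402), 1.495, tolerance = 1e-3)
  expect_equal(odds_ratio(0.402 - 0.204), 1.219, tolerance = 1e-3)
})

test_that("state recoding is a linear reparameterization of the design", {
  tab <- logistic_stay_table(n_subj = 4L, n_per = 30L)
  W <- twostepRL:::within_design(tab)
  # recode different-state from {0,1} to {-1,1}: x* = 2x - 1. A coefficient
  # vector in the new coding reproduces identical linear predictors via the
  # standard reparameterization.
  sdf <- as.numeric(!tab$same_first_state)
  pts <- as.numeric(tab$prev_points); s2 <- as.numeric(tab$session == 2)
  x <- 2 * sdf - 1
  Wstar <- cbind(1, pts, x, s2, pts * x, pts * s2, x * s2, pts * x * s2)
  theta <- c(0.3, 0.4, -0.2, 0.1, -0.15, 0.05, 0.02, -0.01)
  # coefficients transform: effects of x* pick up factor 1/2 and shift the
  # lower-order terms by the same amount
  tstar <- c(theta[1] + theta[3] / 2, theta[2] + theta[5] / 2, theta[3] / 2,
             theta[4] + theta[7] / 2, theta[5] / 2, theta[6] + theta[8] / 2,
             theta[7] / 2, theta[8] / 2)
  expect_equal(drop(W %*% theta), drop(Wstar %*% tstar), tolerance = 1e-12)
})

test_that("an intercept-only pattern is recovered on a 60% stay table", {
  set.seed(7)
  tab <- logistic_stay_table(n_subj = 8L, n_per = 80L, slope = 0)
  tab$stayed <- rbinom(nrow(tab), 1, 0.6)
  fit <- suppressWarnings(
    fit_stay_glm(tab, chains = 1, iter = 500, warmup = 250, seed = 8))
  dr <- fit_draws(fit, "intercept")
  expect_lt(abs(mean(dr) - qlogis(0.6)), 3 * sd(dr) + 0.05)
})

test_that("a known previous-points slope is recovered", {
  tab <- logistic_stay_table(n_subj = 12L, n_per = 100L, slope = 0.4,
                             seed = 2)
  fit <- suppressWarnings(
    fit_stay_glm(tab, chains = 1, iter = 700, warmup = 300, seed = 9))
  dr <- fit_draws(fit, "prev_points")
  expect_lt(abs(mean(dr) - 0.4), 3 * sd(dr) + 0.05)
  s <- stay_glm_summary(fit)
  expect_equal(s$odds_ratio, exp(s$mean))
  int <- fit_draws(fit, "prev_points:prev_state_diff")
  expect_lt(abs(mean(int) - (-0.2)), 3 * sd(int) + 0.05)
})

test_that("permuting previous points within subjects nulls the slope", {
  hits <- 0L
  for (rep in 1:3) {
    tab <- logistic_stay_table(n_subj = 10L, n_per = 80L, slope = 0.4,
                               seed = 10 + rep, permute_points = TRUE)
    fit <- suppressWarnings(
      fit_stay_glm(tab, chains = 1, iter = 500, warmup = 250,
                   seed = 20 + rep))
    s <- stay_glm_summary(fit)
    row <- s[s$coefficient == "prev_points", ]
    hits <- hits + (row$ci_low <= 0 && 0 <= row$ci_high)
  }
  expect_gte(hits, 2L)
})

test_that("serum fits split the amisulpride dummy and drop unlabelled subjects", {
  tab <- logistic_stay_table(n_subj = 9L, n_per = 40L, seed = 5)
  ami <- unique(tab$subject_id[tab$drug == "amisulpride"])
  tab$serum_group[tab$subject_id == ami[1]] <- "high"
  tab$serum_group[tab$subject_id == ami[2]] <- "low"
  expect_message(
    fit <- suppressWarnings(
      fit_stay_glm(tab, chains = 1, iter = 150, warmup = 80, seed = 11,
                   serum = TRUE)),
    "without a serum label")
  expect_true(all(c("ami_low:prev_points", "ami_high:prev_points") %in%
                    fit$design$fixed))
  expect_false(any(grepl("^ami:", fit$design$fixed)))
})

test_that("random slopes link back to generative model parameters", {
  tab <- logistic_stay_table(n_subj = 14L, n_per = 80L, seed = 6)
  fit <- suppressWarnings(
    fit_stay_glm(tab, chains = 1, iter = 400, warmup = 200, seed = 12))
  params <- data.frame(subject_id = unique(tab$subject_id),
                       omega = seq(0.2, 0.8, length.out = 14),
                       gamma = runif(14), eta = runif(14, 0.5, 2))
  out <- link_slopes_to_params(fit, params)
  expect_false(out$degenerate)
  expect_identical(names(out$slope_same),
                   c("term", "estimate", "ci_low", "ci_high"))
  # zero-variance parameters are reported as degenerate, not estimated
  flat <- params; flat$omega <- 0.5; flat$gamma <- 0.5; flat$eta <- 1
  out2 <- link_slopes_to_params(fit, flat)
  expect_true(out2$degenerate)
  # narrow random effects cannot provide subject point slopes
  fitn <- suppressWarnings(
    fit_stay_glm(tab, chains = 1, iter = 150, warmup = 80, seed = 13,
                 random_effects = "narrow"))
  expect_error(link_slopes_to_params(fitn, params), "full")
  expect_error(fit_stay_glm(transform(tab, stayed = 1L)), "degenerate")
})
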