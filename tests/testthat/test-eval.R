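# minimal fit-shaped object for predictive computations with known latents
fake_fit <- function(latent_row, trials, model_id = "M1", S = 8L) {
  cd <- twostepRL:::cohort_data(trials)
  n <- nrow(cd$idx)
  K <- length(latent_row)
  lat <- array(rep(rep(latent_row, n), each = S), c(1, S, n * K))
  structure(list(model_id = model_id, draws = list(latents = lat),
                 subjects = cd$subjects,
                 data = list(fs = cd$fs, a = cd$a, pl = cd$pl, r = cd$r,
                             idx = cd$idx, trials = cd$trials,
                             transition_map = default_transition_map()),
                 options = list(chains = 1L)),
            class = "twostep_fit")
}

test_that("pointwise log-likelihoods sum to the session likelihood", {
  ses <- fixed_session(n = 5)
  ses$drug <- "placebo"; ses$serum_group <- NA_character_
  lat <- c(0.3, -0.2, 0.4, 0.1, 0, -0.1)
  fit <- fake_fit(lat, ses, S = 4L)
  ll <- pointwise_loglik(fit)
  expect_identical(dim(ll), c(4L, 5L))
  nat <- latents_to_native_sessions(lat, "M1")
  expect_equal(unname(rowSums(ll)),
               rep(session_loglik(nat[1, ], "M1", ses), 4), tolerance = 1e-8)
  expect_identical(nrow(attr(ll, "trials")), 5L)
})

test_that("a vanishing inverse temperature gives log(0.5) scores and chance accuracy", {
  cfg <- quick_config(n_trials = 200, seed = 55)
  ses <- simulate_choices(m1_params(0.5, 0.2, 0), "M1", cfg,
                          quick_walks(cfg, 56), seed = 57)  # random chooser
  ses$drug <- "placebo"; ses$serum_group <- NA_character_
  lat <- c(0, 0, -40, 0, 0, 0)  # eta = exp(-40)
  fit <- fake_fit(lat, ses)
  ll <- pointwise_loglik(fit)
  expect_equal(as.numeric(ll), rep(log(0.5), length(ll)), tolerance = 1e-6)
  # modal predictions of any value ordering hit random choices at ~50%
  acc <- posterior_predictive_accuracy(fit, n_draws = 8)
  expect_lt(abs(acc$accuracy - 0.5), 3 * 0.5 / sqrt(200))
})

test_that("a near-deterministic agent is predicted accurately by its own parameters", {
  cfg <- quick_config(n_trials = 150, seed = 51)
  walks <- quick_walks(cfg, 52)
  lat <- c(3, 0, log(25), 0, 0, 0)  # omega ~ 1, eta = 25
  nat <- latents_to_native_sessions(lat, "M1")
  ses <- simulate_choices(nat[1, ], "M1", cfg, walks, seed = 53)
  ses$drug <- "placebo"; ses$serum_group <- NA_character_
  fit <- fake_fit(lat, ses)
  acc <- posterior_predictive_accuracy(fit, n_draws = 8)
  expect_gt(acc$accuracy, 0.9)
  expect_true(all(acc$accuracy >= 0 & acc$accuracy <= 1))
})

test_that("PSIS-LOO matches the analytic Gaussian leave-one-out density", {
  # y_i ~ N(mu, 1), mu ~ N(0, 1): all posteriors are conjugate normals
  set.seed(8)
  n <- 400; S <- 4000
  y <- rnorm(n, 0.3, 1)
  post_var <- 1 / (n + 1); post_mean <- sum(y) * post_var
  mu_draws <- rnorm(S, post_mean, sqrt(post_var))
  log_lik <- vapply(y, function(yi) dnorm(yi, mu_draws, 1, log = TRUE),
                    numeric(S))
  loo <- psis_loo(log_lik)
  analytic <- sum(vapply(seq_len(n), function(i) {
    v <- 1 / (n - 1 + 1); m <- sum(y[-i]) * v
    dnorm(y[i], m, sqrt(v + 1), log = TRUE)
  }, 0))
  expect_lt(abs(loo$elpd - analytic), 2 * loo$se)
  expect_equal(loo$looic, -2 * loo$elpd, tolerance = 1e-10)
  expect_lt(max(loo$pareto_k), 0.7)
  expect_gt(loo$p_loo, 0)
})

test_that("model comparison identities and weights behave", {
  set.seed(9)
  ll <- matrix(rnorm(200 * 50, -1, 0.2), 200, 50)
  l1 <- psis_loo(ll)
  cmp <- loo_compare(list(a = l1, b = l1))
  expect_equal(cmp$delta_elpd, c(0, 0))
  expect_equal(cmp$looic, -2 * cmp$elpd)
  w <- pseudo_bma_weights(list(a = l1, b = l1), n_boot = 400, seed = 2)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(unname(w["a"]), 0.5, tolerance = 0.05)
  # a dominant model takes nearly all the weight
  l2 <- psis_loo(ll + 4)   # elpd difference = 50 * 4 = 200
  w2 <- pseudo_bma_weights(list(a = l1, b = l2), n_boot = 200, seed = 3)
  expect_gt(unname(w2["b"]), 0.99)
  cmp2 <- loo_compare(list(a = l1, b = l2))
  expect_identical(cmp2$model[1], "b")
  # weight order matches elpd order
  expect_identical(order(-c(w2["a"], w2["b"])), order(-c(l1$elpd, l2$elpd)))
  expect_error(loo_compare(list(a = l1, b = psis_loo(ll[, 1:10]))),
               "different trial sets")
})

test_that("posterior predictive checks mirror the fitted behaviour", {
  co <- generate_cohort(quick_spec(n_arm = 2L, n_trials = 60, seed = 61L))
  fit <- suppressWarnings(fit_hierarchical(co$trials, "M1", chains = 1,
                                           iter = 250, warmup = 100,
                                           seed = 62))
  ppc <- posterior_predictive_check(fit, seed = 63)
  expect_identical(sort(unique(ppc$synthetic_trials$subject_id)),
                   sort(fit$subjects$subject_id))
  expect_identical(nrow(ppc$synthetic_trials), nrow(co$trials))
  expect_true(all(c("stay_observed", "stay_synthetic") %in% names(ppc)))
  ppc2 <- posterior_predictive_check(fit, seed = 63)
  expect_identical(ppc$synthetic_trials, ppc2$synthetic_trials)
})
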