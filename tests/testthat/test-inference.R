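# A hand-assembled 2-subject, 3-trial cohort used by the density tests.
tiny_cohort <- function() {
  tm <- default_transition_map()
  mk <- function(id, drug, fs, a, r, sess) {
    data.frame(subject_id = id, session = sess, trial = seq_along(fs),
               first_state = fs, action = a,
               stimulus_id = 2L * (fs - 1L) + a,
               planet = tm[cbind(fs, a)], reward = r, drug = drug,
               serum_group = NA_character_)
  }
  rbind(mk("a", "placebo", c(1L, 2L, 1L), c(1L, 2L, 1L), c(3L, -1L, 2L), 1L),
        mk("a", "placebo", c(2L, 1L, 1L), c(1L, 1L, 2L), c(0L, 4L, -2L), 2L),
        mk("b", "amisulpride", c(1L, 1L, 2L), c(2L, 1L, 2L), c(1L, 1L, 5L), 1L),
        mk("b", "amisulpride", c(2L, 2L, 1L), c(2L, 1L, 1L), c(-3L, 2L, 0L), 2L))
}

tiny_group <- function() {
  R <- diag(6); R[1, 4] <- R[4, 1] <- 0.3
  list(mu = c(0.1, -0.2, 0.3, 0, 0.1, -0.1),
       sigma = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4), R = R,
       beta_ami = c(0.5, -0.2, 0.1), beta_nal = c(0, 0.3, 0))
}

test_that("joint density equals a term-by-term oracle", {
  cohort <- tiny_cohort()
  group <- tiny_group()
  lat <- rbind(c(0.2, -0.1, 0.4, 0.1, 0, -0.2),
               c(-0.3, 0.2, 0.1, 0.5, -0.1, 0.3))
  got <- joint_log_density(cohort, "M1", group, lat)

  # oracle: every term written out independently
  oracle <- sum(dnorm(group$mu, 0, 1, log = TRUE)) +
    sum(dnorm(group$sigma, 0, 1, log = TRUE) + log(2)) +
    sum(dnorm(c(group$beta_ami, group$beta_nal), 0, 1.5, log = TRUE))
  Lc <- t(chol(group$R))
  oracle <- oracle + sum((6 - (2:6) + 2) * log(diag(Lc)[2:6]))
  S <- diag(group$sigma) %*% group$R %*% diag(group$sigma)
  means <- list(group$mu,
                group$mu + c(0, 0, 0, group$beta_ami))
  tm <- default_transition_map()
  for (i in 1:2) {
    d <- lat[i, ] - means[[i]]
    oracle <- oracle - 0.5 * (drop(t(d) %*% solve(S) %*% d) +
                                log(det(S)) + 6 * log(2 * pi))
    id <- c("a", "b")[i]
    for (sess in 1:2) {
      ses <- cohort[cohort$subject_id == id & cohort$session == sess, ]
      base <- lat[i, 1:3]
      x <- if (sess == 1) base else base + lat[i, 4:6]
      pars <- list(omega = pnorm(x[1]), gamma = pnorm(x[2]), eta = exp(x[3]))
      oracle <- oracle + oracle_session_loglik("M1", pars, ses, tm)
    }
  }
  expect_equal(got, oracle, tolerance = 1e-8)
})

test_that("joint density is exchangeable under the null and decomposes by subject", {
  cohort <- tiny_cohort()
  group <- tiny_group()
  group$beta_ami <- c(0, 0, 0); group$beta_nal <- c(0, 0, 0)
  lat <- rbind(c(0.2, -0.1, 0.4, 0.1, 0, -0.2),
               c(-0.3, 0.2, 0.1, 0.5, -0.1, 0.3))
  swapped <- cohort
  swapped$drug <- ifelse(swapped$drug == "placebo", "amisulpride", "placebo")
  expect_equal(joint_log_density(cohort, "M1", group, lat),
               joint_log_density(swapped, "M1", group, lat))

  # removing subject b changes the density by exactly b's prior + likelihood
  full <- joint_log_density(cohort, "M1", group, lat)
  only_a <- joint_log_density(cohort[cohort$subject_id == "a", ], "M1",
                              group, lat[1, , drop = FALSE])
  S <- diag(group$sigma) %*% group$R %*% diag(group$sigma)
  d <- lat[2, ] - group$mu
  prior_b <- -0.5 * (drop(t(d) %*% solve(S) %*% d) + log(det(S)) +
                       6 * log(2 * pi))
  ll_b <- sum(vapply(1:2, function(sess) {
    ses <- cohort[cohort$subject_id == "b" & cohort$session == sess, ]
    x <- if (sess == 1) lat[2, 1:3] else lat[2, 1:3] + lat[2, 4:6]
    session_loglik(c(omega = pnorm(x[1]), gamma = pnorm(x[2]),
                     eta = exp(x[3])), "M1", ses)
  }, 0))
  expect_equal(full - only_a, prior_b + ll_b, tolerance = 1e-8)
})

test_that("with huge hyper-SDs the density tracks the likelihood", {
  cohort <- tiny_cohort()
  group <- tiny_group()
  group$sigma <- rep(1000, 6)
  lat <- matrix(0, 2, 6)
  lat2 <- lat; lat2[1, 1] <- 0.4
  ses_ll <- function(l) sum(vapply(1:2, function(sess) {
    ses <- cohort[cohort$subject_id == "a" & cohort$session == sess, ]
    x <- if (sess == 1) l[1:3] else l[1:3] + l[4:6]
    session_loglik(c(omega = pnorm(x[1]), gamma = pnorm(x[2]),
                     eta = exp(x[3])), "M1", ses)
  }, 0))
  d_joint <- joint_log_density(cohort, "M1", group, lat2) -
    joint_log_density(cohort, "M1", group, lat)
  d_ll <- ses_ll(lat2[1, ]) - ses_ll(lat[1, ])
  expect_equal(d_joint, d_ll, tolerance = 1e-4)
})

test_that("coefficient summaries and effect sizes follow their definitions", {
  s <- summarize_coefficient(rep(2, 2000), "c")
  expect_equal(s$mean, 2)
  expect_equal(c(s$ci_low, s$ci_high), c(2, 2))
  expect_equal(s$tail_prob, 0)
  set.seed(3)
  z <- rnorm(1e5)
  s2 <- summarize_coefficient(z, "z")
  expect_equal(s2$ci_low, -1.96, tolerance = 0.03)
  expect_equal(s2$ci_high, 1.96, tolerance = 0.03)
  expect_equal(s2$tail_prob, 0.5, tolerance = 0.01)
  s3 <- summarize_coefficient(z, "z", tail = "above_zero")
  expect_equal(s2$tail_prob + s3$tail_prob, 1, tolerance = 1e-12)
  expect_error(summarize_coefficient(numeric(0)), "draws")

  expect_equal(effect_size(0, 1, 1), 0)
  expect_equal(effect_size(0.787, 1, 1), 0.5565, tolerance = 1e-4)
  expect_error(effect_size(1, 0, 0), "positive")
})

test_that("the hierarchical fit runs, is seeded, and returns labelled draws", {
  co <- generate_cohort(quick_spec(n_arm = 2L, n_trials = 25, seed = 31L))
  f1 <- suppressWarnings(fit_hierarchical(co$trials, "M1", chains = 2,
                                          iter = 80, warmup = 40, seed = 5))
  f2 <- suppressWarnings(fit_hierarchical(co$trials, "M1", chains = 2,
                                          iter = 80, warmup = 40, seed = 5))
  expect_identical(f1$draws, f2$draws)
  expect_identical(dim(f1$draws$mu), c(2L, 40L, 6L))
  expect_identical(dim(f1$draws$beta)[3], 6L)
  expect_true(all(c("beta_ami_d_omega", "beta_nal_d_eta") %in%
                    dimnames(f1$draws$beta)[[3]]))
  expect_identical(nrow(f1$subjects), 6L)
  expect_true(all(is.finite(fit_draws(f1, "lp"))))
  expect_identical(dim(subject_latent_means(f1)), c(6L, 6L))
  expect_s3_class(drug_effect_summary(f1), "data.frame")
  # serum variant adds the high-serum regressor
  co2 <- generate_cohort(quick_spec(n_arm = 3L, n_trials = 25, seed = 32L,
                                    serum_high_n = 1L, serum_measured_n = 2L))
  f3 <- suppressWarnings(fit_hierarchical(co2$trials, "M1", chains = 1,
                                          iter = 60, warmup = 30, seed = 6,
                                          serum_covariate = TRUE))
  expect_true("beta_serum_d_omega" %in% dimnames(f3$draws$beta)[[3]])
  s <- drug_effect_summary(f3)
  expect_true(any(grepl("high_serum", s$coefficient)))
  expect_error(fit_hierarchical(co$trials, "M1", iter = 10, warmup = 20),
               "exceed")
})

test_that("convergence diagnostics behave on known chains", {
  set.seed(4)
  same <- matrix(rnorm(4000), 4, 1000)
  apart <- same + c(0, 0, 5, 5)
  expect_lt(split_rhat(same), 1.02)
  expect_gt(split_rhat(apart), 1.5)
  expect_gt(ess_basic(same), 2000)
  ar <- matrix(0, 2, 1000)
  for (t in 2:1000) ar[, t] <- 0.95 * ar[, t - 1] + rnorm(2) * 0.1
  expect_lt(ess_basic(ar), 500)
})
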