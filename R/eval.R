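#' Per-draw, per-trial log-likelihood matrix of a fit
#'
#' Recomputes, for each posterior draw of the subject latents, the log
#' probability of every observed choice. Column sums per draw reproduce the
#' likelihood term of the joint density for that draw.
#'
#' @param fit a `twostep_fit`.
#' @param max_draws optional cap on the number of draws (random subsample,
#'   seeded).
#' @param seed seed for the subsample.
#' @return draws x trials matrix with a `trials` attribute labelling the
#'   columns (subject_id, session, trial).
#' @export
pointwise_loglik <- function(fit, max_draws = NULL, seed = 1L) {
  info <- model_par_info(fit$model_id)
  p <- nrow(info)
  arr <- fit$draws$latents
  S <- dim(arr)[1] * dim(arr)[2]
  lat <- matrix(aperm(arr, c(2, 1, 3)), S, dim(arr)[3])
  if (!is.null(max_draws) && max_draws < S) {
    local_rng(seed)
    lat <- lat[sort(sample.int(S, max_draws)), , drop = FALSE]
  }
  ll <- cohort_pointwise_ll_cpp(model_code(fit$model_id), p,
                                kinds_int(fit$model_id), lat,
                                fit$data$fs, fit$data$a, fit$data$pl,
                                fit$data$r, fit$data$idx,
                                fit$data$transition_map)
  attr(ll, "trials") <- fit$data$trials[, c("subject_id", "session", "trial")]
  ll
}

# Generalized Pareto fit to tail exceedances (Zhang & Stephens 2009 style
# profile-posterior estimator with a weak prior pulling khat toward 0.5).
gpd_fit <- function(x) {
  x <- sort(x[x > 0])
  n <- length(x)
  if (n < 5) return(list(k = Inf, sigma = NA_real_))
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  theta <- theta[theta != 0]
  kj <- vapply(theta, function(th) -mean(log1p(-th * x)), 0)
  lj <- n * (log(theta / kj) + kj - 1)
  lj[!is.finite(lj)] <- -Inf
  w <- exp(lj - logsumexp(lj))
  theta_hat <- sum(theta * w)
  k <- -mean(log1p(-theta_hat * x))
  sigma <- k / theta_hat
  list(k = (k * n + 5) / (n + 10), sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

#' PSIS leave-one-out cross-validation
#'
#' Pareto-smoothed importance-sampling estimate of the expected log
#' pointwise predictive density (elpd) from a draws x observations
#' log-likelihood matrix, with the tail of each observation's importance
#' weights replaced by expected order statistics of a fitted generalized
#' Pareto distribution and truncated at the raw maximum. `looic = -2 * elpd`.
#'
#' @param log_lik draws x observations matrix of pointwise log-likelihoods.
#' @return object of class `twostep_loo`: `elpd`, `se`, `looic`, `p_loo`,
#'   `pointwise` (per-observation elpd), `pareto_k`, `n_high_k` (k > 0.7).
#' @export
psis_loo <- function(log_lik) {
  S <- nrow(log_lik); N <- ncol(log_lik)
  if (any(!is.finite(log_lik))) stop("log_lik must be finite")
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  elpd_i <- numeric(N); k_i <- numeric(N); lpd_i <- numeric(N)
  for (j in seq_len(N)) {
    ll <- log_lik[, j]
    lw <- -ll
    lw <- lw - max(lw)
    k_i[j] <- NA_real_
    if (S > 10 && M >= 5) {
      ord <- order(lw)
      tail_ids <- ord[(S - M + 1):S]
      cutoff <- exp(lw[ord[S - M]])
      exc <- exp(lw[tail_ids]) - cutoff
      g <- gpd_fit(exc)
      k_i[j] <- g$k
      if (is.finite(g$k) && is.finite(g$sigma) && g$sigma > 0) {
        q <- qgpd((seq_len(M) - 0.5) / M, g$k, g$sigma) + cutoff
        lw[tail_ids[order(lw[tail_ids])]] <- log(q)
        lw <- pmin(lw, 0)
      }
    }
    elpd_i[j] <- logsumexp(lw + ll) - logsumexp(lw)
    lpd_i[j] <- logsumexp(ll) - log(S)
  }
  structure(list(elpd = sum(elpd_i), se = sqrt(N * stats::var(elpd_i)),
                 looic = -2 * sum(elpd_i), p_loo = sum(lpd_i - elpd_i),
                 pointwise = elpd_i, pareto_k = k_i,
                 n_high_k = sum(k_i > 0.7, na.rm = TRUE), n_obs = N,
                 n_draws = S),
            class = "twostep_loo")
}

#' @export
print.twostep_loo <- function(x, ...) {
  cat("PSIS-LOO: elpd ", round(x$elpd, 1), " (se ", round(x$se, 1),
      "), looic ", round(x$looic, 1), ", p_loo ", round(x$p_loo, 1),
      "; ", x$n_high_k, "/", x$n_obs, " Pareto k > 0.7\n", sep = "")
  invisible(x)
}

#' Compare models by PSIS-LOO
#'
#' @param loos named list of [psis_loo()] results (or of log-likelihood
#'   matrices, which are passed through `psis_loo`) computed on identical
#'   trial sets.
#' @return data frame ordered best first: `model, elpd, se, looic, p_loo,
#'   delta_elpd, se_delta, n_high_k` (`delta_elpd` relative to the best
#'   model; `looic = -2 * elpd` by construction).
#' @export
loo_compare <- function(loos) {
  loos <- lapply(loos, function(x)
    if (inherits(x, "twostep_loo")) x else psis_loo(x))
  if (length(loos) < 1) stop("no models to compare")
  ns <- vapply(loos, function(x) x$n_obs, 0)
  if (length(unique(ns)) != 1) stop("models were evaluated on different trial sets")
  elpd <- vapply(loos, function(x) x$elpd, 0)
  best <- which.max(elpd)
  out <- data.frame(
    model = names(loos) %||% paste0("model", seq_along(loos)),
    elpd = elpd,
    se = vapply(loos, function(x) x$se, 0),
    looic = vapply(loos, function(x) x$looic, 0),
    p_loo = vapply(loos, function(x) x$p_loo, 0),
    delta_elpd = elpd - elpd[best],
    se_delta = vapply(seq_along(loos), function(m) {
      d <- loos[[m]]$pointwise - loos[[best]]$pointwise
      sqrt(length(d) * stats::var(d))
    }, 0),
    n_high_k = vapply(loos, function(x) x$n_high_k, 0))
  out <- out[order(-out$elpd), ]
  rownames(out) <- NULL
  out
}

#' Bootstrapped pseudo-BMA model weights
#'
#' Pseudo Bayesian model averaging: softmax of total elpd, stabilized by the
#' Bayesian bootstrap over observations (Dirichlet(1) weights), averaged
#' over bootstrap replicates.
#'
#' @param loos named list of [psis_loo()] results on identical trial sets.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return named numeric weights summing to 1.
#' @export
pseudo_bma_weights <- function(loos, n_boot = 1000L, seed = 1L) {
  loos <- lapply(loos, function(x)
    if (inherits(x, "twostep_loo")) x else psis_loo(x))
  if (length(loos) < 2) stop("need at least 2 models")
  ptw <- vapply(loos, function(x) x$pointwise, loos[[1]]$pointwise)
  N <- nrow(ptw); M <- ncol(ptw)
  local_rng(seed)
  wsum <- numeric(M)
  for (b in seq_len(n_boot)) {
    g <- stats::rexp(N)
    elpd_b <- N * as.numeric(crossprod(g / sum(g), ptw))
    wsum <- wsum + exp(elpd_b - logsumexp(elpd_b))
  }
  stats::setNames(wsum / n_boot,
                  names(loos) %||% paste0("model", seq_len(M)))
}

#' Posterior predictive choice accuracy per subject
#'
#' For each posterior draw and trial, the predicted choice is the modal
#' choice (argmax of the choice probability, exact ties credited 0.5);
#' accuracy is averaged over draws and trials within subject. The default
#' draw count follows the 4 x 2000 sampling scheme; fits with fewer stored
#' draws use all of them.
#'
#' @param fit a `twostep_fit`.
#' @param n_draws number of posterior draws to use (subsampled, seeded).
#' @param seed seed for the subsample.
#' @return data frame `subject_id, accuracy`.
#' @export
posterior_predictive_accuracy <- function(fit, n_draws = 8000L, seed = 1L) {
  info <- model_par_info(fit$model_id)
  arr <- fit$draws$latents
  S <- dim(arr)[1] * dim(arr)[2]
  lat <- matrix(aperm(arr, c(2, 1, 3)), S, dim(arr)[3])
  if (n_draws < S) {
    local_rng(seed)
    lat <- lat[sort(sample.int(S, n_draws)), , drop = FALSE]
  }
  acc <- pp_accuracy_cpp(model_code(fit$model_id), nrow(info),
                         kinds_int(fit$model_id), lat, fit$data$fs,
                         fit$data$a, fit$data$pl, fit$data$r, fit$data$idx,
                         fit$data$transition_map)
  data.frame(subject_id = fit$subjects$subject_id, accuracy = acc)
}

#' Simulate-and-refit parameter recovery
#'
#' Generates a cohort with known ground truth from `spec`, fits the model,
#' and scores recovery: Pearson correlation and bias between true and
#' posterior-mean subject latents per coordinate, coverage of the 95%
#' posterior intervals, and recovery of the group-level drug coefficients.
#'
#' @param spec a [cohort_spec()].
#' @param chains,iter,warmup,seed,sweeps sampler settings passed to
#'   [fit_hierarchical()].
#' @param serum_covariate passed to [fit_hierarchical()].
#' @return list with `per_parameter` (coordinate-wise r, bias, coverage),
#'   `beta` (true vs posterior-mean drug effects), `fit`, `cohort`.
#' @export
parameter_recovery <- function(spec, chains = 2L, iter = 1250L,
                               warmup = 500L, seed = 1L, sweeps = 2L,
                               serum_covariate = FALSE) {
  cohort <- generate_cohort(spec)
  fit <- fit_hierarchical(cohort$trials, spec$model_id, chains = chains,
                          iter = iter, warmup = warmup, seed = seed,
                          sweeps = sweeps, serum_covariate = serum_covariate)
  lat_nm <- latent_names(spec$model_id)
  truth <- cohort$ground_truth
  est <- subject_latent_means(fit)
  ord <- match(rownames(est), truth$subject_id)
  truth <- truth[ord, ]
  n <- nrow(est); K <- ncol(est)
  arr <- fit$draws$latents
  S <- dim(arr)[1] * dim(arr)[2]
  flat <- matrix(aperm(arr, c(2, 1, 3)), S, dim(arr)[3])
  per <- lapply(seq_len(K), function(k) {
    true_k <- truth[[lat_nm[k]]]
    cols <- (seq_len(n) - 1L) * K + k
    ci <- apply(flat[, cols, drop = FALSE], 2, stats::quantile,
                probs = c(0.025, 0.975))
    data.frame(parameter = lat_nm[k],
               r = stats::cor(true_k, est[, k]),
               bias = mean(est[, k] - true_k),
               coverage = mean(true_k >= ci[1, ] & true_k <= ci[2, ]))
  })
  info <- model_par_info(spec$model_id)
  beta_true <- c(stats::setNames(spec$beta_ami,
                                 paste0("beta_ami_d_", info$name)),
                 stats::setNames(spec$beta_nal,
                                 paste0("beta_nal_d_", info$name)))
  beta_nm <- dimnames(fit$draws$beta)[[3]]
  beta <- do.call(rbind, lapply(intersect(beta_nm, names(beta_true)),
    function(nm) {
      s <- summarize_coefficient(fit_draws(fit, nm), nm)
      s$true <- beta_true[[nm]]
      s$covered <- s$ci_low <= s$true & s$true <= s$ci_high
      s
    }))
  list(per_parameter = do.call(rbind, per), beta = beta, fit = fit,
       cohort = cohort)
}

#' Posterior predictive check of stay behaviour
#'
#' Simulates every subject at their posterior-mean native parameters (both
#' sessions, fresh reward walks with the task's default settings), recodes
#' stay behaviour on the synthetic cohort, and compares the empirical
#' stay-probability patterns; optionally refits the stay GLM on both cohorts
#' for a side-by-side coefficient table.
#'
#' @param fit a `twostep_fit`.
#' @param seed integer seed for the simulation.
#' @param refit_glm also fit the stay GLM on both cohorts.
#' @param glm_args options passed to [fit_stay_glm()] (defaults are a short
#'   sampler run).
#' @return list with `synthetic_trials`, `stay_observed`, `stay_synthetic`
#'   (empirical summaries) and, if requested, `glm_observed`,
#'   `glm_synthetic`, `coefficients` (side-by-side).
#' @export
posterior_predictive_check <- function(fit, seed = 1L, refit_glm = FALSE,
                                       glm_args = list(chains = 1L,
                                                       iter = 700L,
                                                       warmup = 300L)) {
  est <- subject_latent_means(fit)
  n <- nrow(est)
  sims <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    natives <- latents_to_native_sessions(est[i, ], fit$model_id)
    for (sess in 1:2) {
      n_tr <- fit$data$idx[i, 2 * sess]
      if (n_tr == 0) next
      cfg <- task_config(n_trials = n_tr,
                         transition_map = fit$data$transition_map,
                         seed = derive_seed(seed, 5L, i, sess))
      walks <- generate_walk_pair(cfg, seed = derive_seed(seed, 6L, i, sess))
      sims[[2L * (i - 1L) + sess]] <- simulate_choices(
        natives[sess, ], fit$model_id, cfg, walks,
        seed = derive_seed(seed, 7L, i, sess),
        subject_id = fit$subjects$subject_id[i], session_label = sess)
    }
  }
  synth <- do.call(rbind, sims)
  synth <- merge(synth, fit$subjects, by = "subject_id", sort = FALSE)
  obs_tab <- build_stay_table(fit$data$trials)
  syn_tab <- build_stay_table(synth)
  out <- list(synthetic_trials = synth,
              stay_observed = stay_probability_summary(obs_tab),
              stay_synthetic = stay_probability_summary(syn_tab))
  if (refit_glm) {
    fo <- do.call(fit_stay_glm, c(list(obs_tab, seed = seed), glm_args))
    fs <- do.call(fit_stay_glm, c(list(syn_tab, seed = seed + 1L), glm_args))
    so <- stay_glm_summary(fo); ss <- stay_glm_summary(fs)
    out$glm_observed <- fo
    out$glm_synthetic <- fs
    out$coefficients <- data.frame(coefficient = so$coefficient,
                                   observed = so$mean,
                                   synthetic = ss$mean[match(so$coefficient,
                                                             ss$coefficient)])
  }
  out
}
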