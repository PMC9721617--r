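#' @useDynLib twostepRL, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

planet_int <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  m <- match(as.character(x), planet_labels)
  if (anyNA(m)) stop("unknown planet label")
  m
}

#' Flatten a trial table into the compiled-sampler layout
#'
#' Orders trials by subject, session and trial and records 0-based
#' (start, length) offsets for each subject's two sessions. Subjects missing
#' a session contribute only the observed session's trials.
#' @keywords internal
cohort_data <- function(trials) {
  req <- c("subject_id", "session", "trial", "first_state", "action",
           "planet", "reward")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  trials <- trials[order(trials$subject_id, trials$session, trials$trial), ]
  ids <- unique(trials$subject_id)
  n <- length(ids)
  idx <- matrix(0L, n, 4)
  for (i in seq_len(n)) {
    for (sess in 1:2) {
      w <- which(trials$subject_id == ids[i] & trials$session == sess)
      idx[i, 2 * sess - 1] <- if (length(w)) w[1] - 1L else 0L
      idx[i, 2 * sess] <- length(w)
    }
  }
  subjects <- trials[match(ids, trials$subject_id),
                     intersect(c("subject_id", "drug", "serum_group"),
                               names(trials)), drop = FALSE]
  rownames(subjects) <- NULL
  list(fs = as.integer(trials$first_state), a = as.integer(trials$action),
       pl = planet_int(trials$planet), r = as.numeric(trials$reward),
       idx = idx, subjects = subjects, trials = trials)
}

kinds_int <- function(model_id) {
  match(model_par_info(model_id)$kind,
        c("unit_interval", "positive", "unbounded")) - 1L
}

drug_design <- function(subjects, serum_covariate) {
  if (is.null(subjects$drug)) stop("trial table has no drug column")
  bad <- setdiff(unique(subjects$drug),
                 c("placebo", "amisulpride", "naltrexone"))
  if (length(bad)) stop("unknown drug label: ", paste(bad, collapse = ", "))
  X <- cbind(ami = as.numeric(subjects$drug == "amisulpride"),
             nal = as.numeric(subjects$drug == "naltrexone"))
  if (serum_covariate) {
    if (is.null(subjects$serum_group)) stop("no serum_group column")
    X <- cbind(X, serum = as.numeric(!is.na(subjects$serum_group) &
                                       subjects$serum_group == "high"))
  }
  X
}

#' Joint log posterior density of the hierarchical model (reference)
#'
#' Plain-R reference implementation of the unnormalized joint density the
#' sampler targets: hyper-prior terms (means `N(0,1)`, SDs `HalfNormal(0,1)`,
#' correlation `LKJ(2)` up to its normalizing constant, drug coefficients
#' `N(0, 1.5)`), the multivariate-normal subject prior with arm-shifted
#' delta means, and the sequential choice likelihood of every observed
#' session.
#'
#' @param cohort trial table (or `twostep_cohort`) with drug labels.
#' @param model_id choice model.
#' @param group list with `mu`, `sigma`, `R`, `beta_ami`, `beta_nal` and
#'   optionally `beta_serum` (all in estimation space).
#' @param latents n x 2p matrix of subject latents, rows ordered by sorted
#'   subject id.
#' @param serum_covariate include the serum dummy term.
#' @param transition_map task transition map.
#' @return scalar log density.
#' @export
joint_log_density <- function(cohort, model_id, group, latents,
                              serum_covariate = FALSE,
                              transition_map = default_transition_map()) {
  if (inherits(cohort, "twostep_cohort")) cohort <- cohort$trials
  cd <- cohort_data(cohort)
  info <- model_par_info(model_id)
  p <- nrow(info); K <- 2L * p
  n <- nrow(cd$idx)
  if (!is.matrix(latents) || nrow(latents) != n || ncol(latents) != K)
    stop("latents must be an n x 2p matrix matching the cohort")
  X <- drug_design(cd$subjects, serum_covariate)
  betas <- rbind(group$beta_ami, group$beta_nal)
  if (serum_covariate) betas <- rbind(betas, group$beta_serum)
  stopifnot(length(group$mu) == K, length(group$sigma) == K,
            ncol(betas) == p)

  lp <- sum(stats::dnorm(group$mu, 0, 1, log = TRUE)) +
    sum(stats::dnorm(group$sigma, 0, 1, log = TRUE) + log(2)) +
    sum(stats::dnorm(as.numeric(betas), 0, 1.5, log = TRUE))
  Lc <- t(check_corr_matrix(group$R, K))  # lower Cholesky of R
  lp <- lp + sum((K - (2:K) + 2 * 2 - 2) * log(diag(Lc)[2:K]))  # LKJ(2)

  Lsig <- diag(group$sigma) %*% Lc
  logdet <- sum(log(diag(Lsig)))
  for (i in seq_len(n)) {
    m <- c(group$mu[seq_len(p)],
           group$mu[p + seq_len(p)] + as.numeric(X[i, ] %*% betas))
    z <- forwardsolve(Lsig, latents[i, ] - m)
    lp <- lp - 0.5 * sum(z^2) - logdet - K / 2 * log(2 * pi)
    natives <- latents_to_native_sessions(latents[i, ], model_id)
    for (sess in 1:2) {
      len <- cd$idx[i, 2 * sess]
      if (len == 0) next
      rows <- cd$idx[i, 2 * sess - 1] + seq_len(len)
      lp <- lp + session_loglik_cpp(
        model_code(model_id), unname(natives[sess, ]), cd$fs[rows],
        cd$a[rows], cd$pl[rows], cd$r[rows], transition_map)
    }
  }
  if (!is.finite(lp)) stop("non-finite joint log density")
  lp
}

#' Fit the joint two-session hierarchical model
#'
#' Estimates subject-level baseline and session-difference parameters (in
#' estimation space) together with group-level hyper-parameters and drug
#' effects on the session differences, by adaptive Metropolis-within-Gibbs
#' MCMC (see the package vignette for the sampler design). Defaults mirror
#' the estimation contract of the study design: 4 chains, 3000 iterations
#' with 1000 warmup, and a convergence criterion of split-Rhat < 1.01 for
#' all group-level quantities; a warning reports any quantity at or above
#' that threshold.
#'
#' @param cohort trial table in the standard schema (or a `twostep_cohort`).
#' @param model_id `"M1"`, `"M1_sticky"`, `"M2"` or `"M3"`.
#' @param chains number of independent chains.
#' @param iter total iterations per chain (including warmup).
#' @param warmup warmup (adaptation) iterations per chain.
#' @param seed integer seed; chain c uses a seed derived from it.
#' @param serum_covariate add a high-serum dummy regressor on the session
#'   differences (coded 1 for high serum, 0 otherwise).
#' @param stickiness with `model_id = "M1"`, fit the sticky variant.
#' @param sweeps subject-level update sweeps per iteration.
#' @param hyper_rounds hyper-parameter (SD/correlation) update rounds per
#'   iteration; these updates are cheap relative to the subject sweeps.
#' @param init_jitter SD of the random initialization of subject latents.
#' @param transition_map task transition map.
#' @return object of class `twostep_fit`.
#' @export
fit_hierarchical <- function(cohort, model_id = "M1", chains = 4L,
                             iter = 3000L, warmup = 1000L, seed = 1L,
                             serum_covariate = FALSE, stickiness = FALSE,
                             sweeps = 2L, hyper_rounds = 3L,
                             init_jitter = 0.5,
                             transition_map = default_transition_map()) {
  if (inherits(cohort, "twostep_cohort")) cohort <- cohort$trials
  if (stickiness && model_id == "M1") model_id <- "M1_sticky"
  cd <- cohort_data(cohort)
  info <- model_par_info(model_id)
  p <- nrow(info); K <- 2L * p
  n <- nrow(cd$idx)
  X <- drug_design(cd$subjects, serum_covariate)
  present <- table(cd$subjects$drug)
  if (any(present < 2))
    stop("at least 2 subjects per present arm are required")
  if (iter <= warmup) stop("iter must exceed warmup")

  lat_names <- latent_names(model_id)
  groups <- colnames(X)
  beta_names <- as.vector(vapply(groups, function(g)
    paste0("beta_", g, "_d_", info$name), character(p)))
  S <- iter - warmup
  ny <- K * (K - 1) / 2
  corr_names <- outer(lat_names, lat_names, function(a, b) paste0("R[", a, ",", b, "]"))
  corr_names <- corr_names[lower.tri(corr_names)]

  blocks <- list(mu = paste0("mu_", lat_names),
                 sigma = paste0("sigma_", lat_names),
                 beta = beta_names, corr = corr_names)
  draws <- lapply(blocks, function(nm)
    array(NA_real_, c(chains, S, length(nm)),
          dimnames = list(NULL, NULL, nm)))
  draws$latents <- array(NA_real_, c(chains, S, n * K),
                         dimnames = list(NULL, NULL,
                                         paste(rep(cd$subjects$subject_id, each = K),
                                               rep(lat_names, n), sep = ".")))
  draws$lp <- array(NA_real_, c(chains, S, 1),
                    dimnames = list(NULL, NULL, "lp"))
  accept <- matrix(NA_real_, chains, 2,
                   dimnames = list(NULL, c("latents", "hyper")))

  for (ch in seq_len(chains)) {
    local_rng(derive_seed(seed, 100L, ch))
    res <- fit_hier_chain_cpp(model_code(model_id), p, kinds_int(model_id),
                              cd$fs, cd$a, cd$pl, cd$r, cd$idx, X,
                              transition_map, as.integer(iter),
                              as.integer(warmup), as.integer(sweeps),
                              as.integer(hyper_rounds), init_jitter)
    draws$mu[ch, , ] <- res$mu
    draws$sigma[ch, , ] <- res$sigma
    draws$beta[ch, , ] <- res$beta
    draws$corr[ch, , ] <- res$corr
    draws$latents[ch, , ] <- res$latents
    draws$lp[ch, , 1] <- res$lp
    accept[ch, ] <- c(res$accept_latents, res$accept_hyper)
  }

  diag_tab <- diagnostics_table(draws[c("mu", "sigma", "beta", "lp")])
  bad <- diag_tab$quantity[!is.na(diag_tab$rhat) & diag_tab$rhat >= 1.01]
  if (chains > 1 && length(bad))
    warning("Rhat >= 1.01 for: ", paste(bad, collapse = ", "),
            call. = FALSE)

  structure(
    list(model_id = model_id, draws = draws, subjects = cd$subjects,
         data = list(fs = cd$fs, a = cd$a, pl = cd$pl, r = cd$r,
                     idx = cd$idx, X = X, trials = cd$trials,
                     transition_map = transition_map),
         options = list(chains = chains, iter = iter, warmup = warmup,
                        seed = seed, sweeps = sweeps,
                        hyper_rounds = hyper_rounds,
                        serum_covariate = serum_covariate),
         diagnostics = diag_tab, accept = accept),
    class = "twostep_fit")
}

#' Extract draws of one named quantity from a fit
#'
#' @param fit a `twostep_fit` (or `twostep_stay_fit`).
#' @param name quantity name as listed in `fit$diagnostics` /
#'   the draws dimnames.
#' @return numeric vector of draws pooled over chains.
#' @export
fit_draws <- function(fit, name) {
  for (block in names(fit$draws)) {
    nm <- dimnames(fit$draws[[block]])[[3]]
    j <- match(name, nm)
    if (!is.na(j)) return(as.numeric(fit$draws[[block]][, , j]))
  }
  stop("unknown quantity: ", name)
}

#' Posterior means of subject latent vectors
#'
#' @param fit a `twostep_fit`.
#' @return n x 2p matrix (subjects x latent coordinates).
#' @export
subject_latent_means <- function(fit) {
  K <- dim(fit$draws$mu)[3]
  n <- nrow(fit$subjects)
  flat <- apply(fit$draws$latents, 3, mean)
  out <- matrix(flat, n, K, byrow = TRUE,
                dimnames = list(fit$subjects$subject_id,
                                sub("^[^.]*\\.", "", dimnames(fit$draws$latents)[[3]][seq_len(K)])))
  out
}

#' Standardized effect size of a drug coefficient
#'
#' `d = beta / sqrt(sigma_baseline^2 + sigma_delta^2)`, computed draw by
#' draw: the group-mean shift is normalized by the pooled SD of the relevant
#' variance components (baseline and session difference).
#'
#' @param beta_draws draws of the coefficient.
#' @param sigma_baseline_draws,sigma_delta_draws aligned draws of the two
#'   hyper-SDs.
#' @return vector of effect-size draws.
#' @export
effect_size <- function(beta_draws, sigma_baseline_draws, sigma_delta_draws) {
  pooled <- sqrt(sigma_baseline_draws^2 + sigma_delta_draws^2)
  if (any(pooled <= 0)) stop("pooled SD must be positive")
  beta_draws / pooled
}

#' Summarize a posterior coefficient
#'
#' Posterior mean, central 95% credible interval and the requested tail
#' probability (posterior mass below or above zero).
#'
#' @param draws numeric vector of posterior draws.
#' @param name coefficient label.
#' @param tail `"below_zero"` or `"above_zero"`.
#' @return one-row data frame `coefficient, mean, ci_low, ci_high,
#'   tail_prob, tail`.
#' @export
summarize_coefficient <- function(draws, name = "coef",
                                  tail = c("below_zero", "above_zero")) {
  tail <- match.arg(tail)
  if (!length(draws)) stop("no draws supplied")
  ci <- unname(stats::quantile(draws, c(0.025, 0.975)))
  data.frame(coefficient = name, mean = mean(draws),
             ci_low = ci[1], ci_high = ci[2],
             tail_prob = if (tail == "below_zero") mean(draws < 0)
                         else mean(draws > 0),
             tail = tail)
}

#' Drug-effect summary table with effect sizes
#'
#' One row per drug coefficient: posterior mean, 95% CI, P(beta < 0), and
#' the standardized effect size `d` (with its CI) using the matching
#' baseline and session-difference hyper-SDs. With a serum covariate, adds
#' the low-serum (`beta_ami`) and high-serum (`beta_ami + beta_serum`)
#' amisulpride contrasts.
#'
#' @param fit a `twostep_fit`.
#' @return data frame of coefficient summaries.
#' @export
drug_effect_summary <- function(fit) {
  info <- model_par_info(fit$model_id)
  beta_nm <- dimnames(fit$draws$beta)[[3]]
  rows <- list()
  add_row <- function(draws, label, par) {
    s <- summarize_coefficient(draws, label)
    d <- effect_size(draws, fit_draws(fit, paste0("sigma_", par, "0")),
                     fit_draws(fit, paste0("sigma_d_", par)))
    dci <- unname(stats::quantile(d, c(0.025, 0.975)))
    s$d_mean <- mean(d); s$d_ci_low <- dci[1]; s$d_ci_high <- dci[2]
    rows[[length(rows) + 1L]] <<- s
  }
  for (nm in beta_nm) {
    par <- sub("^beta_[^_]+_d_", "", nm)
    add_row(fit_draws(fit, nm), nm, par)
  }
  if (fit$options$serum_covariate) {
    for (par in info$name) {
      ami <- fit_draws(fit, paste0("beta_ami_d_", par))
      ser <- fit_draws(fit, paste0("beta_serum_d_", par))
      add_row(ami, paste0("beta_ami_low_serum_d_", par), par)
      add_row(ami + ser, paste0("beta_ami_high_serum_d_", par), par)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.twostep_fit <- function(x, ...) {
  cat("Hierarchical two-step fit (", x$model_id, "): ",
      nrow(x$subjects), " subjects, ", x$options$chains, " chains x ",
      x$options$iter - x$options$warmup, " draws\n", sep = "")
  bad <- x$diagnostics$quantity[!is.na(x$diagnostics$rhat) &
                                  x$diagnostics$rhat >= 1.01]
  if (x$options$chains > 1)
    cat("max Rhat (group-level): ",
        round(max(x$diagnostics$rhat, na.rm = TRUE), 4),
        if (length(bad)) " [NOT CONVERGED]" else "", "\n", sep = "")
  print(utils::head(drug_effect_summary(x), 12))
  invisible(x)
}

#' @export
summary.twostep_fit <- function(object, ...) {
  drug_effect_summary(object)
}
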