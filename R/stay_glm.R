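#' Build the stay-behaviour table from a cohort
#'
#' One row per trial from the second of each subject-session onwards,
#' coding whether the subject stayed with the previous choice (same target
#' planet), the points received on the previous trial, and whether the
#' first-stage state repeated.
#'
#' @param cohort trial table in the standard schema or a `twostep_cohort`.
#' @return data frame of class `twostep_stay_table`: `subject_id, session,
#'   trial_index, prev_points, same_first_state, stayed, drug, serum_group`.
#' @export
build_stay_table <- function(cohort) {
  if (inherits(cohort, "twostep_cohort")) cohort <- cohort$trials
  if (!is.null(cohort$drug)) {
    bad <- setdiff(unique(cohort$drug),
                   c("placebo", "amisulpride", "naltrexone"))
    if (length(bad)) stop("unknown drug label: ", paste(bad, collapse = ", "))
  }
  cohort <- cohort[order(cohort$subject_id, cohort$session, cohort$trial), ]
  pieces <- list()
  for (id in unique(cohort$subject_id)) {
    for (sess in unique(cohort$session[cohort$subject_id == id])) {
      s <- cohort[cohort$subject_id == id & cohort$session == sess, ]
      ev <- code_stay_events(s)
      if (!nrow(ev)) next
      ev$subject_id <- id
      ev$session <- sess
      ev$drug <- if (!is.null(s$drug)) s$drug[1] else NA_character_
      ev$serum_group <- if (!is.null(s$serum_group)) s$serum_group[1]
                        else NA_character_
      pieces[[length(pieces) + 1L]] <- ev
    }
  }
  out <- do.call(rbind, pieces)
  out <- out[, c("subject_id", "session", "trial_index", "prev_points",
                 "same_first_state", "stayed", "drug", "serum_group")]
  rownames(out) <- NULL
  class(out) <- c("twostep_stay_table", "data.frame")
  out
}

#' Priors of the stay-behaviour hierarchical logistic regression
#'
#' Defaults: random-effect SDs Half-Cauchy(0, 2), slopes Normal(0, 3),
#' intercept Student-t(3, 0, 10), correlation LKJ(2).
#'
#' @param sd_scale half-Cauchy scale of the random-effect SDs.
#' @param slope_sd normal SD of the population slopes.
#' @param intercept_scale,intercept_df Student-t scale and df of the
#'   population intercept.
#' @param lkj_eta LKJ shape of the random-effect correlation matrix.
#' @return named list of prior settings.
#' @export
glm_priors <- function(sd_scale = 2, slope_sd = 3, intercept_scale = 10,
                       intercept_df = 3, lkj_eta = 2) {
  stopifnot(sd_scale > 0, slope_sd > 0, intercept_scale > 0,
            intercept_df > 0, lkj_eta > 0)
  list(sd_scale = sd_scale, slope_sd = slope_sd,
       intercept_scale = intercept_scale, intercept_df = intercept_df,
       lkj_eta = lkj_eta)
}

within_design <- function(tab) {
  pts <- as.numeric(tab$prev_points)
  sdf <- as.numeric(!tab$same_first_state)  # 1 = different first-stage state
  s2 <- as.numeric(tab$session == 2)
  W <- cbind(intercept = 1, prev_points = pts, prev_state_diff = sdf,
             session2 = s2,
             `prev_points:prev_state_diff` = pts * sdf,
             `prev_points:session2` = pts * s2,
             `prev_state_diff:session2` = sdf * s2,
             `prev_points:prev_state_diff:session2` = pts * sdf * s2)
  W
}

#' Fit the hierarchical logistic regression of stay behaviour
#'
#' Bernoulli-logit model of staying with the previous choice as a function
#' of previous points, previous first-stage state (different vs same),
#' session, drug arm, and all their interactions. The within-subject design
#' (intercept, session, previous state, previous points and their
#' interactions) enters as correlated subject-level random effects
#' (`random_effects = "full"`); `"narrow"` restricts the random effects to
#' the intercept and the previous-state and session slopes. Drug terms are
#' population-level only (between-subject factor), coded against the placebo
#' reference. With `serum = TRUE`, the amisulpride dummy is split at the
#' serum dichotomization into low/high effective-dose dummies; amisulpride
#' subjects without a serum label are dropped with a message.
#'
#' With this coding, the population `prev_points` coefficient is the
#' log-odds of staying per additional previous point in same-state trials of
#' session 1 in the placebo arm, and `prev_points:prev_state_diff` is the
#' different-vs-same reduction of that slope.
#'
#' @param tab a stay table from [build_stay_table()].
#' @param priors a [glm_priors()] list.
#' @param chains,iter,warmup,seed,sweeps sampler settings (see
#'   [fit_hierarchical()]).
#' @param serum split the amisulpride dummy into low/high serum.
#' @param theta_rounds population-coefficient update rounds per sweep.
#' @param random_effects `"full"` or `"narrow"`.
#' @return object of class `twostep_stay_fit`.
#' @export
fit_stay_glm <- function(tab, priors = glm_priors(), chains = 4L,
                         iter = 3000L, warmup = 1000L, seed = 1L,
                         serum = FALSE, random_effects = c("full", "narrow"),
                         sweeps = 1L, theta_rounds = 3L) {
  random_effects <- match.arg(random_effects)
  if (serum) {
    drop <- tab$drug == "amisulpride" & (is.na(tab$serum_group) |
                                           !tab$serum_group %in% c("low", "high"))
    if (any(drop)) {
      message("dropping ", length(unique(tab$subject_id[drop])),
              " amisulpride subject(s) without a serum label")
      tab <- tab[!drop, ]
    }
  }
  if (length(unique(tab$stayed)) < 2)
    stop("degenerate outcome: only one stay class present")
  tab <- tab[order(tab$subject_id, tab$session, tab$trial_index), ]
  W <- within_design(tab)
  dummies <- if (serum) {
    cbind(ami_low = as.numeric(tab$drug == "amisulpride" &
                                 tab$serum_group == "low"),
          ami_high = as.numeric(tab$drug == "amisulpride" &
                                  tab$serum_group == "high"),
          nal = as.numeric(tab$drug == "naltrexone"))
  } else {
    cbind(ami = as.numeric(tab$drug == "amisulpride"),
          nal = as.numeric(tab$drug == "naltrexone"))
  }
  Fmat <- W
  for (g in colnames(dummies)) {
    block <- W * dummies[, g]
    colnames(block) <- paste0(g, ":", colnames(W))
    Fmat <- cbind(Fmat, block)
  }
  degenerate <- setdiff(
    colnames(Fmat)[apply(Fmat, 2, function(x) stats::sd(x) == 0)],
    "intercept")
  if (length(degenerate))
    warning("constant predictor column(s): ",
            paste(degenerate, collapse = ", "), call. = FALSE)
  Wre <- if (random_effects == "full") W
         else W[, c("intercept", "prev_state_diff", "session2")]

  ids <- unique(tab$subject_id)
  bounds <- c(0L, cumsum(as.integer(table(factor(tab$subject_id, levels = ids)))))
  # recentering-move bookkeeping: each fixed column's partner random-effect
  # column (within-subject part of the column name) and the subjects whose
  # arm the column applies to
  re_of_fixed <- function(fx) {
    base <- sub("^(ami_low|ami_high|ami|nal):", "", fx)
    m <- match(base, colnames(W))
    if (random_effects == "narrow")
      m <- match(base, c("intercept", "prev_state_diff", "session2"))
    ifelse(is.na(m), -1L, m - 1L)
  }
  subj_dummy <- rowsum(dummies, tab$subject_id, reorder = FALSE) > 0
  member <- matrix(1L, length(ids), ncol(Fmat))
  for (j in seq_len(ncol(Fmat))) {
    g <- sub(":.*$", "", colnames(Fmat)[j])
    if (g %in% colnames(dummies)) member[, j] <- as.integer(subj_dummy[, g])
  }
  qf <- ncol(Fmat); Kre <- ncol(Wre)
  S <- iter - warmup
  re_names <- colnames(Wre)
  corr_names <- outer(re_names, re_names, function(a, b) paste0("R[", a, ",", b, "]"))
  corr_names <- corr_names[lower.tri(corr_names)]

  draws <- list(
    theta = array(NA_real_, c(chains, S, qf),
                  dimnames = list(NULL, NULL, colnames(Fmat))),
    sigma = array(NA_real_, c(chains, S, Kre),
                  dimnames = list(NULL, NULL, paste0("sigma_", re_names))),
    corr = array(NA_real_, c(chains, S, length(corr_names)),
                 dimnames = list(NULL, NULL, corr_names)),
    b = array(NA_real_, c(chains, S, length(ids) * Kre),
              dimnames = list(NULL, NULL,
                              paste(rep(ids, each = Kre),
                                    rep(re_names, length(ids)), sep = "."))),
    lp = array(NA_real_, c(chains, S, 1), dimnames = list(NULL, NULL, "lp")))
  accept <- numeric(chains)
  pr <- c(priors$slope_sd, priors$intercept_scale, priors$intercept_df,
          priors$sd_scale, priors$lkj_eta)

  for (ch in seq_len(chains)) {
    local_rng(derive_seed(seed, 200L, ch))
    res <- fit_stay_glm_cpp(as.integer(tab$stayed), Fmat, Wre,
                            as.integer(bounds),
                            match("intercept", colnames(Fmat)) - 1L, pr,
                            as.integer(iter), as.integer(warmup),
                            as.integer(sweeps), as.integer(theta_rounds),
                            vapply(colnames(Fmat), re_of_fixed, 1L), member)
    draws$theta[ch, , ] <- res$theta
    draws$sigma[ch, , ] <- res$sigma
    draws$corr[ch, , ] <- res$corr
    draws$b[ch, , ] <- res$b
    draws$lp[ch, , 1] <- res$lp
    accept[ch] <- res$accept
  }

  diag_tab <- diagnostics_table(draws[c("theta", "sigma", "lp")])
  bad <- diag_tab$quantity[!is.na(diag_tab$rhat) & diag_tab$rhat >= 1.01]
  if (chains > 1 && length(bad))
    warning("Rhat >= 1.01 for: ", paste(bad, collapse = ", "), call. = FALSE)

  structure(
    list(draws = draws, subjects = data.frame(
           subject_id = ids,
           drug = tab$drug[match(ids, tab$subject_id)],
           serum_group = tab$serum_group[match(ids, tab$subject_id)]),
         design = list(fixed = colnames(Fmat), re = re_names,
                       random_effects = random_effects, serum = serum),
         priors = priors, table = tab,
         options = list(chains = chains, iter = iter, warmup = warmup,
                        seed = seed),
         diagnostics = diag_tab, accept = accept),
    class = c("twostep_stay_fit", "twostep_fit"))
}

#' Posterior coefficient table of a stay-GLM fit (log-odds scale)
#'
#' @param fit a `twostep_stay_fit`.
#' @return data frame with one row per population coefficient: posterior
#'   mean, 95% CI, P(beta < 0) and the odds ratio `exp(mean)`.
#' @export
stay_glm_summary <- function(fit) {
  nm <- dimnames(fit$draws$theta)[[3]]
  out <- do.call(rbind, lapply(nm, function(x)
    summarize_coefficient(fit_draws(fit, x), x)))
  out$odds_ratio <- odds_ratio(out$mean)
  rownames(out) <- NULL
  out
}

#' Odds multiplier implied by a log-odds coefficient
#'
#' @param log_odds coefficient(s) on the log-odds scale.
#' @return `exp(log_odds)`.
#' @export
odds_ratio <- function(log_odds) exp(log_odds)

#' Empirical stay probabilities by previous points
#'
#' Display summary of a stay table: mean stay proportion by previous points
#' (optionally binned), previous-state type and session. Binning is for
#' plotting only and never feeds a likelihood.
#'
#' @param tab a stay table.
#' @param bins number of previous-point bins (`NULL` = one per point value).
#' @return aggregated data frame.
#' @export
stay_probability_summary <- function(tab, bins = NULL) {
  pts <- tab$prev_points
  if (!is.null(bins)) {
    br <- stats::quantile(pts, probs = seq(0, 1, length.out = bins + 1))
    pts <- as.numeric(sub(".*,", "", gsub("[][()]", "",
      cut(pts, unique(br), include.lowest = TRUE))))
  }
  agg <- stats::aggregate(
    list(stay_prob = tab$stayed),
    by = list(prev_points = pts,
              prev_state = ifelse(tab$same_first_state, "same", "different"),
              session = tab$session),
    FUN = mean)
  agg$n <- stats::aggregate(list(n = tab$stayed),
                            by = list(prev_points = pts,
                                      prev_state = ifelse(tab$same_first_state,
                                                          "same", "different"),
                                      session = tab$session),
                            FUN = length)$n
  agg
}

#' Subject-level session-2 stay slopes from a fitted stay GLM
#'
#' Posterior-mean subject-specific slopes of previous points in session 2:
#' the same-state slope and the different-vs-same interaction slope,
#' combining the population terms (including the subject's drug terms) with
#' the subject's random effects. Requires the full random-effects structure.
#' @keywords internal
subject_stay_slopes <- function(fit) {
  if (fit$design$random_effects != "full")
    stop("subject-level point slopes require random_effects = 'full'")
  th <- apply(fit$draws$theta, 3, mean)
  names(th) <- dimnames(fit$draws$theta)[[3]]
  Kre <- length(fit$design$re)
  n <- nrow(fit$subjects)
  bmean <- matrix(apply(fit$draws$b, 3, mean), n, Kre, byrow = TRUE,
                  dimnames = list(fit$subjects$subject_id, fit$design$re))
  gterm <- function(g, base) {
    nmx <- paste0(g, ":", base)
    if (nmx %in% names(th)) th[[nmx]] else 0
  }
  dummies <- if (fit$design$serum)
    cbind(ami_low = fit$subjects$drug == "amisulpride" &
            !is.na(fit$subjects$serum_group) & fit$subjects$serum_group == "low",
          ami_high = fit$subjects$drug == "amisulpride" &
            !is.na(fit$subjects$serum_group) & fit$subjects$serum_group == "high",
          nal = fit$subjects$drug == "naltrexone")
  else cbind(ami = fit$subjects$drug == "amisulpride",
             nal = fit$subjects$drug == "naltrexone")
  same <- th[["prev_points"]] + th[["prev_points:session2"]] +
    bmean[, "prev_points"] + bmean[, "prev_points:session2"]
  diffint <- th[["prev_points:prev_state_diff"]] +
    th[["prev_points:prev_state_diff:session2"]] +
    bmean[, "prev_points:prev_state_diff"] +
    bmean[, "prev_points:prev_state_diff:session2"]
  for (g in colnames(dummies)) {
    same <- same + dummies[, g] *
      (gterm(g, "prev_points") + gterm(g, "prev_points:session2"))
    diffint <- diffint + dummies[, g] *
      (gterm(g, "prev_points:prev_state_diff") +
         gterm(g, "prev_points:prev_state_diff:session2"))
  }
  data.frame(subject_id = fit$subjects$subject_id,
             slope_same = unname(same), slope_diff_vs_same = unname(diffint))
}

#' Relate stay-regression slopes to computational-model parameters
#'
#' Extracts each subject's posterior-mean session-2 random slopes (previous
#' points in same-state trials, and the different-vs-same interaction),
#' standardizes the slopes and the supplied model parameters, and fits two
#' linear models predicting each slope from the parameters.
#'
#' @param fit a `twostep_stay_fit` with full random effects.
#' @param params data frame with `subject_id` and one numeric column per
#'   model parameter (typically the session-2 native parameters).
#' @return list with `slope_same` and `slope_diff_vs_same` coefficient
#'   tables (standardized estimates with 95% confidence intervals), or a
#'   degeneracy report when a predictor has (near-)zero variance.
#' @export
link_slopes_to_params <- function(fit, params) {
  slopes <- subject_stay_slopes(fit)
  if (!all(slopes$subject_id %in% params$subject_id))
    stop("params must cover every subject in the fit")
  params <- params[match(slopes$subject_id, params$subject_id), ]
  pcols <- setdiff(names(params), "subject_id")
  pcols <- pcols[vapply(params[pcols], is.numeric, TRUE)]
  sds <- vapply(params[pcols], stats::sd, 0)
  if (any(!is.finite(sds)) || any(sds < 1e-10))
    return(list(degenerate = TRUE,
                message = paste("zero-variance predictor(s):",
                                paste(pcols[sds < 1e-10], collapse = ", "))))
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  Z <- data.frame(lapply(params[pcols], zs))
  one <- function(y) {
    if (stats::sd(y) < 1e-12)
      return(data.frame(term = pcols, estimate = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_))
    m <- stats::lm(zs(y) ~ ., data = Z)
    ci <- stats::confint(m)
    data.frame(term = rownames(ci), estimate = stats::coef(m),
               ci_low = ci[, 1], ci_high = ci[, 2], row.names = NULL)
  }
  list(slope_same = one(slopes$slope_same),
       slope_diff_vs_same = one(slopes$slope_diff_vs_same),
       degenerate = FALSE)
}
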