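#' Specification of a synthetic study cohort
#'
#' Defines the generative hierarchical structure of a synthetic cohort:
#' subjects per treatment arm, hyper-means and hyper-SDs of the
#' estimation-space latent vector `(baseline', delta')`, their correlation
#' matrix, drug effects on the session differences, and the task settings.
#' Subject latents are drawn from `MVN(mu_arm, S)` with
#' `S = diag(sigma) R diag(sigma)` and `mu_arm` equal to `mu` with the arm's
#' drug effect added to the delta components.
#'
#' The numeric defaults are synthetic study conditions, loosely calibrated
#' to the scale of effects reported for this task family; they are not
#' estimates (see the package vignette).
#'
#' @param model_id generative choice model, see [model_par_info()].
#' @param n_per_arm named integer vector of subjects per arm
#'   (`placebo`, `amisulpride`, `naltrexone`); arms with 0 subjects are
#'   allowed.
#' @param mu hyper-means, named length `2p` (baselines then deltas); `NULL`
#'   uses the model's defaults.
#' @param sigma positive hyper-SDs, length `2p`.
#' @param R correlation matrix, `2p x 2p`, symmetric positive-definite with
#'   unit diagonal.
#' @param beta_ami,beta_nal numeric length-`p` drug effects added to the
#'   delta-component means for the respective arm (zero default).
#' @param serum_high_n,serum_measured_n serum dichotomization within the
#'   amisulpride arm: `serum_measured_n` subjects get a serum label, of
#'   which `serum_high_n` are "high"; the rest of the arm is `NA`.
#' @param n_trials trials per session.
#' @param task optional [task_config()] overriding the per-subject defaults.
#' @param master_seed integer master seed; all per-subject and per-session
#'   seeds are derived from it.
#' @return object of class `twostep_cohort_spec`.
#' @export
cohort_spec <- function(model_id = "M1",
                        n_per_arm = c(placebo = 12L, amisulpride = 12L,
                                      naltrexone = 12L),
                        mu = NULL, sigma = NULL, R = NULL,
                        beta_ami = NULL, beta_nal = NULL,
                        serum_high_n = 0L, serum_measured_n = 0L,
                        n_trials = 200L, task = NULL, master_seed = 1L) {
  info <- model_par_info(model_id)
  p <- nrow(info)
  lat_names <- latent_names(model_id)
  mu <- mu %||% default_hyper_means(model_id)
  sigma <- sigma %||% rep(c(0.8, 0.5), each = p)
  R <- R %||% default_latent_corr(2L * p)
  beta_ami <- beta_ami %||% stats::setNames(rep(0, p), info$name)
  beta_nal <- beta_nal %||% stats::setNames(rep(0, p), info$name)
  stopifnot(length(mu) == 2L * p, length(sigma) == 2L * p,
            all(sigma > 0), length(beta_ami) == p, length(beta_nal) == p)
  arms <- c("placebo", "amisulpride", "naltrexone")
  if (is.null(names(n_per_arm))) names(n_per_arm) <- arms
  stopifnot(all(names(n_per_arm) %in% arms), all(n_per_arm >= 0))
  check_corr_matrix(R, 2L * p)
  if (serum_high_n > serum_measured_n ||
      serum_measured_n > n_per_arm[["amisulpride"]])
    stop("serum group sizes exceed the amisulpride arm")
  structure(
    list(model_id = model_id, n_per_arm = n_per_arm,
         mu = stats::setNames(as.numeric(mu), lat_names),
         sigma = stats::setNames(as.numeric(sigma), lat_names), R = R,
         beta_ami = stats::setNames(as.numeric(beta_ami), info$name),
         beta_nal = stats::setNames(as.numeric(beta_nal), info$name),
         serum_high_n = as.integer(serum_high_n),
         serum_measured_n = as.integer(serum_measured_n),
         n_trials = as.integer(n_trials), task = task,
         master_seed = as.integer(master_seed)),
    class = "twostep_cohort_spec")
}

#' Estimation-space latent names for a model
#' @keywords internal
latent_names <- function(model_id) {
  nm <- model_par_info(model_id)$name
  c(paste0(nm, "0"), paste0("d_", nm))
}

default_hyper_means <- function(model_id) {
  base <- switch(match.arg(model_id, c("M1", "M1_sticky", "M2", "M3")),
    M1 = c(omega = 0.15, gamma = -0.5, eta = -0.5),
    M1_sticky = c(omega = 0.15, gamma = -0.5, eta = -0.5, rho = 0.2, pi = 0),
    M2 = c(omega = 0.15, eta = -0.5, alpha1 = 0.3, alpha2 = 0.8, lambda = 0),
    M3 = c(omega = 0.15, eta = -0.5, alpha = 0.5, lambda = 0))
  c(base, rep(0, length(base)))
}

default_latent_corr <- function(K, rho = 0.15) {
  R <- matrix(rho, K, K)
  diag(R) <- 1
  R
}

check_corr_matrix <- function(R, K) {
  if (!is.matrix(R) || !identical(dim(R), c(K, K)))
    stop("R must be a ", K, "x", K, " matrix")
  if (max(abs(R - t(R))) > 1e-10 || any(abs(diag(R) - 1) > 1e-10))
    stop("R must be symmetric with unit diagonal")
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) stop("R is not positive definite")
  invisible(ch)
}

#' Draw one subject's latent vector
#'
#' Multivariate-normal draw around the arm-shifted hyper-means: the arm's
#' drug effect is added to the delta-component means before sampling.
#'
#' @param spec a [cohort_spec()].
#' @param arm `"placebo"`, `"amisulpride"` or `"naltrexone"`.
#' @param seed integer seed (`NULL` to use the current RNG stream).
#' @return named numeric latent vector of length `2p`.
#' @export
sample_subject_latents <- function(spec, arm = "placebo", seed = NULL) {
  m <- arm_means(spec, arm)
  ch <- check_corr_matrix(spec$R, length(m))
  local_rng(seed)
  z <- stats::rnorm(length(m))
  stats::setNames(
    as.numeric(m + spec$sigma * drop(crossprod(ch, z))), names(spec$mu))
}

arm_means <- function(spec, arm) {
  p <- length(spec$beta_ami)
  m <- spec$mu
  if (arm == "amisulpride") m[p + seq_len(p)] <- m[p + seq_len(p)] + spec$beta_ami
  if (arm == "naltrexone") m[p + seq_len(p)] <- m[p + seq_len(p)] + spec$beta_nal
  m
}

#' Generate a complete synthetic cohort
#'
#' Draws correlated subject latents per arm, converts them to native
#' parameters per session (session 1 from the baselines, session 2 from
#' baseline + delta), simulates two sessions of play per subject on
#' independent reward walks, and returns the trial table together with the
#' ground-truth parameter table. Fully reproducible from
#' `spec$master_seed`.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `twostep_cohort`: list with `trials` (standard
#'   schema: subject_id, session, trial, first_state, action, stimulus_id,
#'   planet, reward, drug, serum_group), `ground_truth` (latents and native
#'   session parameters per subject) and `spec`.
#' @export
generate_cohort <- function(spec) {
  info <- model_par_info(spec$model_id)
  p <- nrow(info)
  arms <- rep(names(spec$n_per_arm), times = spec$n_per_arm)
  n <- length(arms)
  ids <- sprintf("sub%03d", seq_len(n))
  serum <- rep(NA_character_, n)
  ami_idx <- which(arms == "amisulpride")
  if (spec$serum_measured_n > 0) {
    measured <- ami_idx[seq_len(spec$serum_measured_n)]
    serum[measured] <- c(rep("high", spec$serum_high_n),
                         rep("low", spec$serum_measured_n - spec$serum_high_n))
  }

  trials <- vector("list", 2L * n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    lat <- sample_subject_latents(spec, arms[i],
                                  seed = derive_seed(spec$master_seed, 1L, i))
    natives <- latents_to_native_sessions(lat, spec$model_id)
    for (sess in 1:2) {
      cfg <- spec$task %||%
        task_config(n_trials = spec$n_trials,
                    seed = derive_seed(spec$master_seed, 2L, i, sess))
      walks <- generate_walk_pair(cfg,
                                  seed = derive_seed(spec$master_seed, 3L, i, sess))
      trials[[2L * (i - 1L) + sess]] <- simulate_choices(
        natives[sess, ], spec$model_id, cfg, walks,
        seed = derive_seed(spec$master_seed, 4L, i, sess),
        subject_id = ids[i], session_label = sess)
    }
    row <- c(as.list(lat),
             stats::setNames(as.list(natives[1, ]),
                             paste0(info$name, "_s1")),
             stats::setNames(as.list(natives[2, ]),
                             paste0(info$name, "_s2")))
    truth[[i]] <- data.frame(subject_id = ids[i], drug = arms[i],
                             serum_group = serum[i], row,
                             check.names = FALSE)
  }
  trials <- do.call(rbind, trials)
  meta <- data.frame(subject_id = ids, drug = arms, serum_group = serum)
  trials <- merge(trials, meta, by = "subject_id", sort = FALSE)
  trials <- trials[order(trials$subject_id, trials$session, trials$trial), ]
  rownames(trials) <- NULL
  structure(list(trials = trials, ground_truth = do.call(rbind, truth),
                 spec = spec),
            class = "twostep_cohort")
}

#' Cohort specification echoing the published study layout
#'
#' Treatment arms of 38 (amisulpride), 39 (naltrexone) and 35 (placebo)
#' subjects, 200 trials per session with drift levels 0.5/1/2, a serum
#' dichotomization of 18 high / 14 low among 32 serum-measured amisulpride
#' subjects, and an amisulpride effect on the session difference of the
#' model-based weight at the reported scale (0.787 in estimation space, with
#' a -0.33 effect on the inverse-temperature difference). All other drug
#' effects are zero. Hyper-means/SDs are the package's synthetic defaults,
#' not estimates.
#'
#' @param master_seed integer master seed.
#' @return a [cohort_spec()].
#' @export
default_paperlike_spec <- function(master_seed = 20221205L) {
  cohort_spec(
    model_id = "M1",
    n_per_arm = c(placebo = 35L, amisulpride = 38L, naltrexone = 39L),
    beta_ami = c(omega = 0.787, gamma = 0, eta = -0.33),
    beta_nal = c(omega = 0, gamma = 0, eta = 0),
    serum_high_n = 18L, serum_measured_n = 32L,
    n_trials = 200L, master_seed = master_seed)
}

#' Write a trial table to CSV (standard schema)
#'
#' Planets are written as labels (`red`/`green`); all other columns are
#' written as-is. [read_trials()] restores the in-memory integer coding.
#'
#' @param trials trial data frame (or a `twostep_cohort`).
#' @param path output file.
#' @export
write_trials <- function(trials, path) {
  if (inherits(trials, "twostep_cohort")) trials <- trials$trials
  out <- trials
  if (is.numeric(out$planet)) out$planet <- planet_labels[out$planet]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
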