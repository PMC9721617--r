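#' Read and validate a trial table CSV
#'
#' Expects the standard schema (`subject_id, session, trial, first_state,
#' action, stimulus_id, planet, reward, drug, serum_group`). Planets may be
#' labels (`red`/`green`) or integers (1/2) and are returned as integers.
#' Rows violating the record invariants (labels outside their domains,
#' non-integer rewards, rewards outside the bounds, planet inconsistent with
#' the transition map) raise a validation error naming the offending rows;
#' rows with missing required fields are dropped with a message reporting
#' the count.
#'
#' @param path CSV file.
#' @param reward_bounds allowed reward interval.
#' @param transition_map expected deterministic transition map (set `NULL`
#'   to skip the consistency check).
#' @return validated trial data frame.
#' @export
read_trials <- function(path, reward_bounds = c(-4, 5),
                        transition_map = default_transition_map()) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "session", "trial", "first_state", "action",
           "planet", "reward")
  miss <- setdiff(req, names(tr))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  incomplete <- !stats::complete.cases(tr[req])
  if (any(incomplete)) {
    message("dropping ", sum(incomplete), " incomplete row(s)")
    tr <- tr[!incomplete, ]
  }
  tr$planet <- tryCatch(planet_int(tr$planet),
                        error = function(e) stop("unknown planet label"))
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows))
      stop("validation error (", what, ") in row(s): ",
           paste(utils::head(rows, 10), collapse = ", "),
           if (length(rows) > 10) " ..." else "", call. = FALSE)
  }
  bad(!tr$session %in% 1:2, "session not in {1,2}")
  bad(!tr$first_state %in% 1:2, "first_state not in {1,2}")
  bad(!tr$action %in% 1:2, "action not in {1,2}")
  bad(tr$reward != round(tr$reward), "non-integer reward")
  bad(tr$reward < reward_bounds[1] | tr$reward > reward_bounds[2],
      "reward outside bounds")
  if (!is.null(tr$drug))
    bad(!tr$drug %in% c("placebo", "amisulpride", "naltrexone"),
        paste0("unknown drug label: ",
               paste(setdiff(unique(tr$drug),
                             c("placebo", "amisulpride", "naltrexone")),
                     collapse = ", ")))
  if (!is.null(tr$serum_group))
    bad(!(is.na(tr$serum_group) | tr$serum_group %in% c("low", "high")),
        "unknown serum_group label")
  if (!is.null(transition_map))
    bad(tr$planet != transition_map[cbind(tr$first_state, tr$action)],
        "planet inconsistent with the transition map")
  tr$reward <- as.integer(tr$reward)
  tr[order(tr$subject_id, tr$session, tr$trial), ]
}

#' Assemble (or load) a pipeline configuration
#'
#' A pipeline run is fully described by: the input (a trial CSV path or a
#' synthetic [cohort_spec()]), the models to fit, sampler options, requested
#' stages, the output directory, and one master seed from which every
#' stage's seed is derived. A YAML file with the same field names can be
#' loaded by passing its path.
#'
#' @param input path to a trial CSV, or a `twostep_cohort_spec`.
#' @param models character vector of model ids to fit.
#' @param stages subset of `c("simulate", "fit", "behav_glm", "compare",
#'   "ppc")` (`simulate` only applies to a spec input).
#' @param chains,iter,warmup sampler settings shared by all fits.
#' @param fast halve chains and draws (continuous-integration mode).
#' @param serum_covariate serum dummy in the hierarchical model and GLM.
#' @param out_dir output directory.
#' @param master_seed master seed.
#' @return list of class `twostep_pipeline_config`.
#' @export
pipeline_config <- function(input, models = "M1",
                            stages = c("simulate", "fit", "behav_glm",
                                       "compare"),
                            chains = 4L, iter = 3000L, warmup = 1000L,
                            fast = FALSE, serum_covariate = FALSE,
                            out_dir = "twostep_out", master_seed = 1L) {
  if (is.character(input) && length(input) == 1 && grepl("[.]ya?ml$", input)) {
    y <- yaml::read_yaml(input)
    y$input <- y$input %||% y$cohort
    if (!is.null(y$spec)) y$input <- do.call(cohort_spec, y$spec)
    args <- y[intersect(names(y), names(formals(pipeline_config)))]
    return(do.call(pipeline_config, args))
  }
  if (fast) {
    chains <- max(1L, chains %/% 2L)
    iter <- warmup + (iter - warmup) %/% 2L
  }
  structure(list(input = input, models = models, stages = stages,
                 chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup),
                 serum_covariate = serum_covariate, out_dir = out_dir,
                 master_seed = as.integer(master_seed)),
            class = "twostep_pipeline_config")
}

log_stage <- function(log, stage, seed, t0, ...) {
  entry <- data.frame(stage = stage, seed = seed,
                      seconds = round(as.numeric(Sys.time()) - t0, 2), ...)
  rbind(log, entry)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order — simulate (for a spec input),
#' hierarchical fits per model, the stay-behaviour GLM, PSIS-LOO comparison
#' with pseudo-BMA weights, posterior predictive checks — and writes
#' versioned CSV outputs plus a structured run log (stage, seed, duration)
#' to the output directory. Identical config and master seed reproduce
#' identical summaries.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with every stage's in-memory result; on disk:
#'   `trials.csv`/`ground_truth.csv` (simulated input), per-model
#'   `fit_<model>_coefficients.csv` and `fit_<model>_rhat.csv`,
#'   `stay_glm_coefficients.csv`, `model_comparison.csv`,
#'   `pseudo_bma_weights.csv`, `ppc_coefficients.csv`, `run_log.csv`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "twostep_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(); log <- NULL
  seed_of <- function(stage_no) derive_seed(config$master_seed, 9L, stage_no)

  # --- input ---
  t0 <- as.numeric(Sys.time())
  if (inherits(config$input, "twostep_cohort_spec")) {
    if (!"simulate" %in% config$stages)
      stop("a spec input requires the 'simulate' stage")
    cohort <- generate_cohort(config$input)
    trials <- cohort$trials
    write_trials(trials, file.path(config$out_dir, "trials.csv"))
    utils::write.csv(cohort$ground_truth,
                     file.path(config$out_dir, "ground_truth.csv"),
                     row.names = FALSE)
    out$cohort <- cohort
    log <- log_stage(log, "simulate", config$input$master_seed, t0)
  } else {
    trials <- read_trials(config$input)
    log <- log_stage(log, "read", NA_integer_, t0)
  }

  # --- hierarchical fits ---
  if ("fit" %in% config$stages) {
    out$fits <- list()
    for (m in config$models) {
      t0 <- as.numeric(Sys.time())
      sd <- seed_of(match(m, config$models))
      fit <- fit_hierarchical(trials, m, chains = config$chains,
                              iter = config$iter, warmup = config$warmup,
                              seed = sd,
                              serum_covariate = config$serum_covariate)
      out$fits[[m]] <- fit
      utils::write.csv(drug_effect_summary(fit),
                       file.path(config$out_dir,
                                 paste0("fit_", m, "_coefficients.csv")),
                       row.names = FALSE)
      rhat_tab <- fit$diagnostics
      rhat_tab$flagged <- !is.na(rhat_tab$rhat) & rhat_tab$rhat >= 1.01
      utils::write.csv(rhat_tab,
                       file.path(config$out_dir,
                                 paste0("fit_", m, "_rhat.csv")),
                       row.names = FALSE)
      log <- log_stage(log, paste0("fit_", m), sd, t0)
    }
  }

  # --- stay GLM ---
  if ("behav_glm" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    sd <- seed_of(50L)
    tab <- build_stay_table(trials)
    glm_fit <- fit_stay_glm(tab, chains = config$chains, iter = config$iter,
                            warmup = config$warmup, seed = sd,
                            serum = config$serum_covariate)
    out$stay_glm <- glm_fit
    utils::write.csv(stay_glm_summary(glm_fit),
                     file.path(config$out_dir, "stay_glm_coefficients.csv"),
                     row.names = FALSE)
    log <- log_stage(log, "behav_glm", sd, t0)
  }

  # --- model comparison ---
  if ("compare" %in% config$stages && length(out$fits) >= 2) {
    t0 <- as.numeric(Sys.time())
    sd <- seed_of(60L)
    loos <- lapply(out$fits, function(f)
      psis_loo(pointwise_loglik(f, max_draws = 2000L, seed = sd)))
    out$comparison <- loo_compare(loos)
    out$weights <- pseudo_bma_weights(loos, seed = sd)
    utils::write.csv(out$comparison,
                     file.path(config$out_dir, "model_comparison.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(model = names(out$weights),
                                weight = as.numeric(out$weights)),
                     file.path(config$out_dir, "pseudo_bma_weights.csv"),
                     row.names = FALSE)
    log <- log_stage(log, "compare", sd, t0)
  }

  # --- posterior predictive check ---
  if ("ppc" %in% config$stages && length(out$fits)) {
    t0 <- as.numeric(Sys.time())
    sd <- seed_of(70L)
    ppc <- posterior_predictive_check(out$fits[[1]], seed = sd,
                                      refit_glm = TRUE)
    out$ppc <- ppc
    utils::write.csv(ppc$coefficients,
                     file.path(config$out_dir, "ppc_coefficients.csv"),
                     row.names = FALSE)
    log <- log_stage(log, "ppc", sd, t0)
  }

  utils::write.csv(log, file.path(config$out_dir, "run_log.csv"),
                   row.names = FALSE)
  invisible(out)
}
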