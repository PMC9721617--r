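#' Model registry: parameters and their estimation-space transforms
#'
#' Four generative choice models are supported:
#' * `M1` — last-outcome learner: model-based weight `omega`, forgetting
#'   (devaluation) `gamma`, inverse temperature `eta`.
#' * `M1_sticky` — M1 plus response stickiness `rho` (repeat the previous
#'   action slot) and stimulus stickiness `pi` (repeat the previous
#'   spaceship).
#' * `M2` — dual-system temporal-difference learner with separate stage
#'   learning rates `alpha1`, `alpha2` and eligibility trace `lambda`.
#' * `M3` — M2 with the two learning rates tied (`alpha`).
#'
#' Parameters constrained to `[0, 1]` are estimated in inverse-probit space,
#' positive parameters in log space, unbounded parameters (the stickiness
#' biases) in natural space.
#'
#' @param model_id one of `"M1"`, `"M1_sticky"`, `"M2"`, `"M3"`.
#' @return data frame with columns `name` and `kind`
#'   (`unit_interval` / `positive` / `unbounded`).
#' @export
model_par_info <- function(model_id) {
  switch(match.arg(model_id, c("M1", "M1_sticky", "M2", "M3")),
    M1 = data.frame(name = c("omega", "gamma", "eta"),
                    kind = c("unit_interval", "unit_interval", "positive")),
    M1_sticky = data.frame(
      name = c("omega", "gamma", "eta", "rho", "pi"),
      kind = c("unit_interval", "unit_interval", "positive",
               "unbounded", "unbounded")),
    M2 = data.frame(
      name = c("omega", "eta", "alpha1", "alpha2", "lambda"),
      kind = c("unit_interval", "positive", "unit_interval",
               "unit_interval", "unit_interval")),
    M3 = data.frame(
      name = c("omega", "eta", "alpha", "lambda"),
      kind = c("unit_interval", "positive", "unit_interval", "unit_interval")))
}

model_code <- function(model_id) {
  match(match.arg(model_id, c("M1", "M1_sticky", "M2", "M3")),
        c("M1", "M1_sticky", "M2", "M3"))
}

#' Map estimation-space values to native parameter space
#'
#' Parameters constrained to the unit interval are mapped through the
#' standard-normal CDF (inverse probit), positive parameters through `exp`,
#' and unbounded parameters are left unchanged. Session-2 native parameters
#' are obtained by transforming `baseline' + delta'`.
#'
#' @param latent numeric vector in estimation space.
#' @param kind one of `"unit_interval"`, `"positive"`, `"unbounded"`
#'   (recycled along `latent`).
#' @return native-space values.
#' @export
to_native <- function(latent, kind) {
  kind <- rep_len(kind, length(latent))
  out <- latent
  ui <- kind == "unit_interval"; po <- kind == "positive"
  out[ui] <- stats::pnorm(latent[ui])
  out[po] <- exp(latent[po])
  out
}

#' Inverse of [to_native()]
#' @inheritParams to_native
#' @param native numeric vector in native space.
#' @export
to_latent <- function(native, kind) {
  kind <- rep_len(kind, length(native))
  out <- native
  ui <- kind == "unit_interval"; po <- kind == "positive"
  out[ui] <- stats::qnorm(native[ui])
  out[po] <- log(native[po])
  out
}

#' Native session parameters from a subject's latent vector
#'
#' @param latents numeric vector `(baseline', delta')` of length `2 * p`.
#' @param model_id model identifier.
#' @return 2 x p matrix of native parameters, rows = sessions.
#' @export
latents_to_native_sessions <- function(latents, model_id) {
  info <- model_par_info(model_id)
  p <- nrow(info)
  stopifnot(length(latents) == 2L * p)
  base <- latents[seq_len(p)]
  delta <- latents[p + seq_len(p)]
  out <- rbind(to_native(base, info$kind),
               to_native(base + delta, info$kind))
  dimnames(out) <- list(session = c("1", "2"), parameter = info$name)
  out
}
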