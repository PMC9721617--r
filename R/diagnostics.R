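#' Split-chain Gelman-Rubin statistic
#'
#' Each chain is split in half and the classic potential-scale-reduction
#' factor is computed over the resulting half-chains; values below 1.01 are
#' conventionally taken as evidence of convergence. Returns `NA` when only
#' one half-chain pair with near-zero variance is available.
#'
#' @param x draws matrix, chains x iterations.
#' @return scalar R-hat.
#' @export
split_rhat <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  halves <- rbind(x[, seq_len(half), drop = FALSE],
                  x[, (n - half + 1):n, drop = FALSE])
  m <- nrow(halves); len <- ncol(halves)
  means <- rowMeans(halves)
  vars <- apply(halves, 1, stats::var)
  W <- mean(vars)
  B <- len * stats::var(means)
  if (!is.finite(W) || W <= 1e-300) return(NA_real_)
  sqrt((W * (len - 1) / len + B / len) / W)
}

#' Effective sample size (initial positive sequence estimator)
#'
#' @param x draws matrix, chains x iterations.
#' @return scalar effective sample size.
#' @export
ess_basic <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  n_chain <- nrow(x); n <- ncol(x)
  if (n < 4) return(NA_real_)
  xc <- x - rowMeans(x)
  v <- mean(apply(x, 1, stats::var))
  if (!is.finite(v) || v <= 1e-300) return(NA_real_)
  max_lag <- min(n - 2L, 500L)
  rho <- vapply(seq_len(max_lag), function(l) {
    mean(vapply(seq_len(n_chain), function(c)
      sum(xc[c, 1:(n - l)] * xc[c, (1 + l):n]) / (n - 1), 0)) / v
  }, 0)
  # Geyer: sum consecutive pairs while positive
  s <- 0; l <- 1
  while (l + 1 <= max_lag) {
    pair <- rho[l] + rho[l + 1]
    if (pair < 0) break
    s <- s + pair
    l <- l + 2
  }
  n_chain * n / (1 + 2 * s)
}

#' Convergence diagnostics for all group-level quantities of a fit
#'
#' @param draws named list of draws arrays `[chain, iteration, quantity]`.
#' @return data frame `quantity`, `rhat`, `ess`.
#' @keywords internal
diagnostics_table <- function(draws) {
  out <- list()
  for (block in names(draws)) {
    arr <- draws[[block]]
    qn <- dimnames(arr)[[3]]
    for (j in seq_len(dim(arr)[3])) {
      x <- arr[, , j, drop = FALSE]
      dim(x) <- dim(arr)[1:2]
      out[[length(out) + 1L]] <- data.frame(
        quantity = qn[j] %||% paste0(block, "[", j, "]"),
        rhat = split_rhat(x), ess = ess_basic(x))
    }
  }
  do.call(rbind, out)
}
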