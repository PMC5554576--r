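#' Running means of MCMC samples
#'
#' @param x Numeric vector or matrix (iterations in rows).
#' @return Cumulative means: `r_k = (1/k) sum_{j<=k} x_j`, per column for a
#'   matrix.
#' @export
running_means <- function(x) {
  if (is.matrix(x)) {
    stopifnot(nrow(x) >= 1)
    apply(x, 2, function(col) cumsum(col) / seq_along(col))
  } else {
    stopifnot(length(x) >= 1)
    cumsum(x) / seq_along(x)
  }
}

#' Effective sample size of an MCMC series
#'
#' `ESS = N / (1 + 2 sum_k rho_k)` with empirical autocorrelations summed up
#' to the lag before the first nonpositive estimate (initial positive
#' sequence truncation).  A constant series has ESS 0 by convention.
#'
#' @param x Numeric series of length >= 10.
#' @return ESS in `[0, N]`.
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  stopifnot(n >= 10)
  if (var(x) == 0) return(0)
  lag_max <- min(n - 1, max(200L, floor(10 * sqrt(n))))
  rho <- drop(acf(x, lag.max = lag_max, plot = FALSE)$acf)[-1]
  bad <- which(rho <= 0)
  if (length(bad)) rho <- rho[seq_len(bad[1] - 1)]
  min(n, n / (1 + 2 * sum(rho)))
}

#' Trace summaries of a fitted chain
#'
#' Per-stored-iteration log-likelihood, model size `sum(gamma)` and L2 norm
#' of `beta`, plus per-coordinate effective sample sizes of `beta`.
#'
#' @param fit A `cox_ssvs_fit`.
#' @param ess Also compute per-coordinate ESS (can be slow for very large
#'   `p`).
#' @return Object of class `trace_summary` with a data frame `trace`
#'   (`iteration`, `loglik`, `model_size`, `beta_l2`) and, when requested,
#'   `ess` (one value per coefficient).
#' @export
trace_summaries <- function(fit, ess = TRUE) {
  stopifnot(nrow(fit$beta) >= 1)
  tr <- data.frame(iteration = seq_len(nrow(fit$beta)),
                   loglik = fit$loglik,
                   model_size = rowSums(fit$gamma),
                   beta_l2 = sqrt(rowSums(fit$beta^2)))
  ess_v <- if (ess && nrow(fit$beta) >= 10)
    apply(fit$beta, 2, effective_sample_size) else NULL
  structure(list(trace = tr, ess = ess_v), class = "trace_summary")
}

#' @export
print.trace_summary <- function(x, ...) {
  cat(sprintf("trace_summary: %d stored iterations; mean model size %.2f; mean loglik %.1f\n",
              nrow(x$trace), mean(x$trace$model_size), mean(x$trace$loglik)))
  if (!is.null(x$ess))
    cat(sprintf("  beta ESS: median %.0f (range %.0f-%.0f)\n",
                stats::median(x$ess), min(x$ess), max(x$ess)))
  invisible(x)
}
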