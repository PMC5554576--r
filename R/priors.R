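#' Spike-and-slab prior on a regression coefficient
#'
#' Two-component normal mixture `beta_i | gamma_i ~ (1 - gamma_i) N(0, tau^2)
#' + gamma_i N(0, cb^2 tau^2)`: a narrow spike for excluded variables and a
#' `cb`-fold wider slab for included ones.  The defaults `tau = 0.0375`,
#' `cb = 20` give a slab standard deviation of `0.75`, i.e. a 95% prior
#' interval of roughly -1.47 to 1.47 for an included coefficient.
#'
#' @param tau Spike standard deviation, `tau > 0`.
#' @param cb Slab inflation factor, `cb > 1`.
#' @return Object of class `spike_slab_prior`.
#' @export
spike_slab_prior <- function(tau = 0.0375, cb = 20) {
  stopifnot(is.numeric(tau), tau > 0, is.numeric(cb), cb > 1)
  structure(list(tau = tau, cb = cb), class = "spike_slab_prior")
}

#' Spike-and-slab log density
#'
#' @param beta Coefficient value(s).
#' @param gamma Inclusion indicator(s), 0 or 1 (recycled against `beta`).
#' @param prior A [spike_slab_prior()].
#' @return Normal log density with sd `tau` where `gamma = 0` and sd
#'   `cb * tau` where `gamma = 1`.
#' @export
spike_slab_logpdf <- function(beta, gamma, prior) {
  stopifnot(all(gamma %in% c(0, 1)))
  sd <- ifelse(gamma == 1, prior$cb * prior$tau, prior$tau)
  dnorm(beta, mean = 0, sd = sd, log = TRUE)
}

#' Full conditional inclusion probability of gamma_i
#'
#' `P(gamma_i = 1 | beta_i) = a / (a + b)` with
#' `a = f(beta_i | slab) * pi_i` and `b = f(beta_i | spike) * (1 - pi_i)`.
#' Computed from log densities so that extreme density ratios (|beta| far in
#' the slab) do not underflow.
#'
#' @param beta Coefficient value(s).
#' @param pi Prior inclusion probability in `[0, 1]` (recycled).
#' @param prior A [spike_slab_prior()].
#' @return Probability in `[0, 1]`, vectorized over the inputs.
#' @export
gamma_conditional <- function(beta, pi, prior) {
  stopifnot(all(pi >= 0), all(pi <= 1))
  k <- pmax(length(beta), length(pi))
  beta <- rep_len(beta, k)
  pi <- rep_len(pi, k)
  la <- dnorm(beta, 0, prior$cb * prior$tau, log = TRUE) + log(pi)
  lb <- dnorm(beta, 0, prior$tau, log = TRUE) + log1p(-pi)
  out <- 1 / (1 + exp(lb - la))
  out[pi == 0] <- 0
  out[pi == 1] <- 1
  out
}

new_selection_prior <- function(pi, k) {
  structure(as.numeric(pi), k = k, class = "selection_prior")
}

#' @export
print.selection_prior <- function(x, ...) {
  cat(sprintf("selection_prior: p = %d features, sum(pi) = %.3f (a-priori model size k = %s)\n",
              length(x), sum(x), format(attr(x, "k"))))
  invisible(x)
}

#' Uninformative selection prior
#'
#' Constant prior inclusion probabilities `pi_i = k / p`, so that the
#' a-priori expected model size is `k`.
#'
#' @param p Number of features.
#' @param k A-priori expected model size, `0 < k <= p`.
#' @return A `selection_prior` (numeric vector of length `p` with attribute
#'   `k`).
#' @export
uniform_selection_prior <- function(p, k) {
  stopifnot(p >= 1, k > 0)
  if (k > p)
    stop("a-priori model size k cannot exceed the number of features p")
  new_selection_prior(rep(k / p, p), k)
}

#' Selection prior informed by secondary-data dispersion
#'
#' Sets `pi_i = k * sigma_i / sum(sigma)`, so features whose secondary
#' measurements (e.g. copy-number variation) vary more across samples get a
#' proportionally larger prior inclusion probability, while the a-priori
#' expected model size remains `k`.  Entries are clipped into
#' `[eps, 1 - eps]` to avoid degenerate Bernoulli conditionals.
#'
#' @param sigma Nonnegative per-feature dispersions (e.g. standard deviation
#'   of a CNV matrix across samples); not all zero.
#' @param k A-priori expected model size.
#' @param eps Clipping bound.
#' @return A `selection_prior` of length `length(sigma)`.
#' @export
cnv_informed_prior <- function(sigma, k, eps = 1e-6) {
  sigma <- as.numeric(sigma)
  if (any(sigma < 0))
    stop("dispersions must be nonnegative")
  if (sum(sigma) <= 0)
    stop("at least one dispersion must be positive")
  pi <- k * sigma / sum(sigma)
  new_selection_prior(pmin(pmax(pi, eps), 1 - eps), k)
}

#' Scenario selection priors for simulation studies
#'
#' `"correct"` places prior probability 0.8 on the true predictors and 0.1
#' elsewhere; `"incorrect"` places 0.8 on an equally large, randomly drawn
#' set of non-predictors (seeded by the caller's RNG state) and 0.1 on all
#' remaining variables, including the true ones.
#'
#' @param kind `"correct"` or `"incorrect"`.
#' @param truth_indices Indices of the true predictors in `1..p`.
#' @param p Number of features.
#' @param p_high,p_low The two probability levels (defaults 0.8 / 0.1).
#' @return A `selection_prior` of length `p`.
#' @export
scenario_prior <- function(kind = c("correct", "incorrect"), truth_indices, p,
                           p_high = 0.8, p_low = 0.1) {
  kind <- match.arg(kind)
  truth_indices <- as.integer(truth_indices)
  stopifnot(all(truth_indices >= 1), all(truth_indices <= p))
  pi <- rep(p_low, p)
  if (kind == "correct") {
    pi[truth_indices] <- p_high
  } else {
    pool <- setdiff(seq_len(p), truth_indices)
    if (length(truth_indices) > length(pool))
      stop("not enough non-predictors to mis-assign the informative prior")
    pi[sample(pool, length(truth_indices))] <- p_high
  }
  new_selection_prior(pi, sum(pi))
}
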