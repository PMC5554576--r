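#' Block-correlated Gaussian covariates
#'
#' Draws rows from a zero-mean, unit-variance Gaussian whose correlation is
#' `rho^|i-j|` between features `i` and `j` of the same block (an AR(1)
#' structure, generated by the exact recursion
#' `z_i = rho z_{i-1} + sqrt(1 - rho^2) eps_i`) and zero across blocks.
#'
#' @param n Number of samples.
#' @param p Number of features.
#' @param rho Within-block base correlation in `[0, 1)`.
#' @param m Block size; the last block is truncated if `m` does not divide
#'   `p`.
#' @return An `n x p` matrix with columns `V1, ..., Vp`.
#' @export
simulate_block_covariates <- function(n, p, rho = 0.5, m = 100) {
  stopifnot(n >= 1, p >= 1, rho >= 0, rho < 1, m >= 1)
  X <- matrix(rnorm(n * p), n, p)
  if (rho > 0 && m > 1) {
    s <- sqrt(1 - rho^2)
    for (i in seq_len(p)[-1]) {
      if ((i - 1) %% m != 0)              # not a block start
        X[, i] <- rho * X[, i - 1] + s * X[, i]
    }
  }
  colnames(X) <- paste0("V", seq_len(p))
  X
}

#' Weibull parameters from two survival constraints
#'
#' Solves `exp(-eta * t^kappa) = s` at two time points:
#' `kappa = log(log(s1)/log(s2)) / log(t1/t2)` and
#' `eta = -log(s1) / t1^kappa`.  The constraints must describe a survival
#' function that decreases with time, otherwise the implied shape is not
#' positive and an error is raised.
#'
#' @param t1,t2 Distinct positive time points.
#' @param s1,s2 Survival probabilities in `(0, 1)` at `t1`, `t2`.
#' @return Named vector `c(eta, kappa)`.
#' @examples
#' weibull_from_quantiles(12, 0.9, 36, 0.5)  # kappa ~ 1.7145
#' @export
weibull_from_quantiles <- function(t1, s1, t2, s2) {
  stopifnot(t1 > 0, t2 > 0, t1 != t2, s1 > 0, s1 < 1, s2 > 0, s2 < 1)
  if (s1 == s2)
    stop("survival constraints not monotone")
  kappa <- log(log(s1) / log(s2)) / log(t1 / t2)
  if (!is.finite(kappa) || kappa <= 0)
    stop("survival constraints not monotone")
  eta <- -log(s1) / t1^kappa
  c(eta = eta, kappa = kappa)
}

#' Cox-Weibull event times by inverse-transform sampling
#'
#' `T*_l = (-log(U_l) / (eta * exp(x_l'beta)))^(1/kappa)` with
#' `U_l ~ U(0, 1)`, i.e. proportional hazards around a Weibull baseline with
#' cumulative hazard `eta * t^kappa`.
#'
#' @param X Covariate matrix.
#' @param beta True coefficient vector.
#' @param eta,kappa Positive Weibull baseline parameters.
#' @return Vector of uncensored event times, one per row of `X`.
#' @export
simulate_event_times <- function(X, beta, eta, kappa) {
  stopifnot(eta > 0, kappa > 0)
  lp <- as.vector(as.matrix(X) %*% beta)
  U <- runif(nrow(X))
  (-log(U) / (eta * exp(lp)))^(1 / kappa)
}

#' Apply mixed administrative and loss-to-follow-up censoring
#'
#' The censoring time is `C*_l = min(Uniform(0, a_max), Exponential(rate))`,
#' an uninformative mixture of administrative end-of-study censoring and
#' exponential loss to follow-up.  The observed data are
#' `t_l = min(T*_l, C*_l)` and `delta_l = 1(T*_l <= C*_l)` (ties count as
#' events).
#'
#' @param Tstar Uncensored event times.
#' @param a_max Administrative window; `Inf` disables the uniform component.
#' @param rate Exponential loss-to-follow-up rate; `0` disables it.
#' @return `list(time =, status =)`.
#' @export
apply_censoring <- function(Tstar, a_max = 160, rate = 1 / 500) {
  stopifnot(all(Tstar >= 0), a_max > 0, rate >= 0)
  n <- length(Tstar)
  C <- if (is.finite(a_max)) runif(n, 0, a_max) else rep(Inf, n)
  if (rate > 0) C <- pmin(C, rexp(n, rate))
  list(time = pmin(Tstar, C), status = as.numeric(Tstar <= C))
}

#' Define a simulation scenario
#'
#' Encapsulates the study conditions of the simulation design: `n = 200`
#' subjects, `p = 500` block-correlated features (`rho = 0.5`, block size
#' `m = 100`), Cox-Weibull event times whose baseline satisfies
#' `S(12) = 0.9` and `S(36) = 0.5`, and mixed censoring.  The `"sparse"`
#' scenario has true coefficients `(0.75, -0.75, 0.5, -0.5, 0.25, -0.25,
#' 0, ...)`; the `"nonsparse"` scenario draws `k_true = 122` coefficients
#' with magnitudes uniform on `(0.2, 0.8)`, 61 negative and 61 positive, on
#' the first 122 features.
#'
#' @param kind `"sparse"` or `"nonsparse"`.
#' @param seed Seed fixing the scenario itself (the nonsparse coefficient
#'   draw); dataset draws take their own seed in
#'   [simulate_survival_data()].
#' @param n,p,rho,m Dimensions and covariate correlation structure.
#' @param a_max,censor_rate Censoring mixture parameters.
#' @return Object of class `simulation_scenario` with the true coefficient
#'   vector, `truth` (indices of nonzero coefficients) and all parameters.
#' @export
make_scenario <- function(kind = c("sparse", "nonsparse"), seed = 1,
                          n = 200, p = 500, rho = 0.5, m = 100,
                          a_max = 160, censor_rate = 1 / 500) {
  kind <- match.arg(kind)
  wb <- weibull_from_quantiles(12, 0.9, 36, 0.5)
  beta <- numeric(p)
  if (kind == "sparse") {
    k_true <- 6L
    stopifnot(p >= k_true)
    beta[1:6] <- c(0.75, -0.75, 0.5, -0.5, 0.25, -0.25)
  } else {
    k_true <- 122L
    stopifnot(p >= k_true)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    mag <- runif(k_true, 0.2, 0.8)
    sgn <- sample(rep(c(-1, 1), each = k_true / 2))
    beta[seq_len(k_true)] <- sgn * mag
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  structure(list(kind = kind, seed = seed, n = n, p = p, rho = rho, m = m,
                 beta_true = beta, k_true = k_true,
                 truth = seq_len(k_true),
                 eta = wb[["eta"]], kappa = wb[["kappa"]],
                 a_max = a_max, censor_rate = censor_rate),
            class = "simulation_scenario")
}

#' Draw a dataset from a simulation scenario
#'
#' @param scenario A [make_scenario()] result.
#' @param seed Seed for this dataset draw; distinct seeds give independent
#'   training/test sets sharing the same true coefficients.
#' @return A [survival_dataset()] with attributes `beta_true`, `truth` and
#'   `scenario`.
#' @export
simulate_survival_data <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  if (!is.null(seed)) set.seed(seed)
  X <- simulate_block_covariates(scenario$n, scenario$p, scenario$rho,
                                 scenario$m)
  Tstar <- simulate_event_times(X, scenario$beta_true, scenario$eta,
                                scenario$kappa)
  obs <- apply_censoring(Tstar, scenario$a_max, scenario$censor_rate)
  d <- survival_dataset(obs$time, obs$status, X)
  attr(d, "beta_true") <- scenario$beta_true
  attr(d, "truth") <- scenario$truth
  attr(d, "scenario") <- scenario
  d
}
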