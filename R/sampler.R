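#' MCMC chain configuration
#'
#' @param n_iter Total number of Gibbs iterations.
#' @param burn_in Iterations discarded before storage; proposal scales adapt
#'   only during this phase and are frozen afterwards so the post-burn-in
#'   kernel targets the correct posterior.
#' @param thin Store every `thin`-th post-burn-in state.
#' @param seed Optional integer seed; when given, `run_chain()` calls
#'   `set.seed()` so runs are bit-reproducible.
#' @param adapt_window Iterations between proposal-scale adaptations.
#' @param adapt_target Target acceptance rate of the per-coordinate
#'   random-walk updates.
#' @param init_scale Initial proposal standard deviation for every
#'   coordinate.
#' @param collapse Use the indicator-collapsed beta update (see
#'   [update_beta()]).  The default `FALSE` is the canonical stochastic
#'   search kernel whose acceptance ratio conditions on the current
#'   `gamma_i`; `TRUE` marginalizes the indicator out of the prior term,
#'   which targets the same posterior but equilibrates much faster.
#' @return Object of class `chain_config`.
#' @export
chain_config <- function(n_iter = 20000, burn_in = 5000, thin = 1,
                         seed = NULL, adapt_window = 100,
                         adapt_target = 0.35, init_scale = 0.1,
                         collapse = FALSE) {
  stopifnot(n_iter >= 1, burn_in >= 0, burn_in < n_iter, thin >= 1,
            adapt_window >= 1, adapt_target > 0, adapt_target < 1,
            init_scale > 0, is.logical(collapse))
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed,
                 adapt_window = as.integer(adapt_window),
                 adapt_target = adapt_target, init_scale = init_scale,
                 collapse = isTRUE(collapse)),
            class = "chain_config")
}

#' Assemble the model context for the Gibbs sampler
#'
#' Builds the time partition, calibrates the gamma-process baseline prior
#' (unless one is supplied) and bundles data and priors into the fixed
#' context that the `update_*` kernels and [run_chain()] operate on.
#'
#' @param data A [survival_dataset()].
#' @param selection Per-feature prior inclusion probabilities (a
#'   `selection_prior` or plain numeric vector of length `ncol(X)`).
#' @param spike A [spike_slab_prior()].
#' @param c0 Confidence weight of the baseline-hazard prior.
#' @param baseline Optional [baseline_prior()]; calibrated from the data via
#'   the Nelson-Aalen / Weibull fit when `NULL`.
#' @return Object of class `mcmc_model`.
#' @export
mcmc_model <- function(data, selection, spike = spike_slab_prior(), c0 = 2,
                       baseline = NULL) {
  stopifnot(inherits(data, "survival_dataset"))
  pi <- as.numeric(selection)
  if (length(pi) != ncol(data$X))
    stop("selection prior length must equal the number of features")
  stopifnot(all(pi >= 0), all(pi <= 1))
  partition <- partition_time_axis(data$time, data$status)
  if (is.null(baseline))
    baseline <- baseline_prior(partition, data$time, data$status, c0 = c0)
  structure(list(X = data$X, n = nrow(data$X), p = ncol(data$X),
                 partition = partition, J = partition$J,
                 interval = partition$interval,
                 is_event = partition$is_event, d = partition$d,
                 aincr = baseline$alpha_increments, c0 = baseline$c0,
                 tau = spike$tau, cb = spike$cb, pi = pi,
                 spike = spike, baseline = baseline,
                 feature_names = colnames(data$X)),
            class = "mcmc_model")
}

#' Initial MCMC state
#'
#' The chain starts from the empty model: `beta = 0`, `gamma = 0`, and each
#' interval hazard at its prior mean `alpha_increment_j / c0`.
#'
#' @param model An [mcmc_model()].
#' @return Object of class `mcmc_state` holding `beta`, `gamma`, `h` and the
#'   cached linear predictor / likelihood quantities.
#' @export
initial_state <- function(model) {
  s <- list(beta = numeric(model$p), gamma = integer(model$p),
            h = model$aincr / model$c0, theta = numeric(model$n))
  s$etheta <- exp(s$theta)
  s <- refresh_likelihood(s, model)
  structure(s, class = "mcmc_state")
}

# log of the gamma-marginalized spike-and-slab prior density
mixture_logpdf <- function(b, pi, tau, cb) {
  if (pi <= 0) return(dnorm(b, 0, tau, log = TRUE))
  if (pi >= 1) return(dnorm(b, 0, cb * tau, log = TRUE))
  la <- log(pi) + dnorm(b, 0, cb * tau, log = TRUE)
  lb <- log1p(-pi) + dnorm(b, 0, tau, log = TRUE)
  mx <- pmax(la, lb)
  mx + log(exp(la - mx) + exp(lb - mx))
}

# recompute A (cumulative hazard while at risk, excluding own event
# interval), the per-event log terms, and the grouped log-likelihood
refresh_likelihood <- function(state, model) {
  H <- c(0, cumsum(state$h))
  j <- model$interval
  ev <- model$is_event == 1L
  state$A <- H[j] + ifelse(ev, 0, state$h[j])
  state$evterm <- numeric(model$n)
  state$evterm[ev] <- log1mexp(state$h[j[ev]] * state$etheta[ev])
  state$loglik <- sum(-state$A * state$etheta) + sum(state$evterm[ev])
  state
}

#' Adaptive random-walk Metropolis-Hastings sweep over beta
#'
#' Proposes `beta_i' ~ N(beta_i, scale_i^2)` for each coordinate in index
#' order and accepts with probability `min(1, exp(delta log-likelihood +
#' delta log-prior))`.  By default the prior term is the spike-and-slab
#' normal conditional on the current `gamma_i` — the canonical stochastic
#' search update.  With `collapse = TRUE` the indicator is marginalized out
#' of the prior term (`(1 - pi_i) N(0, tau^2) + pi_i N(0, (cb tau)^2)`),
#' which is valid because the likelihood does not involve `gamma` and
#' `gamma_i | beta_i` is redrawn exactly afterwards ([update_gamma()]); the
#' collapsed form targets the identical joint posterior but crosses the
#' spike-slab valley in ordinary random-walk steps instead of waiting for
#' rare joint excursions.  The linear predictor is maintained
#' incrementally, so one coordinate update costs O(n).  Non-finite
#' log-posterior differences are treated as rejections.
#'
#' @param state An [initial_state()] (or later) `mcmc_state`.
#' @param model An [mcmc_model()].
#' @param scales Per-coordinate proposal standard deviations.
#' @param tau_scale Multiplier on the spike/slab standard deviations (used by
#'   the tempered chains; 1 for the target chain).
#' @param collapse Marginalize `gamma_i` out of the prior term.
#' @return `list(state =, accepted =)` with a logical acceptance flag per
#'   coordinate.
#' @export
update_beta <- function(state, model, scales, tau_scale = 1,
                        collapse = FALSE) {
  accepted <- logical(model$p)
  tau <- model$tau * tau_scale
  ev <- model$is_event == 1L
  hj <- state$h[model$interval]
  for (i in seq_len(model$p)) {
    db <- rnorm(1) * scales[i]
    u <- runif(1)
    bnew <- state$beta[i] + db
    dprior <- if (collapse) {
      mixture_logpdf(bnew, model$pi[i], tau, model$cb) -
        mixture_logpdf(state$beta[i], model$pi[i], tau, model$cb)
    } else {
      sd_i <- if (state$gamma[i] == 1L) model$cb * tau else tau
      -0.5 * (bnew^2 - state$beta[i]^2) / sd_i^2
    }
    theta_new <- state$theta + model$X[, i] * db
    e_new <- exp(theta_new)
    evterm_new <- state$evterm
    evterm_new[ev] <- log1mexp(hj[ev] * e_new[ev])
    dll <- sum(-state$A * (e_new - state$etheta)) +
      sum(evterm_new[ev] - state$evterm[ev])
    la <- dll + dprior
    if (is.finite(la) && log(u) < la) {
      state$beta[i] <- bnew
      state$theta <- theta_new
      state$etheta <- e_new
      state$evterm <- evterm_new
      state$loglik <- state$loglik + dll
      accepted[i] <- TRUE
    }
  }
  list(state = state, accepted = accepted)
}

#' Gibbs update of the inclusion indicators
#'
#' Draws each `gamma_i` independently from its Bernoulli full conditional
#' [gamma_conditional()] given the current `beta_i`.
#'
#' @inheritParams update_beta
#' @return The updated state.
#' @export
update_gamma <- function(state, model, tau_scale = 1) {
  tau <- model$tau * tau_scale
  for (i in seq_len(model$p)) {
    u <- runif(1)
    pi <- model$pi[i]
    if (pi <= 0) { state$gamma[i] <- 0L; next }
    if (pi >= 1) { state$gamma[i] <- 1L; next }
    la <- dnorm(state$beta[i], 0, model$cb * tau, log = TRUE) + log(pi)
    lb <- dnorm(state$beta[i], 0, tau, log = TRUE) + log1p(-pi)
    state$gamma[i] <- as.integer(u < 1 / (1 + exp(lb - la)))
  }
  state
}

#' Metropolis-within-Gibbs update of the interval hazards
#'
#' Each `h_j` is proposed from the near-conjugate gamma with shape
#' `alpha_increment_j + d_j` (`d_j` = events in interval `j`) and rate
#' `c0 + sum_{l in R_j \ D_j} exp(x_l'beta)` — the full conditional under
#' the linearization `1 - exp(-h e) ~ h e` of the event factors — and
#' accepted with the Metropolis-Hastings ratio
#' `prod_{events in j} [(1 - e^{-h' e}) / h'] / [(1 - e^{-h e}) / h]`
#' that restores the exact grouped-likelihood target.  With many short
#' intervals `h_j e^{x'beta}` is small and essentially every proposal is
#' accepted; with no events in the interval the gamma draw is exact.
#'
#' @inheritParams update_beta
#' @return The updated state (with likelihood caches refreshed).
#' @export
update_h <- function(state, model) {
  j <- model$interval
  ev <- model$is_event == 1L
  bucket <- vapply(seq_len(model$J), function(jj)
    sum(state$etheta[j == jj]), numeric(1))
  ebucket <- vapply(seq_len(model$J), function(jj)
    sum(state$etheta[ev & j == jj]), numeric(1))
  S <- rev(cumsum(rev(bucket))) - ebucket
  for (jj in seq_len(model$J)) {
    hprop <- rgamma(1, shape = model$aincr[jj] + model$d[jj],
                    rate = model$c0 + S[jj])
    u <- runif(1)
    if (hprop <= 0) hprop <- 1e-300
    if (model$d[jj] == 0) {
      state$h[jj] <- hprop
      next
    }
    el <- state$etheta[ev & j == jj]
    la <- -model$d[jj] * (log(hprop) - log(state$h[jj])) +
      sum(log1mexp(hprop * el) - log1mexp(state$h[jj] * el))
    if (is.finite(la) && log(u) < la) state$h[jj] <- hprop
  }
  refresh_likelihood(state, model)
}

#' Run one Gibbs chain of the spike-and-slab Cox sampler
#'
#' Iterates [update_beta()] (adaptive random-walk Metropolis-Hastings per
#' coordinate), [update_gamma()] (Bernoulli full conditionals) and
#' [update_h()] (gamma full conditionals), starting from the empty model.
#' Proposal scales adapt toward `config$adapt_target` during burn-in only.
#' The default `engine = "cpp"` runs the compiled sampler; `engine = "R"`
#' runs the pure-R kernels above through an identical random-number stream,
#' so both engines produce bit-identical chains for the same seed.
#'
#' @inheritParams mcmc_model
#' @param config A [chain_config()].
#' @param engine `"cpp"` (compiled, fast) or `"R"` (reference kernels).
#' @return Object of class `cox_ssvs_fit` with post-burn-in sample matrices
#'   `beta`, `gamma`, `h`, the log-likelihood trace, per-coordinate
#'   acceptance rates, the frozen proposal scales, and the model context.
#' @examples
#' \donttest{
#' sc <- make_scenario("sparse", seed = 1, n = 60, p = 20)
#' d <- simulate_survival_data(sc, seed = 2)
#' fit <- run_chain(d, uniform_selection_prior(20, 5),
#'                  chain_config(n_iter = 500, burn_in = 100, seed = 3))
#' summarize_selection(fit)$p_m
#' }
#' @export
run_chain <- function(data, selection, config = chain_config(),
                      spike = spike_slab_prior(), c0 = 2, baseline = NULL,
                      engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  model <- mcmc_model(data, selection, spike = spike, c0 = c0,
                      baseline = baseline)
  if (!is.null(config$seed)) set.seed(config$seed)
  raw <- if (engine == "cpp") {
    cpp_run_chain(model$X, model$interval, model$is_event, model$aincr,
                  model$c0, model$tau, model$cb, model$pi,
                  config$n_iter, config$burn_in, config$thin,
                  config$adapt_window, config$adapt_target,
                  config$init_scale, isTRUE(config$collapse))
  } else {
    r_run_chain(model, config)
  }
  new_fit(raw, model, config, engine)
}

# pure-R engine mirroring the compiled sampler's control flow and RNG usage
r_run_chain <- function(model, config) {
  state <- initial_state(model)
  scales <- rep(config$init_scale, model$p)
  acc <- integer(model$p)
  acc_post <- integer(model$p)
  n_keep <- (config$n_iter - config$burn_in) %/% config$thin
  beta_s <- matrix(0, n_keep, model$p)
  gam_s <- matrix(0L, n_keep, model$p)
  h_s <- matrix(0, n_keep, model$J)
  ll_s <- numeric(n_keep)
  kept <- 0L; batch <- 0L; n_post <- 0L
  for (it in seq_len(config$n_iter) - 1L) {
    ub <- update_beta(state, model, scales, collapse = isTRUE(config$collapse))
    state <- ub$state
    if (it < config$burn_in) acc <- acc + ub$accepted
    else acc_post <- acc_post + ub$accepted
    state <- update_gamma(state, model)
    state <- update_h(state, model)
    if (it < config$burn_in && (it + 1L) %% config$adapt_window == 0L) {
      batch <- batch + 1L
      delta <- min(0.25, 1 / sqrt(batch))
      scales <- scales * exp(delta * (acc / config$adapt_window -
                                        config$adapt_target))
      scales <- pmin(pmax(scales, 1e-6), 10)
      acc <- integer(model$p)
    }
    if (it >= config$burn_in) {
      n_post <- n_post + 1L
      if ((it - config$burn_in) %% config$thin == 0L && kept < n_keep) {
        kept <- kept + 1L
        beta_s[kept, ] <- state$beta
        gam_s[kept, ] <- state$gamma
        h_s[kept, ] <- state$h
        ll_s[kept] <- state$loglik
      }
    }
  }
  list(beta = beta_s, gamma = gam_s, h = h_s, loglik = ll_s,
       accept_rate = acc_post / max(1L, n_post), scales = scales)
}

new_fit <- function(raw, model, config, engine, swap = NULL, ladder = NULL) {
  colnames(raw$beta) <- model$feature_names
  colnames(raw$gamma) <- model$feature_names
  structure(list(beta = raw$beta, gamma = raw$gamma, h = raw$h,
                 loglik = as.numeric(raw$loglik),
                 accept_rate = as.numeric(raw$accept_rate),
                 scales = as.numeric(raw$scales),
                 partition = model$partition, baseline = model$baseline,
                 spike = model$spike, pi = model$pi, config = config,
                 engine = engine, n = model$n, p = model$p,
                 feature_names = model$feature_names,
                 n_chains = 1L, swap = swap, ladder = ladder),
            class = "cox_ssvs_fit")
}

#' @export
print.cox_ssvs_fit <- function(x, ...) {
  cat(sprintf("cox_ssvs_fit: %d stored samples (%d chain%s), p = %d, J = %d intervals\n",
              nrow(x$beta), x$n_chains, if (x$n_chains > 1) "s" else "",
              x$p, x$partition$J))
  cat(sprintf("  mean model size %.2f, mean beta acceptance %.2f\n",
              mean(rowSums(x$gamma)), mean(x$accept_rate)))
  if (!is.null(x$swap))
    cat(sprintf("  parallel tempering: swap acceptance %.1f%% (%d/%d)\n",
                100 * x$swap$rate, x$swap$accepts, x$swap$attempts))
  invisible(x)
}

#' Pool post-burn-in samples from several chains
#'
#' Concatenates stored samples, so pooled posterior means (e.g. inclusion
#' probabilities) are the sample-count-weighted means of the per-chain
#' estimates.
#'
#' @param fits List of `cox_ssvs_fit` objects with identical dimensions.
#' @return A single `cox_ssvs_fit` holding the pooled samples.
#' @export
combine_chains <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1),
                                          "cox_ssvs_fit")))
  ref <- fits[[1]]
  for (f in fits[-1]) {
    if (f$p != ref$p || ncol(f$h) != ncol(ref$h))
      stop("chains have mismatched dimensions and cannot be pooled")
  }
  wts <- vapply(fits, function(f) nrow(f$beta), numeric(1))
  out <- ref
  out$beta <- do.call(rbind, lapply(fits, `[[`, "beta"))
  out$gamma <- do.call(rbind, lapply(fits, `[[`, "gamma"))
  out$h <- do.call(rbind, lapply(fits, `[[`, "h"))
  out$loglik <- unlist(lapply(fits, `[[`, "loglik"), use.names = FALSE)
  out$accept_rate <- colSums(wts * do.call(rbind, lapply(fits, `[[`,
                                                         "accept_rate"))) / sum(wts)
  out$n_chains <- sum(vapply(fits, `[[`, integer(1), "n_chains"))
  out
}
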