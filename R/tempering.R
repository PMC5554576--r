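#' Log-linear temperature ladder for prior tempering
#'
#' Chain `ch` (for `ch = 0, ..., n_chains - 1`) runs at temperature
#' `base^ch`, which broadens its spike-and-slab prior by replacing `tau`
#' with `tau * base^ch` (the slab sd becomes `cb * tau * base^ch`).  Only
#' the prior is tempered; the grouped likelihood is shared by all chains.
#' Chain 0 is the untempered target.
#'
#' @param base Ladder ratio, `base >= 1`; `base = 1` makes all chains
#'   identical to the target.
#' @param n_chains Number of chains (>= 2).
#' @param swap_interval Iterations between swap attempts.
#' @return Object of class `temperature_ladder`.
#' @export
temperature_ladder <- function(base = 1.5, n_chains = 6, swap_interval = 10) {
  if (base < 1)
    stop("temperature base must be >= 1")
  stopifnot(n_chains >= 2, swap_interval >= 1)
  structure(list(base = base, n_chains = as.integer(n_chains),
                 temperatures = base^(seq_len(n_chains) - 1),
                 swap_interval = as.integer(swap_interval)),
            class = "temperature_ladder")
}

#' Metropolis swap probability between two tempered chains
#'
#' For chains with (un-normalized, prior-tempered) posterior densities `f`
#' and `g` at current states `theta1`, `theta2`, the probability of
#' accepting a state swap is
#' `min(1, f(theta2) g(theta1) / (f(theta1) g(theta2)))`,
#' computed in log space.
#'
#' @param logf1,logf2 `log f` at the first and second chain's state.
#' @param logg1,logg2 `log g` at the first and second chain's state.
#' @return A probability.
#' @export
swap_probability <- function(logf1, logf2, logg1, logg2) {
  min(1, exp((logf2 - logf1) + (logg1 - logg2)))
}

#' Run the prior-tempered parallel tempering sampler
#'
#' Runs `ladder$n_chains` Gibbs chains in lockstep, chain `ch` using
#' spike-and-slab parameter `tau * base^ch`.  Every `swap_interval`
#' iterations, a uniformly random adjacent pair is proposed to exchange
#' complete states `(beta, gamma, h)` and accepted per
#' [swap_probability()]; since all chains share the likelihood and the
#' gamma/h priors, the swap ratio reduces to the spike-and-slab prior log
#' densities at the two states.  Only the untempered chain's samples are
#' stored.
#'
#' @inheritParams run_chain
#' @param ladder A [temperature_ladder()].
#' @return A `cox_ssvs_fit` for the untempered chain, with `$swap`
#'   containing the overall swap attempt/acceptance counts and rate.
#' @export
run_parallel_tempering <- function(data, selection, config = chain_config(),
                                   ladder = temperature_ladder(),
                                   spike = spike_slab_prior(), c0 = 2,
                                   baseline = NULL) {
  model <- mcmc_model(data, selection, spike = spike, c0 = c0,
                      baseline = baseline)
  if (!is.null(config$seed)) set.seed(config$seed)
  raw <- cpp_run_pt(model$X, model$interval, model$is_event, model$aincr,
                    model$c0, model$tau, model$cb, model$pi,
                    config$n_iter, config$burn_in, config$thin,
                    config$adapt_window, config$adapt_target,
                    config$init_scale, isTRUE(config$collapse),
                    ladder$temperatures, ladder$swap_interval)
  swap <- list(attempts = as.integer(raw$swap_attempts),
               accepts = as.integer(raw$swap_accepts),
               rate = if (raw$swap_attempts > 0)
                 raw$swap_accepts / raw$swap_attempts else NA_real_)
  new_fit(raw, model, config, engine = "cpp", swap = swap, ladder = ladder)
}

#' Tune the temperature base by short pilot runs
#'
#' The swap acceptance rate decreases monotonically in the ladder ratio
#' `base`.  Each pilot run measures the post-burn-in swap rate; the next
#' candidate rescales the ladder spacing by the Gaussian heuristic
#' `base - 1 -> (base - 1) * sqrt(log target / log rate)` (the swap
#' log-ratio's spread grows linearly in `base - 1`, so its rejection
#' exponent grows quadratically), with bracketing as a safety net, until
#' the rate falls in `accept_window` — the upper half of the 20-50% band
#' recommended for parallel tempering.
#'
#' @inheritParams run_parallel_tempering
#' @param pilot_iter Iterations of each pilot run.
#' @param accept_window Acceptable swap-acceptance range.
#' @param max_rounds Maximum number of pilot runs.
#' @return The tuned [temperature_ladder()], with attributes
#'   `pilot_rate` and `pilot_rounds`.
#' @export
tune_ladder <- function(data, selection, ladder = temperature_ladder(),
                        config = chain_config(), spike = spike_slab_prior(),
                        c0 = 2, pilot_iter = 2000,
                        accept_window = c(0.42, 0.52), max_rounds = 8) {
  base <- ladder$base
  lo <- NA_real_  # base giving too-high acceptance (spacing too tight)
  hi <- NA_real_  # base giving too-low acceptance
  rate <- NA_real_
  # a longer pilot tracks the reported overall rate better: the early
  # transient (chains still near their common start) accepts far more swaps
  # than the equilibrium regime and is diluted in longer runs
  pilot_cfg <- chain_config(n_iter = pilot_iter,
                            burn_in = pilot_iter %/% 2,
                            thin = max(1L, pilot_iter %/% 50),
                            seed = config$seed,
                            adapt_window = config$adapt_window,
                            adapt_target = config$adapt_target,
                            init_scale = config$init_scale)
  target <- mean(accept_window)
  for (round in seq_len(max_rounds)) {
    cand <- temperature_ladder(base, ladder$n_chains, ladder$swap_interval)
    pt <- run_parallel_tempering(data, selection, pilot_cfg, cand,
                                 spike = spike, c0 = c0)
    rate <- pt$swap$rate
    if (!is.na(rate) && rate >= accept_window[1] && rate <= accept_window[2])
      break
    if (is.na(rate) || rate > accept_window[2]) lo <- base else hi <- base
    r_cl <- min(max(rate, 1e-3, na.rm = TRUE), 0.99)
    fac <- sqrt(log(target) / log(r_cl))
    # below the window, force real progress toward base -> 1 (where the
    # rate provably approaches 1): the rate can be non-monotone in base
    # far from 1, which would otherwise stall the quadratic heuristic
    if (rate < accept_window[1]) fac <- min(fac, 0.6)
    guess <- 1 + (base - 1) * fac
    # keep the guess inside the known bracket
    if (!is.na(lo) && guess <= lo)
      guess <- if (is.na(hi)) 1 + (lo - 1) * 2 else 1 + sqrt((lo - 1) * (hi - 1))
    if (!is.na(hi) && guess >= hi)
      guess <- if (is.na(lo)) 1 + (hi - 1) / 2 else 1 + sqrt((lo - 1) * (hi - 1))
    base <- max(guess, 1 + 1e-6)
  }
  out <- temperature_ladder(base, ladder$n_chains, ladder$swap_interval)
  attr(out, "pilot_rate") <- rate
  attr(out, "pilot_rounds") <- round
  out
}
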