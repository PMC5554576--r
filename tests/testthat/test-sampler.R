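tiny_data <- function(n = 30, p = 5, seed = 17, beta = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  if (is.null(beta)) beta <- numeric(p)
  Ts <- simulate_event_times(X, beta, 0.05, 1.2)
  obs <- apply_censoring(Ts, a_max = 3 * stats::median(Ts), rate = 0)
  survival_dataset(obs$time, obs$status, X)
}

test_that("two runs with the same seed are identical; seeds matter", {
  d <- tiny_data()
  cfg <- chain_config(n_iter = 400, burn_in = 100, seed = 99)
  f1 <- run_chain(d, uniform_selection_prior(5, 2), cfg)
  f2 <- run_chain(d, uniform_selection_prior(5, 2), cfg)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$gamma, f2$gamma)
  expect_identical(f1$h, f2$h)
  cfg2 <- chain_config(n_iter = 400, burn_in = 100, seed = 100)
  f3 <- run_chain(d, uniform_selection_prior(5, 2), cfg2)
  expect_false(identical(f1$beta, f3$beta))
})

test_that("compiled and pure-R engines produce bit-identical chains", {
  d <- tiny_data(n = 25, p = 4)
  for (collapse in c(FALSE, TRUE)) {
    cfg <- chain_config(n_iter = 300, burn_in = 120, seed = 3,
                        collapse = collapse)
    fc <- run_chain(d, uniform_selection_prior(4, 2), cfg, engine = "cpp")
    fr <- run_chain(d, uniform_selection_prior(4, 2), cfg, engine = "R")
    expect_equal(fc$beta, fr$beta, tolerance = 1e-12)
    expect_equal(unname(fc$gamma), unname(fr$gamma),
                 ignore_attr = TRUE, tolerance = 0)
    expect_equal(fc$h, fr$h, tolerance = 1e-12)
    expect_equal(fc$loglik, fr$loglik, tolerance = 1e-9)
    expect_equal(fc$accept_rate, fr$accept_rate, tolerance = 1e-12)
    expect_equal(fc$scales, fr$scales, tolerance = 1e-12)
  }
})

test_that("stored log-likelihood equals full recomputation (incremental caches are exact)", {
  d <- tiny_data(n = 40, p = 6, beta = c(1, -1, rep(0, 4)))
  fit <- run_chain(d, uniform_selection_prior(6, 2),
                   chain_config(n_iter = 1000, burn_in = 0, seed = 8))
  for (k in c(1, 250, 500, 1000)) {
    expect_equal(fit$loglik[k],
                 grouped_log_likelihood(fit$beta[k, ], fit$h[k, ],
                                        fit$partition, d$X),
                 tolerance = 1e-10)
  }
})

test_that("with zero covariates the sampler reproduces the prior over gamma", {
  # X = 0 makes the likelihood flat in beta, so the stationary law of
  # (beta, gamma) is exactly the spike-and-slab prior: P(gamma_i = 1) = pi_i
  n <- 20
  set.seed(2)
  tm <- rexp(n, 0.1) + 0.5
  d <- survival_dataset(tm, rep(1, n), matrix(0, n, 8))
  pi <- rep(0.3, 8)
  fit <- run_chain(d, pi, chain_config(n_iter = 6000, burn_in = 500,
                                       seed = 31),
                   spike = spike_slab_prior(tau = 0.1, cb = 10))
  sizes <- rowSums(fit$gamma)
  se <- batch_se(sizes)
  expect_lt(abs(mean(sizes) - sum(pi)), 4 * se + 0.05)
  # beta second moment matches the mixture variance (1-pi) tau^2 + pi (cb tau)^2
  v_target <- 0.7 * 0.1^2 + 0.3 * 1^2
  expect_equal(mean(fit$beta^2), v_target, tolerance = 0.15)
})

test_that("gamma sweep long-run on-fraction matches the closed-form conditional at beta = 0", {
  n <- 10
  d <- survival_dataset(1:10, rep(1, n), matrix(0, n, 3))
  model <- mcmc_model(d, rep(0.5, 3))
  state <- initial_state(model)      # beta = 0
  set.seed(5)
  draws <- replicate(3000, sum(update_gamma(state, model)$gamma))
  expect_equal(mean(draws) / 3, 1 / 21, tolerance = 0.012)
})

test_that("hazard update targets the exact interval conditional", {
  # one interval, one event, three censored at-risk subjects, beta = 0,
  # alpha-increment 0.5, c0 = 2.  The near-conjugate proposal is
  # Gamma(shape 1.5, rate 5) (mean 0.3); the exact conditional is
  # proportional to Gamma(h; 0.5, rate 2) * exp(-3h) * (1 - exp(-h)),
  # whose mean a quadrature oracle puts slightly below 0.3.
  d <- survival_dataset(c(1, 0.5, 0.6, 0.7), c(1, 0, 0, 0),
                        matrix(0, 4, 1))
  part <- partition_time_axis(d$time, d$status)
  bp <- baseline_prior(part, d$time, d$status, c0 = 2,
                       eta0 = 0.125, kappa0 = 1)
  expect_equal(bp$alpha_increments, 0.5)
  model <- mcmc_model(d, 0.5, c0 = 2, baseline = bp)
  state <- initial_state(model)
  dens <- function(h) dgamma(h, 0.5, rate = 2) * exp(-3 * h) * (1 - exp(-h))
  z <- integrate(dens, 0, Inf)$value
  oracle_mean <- integrate(function(h) h * dens(h), 0, Inf)$value / z
  expect_lt(oracle_mean, 1.5 / 5)     # correction pulls below the proposal mean
  set.seed(6)
  hs <- numeric(4000)
  for (k in seq_along(hs)) {          # iterate: single MH steps are a chain
    state <- update_h(state, model)
    hs[k] <- state$h[1]
  }
  expect_equal(mean(hs[-(1:200)]), oracle_mean, tolerance = 0.05)
})

test_that("an event-free interval draws its hazard from the conjugate gamma", {
  # censoring beyond the last event creates a second, event-free interval:
  # there the gamma draw is exact with rate c0 + (at-risk exp(x'beta))
  d <- survival_dataset(c(1, 5), c(1, 0), matrix(0, 2, 1))
  part <- partition_time_axis(d$time, d$status)
  expect_equal(part$J, 2L)
  expect_equal(part$d, c(1L, 0L))
  bp <- baseline_prior(part, d$time, d$status, c0 = 2, eta0 = 0.3, kappa0 = 1)
  model <- mcmc_model(d, 0.5, c0 = 2, baseline = bp)
  state <- initial_state(model)
  set.seed(7)
  hs <- replicate(4000, update_h(state, model)$h[2])
  a2 <- bp$alpha_increments[2]
  expect_equal(mean(hs), a2 / 3, tolerance = 0.03)   # shape a2, rate c0 + 1
  expect_equal(var(hs), a2 / 9, tolerance = 0.05)
})

test_that("vanishing proposal scale accepts everything and freezes the chain", {
  d <- tiny_data(n = 20, p = 3)
  fit <- run_chain(d, uniform_selection_prior(3, 1),
                   chain_config(n_iter = 300, burn_in = 0, seed = 4,
                                init_scale = 1e-9))
  expect_true(all(fit$accept_rate > 0.999))
  expect_lt(max(abs(fit$beta)), 1e-6)
})

test_that("adapted acceptance rates settle near the target", {
  d <- tiny_data(n = 60, p = 20, seed = 5,
                 beta = c(0.8, -0.8, rep(0, 18)))
  fit <- run_chain(d, uniform_selection_prior(20, 4),
                   chain_config(n_iter = 4000, burn_in = 2500, seed = 21))
  expect_true(all(fit$accept_rate >= 0.2 & fit$accept_rate <= 0.6))
})

test_that("tiny-model posterior inclusion matches enumeration + quadrature", {
  # p = 2 with tied event times (few intervals); the oracle enumerates
  # gamma, integrates h in closed form and beta on a 2-D grid
  set.seed(12)
  n <- 14
  X <- cbind(rnorm(n), rnorm(n))
  tm <- sample(c(1, 2, 3), n, replace = TRUE) +
    rep(0, n)                        # heavy ties -> J = 3
  st <- rbinom(n, 1, 0.8)
  if (!any(st == 1)) st[1] <- 1
  lp <- 0.9 * X[, 1] - 0.3 * X[, 2]
  # reorder times so that larger risk dies earlier (injects real signal)
  tm <- tm[order(order(-lp))]
  d <- survival_dataset(tm, st, X)
  part <- partition_time_axis(d$time, d$status)
  spike <- spike_slab_prior(tau = 0.15, cb = 6)
  bp <- baseline_prior(part, d$time, d$status, c0 = 2)
  pi <- c(0.4, 0.4)
  oracle <- enumerate_gamma_posterior(d, pi, spike, bp$alpha_increments, 2)
  # both kernel variants (conditional-on-gamma and indicator-collapsed)
  # target the same posterior
  for (collapse in c(FALSE, TRUE)) {
    fit <- run_chain(d, pi, chain_config(n_iter = 12000, burn_in = 2000,
                                         seed = 77, collapse = collapse),
                     spike = spike, c0 = 2, baseline = bp)
    for (i in 1:2) {
      est <- mean(fit$gamma[, i])
      se <- batch_se(fit$gamma[, i])
      expect_lt(abs(est - oracle$marginal[i]), 3 * se + 0.02)
    }
  }
  # oracle sanity: probabilities over the four models sum to one
  expect_equal(sum(oracle$prob), 1, tolerance = 1e-12)
})

test_that("one-variable posterior mean matches a grid quadrature oracle", {
  set.seed(30)
  n <- 100
  X <- matrix(rnorm(n), n, 1)
  Ts <- simulate_event_times(X, 0.9, 0.05, 1.2)
  d <- survival_dataset(Ts, rep(1, n), X)
  part <- partition_time_axis(d$time, d$status)
  spike <- spike_slab_prior(tau = 0.1, cb = 8)
  bp <- baseline_prior(part, d$time, d$status, c0 = 2)
  grid <- seq(-1.5, 2.5, length.out = 301)
  ll <- vapply(grid, function(b)
    hmarg_loglik(b, part, X, bp$alpha_increments, 2), numeric(1))
  pr <- vapply(grid, function(b) {
    la <- log(0.5) + dnorm(b, 0, 0.8, log = TRUE)
    lb <- log(0.5) + dnorm(b, 0, 0.1, log = TRUE)
    m <- max(la, lb); m + log(exp(la - m) + exp(lb - m))
  }, numeric(1))
  w <- exp(ll + pr - max(ll + pr)); w <- w / sum(w)
  oracle_mean <- sum(grid * w)
  fit <- run_chain(d, 0.5, chain_config(n_iter = 12000, burn_in = 2000,
                                        seed = 41),
                   spike = spike, c0 = 2, baseline = bp)
  est <- mean(fit$beta[, 1])
  se <- batch_se(fit$beta[, 1])
  expect_lt(abs(est - oracle_mean), 3 * se + 0.02)
})

test_that("chain pooling averages by sample count", {
  d <- tiny_data(n = 25, p = 4)
  f1 <- run_chain(d, uniform_selection_prior(4, 2),
                  chain_config(n_iter = 300, burn_in = 100, seed = 1))
  f2 <- run_chain(d, uniform_selection_prior(4, 2),
                  chain_config(n_iter = 300, burn_in = 100, seed = 2))
  pooled <- combine_chains(list(f1, f2))
  expect_equal(nrow(pooled$beta), 400)
  expect_equal(colMeans(pooled$gamma),
               (colMeans(f1$gamma) + colMeans(f2$gamma)) / 2)
  # pooling a chain with itself changes no posterior mean
  same <- combine_chains(list(f1, f1))
  expect_equal(colMeans(same$beta), colMeans(f1$beta))
  expect_equal(same$n_chains, 2L)
  # dimension mismatch is refused
  d6 <- tiny_data(n = 25, p = 6)
  f6 <- run_chain(d6, uniform_selection_prior(6, 2),
                  chain_config(n_iter = 300, burn_in = 100, seed = 1))
  expect_error(combine_chains(list(f1, f6)), "mismatch")
})
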