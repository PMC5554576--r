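# Independent oracles used across the test files.  These deliberately avoid
# the package's own computational paths: the likelihood oracle multiplies
# the plain product formula term by term, and the marginal oracle
# integrates the interval hazards out of the grouped likelihood in closed
# form (subset expansion of the event product against the gamma prior).

# direct product-form grouped likelihood, no log-space tricks
naive_grouped_loglik <- function(beta, h, partition, X) {
  e <- exp(as.vector(as.matrix(X) %*% beta))
  total <- 1
  for (j in seq_len(partition$J)) {
    Rj <- partition$risk_sets[[j]]
    Dj <- partition$event_sets[[j]]
    at_risk_only <- setdiff(Rj, Dj)
    term <- exp(-h[j] * sum(e[at_risk_only]))
    for (xi in Dj) term <- term * (1 - exp(-h[j] * e[xi]))
    total <- total * term
  }
  log(total)
}

# log of the grouped likelihood with each h_j integrated out against its
# Gamma(aincr_j, rate c0) prior:
#   I_j = sum over subsets s of D_j of (-1)^|s| (c0 / (c0 + S_j + E_s))^a_j
# where S_j is the at-risk-only sum of exp(x'beta) and E_s the subset sum.
hmarg_loglik <- function(beta, partition, X, aincr, c0) {
  e <- exp(as.vector(as.matrix(X) %*% beta))
  out <- 0
  for (j in seq_len(partition$J)) {
    Rj <- partition$risk_sets[[j]]
    Dj <- partition$event_sets[[j]]
    S <- sum(e[setdiff(Rj, Dj)])
    Ij <- 0
    nd <- length(Dj)
    for (mask in 0:(2^nd - 1)) {
      s <- Dj[bitwAnd(mask, 2^(seq_len(nd) - 1)) > 0]
      Ij <- Ij + (-1)^length(s) * (c0 / (c0 + S + sum(e[s])))^aincr[j]
    }
    # I_j > 0 mathematically; guard against catastrophic cancellation at
    # extreme beta where the posterior mass is negligible anyway
    out <- out + log(max(Ij, 1e-300))
  }
  out
}

# exhaustive posterior over gamma for p <= 2: enumerate gamma, integrate
# beta on a grid against the h-marginalized likelihood
enumerate_gamma_posterior <- function(data, pi, spike, aincr, c0,
                                      grid = seq(-3, 3, length.out = 161)) {
  partition <- partition_time_axis(data$time, data$status)
  p <- ncol(data$X)
  stopifnot(p <= 2)
  combos <- as.matrix(expand.grid(rep(list(0:1), p)))
  dx <- diff(grid)[1]
  post <- numeric(nrow(combos))
  bgrid <- as.matrix(expand.grid(rep(list(grid), p)))
  ll <- apply(bgrid, 1, function(b)
    hmarg_loglik(b, partition, data$X, aincr, c0))
  for (k in seq_len(nrow(combos))) {
    g <- combos[k, ]
    sd_g <- ifelse(g == 1, spike$cb * spike$tau, spike$tau)
    lprior <- rowSums(vapply(seq_len(p), function(i)
      dnorm(bgrid[, i], 0, sd_g[i], log = TRUE), numeric(nrow(bgrid))))
    lpg <- sum(ifelse(g == 1, log(pi), log1p(-pi)))
    mx <- max(ll + lprior)
    post[k] <- exp(lpg + mx) * sum(exp(ll + lprior - mx)) * dx^p
  }
  post <- post / sum(post)
  list(combos = combos, prob = post,
       marginal = vapply(seq_len(p), function(i)
         sum(post[combos[, i] == 1]), numeric(1)))
}

# Monte-Carlo standard error of a posterior-mean estimate from an
# autocorrelated 0/1 (or real) series, via the package-independent batch
# means method
batch_se <- function(x, n_batch = 30) {
  n <- length(x)
  b <- floor(n / n_batch)
  m <- vapply(seq_len(n_batch), function(k) mean(x[((k - 1) * b + 1):(k * b)]),
              numeric(1))
  sd(m) / sqrt(n_batch)
}
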