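#' Construct a right-censored survival dataset
#'
#' Bundles observed times, event indicators and a numeric covariate matrix
#' into the container used throughout the package.
#'
#' @param time Nonnegative event/censoring times, one per subject.
#' @param status Event indicators, strictly coded 0 (censored) / 1 (event).
#' @param X Numeric covariate matrix, one row per subject.  Column names are
#'   used as feature names (generated if absent).
#' @param ids Optional sample identifiers; defaults to `"S1"`, `"S2"`, ...
#' @return An object of class `survival_dataset` with elements `ids`, `time`,
#'   `status` and `X`.
#' @examples
#' d <- survival_dataset(c(2, 5, 3), c(1, 0, 1), matrix(rnorm(6), 3))
#' d$status
#' @export
survival_dataset <- function(time, status, X, ids = NULL) {
  time <- as.numeric(time)
  status <- as.numeric(status)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- length(time)
  if (length(status) != n)
    stop("'time' and 'status' must have equal length")
  if (nrow(X) != n)
    stop("covariate matrix must have one row per subject")
  if (anyNA(time) || any(time < 0))
    stop("times must be nonnegative and non-missing")
  if (anyNA(status) || !all(status %in% c(0, 1)))
    stop("status must be coded 0/1 with no missing values")
  if (anyNA(X))
    stop("covariate matrix must not contain missing values")
  if (is.null(colnames(X)))
    colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (is.null(ids))
    ids <- paste0("S", seq_len(n))
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("sample ids must be unique")
  rownames(X) <- ids
  structure(list(ids = ids, time = time, status = status, X = X),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("survival_dataset: %d subjects, %d features, %d events (%.0f%% censored)\n",
              length(x$time), ncol(x$X), sum(x$status),
              100 * mean(x$status == 0)))
  invisible(x)
}

# subset rows of a survival_dataset
dataset_subset <- function(data, idx) {
  survival_dataset(data$time[idx], data$status[idx],
                   data$X[idx, , drop = FALSE], ids = data$ids[idx])
}

#' Partition the time axis at the event times
#'
#' Breakpoints are placed at the distinct event times except the largest; the
#' final interval is chosen so that the last event lies at its midpoint,
#' i.e. `s_J = s_{J-1} + 2 * (t_max_event - s_{J-1})`.  Intervals are
#' half-open `(s_{j-1}, s_j]`: subject `l` is at risk in interval `j` iff
#' `t_l > s_{j-1}`, and is an event there iff additionally
#' `delta_l = 1` and `t_l <= s_j`.  If a censoring time exceeds the last
#' break, one additional event-free interval is appended past the largest
#' observed time so every subject falls in exactly one interval.
#'
#' @param times Observed times.
#' @param status 0/1 event indicators; at least one event is required.
#' @return An object of class `time_partition` with elements `breaks`
#'   (`s_0 = 0, ..., s_J`), `J`, `interval` (index of the interval containing
#'   each subject's time), `is_event`, `risk_sets`, `event_sets` and `d`
#'   (events per interval).
#' @examples
#' partition_time_axis(c(1, 2), c(1, 1))$breaks  # 0 1 3
#' @export
partition_time_axis <- function(times, status) {
  times <- as.numeric(times)
  status <- as.numeric(status)
  if (any(times <= 0))
    stop("all observed times must be positive")
  if (!any(status == 1))
    stop("cannot partition without events")
  ev <- sort(unique(times[status == 1]))
  t_last <- ev[length(ev)]
  inner <- ev[-length(ev)]
  s_prev <- if (length(inner)) inner[length(inner)] else 0
  s_J <- s_prev + 2 * (t_last - s_prev)
  breaks <- c(0, inner, s_J)
  t_max <- max(times)
  if (t_max >= s_J)                       # censoring beyond the last event:
    breaks <- c(breaks,                   # add one event-free tail interval
                t_max * (1 + 1e-9) + .Machine$double.eps)
  J <- length(breaks) - 1L
  interval <- findInterval(times, breaks, left.open = TRUE)
  stopifnot(all(interval >= 1L), all(interval <= J))
  risk_sets <- lapply(seq_len(J), function(j) which(times > breaks[j]))
  event_sets <- lapply(seq_len(J), function(j)
    which(status == 1 & interval == j))
  structure(list(breaks = breaks, J = J, interval = interval,
                 is_event = as.integer(status == 1),
                 risk_sets = risk_sets, event_sets = event_sets,
                 d = vapply(event_sets, length, integer(1))),
            class = "time_partition")
}

#' Grouped-data log-likelihood of the semiparametric Cox model
#'
#' Evaluates the log of the grouped survival likelihood
#' `prod_j exp(-h_j * sum_{l in R_j \ D_j} e^{x_l'beta}) *
#'  prod_{l in D_j} (1 - exp(-h_j e^{x_l'beta}))`
#' where `R_j` / `D_j` are the risk and event sets of interval `j` and `h_j`
#' the interval hazard increments.  Computed in log space with
#' `log1p`/`expm1` so small `h_j` do not underflow.
#'
#' @param beta Coefficient vector (length `ncol(X)`).
#' @param h Positive interval hazard increments (length `partition$J`).
#' @param partition A [partition_time_axis()] result.
#' @param X Covariate matrix whose rows match the subjects used to build
#'   `partition`.
#' @return The log-likelihood (a finite scalar whenever all `h_j > 0` and the
#'   linear predictor does not overflow).
#' @export
grouped_log_likelihood <- function(beta, h, partition, X) {
  if (length(h) != partition$J)
    stop("'h' must have one element per interval")
  if (any(h <= 0))
    stop("all interval hazards h_j must be positive")
  X <- as.matrix(X)
  if (ncol(X) != length(beta))
    stop("length(beta) must equal ncol(X)")
  theta <- as.vector(X %*% beta)
  e <- exp(theta)
  H <- c(0, cumsum(h))
  j <- partition$interval
  ev <- partition$is_event == 1L
  # cumulative hazard while at risk, excluding own event interval for events
  A <- H[j] + ifelse(ev, 0, h[j])
  sum(-A * e) + sum(log1mexp(h[j[ev]] * e[ev]))
}

#' Nelson-Aalen estimator of the cumulative hazard
#'
#' @param times Observed times.
#' @param status 0/1 event indicators.
#' @return A right-continuous step function `H(t) = sum_{event times u <= t}
#'   d_u / n_u` (identically zero when there are no events), with the jump
#'   locations available through [stats::knots()].
#' @examples
#' H <- nelson_aalen(c(1, 2, 3), c(1, 1, 0))
#' H(2)  # 1/3 + 1/2
#' @export
nelson_aalen <- function(times, status) {
  times <- as.numeric(times)
  status <- as.numeric(status)
  u <- sort(unique(times[status == 1]))
  if (!length(u)) {
    f <- function(t) rep(0, length(t))
    return(structure(f, class = c("nelson_aalen", "function")))
  }
  d <- vapply(u, function(t) sum(times == t & status == 1), numeric(1))
  n_risk <- vapply(u, function(t) sum(times >= t), numeric(1))
  H <- cumsum(d / n_risk)
  structure(stats::stepfun(u, c(0, H)),
            class = c("nelson_aalen", "stepfun", "function"))
}

#' Calibrate the Weibull initial cumulative hazard
#'
#' Chooses `(eta0, kappa0)` so that `H*(t) = eta0 * t^kappa0` tracks the
#' Nelson-Aalen estimate of the data: ordinary least squares of
#' `log H(t) = log eta0 + kappa0 log t` over the Nelson-Aalen jump points.
#'
#' @param times Observed times (at least two distinct event times).
#' @param status 0/1 event indicators.
#' @return Named vector `c(eta0, kappa0)`, both positive.
#' @seealso [weibull_loglog_fit()] for the regression on given points.
#' @export
fit_weibull_initial <- function(times, status) {
  H <- nelson_aalen(times, status)
  u <- stats::knots(H)
  if (length(u) < 2)
    stop("need at least two distinct event times to calibrate the Weibull hazard")
  weibull_loglog_fit(u, H(u))
}

#' Least-squares Weibull fit to cumulative-hazard points
#'
#' @param time Positive evaluation points.
#' @param cumhaz Positive cumulative-hazard values at `time`.
#' @return Named vector `c(eta0, kappa0)` from the ordinary least-squares fit
#'   of `log(cumhaz)` on `log(time)`.
#' @export
weibull_loglog_fit <- function(time, cumhaz) {
  if (length(time) < 2)
    stop("need at least two points")
  if (any(time <= 0) || any(cumhaz <= 0))
    stop("time and cumulative hazard must be positive")
  fit <- lsfit(log(time), log(cumhaz))
  kappa0 <- unname(fit$coefficients[2])
  eta0 <- exp(unname(fit$coefficients[1]))
  if (kappa0 <= 0)
    stop("calibrated Weibull shape is not positive; cumulative hazard must increase with time")
  c(eta0 = eta0, kappa0 = kappa0)
}

#' Gamma-process shape increments for the baseline hazard prior
#'
#' The cumulative shape is `alpha_{0j} = c0 * H*(s_j)` with
#' `H*(t) = eta0 * t^kappa0`, so the per-interval increment is
#' `c0 * eta0 * (s_j^kappa0 - s_{j-1}^kappa0)`.
#'
#' @param partition A [partition_time_axis()] result.
#' @param eta0,kappa0 Positive Weibull parameters of `H*`.
#' @param c0 Positive confidence weight attached to the initial guess.
#' @return Vector of `partition$J` strictly positive increments that
#'   telescope to `c0 * H*(s_J)`.
#' @export
alpha_increments <- function(partition, eta0, kappa0, c0) {
  stopifnot(c0 > 0, eta0 > 0, kappa0 > 0)
  diff(c0 * eta0 * partition$breaks^kappa0)
}

#' Baseline hazard prior calibrated from the data
#'
#' Convenience wrapper: Nelson-Aalen estimate, Weibull log-log calibration
#' and the gamma-process shape increments for a given partition.
#'
#' @inheritParams alpha_increments
#' @param times,status The survival data used for calibration.
#' @param eta0,kappa0 Optional fixed Weibull parameters; calibrated from the
#'   data when `NULL`.
#' @return Object of class `baseline_prior` with elements `c0`, `eta0`,
#'   `kappa0` and `alpha_increments`.
#' @export
baseline_prior <- function(partition, times, status, c0 = 2,
                           eta0 = NULL, kappa0 = NULL) {
  if (is.null(eta0) || is.null(kappa0)) {
    wb <- fit_weibull_initial(times, status)
    eta0 <- wb[["eta0"]]
    kappa0 <- wb[["kappa0"]]
  }
  structure(list(c0 = c0, eta0 = eta0, kappa0 = kappa0,
                 alpha_increments = alpha_increments(partition, eta0, kappa0, c0)),
            class = "baseline_prior")
}
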