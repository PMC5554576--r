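#' Posterior selection summary
#'
#' Computes per-feature posterior inclusion probabilities (column means of
#' the stored `gamma`), the mean model size `p_m` (rounded average number of
#' included variables per iteration) and the top model: the `p_m` variables
#' with the highest inclusion probability, ties broken by lower index.
#'
#' @param fit A `cox_ssvs_fit` (possibly pooled via [combine_chains()]), or
#'   a list with matrices `gamma` and `beta`.
#' @return Object of class `selection_summary` with `inclusion_probs`,
#'   `p_m`, `selected` (sorted indices), `beta_mean`, `beta_sd` and
#'   `feature_names`.
#' @export
summarize_selection <- function(fit) {
  gamma <- fit$gamma
  beta <- fit$beta
  stopifnot(is.matrix(gamma), nrow(gamma) >= 1)
  inc <- colMeans(gamma)
  p_m <- as.integer(round(mean(rowSums(gamma))))
  selected <- if (p_m > 0)
    sort(order(-inc, seq_along(inc))[seq_len(p_m)]) else integer(0)
  structure(list(inclusion_probs = inc, p_m = p_m, selected = selected,
                 beta_mean = colMeans(beta), beta_sd = apply(beta, 2, sd),
                 feature_names = colnames(beta)),
            class = "selection_summary")
}

#' @export
print.selection_summary <- function(x, ...) {
  cat(sprintf("selection_summary: p_m = %d of %d variables selected\n",
              x$p_m, length(x$inclusion_probs)))
  if (x$p_m > 0) {
    nm <- if (!is.null(x$feature_names)) x$feature_names[x$selected]
          else as.character(x$selected)
    cat("  top model:", paste(sprintf("%s (%.2f)", nm,
                                      x$inclusion_probs[x$selected]),
                              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Selection summary as a data frame
#'
#' @param summary A [summarize_selection()] result.
#' @return Data frame with columns `feature`, `inclusion_prob`, `beta_mean`,
#'   `beta_sd`, `selected`.
#' @export
selection_table <- function(summary) {
  data.frame(feature = summary$feature_names %||%
               as.character(seq_along(summary$inclusion_probs)),
             inclusion_prob = summary$inclusion_probs,
             beta_mean = summary$beta_mean, beta_sd = summary$beta_sd,
             selected = seq_along(summary$inclusion_probs) %in%
               summary$selected,
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Confusion counts of a selected variable set against the truth
#'
#' @param selected Indices of selected variables.
#' @param truth Indices of the true predictors.
#' @param p Total number of variables.
#' @return Named vector `c(tp, fn, fp, tn)`; `tp + fn = length(truth)` and
#'   the four counts sum to `p`.
#' @export
confusion_counts <- function(selected, truth, p) {
  selected <- unique(as.integer(selected))
  truth <- unique(as.integer(truth))
  stopifnot(all(selected >= 1 & selected <= p),
            all(truth >= 1 & truth <= p))
  tp <- length(intersect(selected, truth))
  c(tp = tp, fn = length(truth) - tp, fp = length(selected) - tp,
    tn = p - length(union(selected, truth)))
}

#' Predicted survival curves from the selected model
#'
#' Plug-in predictor: `S(t | x) = exp(-H0(t) * exp(x_sel' beta_sel))`, where
#' `H0` is the step cumulative sum of the posterior-mean interval hazards
#' and `beta_sel` the posterior means restricted to the selected variables
#' (all others set to zero).  With `mode = "refit"`, a short second chain is
#' run on the selected columns only (all forced into the model) and its
#' posterior means are used instead.
#'
#' @param fit The fitted `cox_ssvs_fit` (provides the hazard samples and
#'   partition; and the training data context for refitting).
#' @param summary Its [summarize_selection()].
#' @param X_new Covariate matrix of the subjects to predict (same columns as
#'   the training data).
#' @param mode `"plugin"` (default) or `"refit"`.
#' @param train_data Training [survival_dataset()], required for
#'   `mode = "refit"`.
#' @param refit_config [chain_config()] for the refit chain.
#' @return Object of class `survival_prediction` with the break points, the
#'   baseline cumulative hazard steps, per-subject risk scores, and the
#'   linear predictor used.
#' @export
predict_survival <- function(fit, summary = summarize_selection(fit), X_new,
                             mode = c("plugin", "refit"), train_data = NULL,
                             refit_config = chain_config(n_iter = 5000,
                                                         burn_in = 1000)) {
  mode <- match.arg(mode)
  X_new <- as.matrix(X_new)
  stopifnot(ncol(X_new) == length(summary$beta_mean))
  if (mode == "plugin") {
    beta <- numeric(length(summary$beta_mean))
    beta[summary$selected] <- summary$beta_mean[summary$selected]
    h_mean <- colMeans(fit$h)
    breaks <- fit$partition$breaks
  } else {
    if (is.null(train_data))
      stop("mode = 'refit' needs the training dataset")
    if (length(summary$selected) > 0) {
      sub <- survival_dataset(train_data$time, train_data$status,
                              train_data$X[, summary$selected, drop = FALSE],
                              ids = train_data$ids)
      refit <- run_chain(sub, rep(1, length(summary$selected)),
                         refit_config, spike = fit$spike,
                         c0 = fit$baseline$c0)
      beta <- numeric(length(summary$beta_mean))
      beta[summary$selected] <- colMeans(refit$beta)
      h_mean <- colMeans(refit$h)
      breaks <- refit$partition$breaks
    } else {
      refit <- run_chain(train_data, rep(0, ncol(train_data$X)),
                         refit_config, spike = fit$spike,
                         c0 = fit$baseline$c0)
      beta <- numeric(length(summary$beta_mean))
      h_mean <- colMeans(refit$h)
      breaks <- refit$partition$breaks
    }
  }
  lp <- as.vector(X_new %*% beta)
  structure(list(breaks = breaks, H0 = cumsum(h_mean), lp = lp,
                 beta = beta, mode = mode, n = nrow(X_new)),
            class = "survival_prediction")
}

#' Evaluate predicted survival probabilities
#'
#' @param pred A [predict_survival()] result.
#' @param times Evaluation times.
#' @return `n x length(times)` matrix of survival probabilities; curves
#'   start at 1, are non-increasing, and are extrapolated flat beyond the
#'   last break (with a warning).
#' @export
surv_prob <- function(pred, times) {
  stopifnot(inherits(pred, "survival_prediction"), all(times >= 0))
  if (any(times > pred$breaks[length(pred$breaks)]))
    warning("evaluation beyond the last interval; curves extrapolated flat")
  H0 <- stats::stepfun(pred$breaks[-1], c(0, pred$H0))(times)
  exp(-outer(exp(pred$lp), H0))
}

# Kaplan-Meier estimate as a left-limit-capable step function
km_stepfun <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  kt <- sf$time[sf$n.event > 0]
  ks <- sf$surv[sf$n.event > 0]
  if (!length(kt))
    return(function(t, left = FALSE) rep(1, length(t)))
  f_right <- stats::stepfun(kt, c(1, ks))
  function(t, left = FALSE) {
    if (left) f_right(t - .Machine$double.eps^0.5 * pmax(1, abs(t))) else f_right(t)
  }
}

#' Censoring-weighted Brier score curve
#'
#' Graf-style Brier score with inverse-probability-of-censoring weights from
#' the Kaplan-Meier estimate of the censoring distribution on the test set:
#' at each grid time `t`, subjects with an observed event by `t` contribute
#' `S_hat(t|x)^2 / G(t_l-)`, subjects still under observation contribute
#' `(1 - S_hat(t|x))^2 / G(t)`, and subjects censored before `t` are
#' dropped (their mass is carried by the weights).  Terms whose censoring
#' weight is zero are dropped by convention.
#'
#' @param surv Matrix of predicted survival probabilities
#'   (`subjects x grid`), or a single predicted curve recycled for all
#'   subjects (length = `length(grid)`).
#' @param time,status Observed test times and 0/1 event indicators.
#' @param grid Evaluation times.
#' @return Data frame with columns `time` and `bs` (`BS(t) in [0, 1]`).
#' @export
brier_curve <- function(surv, time, status, grid) {
  n <- length(time)
  stopifnot(length(status) == n, all(status %in% c(0, 1)), all(grid >= 0))
  if (is.vector(surv))
    surv <- matrix(surv, n, length(grid), byrow = TRUE)
  stopifnot(nrow(surv) == n, ncol(surv) == length(grid))
  G <- km_stepfun(time, 1 - status)     # censoring distribution
  Gt <- G(grid)
  Gtl <- G(time, left = TRUE)
  bs <- vapply(seq_along(grid), function(k) {
    t <- grid[k]
    died <- time <= t & status == 1
    alive <- time > t
    w_died <- ifelse(died & Gtl > 0, 1 / Gtl, 0)
    w_alive <- if (Gt[k] > 0) 1 / Gt[k] else 0
    sum(w_died[died] * surv[died, k]^2) / n +
      sum(w_alive * (1 - surv[alive, k])^2) / n
  }, numeric(1))
  data.frame(time = grid, bs = bs)
}

#' Integrated Brier score
#'
#' Time average `(1 / t_max) * integral_0^t_max BS(t) dt` by the trapezoid
#' rule on the curve's grid.
#'
#' @param bs A [brier_curve()] data frame (or any with columns `time`,
#'   `bs`).
#' @param t_max Upper integration limit; the curve is extended flat from its
#'   last grid point if needed.
#' @return The IBS, a number in `[0, 1]`.
#' @export
integrated_brier_score <- function(bs, t_max) {
  stopifnot(nrow(bs) >= 1, t_max > 0)
  t <- bs$time
  y <- bs$bs
  keep <- t <= t_max
  t <- t[keep]; y <- y[keep]
  if (!length(t))
    stop("empty evaluation grid below t_max")
  if (t[1] > 0) { t <- c(0, t); y <- c(y[1], y) }
  if (t[length(t)] < t_max) { t <- c(t, t_max); y <- c(y, y[length(y)]) }
  sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2) / t_max
}

#' Prediction-error evaluation against the Kaplan-Meier reference
#'
#' Computes the IPCW Brier-score curve and IBS on a test set for (a) the
#' selected-model predictor and (b) the covariate-free Kaplan-Meier curve of
#' the training data, on the grid of unique test event times up to `t_max`
#' plus the endpoints.
#'
#' @param fit A `cox_ssvs_fit` from the training data.
#' @param train Training [survival_dataset()] (for the reference curve).
#' @param test Test [survival_dataset()].
#' @param t_max Upper evaluation limit.
#' @param summary Optional precomputed [summarize_selection()].
#' @param mode Prediction mode passed to [predict_survival()].
#' @return Object of class `prediction_result`: the grid, both Brier curves
#'   and both IBS values.
#' @export
evaluate_prediction <- function(fit, train, test, t_max = 80,
                                summary = summarize_selection(fit),
                                mode = c("plugin", "refit")) {
  mode <- match.arg(mode)
  pred <- predict_survival(fit, summary, test$X, mode = mode,
                           train_data = train)
  grid <- sort(unique(c(0, test$time[test$status == 1 &
                                       test$time <= t_max], t_max)))
  sm <- suppressWarnings(surv_prob(pred, grid))
  bs_model <- brier_curve(sm, test$time, test$status, grid)
  km <- km_stepfun(train$time, train$status)
  bs_ref <- brier_curve(km(grid), test$time, test$status, grid)
  structure(list(grid = grid, bs_model = bs_model, bs_reference = bs_ref,
                 ibs_model = integrated_brier_score(bs_model, t_max),
                 ibs_reference = integrated_brier_score(bs_ref, t_max),
                 t_max = t_max, mode = mode),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("prediction_result (t_max = %g, %s): IBS model %.4f vs Kaplan-Meier reference %.4f\n",
              x$t_max, x$mode, x$ibs_model, x$ibs_reference))
  invisible(x)
}
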