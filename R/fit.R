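#' Deterministic model predictions for each trial (teacher-forced replay)
#'
#' Replays a participant's trial log under given learner parameters: for each
#' learning sequence the belief map starts uniform and is conditioned on the
#' participant's *actual* executed actions and observed rewards for trials
#' 1..t-1 (decay then update); the prediction for trial t is the MAP of the
#' decayed map. Predictions are deterministic (`explore_sd` plays no role).
#' The first trial of each sequence has no prediction (`NA`); while the map
#' is still uniform (e.g. `kappa = 0`) the fallback prediction is the grid
#' center (0, 0).
#'
#' @param records trial-log data frame for one participant: columns
#'   `target_index`, `trial_index`, `executed_alpha`, `executed_beta`,
#'   `displayed_cents`. Trial indices must be contiguous from 1 within each
#'   target.
#' @param params a [learner_params] (uses `lam`, `w_alpha`, `w_beta`,
#'   `kappa`).
#' @param G belief-map resolution used for the replay.
#' @param max_cents per-trial reward maximum used to rescale displayed
#'   rewards to fractions.
#' @return Data frame with columns `target_index`, `trial_index`,
#'   `pred_alpha`, `pred_beta` aligned with `records` (sorted by target then
#'   trial).
#' @export
predict_next_actions <- function(records, params, G = 200, max_cents = 50) {
  records <- validate_sequences(records)
  pred <- replay_predict_cpp(records$target_index,
                             records$executed_alpha, records$executed_beta,
                             records$displayed_cents / max_cents,
                             params$lam, params$w_alpha, params$w_beta,
                             params$kappa, as.integer(G))
  data.frame(target_index = records$target_index,
             trial_index = records$trial_index,
             pred_alpha = pred[, 1L], pred_beta = pred[, 2L])
}

validate_sequences <- function(records) {
  needed <- c("target_index", "trial_index", "executed_alpha",
              "executed_beta", "displayed_cents")
  miss <- setdiff(needed, names(records))
  if (length(miss)) {
    stop("records missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if ("participant_id" %in% names(records) &&
      length(unique(records$participant_id)) > 1L) {
    stop("records must belong to a single participant; see fit_cohort()",
         call. = FALSE)
  }
  records <- records[order(records$target_index, records$trial_index), ,
                     drop = FALSE]
  bad <- tapply(records$trial_index, records$target_index,
                function(ti) !identical(as.integer(ti), seq_along(ti)))
  if (any(unlist(bad))) {
    stop("trial_index must be contiguous from 1 within each target",
         call. = FALSE)
  }
  records
}

#' Variance explained in trial-to-trial trajectory decisions
#'
#' Pooled two-dimensional coefficient of determination,
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}}, between predicted and observed
#' trial-to-trial change vectors \eqn{(\Delta\alpha, \Delta\beta)}. Sums of
#' squares pool both dimensions; `SS_tot` is taken about the per-dimension
#' mean observed change. Can be negative when predictions do worse than the
#' mean change.
#'
#' @param predicted,observed n x 2 matrices (or data frames) of paired change
#'   vectors, n >= 2.
#' @return A single fraction in \eqn{(-\infty, 1]}.
#' @export
#' @examples
#' obs <- cbind(c(0.1, -0.2, 0.3), c(0, 0.1, -0.1))
#' variance_explained(obs, obs)  # 1
variance_explained <- function(predicted, observed) {
  predicted <- as.matrix(predicted)
  observed <- as.matrix(observed)
  stopifnot(ncol(predicted) == 2L, ncol(observed) == 2L,
            nrow(predicted) == nrow(observed))
  ok <- stats::complete.cases(predicted) & stats::complete.cases(observed)
  predicted <- predicted[ok, , drop = FALSE]
  observed <- observed[ok, , drop = FALSE]
  if (nrow(observed) < 2L) {
    stop("need at least 2 complete change pairs", call. = FALSE)
  }
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum(sweep(observed, 2L, colMeans(observed))^2)
  1 - ss_res / ss_tot
}

# Trial-to-trial changes: observed a_t - a_{t-1} and predicted pred_t -
# a_{t-1}, for trials >= 2 of each sequence of a validated, ordered log.
trial_changes <- function(records, pred) {
  later <- records$trial_index > 1L
  prev <- which(later) - 1L
  obs <- cbind(records$executed_alpha[later] - records$executed_alpha[prev],
               records$executed_beta[later] - records$executed_beta[prev])
  prd <- cbind(pred$pred_alpha[later] - records$executed_alpha[prev],
               pred$pred_beta[later] - records$executed_beta[prev])
  colnames(obs) <- colnames(prd) <- c("d_alpha", "d_beta")
  list(observed = obs, predicted = prd)
}

#' Fit the 4-parameter Bayesian learner to one participant's trial log
#'
#' Estimates the learner's four free parameters — memory decay `lam`,
#' internal error weights `w_alpha` and `w_beta`, and learning rate `kappa`
#' — by minimizing the summed squared distance between the model's
#' deterministic next-action predictions (see [predict_next_actions()]) and
#' the participant's executed actions, over all learning sequences and
#' trials from the second onward. Exploration noise is not fitted; residual
#' action noise is absorbed by the loss.
#'
#' Optimization is multi-start Nelder-Mead on transformed parameters
#' (logit for `lam`, log for the rest): a coarse parameter grid is scored
#' first, local searches start from the best `n_starts` grid points, and the
#' best local solution is polished by a restart. Deterministic given data and
#' settings.
#'
#' @param records one participant's trial log (see [predict_next_actions()]
#'   for required columns).
#' @param G belief-map resolution used during fitting. 100 by default: the
#'   replay cost scales with G^2 and the action predictions are insensitive
#'   to resolution beyond the exploration noise scale (2/G = 0.02 at the
#'   default).
#' @param max_cents reward scaling, see [predict_next_actions()].
#' @param n_starts number of coarse-grid points used as local-search starts.
#' @param control passed to [stats::optim()] Nelder-Mead (default
#'   `maxit = 200`, `reltol = 1e-5`).
#' @param start_grid optional data frame of starting values with columns
#'   `lam`, `w_alpha`, `w_beta`, `kappa` replacing the built-in coarse grid.
#' @return An object of class `"learner_fit"`: a list with elements `params`
#'   (a [learner_params], `explore_sd = 0`), `loss`, `variance_explained`
#'   (pooled R^2 of trial-to-trial changes), `r2_by_dim`, `n_trials_used`,
#'   `diagnostics` (function evaluations, convergence flags, per-start
#'   losses), `predictions`, `records`, `G`, `max_cents`.
#' @seealso [predict.learner_fit()], [fit_cohort()], [variance_explained()]
#' @export
#' @examples
#' set.seed(42)
#' lp <- learner_params(0.4, 0.8, 0.2, 50, explore_sd = 0.05)
#' cfg <- reward_config("alpha")
#' recs <- do.call(rbind, lapply(1:6, function(i) {
#'   d <- simulate_sequence(sample_target(), cfg, lp, n_trials = 15, G = 40)
#'   d$target_index <- i
#'   d
#' }))
#' fit <- fit_learner(recs, G = 40, n_starts = 1,
#'                    control = list(maxit = 60))
#' coef(fit)
fit_learner <- function(records, G = 100, max_cents = 50, n_starts = 2,
                        control = list(), start_grid = NULL) {
  records <- validate_sequences(records)
  if (min(tapply(records$trial_index, records$target_index, length)) < 2L) {
    stop("each learning sequence needs at least 2 trials", call. = FALSE)
  }
  control <- utils::modifyList(list(maxit = 200, reltol = 1e-5), control)
  frac <- records$displayed_cents / max_cents
  later <- records$trial_index > 1L
  obs_a <- records$executed_alpha
  obs_b <- records$executed_beta
  Gi <- as.integer(G)

  objective <- function(th) {
    pred <- replay_predict_cpp(records$target_index, obs_a, obs_b, frac,
                               stats::plogis(th[1L]), exp(th[2L]),
                               exp(th[3L]), exp(th[4L]), Gi)
    sum((pred[later, 1L] - obs_a[later])^2 +
          (pred[later, 2L] - obs_b[later])^2)
  }

  if (is.null(start_grid)) {
    start_grid <- expand.grid(lam = c(0.2, 0.45, 0.7),
                              w_alpha = c(0.3, 0.7),
                              w_beta = c(0.3, 0.7),
                              kappa = c(15, 60))
  }
  to_theta <- function(g) c(stats::qlogis(min(max(g[["lam"]], 1e-4), 1 - 1e-4)),
                            log(g[["w_alpha"]]), log(g[["w_beta"]]),
                            log(g[["kappa"]]))
  grid_theta <- lapply(seq_len(nrow(start_grid)),
                       function(i) to_theta(start_grid[i, ]))
  grid_loss <- vapply(grid_theta, objective, numeric(1))
  starts <- order(grid_loss)[seq_len(min(n_starts, length(grid_theta)))]

  best <- NULL
  per_start <- numeric(0)
  evals <- length(grid_loss)
  for (i in starts) {
    o <- stats::optim(grid_theta[[i]], objective, method = "Nelder-Mead",
                      control = control)
    evals <- evals + o$counts[["function"]]
    per_start <- c(per_start, o$value)
    if (is.null(best) || o$value < best$value) best <- o
  }
  # polish: restart the simplex at the incumbent
  o <- stats::optim(best$par, objective, method = "Nelder-Mead",
                    control = control)
  evals <- evals + o$counts[["function"]]
  if (o$value < best$value) best <- o

  params <- learner_params(lam = stats::plogis(best$par[1L]),
                           w_alpha = exp(best$par[2L]),
                           w_beta = exp(best$par[3L]),
                           kappa = exp(best$par[4L]),
                           explore_sd = 0)
  pred <- predict_next_actions(records, params, G = G,
                               max_cents = max_cents)
  ch <- trial_changes(records, pred)
  r2 <- variance_explained(ch$predicted, ch$observed)
  r2_dim <- vapply(1:2, function(j) {
    1 - sum((ch$observed[, j] - ch$predicted[, j])^2) /
      sum((ch$observed[, j] - mean(ch$observed[, j]))^2)
  }, numeric(1))
  names(r2_dim) <- c("alpha", "beta")

  structure(list(params = params,
                 loss = best$value,
                 variance_explained = r2,
                 r2_by_dim = r2_dim,
                 n_trials_used = sum(later),
                 diagnostics = list(evals = evals,
                                    convergence = best$convergence,
                                    start_losses = per_start,
                                    grid_losses = grid_loss),
                 predictions = pred,
                 records = records,
                 G = G,
                 max_cents = max_cents,
                 call = match.call()),
            class = "learner_fit")
}

#' @export
print.learner_fit <- function(x, ...) {
  cat("Bayesian credit-assignment learner fit\n")
  cat(sprintf("  lam = %.3f, w_alpha = %.3f, w_beta = %.3f, kappa = %.2f\n",
              x$params$lam, x$params$w_alpha, x$params$w_beta,
              x$params$kappa))
  cat(sprintf("  loss (sum sq. action prediction error) = %.4g over %d trials\n",
              x$loss, x$n_trials_used))
  cat(sprintf("  variance explained in trial-to-trial changes = %.1f%%\n",
              100 * x$variance_explained))
  invisible(x)
}

#' @export
summary.learner_fit <- function(object, ...) {
  structure(list(coef = coef(object),
                 loss = object$loss,
                 variance_explained = object$variance_explained,
                 r2_by_dim = object$r2_by_dim,
                 n_trials_used = object$n_trials_used,
                 n_sequences = length(unique(object$records$target_index)),
                 diagnostics = object$diagnostics,
                 G = object$G),
            class = "summary.learner_fit")
}

#' @export
print.summary.learner_fit <- function(x, ...) {
  cat("Bayesian credit-assignment learner fit\n\n")
  cat("Parameters:\n")
  print(round(x$coef, 4))
  cat(sprintf("\n%d sequences, %d predicted trials, belief grid %d x %d\n",
              x$n_sequences, x$n_trials_used, x$G, x$G))
  cat(sprintf("Loss: %.4g   R2 (pooled changes): %.3f  [alpha %.3f, beta %.3f]\n",
              x$loss, x$variance_explained, x$r2_by_dim[["alpha"]],
              x$r2_by_dim[["beta"]]))
  cat(sprintf("Optimizer: %d evaluations, convergence flag %d\n",
              x$diagnostics$evals, x$diagnostics$convergence))
  invisible(x)
}

#' @export
coef.learner_fit <- function(object, ...) {
  c(lam = object$params$lam, w_alpha = object$params$w_alpha,
    w_beta = object$params$w_beta, kappa = object$params$kappa)
}

#' Predicted next actions from a fitted learner
#'
#' @param object a `"learner_fit"`.
#' @param newdata optional trial log to replay under the fitted parameters;
#'   defaults to the fitting data.
#' @param ... unused.
#' @return As [predict_next_actions()].
#' @export
predict.learner_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$predictions)
  predict_next_actions(newdata, object$params, G = object$G,
                       max_cents = object$max_cents)
}

#' @export
fitted.learner_fit <- function(object, ...) object$predictions

#' Action-prediction residuals
#'
#' Observed minus predicted executed parameters per trial (NA for the first
#' trial of each sequence).
#'
#' @param object a `"learner_fit"`.
#' @param ... unused.
#' @return n x 2 matrix with columns `alpha`, `beta`.
#' @export
residuals.learner_fit <- function(object, ...) {
  r <- cbind(alpha = object$records$executed_alpha - object$predictions$pred_alpha,
             beta = object$records$executed_beta - object$predictions$pred_beta)
  r
}

#' Simulate new sequences from a fitted learner
#'
#' Regenerates learning sequences from the fitted parameters against the same
#' targets the participant faced, using the task's reward condition. Useful
#' for posterior-predictive style checks and the fit/refit fixed-point test.
#'
#' @param object a `"learner_fit"`.
#' @param nsim number of replicate cohorts (each covering all targets).
#' @param seed RNG seed.
#' @param cfg a [reward_config]; defaults to an alpha-reward condition with
#'   the object's `max_cents`.
#' @param explore_sd exploration noise for the simulation (the fit itself
#'   carries none).
#' @param ... unused.
#' @return A trial-log data frame (with `replicate` column when `nsim > 1`).
#' @export
simulate.learner_fit <- function(object, nsim = 1, seed = NULL,
                                 cfg = NULL, explore_sd = 0, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cfg)) cfg <- reward_config("alpha", max_cents = object$max_cents)
  p <- object$params
  lp <- learner_params(p$lam, p$w_alpha, p$w_beta, p$kappa, explore_sd)
  targets <- unique(object$records[, c("target_index", "target_alpha",
                                       "target_beta")])
  out <- do.call(rbind, lapply(seq_len(nsim), function(rep) {
    d <- do.call(rbind, lapply(seq_len(nrow(targets)), function(i) {
      s <- simulate_sequence(c(targets$target_alpha[i], targets$target_beta[i]),
                             cfg, lp, n_trials = max(object$records$trial_index),
                             G = object$G)
      s$target_index <- targets$target_index[i]
      s
    }))
    d$replicate <- rep
    d
  }))
  if (nsim == 1L) out$replicate <- NULL
  out
}

#' Diagnostic plot for a fitted learner
#'
#' Scatter of predicted against observed trial-to-trial changes, one panel
#' per parameter dimension, with the identity line.
#'
#' @param x a `"learner_fit"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.learner_fit <- function(x, ...) {
  ch <- trial_changes(x$records, x$predictions)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (j in 1:2) {
    nm <- c("direction", "curvature")[j]
    graphics::plot(ch$observed[, j], ch$predicted[, j],
                   xlab = sprintf("observed %s change", nm),
                   ylab = sprintf("predicted %s change", nm),
                   pch = 16, cex = 0.4, col = grDevices::grey(0, 0.4), ...)
    graphics::abline(0, 1, col = 2)
  }
  invisible(x)
}

#' Fit the learner to every participant in a cohort log
#'
#' @param records a trial log with a `participant_id` column.
#' @param ... passed to [fit_learner()].
#' @return A list of class `"cohort_fits"`: `fits` (named list of
#'   `"learner_fit"`), `params` (data frame of fitted parameters, loss and
#'   variance explained per participant).
#' @export
fit_cohort <- function(records, ...) {
  stopifnot("participant_id" %in% names(records))
  ids <- unique(records$participant_id)
  fits <- lapply(ids, function(id) {
    fit_learner(records[records$participant_id == id, , drop = FALSE], ...)
  })
  names(fits) <- ids
  params <- do.call(rbind, lapply(ids, function(id) {
    f <- fits[[id]]
    cbind(data.frame(participant_id = id,
                     condition = if ("condition" %in% names(records))
                       records$condition[records$participant_id == id][1L]
                     else NA_character_),
          as.data.frame(as.list(coef(f))),
          data.frame(loss = f$loss,
                     variance_explained = f$variance_explained,
                     convergence = f$diagnostics$convergence))
  }))
  structure(list(fits = fits, params = params), class = "cohort_fits")
}

#' @export
print.cohort_fits <- function(x, ...) {
  cat(sprintf("Learner fits for %d participants\n", nrow(x$params)))
  print(x$params, digits = 3)
  invisible(x)
}
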