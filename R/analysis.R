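#' Trial-indexed learning curves
#'
#' Averages performance at each trial index over all (participant, target)
#' learning sequences: the absolute parameter error `|executed - target|`
#' for direction or curvature (parameter units), or the displayed reward
#' (cents).
#'
#' @param records a trial-log data frame.
#' @param by which series to average: `"alpha_error"`, `"beta_error"` or
#'   `"reward"`.
#' @return Data frame with `trial_index`, `mean`, `sem` (NA where only one
#'   sequence contributes) and `n`.
#' @export
learning_curves <- function(records,
                            by = c("alpha_error", "beta_error", "reward")) {
  by <- match.arg(by)
  v <- switch(by,
              alpha_error = abs(records$executed_alpha - records$target_alpha),
              beta_error = abs(records$executed_beta - records$target_beta),
              reward = records$displayed_cents)
  ti <- records$trial_index
  agg <- data.frame(trial_index = sort(unique(ti)))
  agg$mean <- as.numeric(tapply(v, ti, mean))
  n <- as.integer(tapply(v, ti, length))
  s <- as.numeric(tapply(v, ti, stats::sd))
  agg$sem <- ifelse(n > 1L, s / sqrt(n), NA_real_)
  agg$n <- n
  agg
}

#' Exponential fit of a learning curve
#'
#' Least-squares fit of \eqn{y(t) = A e^{-t/\tau} + c} so the decay constant
#' `tau` is in trials. For a fixed `tau` the amplitude and asymptote are a
#' linear regression, so `tau` is profiled: the residual sum of squares is
#' scanned on a log-spaced grid and the bracketing interval is refined with
#' [stats::optimize()]. Deterministic given settings.
#'
#' @param y series values (one per trial).
#' @param t trial indices (defaults to `1:length(y)`).
#' @param tau_range search range for the decay constant, in trials.
#' @param n_grid size of the log-spaced profiling grid.
#' @return An object of class `"exp_fit"`: `amplitude`, `tau`, `asymptote`,
#'   `rss`, and `flag` (`"ok"`, `"tau_at_bound"`, or `"unidentifiable"` for
#'   near-constant series whose amplitude is indistinguishable from 0).
#' @export
#' @examples
#' t <- 1:25
#' f <- fit_exponential(0.5 * exp(-t / 3) + 0.2)
#' unlist(f[c("amplitude", "tau", "asymptote")])
fit_exponential <- function(y, t = seq_along(y), tau_range = c(0.2, 500),
                            n_grid = 60) {
  stopifnot(length(y) >= 4L, length(t) == length(y))
  profile_rss <- function(tau) {
    b <- exp(-t / tau)
    f <- stats::lm.fit(cbind(1, b), y)
    sum(f$residuals^2)
  }
  ltau <- seq(log(tau_range[1L]), log(tau_range[2L]), length.out = n_grid)
  rss <- vapply(ltau, function(l) profile_rss(exp(l)), numeric(1))
  i <- which.min(rss)
  lo <- ltau[max(1L, i - 1L)]
  hi <- ltau[min(n_grid, i + 1L)]
  opt <- stats::optimize(function(l) profile_rss(exp(l)), c(lo, hi),
                         tol = 1e-10)
  tau <- exp(opt$minimum)
  b <- exp(-t / tau)
  cf <- stats::lm.fit(cbind(asymptote = 1, amplitude = b), y)$coefficients
  flag <- "ok"
  scale_y <- max(stats::sd(y), .Machine$double.eps)
  if (abs(cf[["amplitude"]]) < 1e-8 * max(scale_y, 1)) flag <- "unidentifiable"
  else if (i == 1L || i == n_grid) flag <- "tau_at_bound"
  structure(list(amplitude = unname(cf[["amplitude"]]), tau = tau,
                 asymptote = unname(cf[["asymptote"]]),
                 rss = opt$objective, flag = flag),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("Exponential fit: y(t) = %.4g * exp(-t/%.4g) + %.4g  (rss %.3g%s)\n",
              x$amplitude, x$tau, x$asymptote, x$rss,
              if (x$flag != "ok") paste0("; ", x$flag) else ""))
  invisible(x)
}

#' Per-condition decay constants and asymptotes
#'
#' Fits an exponential to the group-average learning curve of each movement
#' property within each condition, summarizing how fast and how completely
#' direction and curvature errors are reduced. The study's headline effect
#' is that the reward-weighted property has the smaller decay constant
#' (faster learning).
#'
#' @param records a trial-log data frame with a `condition` column.
#' @param ... passed to [fit_exponential()].
#' @return Data frame with one row per condition x dimension: `condition`,
#'   `dimension`, `tau`, `asymptote`, `amplitude`, `rss`, `flag`.
#' @export
asymptote_summary <- function(records, ...) {
  stopifnot("condition" %in% names(records))
  rows <- list()
  for (cond in unique(records$condition)) {
    rc <- records[records$condition == cond, , drop = FALSE]
    for (dim in c("alpha", "beta")) {
      curve <- learning_curves(rc, by = paste0(dim, "_error"))
      f <- fit_exponential(curve$mean, curve$trial_index, ...)
      rows[[length(rows) + 1L]] <-
        data.frame(condition = cond, dimension = dim, tau = f$tau,
                   asymptote = f$asymptote, amplitude = f$amplitude,
                   rss = f$rss, flag = f$flag)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Quiver summary of trial-to-trial parameter changes
#'
#' Bins every trial (except the last of each sequence) by its current
#' absolute normalized errors (|executed - target|/2 per dimension) and
#' averages, per bin, the change in those absolute errors to the next trial
#' — observed, and, when fitted parameters are supplied, model-predicted via
#' [predict_next_actions()]. Negative components mean the error shrank. The
#' binned field mirrors the study's quiver comparison of data and model.
#'
#' @param records a trial-log data frame (one or more participants).
#' @param fits optional: a `"cohort_fits"` object, a named list of
#'   [learner_params] keyed by participant id, or a single [learner_params]
#'   applied to all participants.
#' @param bin_width bin width in normalized error units.
#' @param min_n bins with fewer trials are dropped.
#' @param G map resolution for model predictions (ignored when `fits` is a
#'   `"cohort_fits"`, which carries its own).
#' @param max_cents reward scaling for model predictions.
#' @return Data frame with one row per populated bin: bin centers
#'   `alpha_err`, `beta_err`, counts `n`, observed mean change
#'   (`obs_d_alpha`, `obs_d_beta`) and, with `fits`, model mean change
#'   (`mod_d_alpha`, `mod_d_beta`).
#' @export
quiver_summary <- function(records, fits = NULL, bin_width = 0.1, min_n = 5,
                           G = 100, max_cents = 50) {
  if (!"participant_id" %in% names(records)) {
    records$participant_id <- "p01"
  }
  with_model <- !is.null(fits)
  parts <- split(records, records$participant_id)
  rows <- lapply(names(parts), function(pid) {
    rp <- parts[[pid]]
    rp <- rp[order(rp$target_index, rp$trial_index), , drop = FALSE]
    if (with_model) {
      par_p <- participant_params(fits, pid)
      Gp <- if (inherits(fits, "cohort_fits")) fits$fits[[pid]]$G else G
      pred <- predict_next_actions(rp, par_p, G = Gp, max_cents = max_cents)
    }
    cur <- rp$trial_index < max(rp$trial_index)
    nxt <- which(cur) + 1L
    # drop sequence boundaries
    same <- rp$target_index[nxt] == rp$target_index[cur]
    cur_i <- which(cur)[same]
    nxt_i <- nxt[same]
    ea_cur <- abs(rp$executed_alpha[cur_i] - rp$target_alpha[cur_i]) / 2
    eb_cur <- abs(rp$executed_beta[cur_i] - rp$target_beta[cur_i]) / 2
    ea_nxt <- abs(rp$executed_alpha[nxt_i] - rp$target_alpha[nxt_i]) / 2
    eb_nxt <- abs(rp$executed_beta[nxt_i] - rp$target_beta[nxt_i]) / 2
    data.frame(
      alpha_err = ea_cur,
      beta_err = eb_cur,
      obs_d_alpha = ea_nxt - ea_cur,
      obs_d_beta = eb_nxt - eb_cur,
      mod_d_alpha = if (with_model)
        abs(pred$pred_alpha[nxt_i] - rp$target_alpha[nxt_i]) / 2 - ea_cur
      else NA_real_,
      mod_d_beta = if (with_model)
        abs(pred$pred_beta[nxt_i] - rp$target_beta[nxt_i]) / 2 - eb_cur
      else NA_real_)
  })
  d <- do.call(rbind, rows)
  d$bin_a <- floor(d$alpha_err / bin_width)
  d$bin_b <- floor(d$beta_err / bin_width)
  key <- interaction(d$bin_a, d$bin_b, drop = TRUE)
  agg <- do.call(rbind, lapply(split(d, key), function(g) {
    data.frame(alpha_err = (g$bin_a[1L] + 0.5) * bin_width,
               beta_err = (g$bin_b[1L] + 0.5) * bin_width,
               n = nrow(g),
               obs_d_alpha = mean(g$obs_d_alpha),
               obs_d_beta = mean(g$obs_d_beta),
               mod_d_alpha = mean(g$mod_d_alpha),
               mod_d_beta = mean(g$mod_d_beta))
  }))
  agg <- agg[agg$n >= min_n, , drop = FALSE]
  agg <- agg[order(agg$alpha_err, agg$beta_err), , drop = FALSE]
  rownames(agg) <- NULL
  if (!with_model) agg$mod_d_alpha <- agg$mod_d_beta <- NULL
  agg
}

participant_params <- function(fits, pid) {
  if (inherits(fits, "cohort_fits")) {
    f <- fits$fits[[pid]]
    if (is.null(f)) stop("no fit for participant ", pid, call. = FALSE)
    return(f$params)
  }
  if (inherits(fits, "learner_params")) return(fits)
  if (is.list(fits) && !is.null(fits[[pid]])) {
    p <- fits[[pid]]
    if (inherits(p, "learner_fit")) return(p$params)
    if (inherits(p, "learner_params")) return(p)
  }
  stop("cannot resolve learner parameters for participant ", pid,
       call. = FALSE)
}

#' Session-wise meta-learning summary
#'
#' Groups each participant's targets, in presentation order, into sessions
#' (canonically 5 sessions of 10 targets) and summarizes the amount of
#' learning per sequence as the mean over the last `last_trials` attempts of
#' the direction error, curvature error and displayed reward. A decrease in
#' late-session error across sessions indicates learning-to-learn across
#' target trajectories.
#'
#' @param records a trial-log data frame with `participant_id` and
#'   `condition` columns.
#' @param n_per_session targets per session. The default 10 requires each
#'   participant to have the canonical 50 targets; supply an explicit value
#'   for other designs.
#' @param last_trials how many final attempts define end-of-sequence
#'   performance.
#' @return Data frame per condition x session: means and sems of the three
#'   end-of-sequence measures over (participant, target) sequences.
#' @export
meta_learning_summary <- function(records, n_per_session = NULL,
                                  last_trials = 5) {
  stopifnot(all(c("participant_id", "condition") %in% names(records)))
  counts <- tapply(records$target_index, records$participant_id,
                   function(x) length(unique(x)))
  if (is.null(n_per_session)) {
    if (!all(counts == 50L)) {
      stop("participants do not all have 50 targets; supply n_per_session",
           call. = FALSE)
    }
    n_per_session <- 10L
  }
  if (any(counts %% n_per_session != 0)) {
    stop("number of targets is not a multiple of n_per_session",
         call. = FALSE)
  }
  n_trials <- max(records$trial_index)
  late <- records[records$trial_index > n_trials - last_trials, , drop = FALSE]
  key <- interaction(late$participant_id, late$target_index, drop = TRUE)
  seq_sum <- do.call(rbind, lapply(split(late, key), function(g) {
    data.frame(condition = g$condition[1L],
               session = (g$target_index[1L] - 1L) %/% n_per_session + 1L,
               alpha_error = mean(abs(g$executed_alpha - g$target_alpha)),
               beta_error = mean(abs(g$executed_beta - g$target_beta)),
               reward = mean(g$displayed_cents))
  }))
  key2 <- interaction(seq_sum$condition, seq_sum$session, drop = TRUE)
  out <- do.call(rbind, lapply(split(seq_sum, key2), function(g) {
    sem <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
    data.frame(condition = g$condition[1L], session = g$session[1L],
               n_sequences = nrow(g),
               alpha_error = mean(g$alpha_error),
               alpha_error_sem = sem(g$alpha_error),
               beta_error = mean(g$beta_error),
               beta_error_sem = sem(g$beta_error),
               reward = mean(g$reward), reward_sem = sem(g$reward))
  }))
  out <- out[order(out$condition, out$session), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plot group learning curves
#'
#' Mean +/- sem of the direction error, curvature error and reward as a
#' function of trial, one panel per measure, one line per condition.
#'
#' @param records a trial-log data frame with a `condition` column.
#' @export
plot_learning_curves <- function(records) {
  stopifnot("condition" %in% names(records))
  conds <- unique(records$condition)
  measures <- c("alpha_error", "beta_error", "reward")
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  for (m in measures) {
    curves <- lapply(conds, function(cc)
      learning_curves(records[records$condition == cc, ], by = m))
    ylim <- range(unlist(lapply(curves, function(d)
      c(d$mean - d$sem, d$mean + d$sem))), na.rm = TRUE)
    graphics::plot(NULL, xlim = range(records$trial_index), ylim = ylim,
                   xlab = "trial", ylab = gsub("_", " ", m))
    for (i in seq_along(conds)) {
      d <- curves[[i]]
      graphics::lines(d$trial_index, d$mean, col = i, lwd = 2)
      ok <- !is.na(d$sem)
      graphics::arrows(d$trial_index[ok], d$mean[ok] - d$sem[ok],
                       d$trial_index[ok], d$mean[ok] + d$sem[ok],
                       angle = 90, code = 3, length = 0.02, col = i)
    }
    graphics::legend("topright", legend = conds, col = seq_along(conds),
                     lwd = 2, bty = "n", cex = 0.8)
  }
  invisible(NULL)
}

#' Plot a quiver summary
#'
#' Observed (and, if present, model-predicted) mean change vectors over the
#' (direction error, curvature error) plane.
#'
#' @param qs output of [quiver_summary()].
#' @param scale arrow scale factor.
#' @export
plot_quiver <- function(qs, scale = 1) {
  graphics::plot(qs$alpha_err, qs$beta_err, pch = 16, cex = 0.4,
                 xlab = "|direction error| (normalized)",
                 ylab = "|curvature error| (normalized)")
  graphics::arrows(qs$alpha_err, qs$beta_err,
                   qs$alpha_err + scale * qs$obs_d_alpha,
                   qs$beta_err + scale * qs$obs_d_beta,
                   length = 0.04, col = "grey40")
  if (!is.null(qs$mod_d_alpha)) {
    graphics::arrows(qs$alpha_err, qs$beta_err,
                     qs$alpha_err + scale * qs$mod_d_alpha,
                     qs$beta_err + scale * qs$mod_d_beta,
                     length = 0.04, col = "black")
    graphics::legend("topright", legend = c("observed", "model"),
                     col = c("grey40", "black"), lwd = 1, bty = "n")
  }
  invisible(NULL)
}
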