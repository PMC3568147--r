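#' Learner parameters for the Bayesian credit-assignment model
#'
#' The model maintains a normalized probability map over candidate targets in
#' (direction, curvature) space. Four parameters govern learning; one more
#' (`explore_sd`) is simulation-only action noise and is never fitted.
#'
#' @param lam memory decay in \[0, 1\]: each inter-trial interval mixes the
#'   map toward uniform, `lam * map + (1 - lam) * uniform`. 1 is perfect
#'   recall, 0 total forgetting.
#' @param w_alpha,w_beta internal (subjective) weights, >= 0, with which the
#'   learner approximates the reward function from squared normalized errors.
#' @param kappa learning rate > 0 scaling the influence of the reward
#'   prediction error on the map update.
#' @param explore_sd simulation-only Gaussian exploration noise (sd, in
#'   parameter units) added to the selected action.
#' @return An object of class `"learner_params"`.
#' @export
#' @examples
#' learner_params(lam = 0.32, w_alpha = 0.8, w_beta = 0.2, kappa = 20)
learner_params <- function(lam, w_alpha, w_beta, kappa, explore_sd = 0) {
  stopifnot(is.numeric(lam), length(lam) == 1L, lam >= 0, lam <= 1,
            is.numeric(w_alpha), w_alpha >= 0,
            is.numeric(w_beta), w_beta >= 0,
            is.numeric(kappa), kappa >= 0,
            is.numeric(explore_sd), explore_sd >= 0)
  structure(list(lam = lam, w_alpha = w_alpha, w_beta = w_beta,
                 kappa = kappa, explore_sd = explore_sd),
            class = "learner_params")
}

#' @export
print.learner_params <- function(x, ...) {
  cat(sprintf("Learner: lam = %.3g, w_alpha = %.3g, w_beta = %.3g, kappa = %.3g, explore_sd = %.3g\n",
              x$lam, x$w_alpha, x$w_beta, x$kappa, x$explore_sd))
  invisible(x)
}

#' Grid cell centers of the probability map
#'
#' The map is cell-centered on \eqn{[-1, 1]}: cell i (1-based) has center
#' \eqn{-1 + (2i - 1)/G}.
#'
#' @param G grid resolution per dimension.
#' @return Numeric vector of G cell centers.
#' @export
map_centers <- function(G) -1 + (2 * seq_len(G) - 1) / G

#' Initialize a uniform probability map
#'
#' @param G grid resolution per dimension (>= 2); 200 in the canonical
#'   configuration.
#' @return A `"prob_map"`: a G x G matrix (rows index direction, columns
#'   curvature) of non-negative values summing to 1.
#' @export
init_map <- function(G = 200) {
  stopifnot(length(G) == 1L, G >= 2)
  m <- matrix(1 / G^2, nrow = G, ncol = G)
  structure(m, class = c("prob_map", "matrix"))
}

as_prob_map <- function(m) {
  structure(m, class = c("prob_map", "matrix"))
}

#' Apply memory decay to a probability map
#'
#' Linear forgetting toward the flat prior: returns
#' `lam * map + (1 - lam) * uniform`. This is the unique linear scheme for
#' which `lam = 1` leaves the map untouched (perfect recall) and `lam = 0`
#' resets it to uniform; repeated application with `lam < 1` contracts the
#' map to uniform geometrically.
#'
#' @param map a normalized `"prob_map"`.
#' @param lam memory decay in \[0, 1\].
#' @return The decayed, still-normalized map.
#' @export
apply_decay <- function(map, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) ||
      lam < 0 || lam > 1) {
    stop("lam must be a single number in [0, 1]", call. = FALSE)
  }
  G2 <- length(map)
  as_prob_map(lam * unclass(map) + (1 - lam) / G2)
}

#' Predicted-reward surface over candidate targets
#'
#' For every candidate target cell, the learner's subjective prediction of
#' the reward fraction had that cell been the true target:
#' \deqn{\hat r(pos) = 1 - (w_\alpha \Delta_\alpha^2 + w_\beta \Delta_\beta^2)}
#' with \eqn{\Delta} the normalized errors between the executed parameters
#' and the cell center. Note the learner's internal approximation penalizes
#' squared errors, whereas the task's actual reward is linear in the errors.
#'
#' @param executed executed [traj_params] (or numeric pair).
#' @param params a [learner_params] (only `w_alpha`, `w_beta` used).
#' @param G grid resolution.
#' @return A G x G matrix of predicted reward fractions (rows = direction).
#' @export
predicted_reward_map <- function(executed, params, G = 200) {
  executed <- as_traj_params(executed)
  centers <- map_centers(G)
  da2 <- ((executed[["alpha"]] - centers) / 2)^2
  db2 <- ((executed[["beta"]] - centers) / 2)^2
  1 - outer(params$w_alpha * da2, params$w_beta * db2, `+`)
}

#' Bayesian map update from one reward observation
#'
#' The reward prediction error at each candidate cell,
#' \eqn{e(pos) = \hat r(pos) - r_t}, defines a likelihood kernel
#' \eqn{\exp(-\kappa e(pos)^2)}; the posterior is the renormalized product
#' of the prior map and this kernel. Cells whose hypothesized target would
#' have predicted the observed reward gain mass; a larger `kappa` sharpens
#' the update. If the posterior underflows to all zeros the prior is
#' returned unchanged with a warning.
#'
#' @param prior a normalized `"prob_map"`.
#' @param executed executed [traj_params] for the trial.
#' @param observed reward fraction actually observed, in \[0, 1\] (the
#'   displayed, clipped reward rescaled by the per-trial maximum).
#' @param params a [learner_params] (uses `w_alpha`, `w_beta`, `kappa`).
#' @return The posterior `"prob_map"`, normalized.
#' @export
update_map <- function(prior, executed, observed, params) {
  G <- nrow(prior)
  rhat <- predicted_reward_map(executed, params, G)
  post <- unclass(prior) * exp(-params$kappa * (rhat - observed)^2)
  s <- sum(post)
  if (!is.finite(s) || s <= 0) {
    warning("posterior numerically degenerate; keeping prior", call. = FALSE)
    return(as_prob_map(unclass(prior)))
  }
  as_prob_map(post / s)
}

map_is_uniform <- function(map) {
  mx <- max(map)
  (mx - min(map)) <= mx * 1e-12
}

#' Select the next action from the belief map
#'
#' Maximum-a-posteriori selection: the center of the highest-probability cell
#' plus i.i.d. Gaussian exploration noise per dimension. Ties go to the first
#' maximal cell in storage (column-major) order, deterministically. On a
#' still-uniform map — before any informative update — the default is a
#' uniform random draw over \eqn{[-1, 1]^2}, so simulated learners start by
#' exploring the space; set `uniform_start = "map"` to use the tie-break
#' instead.
#'
#' @param map a normalized `"prob_map"`.
#' @param explore_sd exploration noise sd (parameter units).
#' @param uniform_start behavior on a uniform map: `"random"` (default) or
#'   `"map"`.
#' @return A [traj_params] action (may fall outside \eqn{[-1,1]^2} through
#'   noise).
#' @export
select_action <- function(map, explore_sd = 0,
                          uniform_start = c("random", "map")) {
  uniform_start <- match.arg(uniform_start)
  if (uniform_start == "random" && map_is_uniform(map)) {
    draw <- stats::runif(2, -1, 1)
    return(traj_params(draw[1L], draw[2L]))
  }
  G <- nrow(map)
  centers <- map_centers(G)
  k <- which.max(map)  # first maximum in column-major order
  i <- (k - 1L) %% G + 1L   # row: direction
  j <- (k - 1L) %/% G + 1L  # column: curvature
  noise <- if (explore_sd > 0) stats::rnorm(2, 0, explore_sd) else c(0, 0)
  traj_params(centers[i] + noise[1L], centers[j] + noise[2L])
}

#' Simulate one learning sequence against a fixed target
#'
#' Iterates the model for `n_trials` attempts at a single hidden target:
#' decay the map, select an action, observe the (clipped, rescaled) reward,
#' update the map. The learner sees only what a participant sees — the
#' displayed reward as a fraction of the per-trial maximum.
#'
#' @param target target [traj_params].
#' @param cfg a [reward_config].
#' @param params a [learner_params].
#' @param n_trials number of attempts (>= 1); 25 in the canonical protocol.
#' @param G belief-map resolution.
#' @param uniform_start first-trial behavior, see [select_action()].
#' @return Data frame with one row per trial: `trial_index`, `target_alpha`,
#'   `target_beta`, `executed_alpha`, `executed_beta`, `raw_fraction`,
#'   `displayed_cents`.
#' @export
#' @examples
#' set.seed(1)
#' seq1 <- simulate_sequence(traj_params(0.5, -0.2), reward_config("alpha"),
#'                           learner_params(0.9, 0.8, 0.2, 40, 0.02),
#'                           n_trials = 10, G = 50)
simulate_sequence <- function(target, cfg, params, n_trials = 25, G = 200,
                              uniform_start = c("random", "map")) {
  target <- as_traj_params(target)
  uniform_start <- match.arg(uniform_start)
  stopifnot(n_trials >= 1)
  map <- init_map(G)
  out <- data.frame(trial_index = seq_len(n_trials),
                    target_alpha = target[["alpha"]],
                    target_beta = target[["beta"]],
                    executed_alpha = NA_real_, executed_beta = NA_real_,
                    raw_fraction = NA_real_, displayed_cents = NA_real_)
  for (t in seq_len(n_trials)) {
    map <- apply_decay(map, params$lam)
    a <- select_action(map, params$explore_sd, uniform_start)
    rw <- reward(a, target, cfg)
    out$executed_alpha[t] <- a[["alpha"]]
    out$executed_beta[t] <- a[["beta"]]
    out$raw_fraction[t] <- rw$raw_fraction
    out$displayed_cents[t] <- rw$displayed_cents
    map <- update_map(map, a, rw$displayed_cents / cfg$max_cents, params)
  }
  out
}

#' Export a probability map as CSV
#'
#' Writes the G x G map as a plain CSV matrix (rows = direction cells in
#' increasing order, columns = curvature cells); pass a path ending in `.gz`
#' for gzip compression.
#'
#' @param map a `"prob_map"`.
#' @param path output path.
#' @export
write_prob_map <- function(map, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(unclass(map), con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
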