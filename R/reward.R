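#' Reward configuration for one experimental condition
#'
#' Each trial earns a monetary score from the weighted composite error between
#' the executed and target trajectory parameters. One movement property
#' (direction or curvature) carries the large weight `W`, the other the small
#' weight `w`; the score fraction is scaled to cents. Canonically W = 0.8,
#' w = 0.2 and a perfect trial is worth 50 cents.
#'
#' @param weighted_dimension which property carries the large weight:
#'   `"alpha"` (direction) or `"beta"` (curvature).
#' @param W large weight.
#' @param w small weight.
#' @param max_cents money for a perfect trial, in cents.
#' @return An object of class `"reward_config"`. Its `condition` element is
#'   the canonical condition label, `"alpha_reward"` or `"beta_reward"`.
#' @export
#' @examples
#' reward_config("alpha")
#' reward_config("beta")
reward_config <- function(weighted_dimension = c("alpha", "beta"),
                          W = 0.8, w = 0.2, max_cents = 50) {
  weighted_dimension <- match.arg(weighted_dimension)
  stopifnot(is.numeric(W), is.numeric(w), W >= 0, w >= 0,
            is.numeric(max_cents), max_cents > 0)
  structure(list(weighted_dimension = weighted_dimension,
                 W = W, w = w, max_cents = max_cents,
                 condition = paste0(weighted_dimension, "_reward")),
            class = "reward_config")
}

#' @export
print.reward_config <- function(x, ...) {
  cat(sprintf("Reward condition '%s': weight %.3g on %s error, %.3g on %s error; max %g cents/trial\n",
              x$condition, x$W, x$weighted_dimension, x$w,
              setdiff(c("alpha", "beta"), x$weighted_dimension), x$max_cents))
  invisible(x)
}

#' Normalized absolute parameter errors
#'
#' The direction and curvature errors are normalized by the full width (2) of
#' the target parameter range \eqn{[-1, 1]}, so each error lies in \[0, 1\]
#' whenever both the executed and target values are in range; out-of-range
#' executions can exceed 1.
#'
#' @param executed,target [traj_params] (or numeric `(alpha, beta)` pairs).
#' @return Named numeric vector `c(delta_alpha = , delta_beta = )`.
#' @export
#' @examples
#' normalized_errors(c(1, 0), c(-1, 0))  # delta_alpha = 1
normalized_errors <- function(executed, target) {
  executed <- as_traj_params(executed)
  target <- as_traj_params(target)
  c(delta_alpha = abs(executed[["alpha"]] - target[["alpha"]]) / 2,
    delta_beta = abs(executed[["beta"]] - target[["beta"]]) / 2)
}

#' Reward for one trial
#'
#' The raw score fraction is the linear penalty
#' \deqn{1 - (W \Delta_{weighted} + w \Delta_{unweighted})}
#' on the normalized absolute errors; it is negative when errors exceed the
#' target range. The displayed reward multiplies the fraction by `max_cents`
#' and clips negatives to zero — participants are only ever shown a
#' non-negative amount.
#'
#' @param executed,target [traj_params] (or numeric `(alpha, beta)` pairs).
#' @param cfg a [reward_config].
#' @return List with `raw_fraction` (dimensionless, may be negative) and
#'   `displayed_cents` (`max(0, raw_fraction) * max_cents`).
#' @export
#' @examples
#' reward(c(0.2, 0.2), c(0.2, 0.2), reward_config("alpha"))  # 50 cents
reward <- function(executed, target, cfg = reward_config("alpha")) {
  stopifnot(inherits(cfg, "reward_config"))
  d <- normalized_errors(executed, target)
  raw <- raw_fraction_from_errors(d[["delta_alpha"]], d[["delta_beta"]], cfg)
  list(raw_fraction = raw,
       displayed_cents = max(0, raw) * cfg$max_cents)
}

raw_fraction_from_errors <- function(delta_alpha, delta_beta, cfg) {
  if (cfg$weighted_dimension == "alpha") {
    1 - (cfg$W * delta_alpha + cfg$w * delta_beta)
  } else {
    1 - (cfg$W * delta_beta + cfg$w * delta_alpha)
  }
}

#' Session payout
#'
#' Participants keep the best reward they achieved among the attempts at each
#' target; the session payout sums these per-target maxima. With 50 targets
#' and a perfect trial on each, the payout is 2500 cents = 25 dollars.
#'
#' @param records a trial-log data frame with columns `target_index` and
#'   `displayed_cents` (one participant's session).
#' @return Total payout in cents.
#' @export
session_payout <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("target_index", "displayed_cents") %in% names(records))) {
    stop("records must have columns target_index and displayed_cents",
         call. = FALSE)
  }
  if (nrow(records) == 0L) stop("empty session", call. = FALSE)
  best <- tapply(records$displayed_cents, records$target_index, max)
  sum(best)
}
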