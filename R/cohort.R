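#' Cohort configuration for synthetic experiments
#'
#' Describes a full synthetic experiment with the study's design: two reward
#' conditions with eight participants each, 50 hidden targets per participant
#' and 25 attempts per target (1250 reaches per participant). Each synthetic
#' participant gets individual learner parameters drawn from
#' `learner_distribution`.
#'
#' @param n_participants_per_condition participants per reward condition.
#' @param n_targets hidden target trajectories per participant.
#' @param n_trials attempts per target.
#' @param conditions list of [reward_config]s, one per condition.
#' @param learner_distribution either `NULL` (use
#'   [default_learner_distribution()] per condition) or a function
#'   `function(cfg)` returning such a distribution for a given condition.
#' @param G belief-map resolution used to simulate the learners (200
#'   canonical).
#' @param master_seed integer seed from which all per-participant seeds are
#'   derived.
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_participants_per_condition = 8,
                          n_targets = 50,
                          n_trials = 25,
                          conditions = list(reward_config("alpha"),
                                            reward_config("beta")),
                          learner_distribution = NULL,
                          G = 200,
                          master_seed = 1) {
  stopifnot(n_participants_per_condition >= 1, n_targets >= 1,
            n_trials >= 1, length(conditions) >= 1,
            all(vapply(conditions, inherits, logical(1), "reward_config")))
  structure(list(n_participants_per_condition = n_participants_per_condition,
                 n_targets = n_targets, n_trials = n_trials,
                 conditions = conditions,
                 learner_distribution = learner_distribution,
                 G = G, master_seed = master_seed),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d condition(s) x %d participants x %d targets x %d trials (G = %d, seed %d)\n",
              length(x$conditions), x$n_participants_per_condition,
              x$n_targets, x$n_trials, x$G, x$master_seed))
  invisible(x)
}

#' Default learner-parameter distribution for a reward condition
#'
#' Synthetic participants mimic the study's reported group: the memory decay
#' is centered at the per-condition group estimate (0.32 for the
#' direction-weighted condition, 0.54 for the curvature-weighted one) with
#' the reported 0.1 spread; the internal error weights are centered on the
#' condition's true reward weights; the learning rate and exploration noise
#' are fixed assumptions chosen so that simulated learning curves plateau
#' within the 25 attempts, as the group curves do.
#'
#' @param cfg a [reward_config] identifying the condition.
#' @return A list of `c(mean, sd)` pairs for `lam`, `w_alpha`, `w_beta`,
#'   `kappa` and `explore_sd` (sd 0 means the parameter is fixed). Draws are
#'   truncated to each parameter's valid range.
#' @export
default_learner_distribution <- function(cfg) {
  lam_mean <- if (cfg$weighted_dimension == "alpha") 0.32 else 0.54
  wa_mean <- if (cfg$weighted_dimension == "alpha") cfg$W else cfg$w
  wb_mean <- if (cfg$weighted_dimension == "alpha") cfg$w else cfg$W
  list(lam = c(lam_mean, 0.1),
       w_alpha = c(wa_mean, 0.05),
       w_beta = c(wb_mean, 0.05),
       kappa = c(50, 10),
       explore_sd = c(0.05, 0))
}

draw_learner_params <- function(dist) {
  draw <- function(ms, lo, hi) {
    v <- if (ms[2L] > 0) stats::rnorm(1, ms[1L], ms[2L]) else ms[1L]
    min(max(v, lo), hi)
  }
  learner_params(lam = draw(dist$lam, 0, 1),
                 w_alpha = draw(dist$w_alpha, 0.01, Inf),
                 w_beta = draw(dist$w_beta, 0.01, Inf),
                 kappa = draw(dist$kappa, 1, Inf),
                 explore_sd = draw(dist$explore_sd, 0, Inf))
}

trial_log_columns <- c("participant_id", "condition", "target_index",
                       "trial_index", "target_alpha", "target_beta",
                       "executed_alpha", "executed_beta", "raw_fraction",
                       "displayed_cents")

#' Generate a full synthetic cohort
#'
#' For every condition and participant: draws individual learner parameters
#' from the condition's distribution, samples the participant's target set
#' (without replacement from the 441-cell parameter grid), and simulates
#' every learning sequence with [simulate_sequence()]. All randomness derives
#' from `master_seed` through per-participant sub-seeds, so logs are
#' reproducible record for record.
#'
#' @param cfg a [cohort_config].
#' @return A trial-log data frame with columns `participant_id`, `condition`,
#'   `target_index`, `trial_index`, `target_alpha`, `target_beta`,
#'   `executed_alpha`, `executed_beta`, `raw_fraction`, `displayed_cents`,
#'   plus an attribute `"learners"`: the data frame of true per-participant
#'   parameters (useful for parameter-recovery studies).
#' @export
#' @examples
#' cc <- cohort_config(n_participants_per_condition = 1, n_targets = 2,
#'                     n_trials = 5, G = 40)
#' log <- generate_cohort(cc)
#' nrow(log)  # 2 conditions x 1 participant x 2 targets x 5 trials
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  n_cond <- length(cfg$conditions)
  n_pp <- cfg$n_participants_per_condition
  set.seed(cfg$master_seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_cond * n_pp)
  grid <- expand.grid(alpha = target_grid(), beta = target_grid())
  if (cfg$n_targets > nrow(grid)) {
    stop("n_targets exceeds the ", nrow(grid), "-cell target grid",
         call. = FALSE)
  }
  logs <- vector("list", n_cond * n_pp)
  learners <- vector("list", n_cond * n_pp)
  k <- 0L
  for (ci in seq_len(n_cond)) {
    cond <- cfg$conditions[[ci]]
    dist <- if (is.null(cfg$learner_distribution)) {
      default_learner_distribution(cond)
    } else {
      cfg$learner_distribution(cond)
    }
    for (pi in seq_len(n_pp)) {
      k <- k + 1L
      pid <- sprintf("%s_p%02d", cond$condition, pi)
      set.seed(sub_seeds[k])
      lp <- draw_learner_params(dist)
      tg_rows <- sample.int(nrow(grid), cfg$n_targets)
      seqs <- lapply(seq_len(cfg$n_targets), function(i) {
        d <- simulate_sequence(c(grid$alpha[tg_rows[i]], grid$beta[tg_rows[i]]),
                               cond, lp, n_trials = cfg$n_trials, G = cfg$G)
        d$target_index <- i
        d
      })
      d <- do.call(rbind, seqs)
      d$participant_id <- pid
      d$condition <- cond$condition
      logs[[k]] <- d[, trial_log_columns]
      learners[[k]] <- data.frame(participant_id = pid,
                                  condition = cond$condition,
                                  lam = lp$lam, w_alpha = lp$w_alpha,
                                  w_beta = lp$w_beta, kappa = lp$kappa,
                                  explore_sd = lp$explore_sd)
    }
  }
  out <- do.call(rbind, logs)
  rownames(out) <- NULL
  attr(out, "learners") <- do.call(rbind, learners)
  out
}

#' Write / read a trial log as CSV
#'
#' Ten fixed columns in stable order, UTF-8, header row, `.` decimal mark.
#' Numeric fields are written with 17 significant digits so the read-back
#' log reproduces every double bit for bit.
#'
#' @param records non-empty trial-log data frame (must contain the ten
#'   canonical columns).
#' @param path file path.
#' @return `read_trial_log` returns the trial-log data frame;
#'   `write_trial_log` returns `path` invisibly.
#' @export
write_trial_log <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("refusing to write an empty trial log", call. = FALSE)
  }
  miss <- setdiff(trial_log_columns, names(records))
  if (length(miss)) {
    stop("trial log missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- records[, trial_log_columns]
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, colClasses = "character",
                       fileEncoding = "UTF-8")
  miss <- setdiff(trial_log_columns, names(d))
  if (length(miss)) {
    stop("malformed trial log ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  int_cols <- c("target_index", "trial_index")
  num_cols <- setdiff(trial_log_columns,
                      c("participant_id", "condition", int_cols))
  for (nm in c(int_cols, num_cols)) {
    v <- suppressWarnings(as.numeric(d[[nm]]))
    if (anyNA(v) && !all(is.na(d[[nm]]))) {
      row <- which(is.na(v) & !is.na(d[[nm]]))[1L]
      stop(sprintf("malformed trial log %s: line %d, column '%s' is not numeric",
                   path, row + 1L, nm), call. = FALSE)
    }
    d[[nm]] <- if (nm %in% int_cols) as.integer(v) else v
  }
  d[, trial_log_columns]
}
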