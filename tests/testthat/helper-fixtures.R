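# Shared fixtures: all synthetic, generated in code at test time.

# One synthetic participant's trial log at fixed learner parameters.
gen_participant <- function(cond = "alpha", lam = 0.32, w_dom = 0.8,
                            kappa = 50, explore_sd = 0.05, n_targets = 10,
                            n_trials = 25, G = 60, seed = 1) {
  cfg <- reward_config(cond)
  wa <- if (cond == "alpha") w_dom else 1 - w_dom
  set.seed(seed)
  lp <- learner_params(lam, wa, 1 - wa, kappa, explore_sd)
  recs <- do.call(rbind, lapply(seq_len(n_targets), function(i) {
    d <- simulate_sequence(sample_target(), cfg, lp, n_trials, G = G)
    d$target_index <- i
    d
  }))
  recs
}

# A flawless performer: every executed parameter equals the target.
perfect_records <- function(n_targets = 50, n_trials = 25,
                            condition = "alpha_reward") {
  g <- expand.grid(trial_index = seq_len(n_trials),
                   target_index = seq_len(n_targets))
  set.seed(99)
  ta <- sample(target_grid(), n_targets, replace = TRUE)
  tb <- sample(target_grid(), n_targets, replace = TRUE)
  data.frame(participant_id = "perfect", condition = condition,
             target_index = g$target_index, trial_index = g$trial_index,
             target_alpha = ta[g$target_index],
             target_beta = tb[g$target_index],
             executed_alpha = ta[g$target_index],
             executed_beta = tb[g$target_index],
             raw_fraction = 1, displayed_cents = 50)
}

# Brute-force single-trial map update: explicit cell-by-cell loops, no
# vectorization, independent of the package's linear-algebra path.
brute_update_map <- function(prior, executed, observed, params) {
  G <- nrow(prior)
  centers <- -1 + (2 * seq_len(G) - 1) / G
  post <- matrix(0, G, G)
  for (i in seq_len(G)) {
    for (j in seq_len(G)) {
      da <- (executed[1] - centers[i]) / 2
      db <- (executed[2] - centers[j]) / 2
      rhat <- 1 - (params$w_alpha * da^2 + params$w_beta * db^2)
      post[i, j] <- prior[i, j] * exp(-params$kappa * (rhat - observed)^2)
    }
  }
  post / sum(post)
}

# Teacher-forced replay assembled step by step from the exported R map
# operations; used as an independent oracle for the compiled replay.
replay_r <- function(records, params, G, max_cents = 50) {
  records <- records[order(records$target_index, records$trial_index), ]
  pred <- matrix(NA_real_, nrow(records), 2)
  centers <- map_centers(G)
  for (tg in unique(records$target_index)) {
    idx <- which(records$target_index == tg)
    map <- init_map(G)
    for (k in seq_along(idx)) {
      map <- apply_decay(map, params$lam)
      if (k > 1L) {
        if ((max(map) - min(map)) <= max(map) * 1e-12) {
          pred[idx[k], ] <- c(0, 0)
        } else {
          w <- which.max(map)
          pred[idx[k], ] <- c(centers[(w - 1) %% G + 1],
                              centers[(w - 1) %/% G + 1])
        }
      }
      map <- update_map(map,
                        c(records$executed_alpha[idx[k]],
                          records$executed_beta[idx[k]]),
                        records$displayed_cents[idx[k]] / max_cents, params)
    }
  }
  pred
}
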