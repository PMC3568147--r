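test_that("noiseless self-generated data is predicted exactly from trial 2 on", {
  G <- 40
  lp <- learner_params(0.7, 0.8, 0.2, 50, explore_sd = 0)
  recs <- gen_participant(lam = 0.7, w_dom = 0.8, kappa = 50,
                          explore_sd = 0, n_targets = 5, n_trials = 12,
                          G = G, seed = 17)
  pred <- predict_next_actions(recs, lp, G = G)
  later <- recs$trial_index > 1
  expect_equal(pred$pred_alpha[later], recs$executed_alpha[later],
               tolerance = 1e-12)
  expect_equal(pred$pred_beta[later], recs$executed_beta[later],
               tolerance = 1e-12)

  ch_obs <- cbind(diff(recs$executed_alpha), diff(recs$executed_beta))
  keep <- recs$trial_index[-1] > 1
  ch_pred <- cbind(pred$pred_alpha[-1] - recs$executed_alpha[-nrow(recs)],
                   pred$pred_beta[-1] - recs$executed_beta[-nrow(recs)])
  expect_equal(variance_explained(ch_pred[keep, ], ch_obs[keep, ]), 1)
})

test_that("zero learning rate predicts the uniform-map fallback everywhere", {
  recs <- gen_participant(n_targets = 2, n_trials = 5, G = 20, seed = 19)
  pred <- predict_next_actions(recs, learner_params(0.5, 0.8, 0.2, 0), G = 20)
  later <- recs$trial_index > 1
  expect_true(all(pred$pred_alpha[later] == 0))
  expect_true(all(pred$pred_beta[later] == 0))
})

test_that("replay validates its input contract", {
  recs <- gen_participant(n_targets = 2, n_trials = 4, G = 20, seed = 23)
  lp <- learner_params(0.5, 0.8, 0.2, 10)
  bad <- recs[recs$trial_index != 2, ]
  expect_error(predict_next_actions(bad, lp, G = 20), "contiguous")
  expect_error(predict_next_actions(
    recs[, setdiff(names(recs), "executed_alpha")], lp, G = 20),
    "missing col")
  two <- rbind(cbind(recs, participant_id = "a"),
               cbind(recs, participant_id = "b"))
  expect_error(fit_learner(two), "single participant")
})

test_that("variance explained: identity, mean predictor, and longhand arithmetic", {
  obs <- cbind(c(0.2, -0.1, 0.4), c(0.0, 0.3, -0.2))
  expect_equal(variance_explained(obs, obs), 1)

  mean_pred <- matrix(rep(colMeans(obs), each = 3), 3)
  expect_equal(variance_explained(mean_pred, obs), 0)

  pred <- cbind(c(0.1, 0.0, 0.3), c(0.1, 0.2, -0.1))
  # longhand: ss_res = 6 * 0.01; ss_tot about means (1/6, 1/30)
  ss_res <- (0.2 - 0.1)^2 + (-0.1 - 0)^2 + (0.4 - 0.3)^2 +
    (0 - 0.1)^2 + (0.3 - 0.2)^2 + (-0.2 + 0.1)^2
  ma <- (0.2 - 0.1 + 0.4) / 3
  mb <- (0 + 0.3 - 0.2) / 3
  ss_tot <- (0.2 - ma)^2 + (-0.1 - ma)^2 + (0.4 - ma)^2 +
    (0 - mb)^2 + (0.3 - mb)^2 + (-0.2 - mb)^2
  expect_equal(variance_explained(pred, obs), 1 - ss_res / ss_tot)

  expect_error(variance_explained(obs[1, , drop = FALSE],
                                  obs[1, , drop = FALSE]), "2 complete")
})

test_that("fitting noiseless self-generated data reaches the loss floor", {
  recs <- gen_participant(lam = 0.45, w_dom = 0.8, kappa = 40,
                          explore_sd = 0, n_targets = 8, n_trials = 15,
                          G = 50, seed = 29)
  fit <- fit_learner(recs, G = 50,
                     start_grid = data.frame(lam = 0.45, w_alpha = 0.8,
                                             w_beta = 0.2, kappa = 40),
                     n_starts = 1, control = list(maxit = 20))
  expect_lte(fit$loss, 1e-6)
  expect_equal(fit$variance_explained, 1)
})

test_that("fitted parameters recover the generating learner", {
  recs <- gen_participant(lam = 0.32, w_dom = 0.8, kappa = 50,
                          explore_sd = 0.05, n_targets = 15, n_trials = 25,
                          G = 60, seed = 31)
  fit <- fit_learner(recs, G = 60)
  cf <- coef(fit)
  expect_lt(abs(cf[["lam"]] - 0.32), 0.1)
  expect_lt(abs(cf[["w_alpha"]] - 0.8), 0.15)
  expect_gt(fit$variance_explained, 0.3)
})

test_that("fitting is invariant to the ordering of target sequences", {
  recs <- gen_participant(n_targets = 4, n_trials = 8, G = 30, seed = 37)
  remap <- c(3L, 1L, 4L, 2L)
  shuffled <- recs
  shuffled$target_index <- remap[recs$target_index]
  shuffled <- shuffled[order(shuffled$target_index, shuffled$trial_index), ]
  lp <- learner_params(0.5, 0.7, 0.3, 30)
  loss_of <- function(d) {
    p <- predict_next_actions(d, lp, G = 30)
    later <- d$trial_index > 1
    sum((p$pred_alpha[later] - d$executed_alpha[later])^2 +
          (p$pred_beta[later] - d$executed_beta[later])^2)
  }
  expect_equal(loss_of(recs), loss_of(shuffled), tolerance = 1e-12)

  f1 <- fit_learner(recs, G = 30, n_starts = 1, control = list(maxit = 60))
  f2 <- fit_learner(shuffled, G = 30, n_starts = 1,
                    control = list(maxit = 60))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-4)
})

test_that("fit / regenerate / refit is a fixed point within tolerance", {
  recs <- gen_participant(lam = 0.4, w_dom = 0.8, kappa = 50,
                          explore_sd = 0.05, n_targets = 10, n_trials = 20,
                          G = 50, seed = 41)
  fit <- fit_learner(recs, G = 50)
  # regenerate with the same exploration noise the original data carried:
  # noiseless regeneration leaves (lam, kappa) set-identified on a
  # zero-loss plateau of identical MAP sequences
  regen <- simulate(fit, seed = 42, cfg = reward_config("alpha"),
                    explore_sd = 0.05)
  refit <- fit_learner(regen, G = 50)
  expect_lt(abs(coef(refit)[["lam"]] - coef(fit)[["lam"]]), 0.1)
  expect_lt(abs(coef(refit)[["w_alpha"]] - coef(fit)[["w_alpha"]]), 0.15)
})

test_that("learner_fit methods expose the fit coherently", {
  recs <- gen_participant(n_targets = 3, n_trials = 6, G = 25, seed = 43)
  fit <- fit_learner(recs, G = 25, n_starts = 1, control = list(maxit = 40))
  expect_s3_class(fit, "learner_fit")
  expect_named(coef(fit), c("lam", "w_alpha", "w_beta", "kappa"))
  expect_identical(nrow(predict(fit)), nrow(recs))
  r <- residuals(fit)
  later <- fit$records$trial_index > 1
  expect_equal(r[later, "alpha"],
               fit$records$executed_alpha[later] -
                 fit$predictions$pred_alpha[later])
  expect_output(print(fit), "variance explained")
  expect_output(print(summary(fit)), "Optimizer")
})

test_that("parameter recovery across a small synthetic cohort", {
  fit_one <- function(cond, lam, seed) {
    recs <- gen_participant(cond = cond, lam = lam, w_dom = 0.8, kappa = 50,
                            explore_sd = 0.05, n_targets = 15, n_trials = 25,
                            G = 60, seed = seed)
    coef(fit_learner(recs, G = 60, n_starts = 2,
                     control = list(maxit = 150)))
  }
  ma <- do.call(rbind, lapply(1:20, function(s) fit_one("alpha", 0.32, 100 + s)))
  mb <- do.call(rbind, lapply(1:20, function(s) fit_one("beta", 0.54, 300 + s)))
  expect_lte(stats::median(abs(ma[, "lam"] - 0.32)), 0.1)
  expect_lte(stats::median(abs(mb[, "lam"] - 0.54)), 0.1)
  expect_lte(stats::median(abs(ma[, "w_alpha"] - 0.8)), 0.15)
  expect_lte(stats::median(abs(mb[, "w_beta"] - 0.8)), 0.15)
})
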