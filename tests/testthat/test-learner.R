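test_that("initial map is uniform and normalized", {
  m <- init_map(200)
  expect_equal(dim(m), c(200L, 200L))
  expect_true(all(m == 2.5e-5))
  expect_equal(sum(m), 1)
  expect_true(all(init_map(2) == 0.25))
})

test_that("memory decay is a convex combination with the uniform map", {
  m <- init_map(10)
  m[3, 4] <- m[3, 4] + 0.5
  m <- m / sum(m)
  expect_equal(unclass(apply_decay(m, 1)), unclass(m))
  expect_true(all(abs(apply_decay(m, 0) - 0.01) < 1e-15))

  # hand-computed 2x2 case: 0.5 * map + 0.5 * 0.25
  m2 <- matrix(c(0.7, 0.1, 0.1, 0.1), 2, 2)
  expect_equal(as.numeric(apply_decay(structure(m2, class = c("prob_map", "matrix")), 0.5)),
               c(0.475, 0.175, 0.175, 0.175))

  expect_error(apply_decay(m, 1.2), "\\[0, 1\\]")
  expect_error(apply_decay(m, -0.1), "\\[0, 1\\]")
})

test_that("repeated decay contracts the map to uniform", {
  G <- 20
  set.seed(1)
  m <- init_map(G)
  m[] <- stats::runif(G^2)
  m <- m / sum(m)
  m0 <- m
  tv <- function(x) 0.5 * sum(abs(x - 1 / G^2))
  prev <- tv(m)
  for (k in 1:10) {
    m <- apply_decay(m, 0.6)
    expect_equal(sum(m), 1, tolerance = 1e-12)
    expect_lt(tv(m), prev)
    expect_equal(tv(m), 0.6^k * tv(m0), tolerance = 1e-10)
    prev <- tv(m)
  }
})

test_that("predicted reward surface: maximum at the executed cell, flat when unweighted", {
  G <- 21
  centers <- map_centers(G)
  lp <- learner_params(1, 0.8, 0.2, 10)
  ex <- c(centers[5], centers[13])
  rhat <- predicted_reward_map(ex, lp, G)
  expect_equal(rhat[5, 13], 1)
  expect_true(all(rhat <= 1))

  lp0 <- learner_params(1, 0, 0, 10)
  expect_true(all(predicted_reward_map(c(0.3, -0.7), lp0, G) == 1))

  # symmetric weights at the origin: surface invariant to axis swap
  lps <- learner_params(1, 1, 1, 10)
  rh <- predicted_reward_map(c(0, 0), lps, G)
  expect_equal(rh, t(rh), tolerance = 1e-14)
})

test_that("map update matches a brute-force cell-by-cell oracle", {
  lp <- learner_params(0.9, 0.8, 0.2, 25)
  set.seed(5)
  for (k in 1:5) {
    prior <- init_map(5)
    prior[] <- stats::runif(25)
    prior <- prior / sum(prior)
    ex <- stats::runif(2, -1.2, 1.2)
    obs <- stats::runif(1)
    post <- update_map(prior, ex, obs, lp)
    oracle <- brute_update_map(prior, ex, obs, lp)
    expect_equal(unclass(post), oracle, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(sum(post), 1, tolerance = 1e-12)
    expect_true(all(post >= 0))
  }
})

test_that("zero learning rate leaves the map unchanged", {
  lp <- learner_params(1, 0.8, 0.2, 0)
  prior <- update_map(init_map(8), c(0.2, 0.2), 0.9,
                      learner_params(1, 1, 1, 30))
  post <- update_map(prior, c(-0.5, 0.1), 0.3, lp)
  expect_equal(unclass(post), unclass(prior), tolerance = 1e-14)
})

test_that("a confirming reward concentrates mass at the executed cell", {
  G <- 25
  lp <- learner_params(1, 5, 5, 400)
  centers <- map_centers(G)
  ex <- c(centers[8], centers[20])
  post <- init_map(G)
  for (k in 1:3) post <- update_map(post, ex, 1, lp)
  w <- which.max(post)
  expect_equal(c((w - 1) %% G + 1, (w - 1) %/% G + 1), c(8, 20))
  # symmetric around the executed cell in each axis
  expect_equal(post[7, 20], post[9, 20], tolerance = 1e-12)
  expect_equal(post[8, 19], post[8, 21], tolerance = 1e-12)
})

test_that("numerically degenerate posterior falls back to the prior with a warning", {
  lp <- learner_params(1, 1, 1, 1e6)
  prior <- init_map(10)
  expect_warning(post <- update_map(prior, c(5, 5), 1, lp), "degenerate")
  expect_equal(unclass(post), unclass(prior))
})

test_that("action selection: MAP center, seeded uniform start, deterministic tie-break", {
  G <- 10
  m <- init_map(G)
  m[4, 7] <- 1
  m <- m / sum(m)
  a <- select_action(m, explore_sd = 0)
  expect_equal(unclass(a),
               c(alpha = map_centers(G)[4], beta = map_centers(G)[7]))

  u <- init_map(G)
  set.seed(11)
  d1 <- select_action(u, explore_sd = 0)
  set.seed(11)
  d2 <- select_action(u, explore_sd = 0)
  expect_identical(d1, d2)
  expect_true(all(abs(unclass(d1)) <= 1))

  # two tied maxima: lowest column-major index wins
  m2 <- init_map(G)
  m2[3, 2] <- m2[8, 5] <- 1
  m2 <- m2 / sum(m2)
  a2 <- select_action(m2, explore_sd = 0, uniform_start = "map")
  expect_equal(unclass(a2),
               c(alpha = map_centers(G)[3], beta = map_centers(G)[2]))
})

test_that("simulated sequences learn: late rewards beat early rewards", {
  cfg <- reward_config("alpha")
  lp <- learner_params(1, 0.8, 0.2, 60, 0.02)
  set.seed(21)
  gain <- replicate(100, {
    d <- simulate_sequence(sample_target(), cfg, lp, 25, G = 40)
    mean(d$displayed_cents[21:25]) - mean(d$displayed_cents[1:5])
  })
  expect_gt(mean(gain), 0)
  expect_gt(stats::t.test(gain)$statistic, 3)
})

test_that("sequence bookkeeping: record count and no-learning null", {
  cfg <- reward_config("beta")
  set.seed(31)
  d <- simulate_sequence(c(0.5, 0.5), cfg, learner_params(0.5, 0.8, 0.2, 50, 0.05), 25, G = 30)
  expect_identical(nrow(d), 25L)
  expect_identical(d$trial_index, 1:25)

  # kappa = 0: the map never leaves uniform, so every action is a fresh
  # uniform draw and rewards carry no trend
  set.seed(32)
  d0 <- replicate(60, {
    s <- simulate_sequence(c(0, 0), cfg, learner_params(1, 0.8, 0.2, 0, 0), 10, G = 20)
    mean(s$displayed_cents[6:10]) - mean(s$displayed_cents[1:5])
  })
  expect_lt(abs(stats::t.test(d0)$statistic), 3)
})

test_that("every simulated trial leaves a normalized map (probability bookkeeping)", {
  # indirect check through update_map on random inputs of varied sharpness
  set.seed(41)
  for (k in 1:20) {
    lp <- learner_params(stats::runif(1), stats::runif(1, 0, 2),
                         stats::runif(1, 0, 2), stats::runif(1, 0, 150))
    m <- init_map(15)
    for (s in 1:5) {
      m <- apply_decay(m, lp$lam)
      m <- update_map(m, stats::runif(2, -1, 1), stats::runif(1), lp)
      expect_equal(sum(m), 1, tolerance = 1e-12)
      expect_true(all(m >= 0))
    }
  }
})

test_that("compiled replay agrees with the step-by-step R composition", {
  lp <- learner_params(0.6, 0.9, 0.3, 35)
  recs <- gen_participant(n_targets = 3, n_trials = 6, G = 25, seed = 13,
                          lam = 0.6, w_dom = 0.9, kappa = 35)
  pred_cpp <- predict_next_actions(recs, lp, G = 25)
  pred_r <- replay_r(recs, lp, G = 25)
  expect_equal(pred_cpp$pred_alpha, pred_r[, 1], tolerance = 1e-12)
  expect_equal(pred_cpp$pred_beta, pred_r[, 2], tolerance = 1e-12)

  # hand-stepped single short sequence on a 5x5 grid
  one <- recs[recs$target_index == 1, ][1:3, ]
  expect_equal(as.matrix(predict_next_actions(one, lp, G = 5)[, 3:4]),
               replay_r(one, lp, G = 5), ignore_attr = TRUE,
               tolerance = 1e-12)
})
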