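test_that("learning curves: perfect performer and single-record edge case", {
  perfect <- perfect_records(n_targets = 5, n_trials = 10)
  for (m in c("alpha_error", "beta_error")) {
    curve <- learning_curves(perfect, by = m)
    expect_true(all(curve$mean == 0))
    expect_identical(nrow(curve), 10L)
  }
  rcurve <- learning_curves(perfect, by = "reward")
  expect_true(all(rcurve$mean == 50))

  single <- perfect[1, ]
  c1 <- learning_curves(single, by = "reward")
  expect_identical(nrow(c1), 1L)
  expect_true(is.na(c1$sem))
  expect_identical(c1$n, 1L)
})

test_that("exponential fit recovers noiseless curves to high precision", {
  t <- 1:25
  f <- fit_exponential(0.5 * exp(-t / 3) + 0.2, t)
  expect_equal(f$amplitude, 0.5, tolerance = 1e-6)
  expect_equal(f$tau, 3, tolerance = 1e-6)
  expect_equal(f$asymptote, 0.2, tolerance = 1e-6)
  expect_identical(f$flag, "ok")

  set.seed(61)
  for (k in 1:100) {
    A <- stats::runif(1, 0.2, 1)
    tau <- stats::runif(1, 1, 12)
    cc <- stats::runif(1, 0, 0.5)
    fk <- fit_exponential(A * exp(-t / tau) + cc, t)
    expect_equal(fk$amplitude, A, tolerance = 1e-6)
    expect_equal(fk$tau, tau, tolerance = 1e-5)
    expect_equal(fk$asymptote, cc, tolerance = 1e-6)
  }
})

test_that("exponential fit flags degenerate and noisy regimes sensibly", {
  const <- fit_exponential(rep(0.37, 20))
  expect_equal(const$asymptote + const$amplitude * mean(exp(-(1:20) / const$tau)),
               0.37, tolerance = 1e-6)
  expect_identical(const$flag, "unidentifiable")

  set.seed(62)
  t <- 1:25
  taus <- replicate(20, {
    y <- 0.6 * exp(-t / 4) + 0.15 + stats::rnorm(25, 0, 0.02)
    fit_exponential(y, t)$tau
  })
  expect_lt(abs(stats::median(taus) - 4) / 4, 0.2)
})

test_that("the reward-weighted property is learned faster (tau ordering)", {
  cc <- cohort_config(5, 30, 25, G = 64, master_seed = 42)
  log <- generate_cohort(cc)
  asym <- asymptote_summary(log)
  get <- function(cond, dim) asym$tau[asym$condition == cond &
                                        asym$dimension == dim]
  expect_lt(get("alpha_reward", "alpha"), get("alpha_reward", "beta"))
  expect_lt(get("beta_reward", "beta"), get("beta_reward", "alpha"))

  perfect <- perfect_records(n_targets = 6, n_trials = 10)
  pa <- asymptote_summary(perfect)
  expect_true(all(abs(pa$asymptote) < 1e-6))
})

test_that("symmetric reward weights learn both dimensions at matched rates", {
  sym <- reward_config("alpha", W = 0.5, w = 0.5)
  cc <- cohort_config(6, 25, 25, conditions = list(sym), G = 64,
                      master_seed = 17,
                      learner_distribution = function(cfg) {
                        list(lam = c(0.4, 0), w_alpha = c(0.5, 0),
                             w_beta = c(0.5, 0), kappa = c(50, 0),
                             explore_sd = c(0.05, 0))
                      })
  log <- generate_cohort(cc)
  asym <- asymptote_summary(log)
  expect_lt(abs(log(asym$tau[asym$dimension == "alpha"] /
                      asym$tau[asym$dimension == "beta"])), log(2))
})

test_that("quiver summary is self-consistent and conserves the mean change", {
  G <- 40
  lp <- learner_params(0.7, 0.8, 0.2, 50, explore_sd = 0)
  recs <- gen_participant(lam = 0.7, w_dom = 0.8, kappa = 50,
                          explore_sd = 0, n_targets = 6, n_trials = 10,
                          G = G, seed = 71)
  recs$participant_id <- "p01"
  qs <- quiver_summary(recs, fits = list(p01 = lp), min_n = 1, G = G)
  expect_equal(qs$mod_d_alpha, qs$obs_d_alpha, tolerance = 1e-12)
  expect_equal(qs$mod_d_beta, qs$obs_d_beta, tolerance = 1e-12)

  # weighted bin means aggregate back to the overall mean change
  ea <- abs(recs$executed_alpha - recs$target_alpha) / 2
  eb <- abs(recs$executed_beta - recs$target_beta) / 2
  cur <- recs$trial_index < 10
  nxt <- which(cur) + 1
  overall <- c(mean(ea[nxt] - ea[cur]), mean(eb[nxt] - eb[cur]))
  expect_equal(sum(qs$n * qs$obs_d_alpha) / sum(qs$n), overall[1],
               tolerance = 1e-12)
  expect_equal(sum(qs$n * qs$obs_d_beta) / sum(qs$n), overall[2],
               tolerance = 1e-12)

  # sparse bins are dropped, not zero-filled
  qs5 <- quiver_summary(recs, min_n = 5, G = G)
  expect_true(all(qs5$n >= 5))
  expect_lt(nrow(qs5), nrow(qs))
})

test_that("meta-learning summary groups targets into sessions of 10", {
  cc <- cohort_config(1, 50, 25, G = 32, master_seed = 19)
  log <- generate_cohort(cc)
  meta <- meta_learning_summary(log)
  expect_identical(sort(unique(meta$session)), 1:5)
  expect_true(all(meta$n_sequences == 10))

  # hand-built sequence: known values on the last 5 trials
  hand <- perfect_records(n_targets = 50, n_trials = 25)
  hand$executed_alpha <- hand$target_alpha +
    ifelse(hand$trial_index > 20, 0.3, 1)
  hand$displayed_cents <- ifelse(hand$trial_index > 20, 40, 0)
  mh <- meta_learning_summary(hand)
  expect_true(all(abs(mh$alpha_error - 0.3) < 1e-12))
  expect_true(all(mh$reward == 40))

  short <- log[log$target_index <= 7, ]
  expect_error(meta_learning_summary(short), "n_per_session")
  expect_error(meta_learning_summary(short, n_per_session = 2), "multiple")
})

test_that("plot helpers run without error on a small cohort", {
  cc <- cohort_config(1, 4, 6, G = 24, master_seed = 21)
  log <- generate_cohort(cc)
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path)
  expect_no_error(plot_learning_curves(log))
  expect_no_error(plot_quiver(quiver_summary(log, min_n = 1)))
  expect_no_error(plot(generate_trajectory(c(0.3, 0.5))))
  grDevices::dev.off()
  expect_true(file.exists(path))
})
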