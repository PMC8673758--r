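test_that("the stay/shift table matches a hand-enumerated oracle on a toy log", {
  ev <- build_strategy_events(toy_log())
  expected <- toy_expected_events()
  got <- ev[, names(expected)]
  rownames(got) <- NULL
  expect_equal(got, expected)
  # gaps are raw-trial distances and can exceed the occasion lag
  expect_equal(ev$gap, ev$offered_trial - ev$trial)
  expect_true(any(ev$gap > ev$lag))
})

test_that("stay events use offered occasions, not raw trials, and drop absent occasions", {
  # a stimulus chosen on the last trial is never offered again: no rows
  ev <- build_strategy_events(toy_log())
  expect_false(any(ev$stimulus == "A" & ev$trial == 9))
  # lag-3 row absent when only two further occasions exist
  expect_equal(sum(ev$stimulus == "A" & ev$trial == 6), 2L)
})

test_that("a deterministic stay agent yields stay indicators of one", {
  sch <- quick_schedule(5, 60)
  s <- run_session(agent_fixed_option("A"), sch, seed = 2)
  ev <- build_strategy_events(s)
  expect_true(all(ev$stay[ev$stimulus == "A"] == 1))
})

test_that("WSLS coefficients are near zero for a random chooser", {
  sessions <- cached("random_sessions", function() {
    sim_sessions(random_params(), 20, seed0 = 800)
  })
  ws <- wsls_regression(sessions, scheme = "combined")
  sm <- summary(ws)
  expect_true(all(abs(sm$mean) < 2 * sm$se + 0.05))
})

test_that("a credit-assigning agent shows positive, decaying win-stay effects", {
  sessions <- cached("credit_sessions", function() {
    sim_sessions(credit_params(), 20, seed0 = 850)
  })
  ws <- wsls_regression(sessions, scheme = "separate_adaptive")
  expect_setequal(unique(ws$lag), 1:3)
  sm <- summary(ws)
  w1 <- sm$mean[sm$regressor == "win_stay_t1"]
  w3 <- sm$mean[sm$regressor == "win_stay_t3"]
  expect_gt(w1, 2 * sm$se[sm$regressor == "win_stay_t1"])
  expect_gt(w1, w3)
  # maladaptive scheme mirrors the adaptive one with flipped signs
  mal <- summary(wsls_regression(sessions, scheme = "maladaptive"))
  expect_lt(mal$mean[mal$regressor == "win_shift_t1"], 0)
})

test_that("credit matrices have 16 cells with a 3x3 grid of interest", {
  sessions <- cached("credit_sessions", function() {
    sim_sessions(credit_params(), 20, seed0 = 850)
  })
  cm <- cached("credit_cm", function() credit_matrix(sessions))
  expect_equal(dim(cm$matrix), c(4, 4))
  expect_equal(sum(cm$of_interest), 9)
  expect_error(credit_matrix(list(toy_log())), "too short")
})

test_that("diagonal dominance holds for credit assignment and not for a GRS-only agent", {
  sessions <- cached("credit_sessions", function() {
    sim_sessions(credit_params(), 20, seed0 = 850)
  })
  cm <- cached("credit_cm", function() credit_matrix(sessions))
  dd <- diagonal_dominance(cm, per_session = TRUE)
  expect_gt(mean(dd), 2 * sd(dd) / sqrt(length(dd)))

  grs_sessions <- cached("grs_sessions", function() {
    sim_sessions(grs_only_params(), 20, seed0 = 900)
  })
  cm_grs <- cached("grs_cm", function() credit_matrix(grs_sessions))
  dd_grs <- diagonal_dominance(cm_grs, per_session = TRUE)
  expect_lt(abs(mean(dd_grs)), 2 * sd(dd_grs) / sqrt(length(dd_grs)) + 0.02)
})

test_that("diagonal dominance grows with the generating learning rate", {
  dd <- sapply(c(0.1, 0.4, 0.8), function(a) {
    sessions <- sim_sessions(credit_params(alpha = a, beta = 8), 15,
                             seed0 = 950 + round(1000 * a))
    mean(diagonal_dominance(credit_matrix(sessions), per_session = TRUE))
  })
  expect_gte(dd[2], dd[1] - 0.05)
  expect_gte(dd[3], dd[2] - 0.05)
  expect_gt(dd[3], dd[1])
})

test_that("win-stay strength increases with the generating learning rate", {
  ws1 <- summary(wsls_regression(cached("ws_alpha_low", function() {
    sim_sessions(model_params(alpha = 0.1), 30, seed0 = 301)
  }), scheme = "separate_adaptive"))
  ws2 <- summary(wsls_regression(cached("ws_alpha_high", function() {
    sim_sessions(model_params(alpha = 0.8), 30, seed0 = 308)
  }), scheme = "separate_adaptive"))
  expect_gt(ws2$mean[ws2$regressor == "win_stay_t1"],
            ws1$mean[ws1$regressor == "win_stay_t1"])
})

test_that("the reward-history profile separates reward tracking from reward indifference", {
  # GRS-dominant agent: weak credit assignment but strong reward-state
  # coupling makes recent rewards (whoever earned them) promote staying
  grs_dom <- cached("grs_dom_sessions", function() {
    sim_sessions(model_params(alpha = 0.3, alpha_R = 0.5, w_R = 0.9,
                              alpha_CL = 0, lambda_CS = 0.7, w_CL = 0,
                              w_CS = 0.4, side_bias = 0, beta = 6),
                 20, seed0 = 1000)
  })
  prof <- grs_reward_history_profile(credit_matrix(grs_dom))
  expect_equal(prof$lag, 1:3)
  expect_gt(mean(prof$estimate), 0)

  indiff <- cached("random_sessions", function() {
    sim_sessions(random_params(), 20, seed0 = 800)
  })
  prof0 <- grs_reward_history_profile(credit_matrix(indiff))
  expect_true(all(abs(prof0$estimate) < 2 * prof0$se + 0.05))
})

test_that("the GRS influence on learning is the product of weight and learning rate", {
  expect_equal(grs_influence(model_params(w_R = 0, alpha = 0.9)), 0)
  expect_equal(grs_influence(model_params(w_R = 0.9, alpha = 0)), 0)
  expect_equal(grs_influence(model_params(w_R = 0.5, alpha = 0.4)), 0.2)
})

test_that("performance statistics score value-guided accuracy and rewards", {
  p <- credit_params(alpha = 0.7, beta = 500)
  s_greedy <- sim_sessions(p, 5, seed0 = 1100)
  perf <- performance_stats(s_greedy, p)
  expect_true(all(perf$accuracy > 0.95))
  expect_equal(perf$reward_total,
               vapply(s_greedy, function(s) sum(s$trials$reward), numeric(1)))

  s_rand <- sim_sessions(random_params(), 10, seed0 = 1150)
  perf_r <- performance_stats(s_rand, model_params(alpha = 0.4, beta = 5))
  expect_lt(abs(mean(perf_r$accuracy) - 0.5), 0.1)

  # value-guided choice earns more than random choice on the same schedules
  s_best <- sim_sessions(p, 10, seed0 = 1150)
  expect_gt(mean(vapply(s_best, function(s) sum(s$trials$reward),
                        numeric(1))),
            mean(perf_r$reward_total))

  roll <- attr(perf, "rolling")[[1]]
  expect_equal(length(roll), 200)
  expect_true(all(roll[20:200] >= 0 & roll[20:200] <= 1, na.rm = TRUE))
})

test_that("condition contrasts are null-calibrated and detect nothing on shuffled labels", {
  set.seed(5)
  df <- data.frame(value = rnorm(40),
                   condition = rep(c("sham", "tus_47_12o"), each = 20),
                   subject = rep(paste0("m", 1:4), 10))
  cc <- condition_contrast(df)
  expect_lt(abs(cc$statistic), 3)
  expect_true(is.finite(cc$p_value))

  # permutation null: shuffled labels give a near-zero average effect
  effects <- replicate(30, {
    d <- df
    d$condition <- sample(d$condition)
    condition_contrast(d)$estimate
  })
  expect_lt(abs(mean(effects)), 2 * sd(effects) / sqrt(length(effects)) + 0.05)

  expect_error(condition_contrast(df[df$condition == "sham", ]),
               "at least 2 conditions")
})

test_that("the contrast accepts a trial-history fixed effect and degrades gracefully", {
  set.seed(6)
  df <- data.frame(value = rnorm(120),
                   condition = rep(c("sham", "tus_47_12o"), each = 60),
                   subject = rep(paste0("m", 1:4), 30),
                   lag = rep(1:3, 40))
  cc <- condition_contrast(df, history = "lag")
  expect_true(is.finite(cc$p_value))
  # a no-variance outcome forces a singular random-effect fit -> fallback
  df$value <- rep(c(0, 1e-9), 60)
  cc2 <- suppressWarnings(condition_contrast(df))
  expect_true(is.finite(cc2$statistic))
})
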