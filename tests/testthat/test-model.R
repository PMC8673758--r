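test_that("the latent state initializes to the printed values", {
  st <- init_state()
  expect_equal(unname(st$Q), c(0.5, 0.5, 0.5))
  expect_equal(st$R_trace, 0)
  expect_equal(st$CL_trace, 0)
  expect_equal(unname(st$CS_trace), c(0, 0, 0))
})

test_that("elementary trace updates follow the update equations", {
  expect_equal(update_r_trace(0, 1, 0.5), 0.5)
  expect_equal(update_r_trace(0.4, 1, 0), 0.4)
  expect_equal(update_r_trace(0.5, 0, 0.2), 0.4)

  expect_equal(prediction_error(0.5, 1, 0.9, 0), 0.5)
  expect_equal(prediction_error(1, 1, 0.3, 0), 0)
  expect_equal(prediction_error(0.5, 1, 0.4, 0.5), 0.7)

  expect_equal(update_q(0.5, 0.5, 0.5), 0.75)
  expect_equal(update_q(0.8, 0.5, 0), 0.8)

  expect_equal(update_cl_trace(0, "left", 1), 1)
  expect_equal(update_cl_trace(0.5, "left", 0), 0.5)
  expect_equal(update_cl_trace(0, "right", 0.3), -0.3)

  cs <- advance_cs_traces(c(A = 1, B = 0.5, C = 0), "B", 0.8)
  expect_equal(unname(cs$decayed), c(0.8, 0.4, 0))
  expect_equal(unname(cs$end_of_trial), c(0.8, 1, 0))
  cs0 <- advance_cs_traces(c(A = 1, B = 1, C = 1), "A", 0)
  expect_equal(unname(cs0$decayed), c(0, 0, 0))
  expect_equal(unname(cs0$end_of_trial["A"]), 1)
})

test_that("decision value combines Q difference, side bias and trace bonuses", {
  p <- model_params(w_CL = 0.5, w_CS = 0.3, side_bias = 0)
  st <- init_state()
  dv <- decision_value(st, "A", "B", p)
  expect_equal(dv$DV, 0)  # symmetric fresh state
  st$CL_trace <- 1        # all-left history
  dv <- decision_value(st, "A", "B", p)
  expect_equal(dv$CL_bonus, -1)
  expect_equal(dv$DV, -0.5)
  st$CL_trace <- 0
  st$CS_trace <- c(A = 0, B = 1, C = 0)  # right stimulus trace high
  dv <- decision_value(st, "A", "B", p)
  expect_equal(dv$CS_bonus, 1)
  expect_equal(dv$DV, 0.3)
})

test_that("choice probability is a softmax on the decision value", {
  expect_equal(choice_probability(3.7, 0, "right")$p_right, 0.5)
  expect_equal(choice_probability(1, 1, "right")$p_right, 1 / (1 + exp(-1)),
               tolerance = 1e-10)
  cp <- choice_probability(0.8, 2, "left")
  expect_equal(cp$p_choice, 1 - cp$p_right)
})

test_that("session log-likelihood matches an independent trial-loop oracle", {
  sch <- quick_schedule(seed = 4)
  set.seed(99)
  for (i in 1:8) {
    p <- model_params(alpha = runif(1), alpha_R = runif(1),
                      w_R = runif(1, -1, 1), alpha_CL = runif(1),
                      lambda_CS = runif(1), w_CL = runif(1, -1, 1),
                      w_CS = runif(1, -1, 1), side_bias = runif(1, -1, 1),
                      beta = runif(1, 0, 10))
    s <- simulate_agent(model_params(), sch, seed = i)
    expect_equal(session_loglik(p, s), oracle_loglik(p, s),
                 tolerance = 1e-10)
  }
  # dual-rate variant against the same oracle
  pd <- dual_rate_params(alpha_pos = 0.7, alpha_neg = 0.2, w_R = 0.4,
                         alpha_R = 0.3, beta = 4)
  s <- simulate_agent(pd, sch, seed = 31)
  expect_equal(session_loglik(pd, s), oracle_loglik(pd, s, dual = TRUE),
               tolerance = 1e-10)
})

test_that("with auxiliary parameters zeroed the model is Rescorla-Wagner + softmax", {
  p <- model_params(alpha = 0.35, alpha_R = 0, w_R = 0, alpha_CL = 0,
                    lambda_CS = 0, w_CL = 0, w_CS = 0, side_bias = 0,
                    beta = 3)
  s <- simulate_agent(p, quick_schedule(6), seed = 17)
  expect_equal(session_loglik(p, s),
               rw_softmax_loglik(0.35, 3, s), tolerance = 1e-10)
})

test_that("a flat softmax gives every choice probability one half", {
  s <- simulate_agent(random_params(), quick_schedule(2), seed = 3)
  expect_equal(session_loglik(random_params(), s), 200 * log(0.5),
               tolerance = 1e-12)
})

test_that("latent traces respect their bounds and p_left + p_right = 1", {
  p <- model_params(alpha = 0.9, alpha_R = 0.8, w_R = 0.9, alpha_CL = 0.7,
                    lambda_CS = 0.9, w_CL = -0.8, w_CS = 0.9,
                    side_bias = -0.5, beta = 6)
  for (seed in 1:5) {
    s <- simulate_agent(p, quick_schedule(seed), seed = seed + 50)
    d <- session_loglik(p, s, details = TRUE)$trials
    expect_true(all(d$r_trace >= 0 & d$r_trace <= 1))
    expect_true(all(d$cl_trace >= -1 & d$cl_trace <= 1))
    expect_true(all(d[, c("cs_a", "cs_b", "cs_c")] >= 0 &
                      d[, c("cs_a", "cs_b", "cs_c")] <= 1))
    expect_true(all(d$p_right > 0 & d$p_right < 1))
    expect_true(all(d$p_choice > 0 & d$p_choice < 1))
    ok_left <- d$loc == 1
    expect_equal(d$p_choice[ok_left], 1 - d$p_right[ok_left])
    expect_equal(d$p_choice[!ok_left], d$p_right[!ok_left])
  }
})

test_that("with w_R = 0 and binary rewards, Q values stay in [0, 1]", {
  p <- model_params(alpha = 0.95, w_R = 0, beta = 2)
  for (seed in 1:5) {
    s <- simulate_agent(p, quick_schedule(seed), seed = seed)
    d <- session_loglik(p, s, details = TRUE)$trials
    expect_true(all(d[, c("q_a", "q_b", "q_c")] >= 0 &
                      d[, c("q_a", "q_b", "q_c")] <= 1))
  }
})

test_that("raising beta weakly increases the probability of the higher-DV side", {
  s <- simulate_agent(model_params(), quick_schedule(9), seed = 2)
  betas <- c(0, 0.5, 1, 2, 5, 20, 100)
  base <- model_params()
  pc <- sapply(betas, function(b) {
    p <- base
    p["beta"] <- b
    d <- session_loglik(p, s, details = TRUE)$trials
    # probability assigned to whichever side the DV favours
    ifelse(d$dv >= 0, d$p_right, 1 - d$p_right)
  })
  for (j in 2:length(betas)) expect_true(all(pc[, j] >= pc[, j - 1] - 1e-12))
})

test_that("large beta does not overflow the likelihood", {
  p <- model_params(beta = 1e6, alpha = 0.5)
  s <- simulate_agent(model_params(), quick_schedule(1), seed = 1)
  expect_true(is.finite(session_loglik(p, s)))
})

test_that("simulation and evaluation share one state-advance routine", {
  p <- model_params(w_CL = 0.3, w_CS = 0.4, side_bias = 0.1)
  sch <- quick_schedule(12)
  s <- simulate_agent(p, sch, seed = 77)
  expect_identical(s, simulate_agent(p, sch, seed = 77))
  d <- session_loglik(p, s, details = TRUE)$trials
  # re-simulating with the same seed reproduces the same offers + uniforms,
  # so the evaluated choice probabilities must match the generative ones
  set.seed(77)
  off <- sample_offer(200)
  u_choice <- runif(200)
  went_right <- s$trials$chosen_side == "right"
  expect_identical(went_right, u_choice < d$p_right)
})

test_that("a greedy agent concentrates choice on the higher-Q option", {
  p <- credit_params(alpha = 0.7, beta = 100)
  s <- simulate_agent(p, quick_schedule(3), seed = 21)
  d <- session_loglik(p, s, details = TRUE)$trials
  qmat <- as.matrix(d[, c("q_a", "q_b", "q_c")])
  tr <- s$trials
  ql <- qmat[cbind(1:200, match(tr$left_option, c("A", "B", "C")))]
  qr <- qmat[cbind(1:200, match(tr$right_option, c("A", "B", "C")))]
  scored <- abs(ql - qr) > 0.1  # clear value differences: greedy limit
  best <- ifelse(qr > ql, "right", "left")
  expect_gt(mean(tr$chosen_side[scored] == best[scored]), 0.95)

  s0 <- simulate_agent(random_params(), quick_schedule(3), seed = 22)
  expect_lt(abs(mean(s0$trials$chosen_side == "left") - 0.5), 0.1)
})

test_that("the generating parameters dominate perturbed ones in likelihood", {
  p_true <- model_params(alpha = 0.4, beta = 5)
  for (shift in c(-0.2, 0.2)) {
    p_alt <- p_true
    p_alt["alpha"] <- p_true[["alpha"]] + shift
    delta <- sapply(1:30, function(i) {
      s <- simulate_agent(p_true, quick_schedule(i, 150), seed = 300 + i)
      session_loglik(p_true, s) - session_loglik(p_alt, s)
    })
    expect_gt(mean(delta), 0)
  }
})

test_that("out-of-bounds parameters are rejected", {
  expect_error(model_params(alpha = 1.2), "out of bounds")
  expect_error(model_params(w_R = -1.5), "out of bounds")
  expect_error(model_params(beta = -1), "out of bounds")
  expect_error(dual_rate_params(alpha_neg = 2), "out of bounds")
})
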