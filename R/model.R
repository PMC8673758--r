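#' Initial latent state of the model
#'
#' At the start of each session all three Q values are 0.5 and the reward
#' trace, location trace and stimulus traces are zero.  Stimuli are new in
#' every session, so no state carries across sessions.
#'
#' @return A list with elements `Q` (length-3, named A/B/C), `R_trace`,
#'   `CL_trace` and `CS_trace` (length-3, named A/B/C).
#' @export
init_state <- function() {
  list(Q = c(A = 0.5, B = 0.5, C = 0.5),
       R_trace = 0,
       CL_trace = 0,
       CS_trace = c(A = 0, B = 0, C = 0))
}

#' Elementary trial-wise updates of the latent traces
#'
#' These are the scalar building blocks of the model, exposed mainly for
#' documentation and testing; [session_loglik()] and [simulate_agent()] run
#' the same arithmetic in compiled code.
#'
#' `update_r_trace()` moves the global reward trace toward the outcome:
#' `R' = R + alpha_R * (r - R)`.
#'
#' @param R_trace current reward trace.
#' @param r outcome, 0 or 1.
#' @param alpha_R reward-trace learning rate in `[0, 1]`.
#' @return The updated trace.
#' @export
update_r_trace <- function(R_trace, r, alpha_R) {
  stopifnot(r %in% c(0, 1), alpha_R >= 0, alpha_R <= 1)
  R_trace + alpha_R * (r - R_trace)
}

#' @rdname update_r_trace
#' @details `prediction_error()` uses the reward trace from *before* this
#'   trial's reward-trace update: `PE = r + w_R * R_trace - Q_chosen`.
#' @param Q_chosen value of the chosen option.
#' @param w_R reward-trace weight in `[-1, 1]`.
#' @export
prediction_error <- function(Q_chosen, r, R_trace, w_R) {
  r + w_R * R_trace - Q_chosen
}

#' @rdname update_r_trace
#' @param PE prediction error.
#' @param alpha Q learning rate in `[0, 1]`.
#' @export
update_q <- function(Q_chosen, PE, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  Q_chosen + alpha * PE
}

#' @rdname update_r_trace
#' @details `update_cl_trace()` codes the chosen side as +1 (left) or -1
#'   (right) and moves the location trace toward it.
#' @param CL_trace current location trace.
#' @param chosen_side `"left"` or `"right"`.
#' @param alpha_CL location-trace learning rate in `[0, 1]`.
#' @export
update_cl_trace <- function(CL_trace, chosen_side, alpha_CL) {
  stopifnot(alpha_CL >= 0, alpha_CL <= 1)
  L <- if (identical(chosen_side, "left")) 1 else -1
  CL_trace + alpha_CL * (L - CL_trace)
}

#' @rdname update_r_trace
#' @details `advance_cs_traces()` decays all stimulus traces by
#'   `lambda_CS`; the decayed values feed the decision value on the current
#'   trial.  At the end of the trial the chosen option's trace is set to 1.
#' @param CS_trace named length-3 vector of stimulus traces.
#' @param chosen_option option label chosen this trial.
#' @param lambda_CS decay factor in `[0, 1]`.
#' @return For `advance_cs_traces()`: a list with `decayed` (the traces
#'   entering the decision value) and `end_of_trial` (after the chosen
#'   trace is reset to 1).
#' @export
advance_cs_traces <- function(CS_trace, chosen_option, lambda_CS) {
  stopifnot(lambda_CS >= 0, lambda_CS <= 1)
  decayed <- lambda_CS * CS_trace
  end <- decayed
  end[option_index(chosen_option)] <- 1
  list(decayed = decayed, end_of_trial = end)
}

#' Decision value and choice probability
#'
#' The decision value is the evidence for a rightward choice:
#' `DV = Q(right) - Q(left) + side_bias + w_CL * (-CL) + w_CS *
#' (CS(right) - CS(left))`, where the stimulus traces are the trial-wise
#' decayed values.  The probability of choosing right is a softmax,
#' `p(right) = 1 / (1 + exp(-beta * DV))`.
#'
#' @param state a latent state as from [init_state()], with `CS_trace`
#'   already decayed for the current trial.
#' @param left_option,right_option offered option labels.
#' @param params a [model_params()] vector.
#' @return `decision_value()` returns a list with `DV_simple`, `CL_bonus`,
#'   `CS_bonus` and `DV`.
#' @export
decision_value <- function(state, left_option, right_option, params) {
  stopifnot(left_option != right_option)
  l <- option_index(left_option)
  r <- option_index(right_option)
  dv_simple <- unname(state$Q[r] - state$Q[l] + params[["side_bias"]])
  cl_bonus <- -state$CL_trace
  cs_bonus <- unname(state$CS_trace[r] - state$CS_trace[l])
  list(DV_simple = dv_simple, CL_bonus = cl_bonus, CS_bonus = cs_bonus,
       DV = dv_simple + params[["w_CL"]] * cl_bonus +
         params[["w_CS"]] * cs_bonus)
}

#' @rdname decision_value
#' @param DV decision value (evidence for right).
#' @param beta inverse temperature, `>= 0`.
#' @param chosen_side `"left"` or `"right"`.
#' @return `choice_probability()` returns a list with `p_right` and
#'   `p_choice` (the probability of the observed choice).
#' @export
choice_probability <- function(DV, beta, chosen_side) {
  stopifnot(beta >= 0)
  p_right <- plogis(beta * DV)
  p_choice <- if (identical(chosen_side, "right")) p_right else 1 - p_right
  list(p_right = p_right, p_choice = p_choice)
}

session_vectors <- function(session) {
  tr <- session$trials
  list(left = option_index(tr$left_option) - 1L,
       right = option_index(tr$right_option) - 1L,
       chosen = option_index(tr$chosen_option) - 1L,
       reward = as.integer(tr$reward))
}

#' Log-likelihood of a session under the model
#'
#' Runs a single forward pass over the session: on each trial the stimulus
#' traces decay, the decision value and choice probability are computed
#' from the current state, and the state then advances on the observed
#' choice and reward (prediction error using the pre-update reward trace,
#' chosen Q updated, reward trace updated, chosen stimulus trace reset to 1,
#' location trace updated).  The log-likelihood is the sum of the log
#' probabilities of the observed choices, computed through a numerically
#' stable log-sigmoid so large `beta` cannot overflow.
#'
#' @param params a [model_params()] or [dual_rate_params()] vector.
#' @param session a [session_log()].
#' @param details if `TRUE`, also return the per-trial latent trajectory
#'   (Q values, traces, decision value, choice probabilities, prediction
#'   error, and the chosen/unchosen/unpresented option values used by the
#'   design-matrix builders).
#' @return If `details = FALSE`, the scalar log-likelihood.  Otherwise a
#'   list with `loglik`, `trials` (one row per trial) and `final_state`.
#' @export
#' @examples
#' sch <- generate_schedule(schedule_config(n_trials = 50, seed = 1))
#' s <- simulate_agent(model_params(), sch, seed = 2)
#' session_loglik(model_params(), s)
session_loglik <- function(params, session, details = FALSE) {
  dual <- is_dual(params)
  check_params(as.numeric(params), dual)
  v <- session_vectors(session)
  res <- cpp_session_pass(as.numeric(params), dual, v$left, v$right,
                          v$chosen, v$reward, details)
  if (!is.finite(res$loglik)) {
    stop("non-finite session log-likelihood: parameter-space guard failure",
         call. = FALSE)
  }
  if (!details) return(res$loglik)
  res$trials <- as.data.frame(res$trials)
  res
}

#' Simulate a model-based agent on a schedule
#'
#' Samples offers and sides pseudo-randomly, generates choices from the
#' model's softmax probabilities and outcomes from the schedule.  The state
#' evolves through exactly the same compiled advance routine as
#' [session_loglik()], so evaluating the produced log under the generating
#' parameters reproduces the simulated choice probabilities bit for bit.
#'
#' @inheritParams session_loglik
#' @param schedule a `reward_schedule`.
#' @param n_trials number of trials (defaults to the schedule length).
#' @param seed integer seed; the session is fully reproducible from it.
#' @param subject,condition metadata stored on the log.
#' @return A [session_log()].
#' @export
simulate_agent <- function(params, schedule, n_trials = nrow(schedule),
                           seed = 1L, subject = "sim", condition = "sham") {
  dual <- is_dual(params)
  check_params(as.numeric(params), dual)
  stopifnot(n_trials <= nrow(schedule))
  set.seed(seed)
  offers <- sample_offer(n_trials)
  u_choice <- runif(n_trials)
  u_reward <- runif(n_trials)
  left <- option_index(offers$left_option) - 1L
  right <- option_index(offers$right_option) - 1L
  sim <- cpp_simulate_pass(as.numeric(params), dual,
                           unclass(schedule)[seq_len(n_trials), , drop = FALSE],
                           left, right, u_choice, u_reward)
  chosen <- OPTIONS[sim$chosen + 1L]
  side <- ifelse(chosen == offers$left_option, "left", "right")
  session_log(trials = data.frame(trial = seq_len(n_trials) - 1L,
                                  offer_1 = pmin(offers$left_option,
                                                 offers$right_option),
                                  offer_2 = pmax(offers$left_option,
                                                 offers$right_option),
                                  left_option = offers$left_option,
                                  right_option = offers$right_option,
                                  chosen_option = chosen,
                                  chosen_side = side,
                                  reward = sim$reward,
                                  stringsAsFactors = FALSE),
              subject = subject, condition = condition, seed = seed,
              schedule = schedule)
}
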