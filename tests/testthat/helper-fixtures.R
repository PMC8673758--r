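# Shared fixtures built in code.  Heavy objects (hierarchical fits of
# full-size cohorts) are computed once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, fn) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, fn(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

quick_schedule <- function(seed = 1, n_trials = 200) {
  generate_schedule(schedule_config(n_trials = n_trials, seed = seed))
}

# simulate a small batch of sessions from one parameter set
sim_sessions <- function(params, n_sessions, n_trials = 200, seed0 = 1,
                         subjects = paste0("m", (seq_len(n_sessions) - 1) %% 4 + 1),
                         condition = "sham") {
  lapply(seq_len(n_sessions), function(i) {
    sch <- quick_schedule(seed = seed0 + i, n_trials = n_trials)
    simulate_agent(params, sch, seed = 10000 + seed0 + i,
                   subject = subjects[i], condition = condition)
  })
}

# a purely random chooser expressed in model terms
random_params <- function() {
  model_params(alpha = 0, alpha_R = 0, w_R = 0, alpha_CL = 0,
               lambda_CS = 0, w_CL = 0, w_CS = 0, side_bias = 0, beta = 0)
}

# strong credit assignment, no auxiliary traces
credit_params <- function(alpha = 0.5, beta = 8) {
  model_params(alpha = alpha, alpha_R = 0, w_R = 0, alpha_CL = 0,
               lambda_CS = 0, w_CL = 0, w_CS = 0, side_bias = 0, beta = beta)
}

# choice-blind reward tracker: values never update from own outcomes
grs_only_params <- function() {
  model_params(alpha = 0, alpha_R = 0.5, w_R = 0.5, alpha_CL = 0,
               lambda_CS = 0, w_CL = 0, w_CS = 0, side_bias = 0, beta = 8)
}

# --- named fixture constructors (self-contained, cached) ----------------

mle_sessions_fx <- function() {
  cached("mle_sessions", function() {
    sim_sessions(model_params(), 20, seed0 = 400)
  })
}

mle_fits_fx <- function() {
  cached("mle_fits", function() {
    sessions <- mle_sessions_fx()
    lapply(seq_along(sessions), function(i) {
      mle_fit(sessions[[i]], n_starts = 6, seed = i)
    })
  })
}

em_sessions_fx <- function() {
  cached("em_sessions", function() {
    c(sim_sessions(model_params(), 6, n_trials = 150, seed0 = 600),
      sim_sessions(model_params(alpha = 0.25), 4, n_trials = 150,
                   seed0 = 650, condition = "tus_47_12o"))
  })
}

em_fit_fx <- function() {
  cached("em_fit", function() {
    iterative_map(em_sessions_fx(), seed = 7, max_iter = 200)
  })
}

# full-size study cohort (40 sham + 20 TUS sessions of 200 trials) and its
# hierarchical fit; shared by the fitting, recovery and dissociation checks
acc_cohort_fx <- function() {
  cached("acc_cohort", function() make_cohort(cohort_spec(master_seed = 101L)))
}

acc_fit_fx <- function() {
  cached("acc_fit", function() {
    iterative_map(acc_cohort_fx()$sessions, seed = 101L)
  })
}

# Hand-built 10-trial log used for exhaustive enumeration of the
# occasion-lagged stay/shift table.
toy_log <- function() {
  trials <- data.frame(
    trial = 0:9,
    left_option  = c("A", "B", "A", "A", "A", "B", "A", "A", "B", "A"),
    right_option = c("B", "C", "C", "B", "C", "C", "B", "C", "C", "B"),
    chosen_option = c("A", "C", "A", "B", "C", "B", "A", "C", "B", "A"),
    reward = c(1, 0, 1, 0, 1, 1, 0, 0, 1, 1),
    stringsAsFactors = FALSE)
  trials$offer_1 <- pmin(trials$left_option, trials$right_option)
  trials$offer_2 <- pmax(trials$left_option, trials$right_option)
  trials$chosen_side <- ifelse(trials$chosen_option == trials$left_option,
                               "left", "right")
  session_log(trials, subject = "toy", condition = "sham")
}

# Expected stay/shift table for toy_log(), enumerated by hand:
# columns: stimulus, trial chosen, outcome, lag, offered_trial, stay.
toy_expected_events <- function() {
  e <- rbind(
    c("A", 0, 1, 1, 2, 1), c("A", 0, 1, 2, 3, 0), c("A", 0, 1, 3, 4, 0),
    c("A", 2, 1, 1, 3, 0), c("A", 2, 1, 2, 4, 0), c("A", 2, 1, 3, 6, 1),
    c("A", 6, 0, 1, 7, 0), c("A", 6, 0, 2, 9, 1),
    c("B", 3, 0, 1, 5, 1), c("B", 3, 0, 2, 6, 0), c("B", 3, 0, 3, 8, 1),
    c("B", 5, 1, 1, 6, 0), c("B", 5, 1, 2, 8, 1), c("B", 5, 1, 3, 9, 0),
    c("B", 8, 1, 1, 9, 0),
    c("C", 1, 0, 1, 2, 0), c("C", 1, 0, 2, 4, 1), c("C", 1, 0, 3, 5, 0),
    c("C", 4, 1, 1, 5, 0), c("C", 4, 1, 2, 7, 1), c("C", 4, 1, 3, 8, 0),
    c("C", 7, 0, 1, 8, 0))
  data.frame(stimulus = e[, 1],
             trial = as.integer(e[, 2]),
             outcome = as.integer(e[, 3]),
             lag = as.integer(e[, 4]),
             offered_trial = as.integer(e[, 5]),
             stay = as.integer(e[, 6]),
             stringsAsFactors = FALSE)
}
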