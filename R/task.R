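#' Configuration of a reward schedule
#'
#' Describes the drifting reward probabilities of the three-option restless
#' bandit session.  Option A drifts from high to low reward probability and
#' option C from low to high, exchanging roles around `reversal_fraction`;
#' option B wanders within a mid-range band.  Smooth random perturbations
#' decorrelate the three trajectories; schedules are rejection-sampled until
#' the mean pairwise shared variance (squared Pearson correlation) of the
#' three probability columns is at most `max_shared_variance`.
#'
#' @param n_trials number of trials in the session (default 200).
#' @param option_ranges list of three `c(lo, hi)` probability ranges, named
#'   `A`, `B`, `C`.  Each generated column attains both endpoints.
#' @param reversal_fraction position of the mid-session reversal as a
#'   fraction of the session, in `(0, 1)`.
#' @param reversal_width width of the reversal transition as a fraction of
#'   the session.
#' @param drift_smoothness width (in trials) of the Gaussian kernel used to
#'   smooth the random perturbations.
#' @param drift_amplitude standard deviation of the smoothed perturbations,
#'   in probability units, before rescaling into the option ranges.
#' @param max_shared_variance bound on the mean pairwise squared Pearson
#'   correlation between option columns, in `[0, 1]` (default 0.22).
#' @param max_attempts rejection-sampling budget before the configuration is
#'   declared infeasible.
#' @param seed integer seed making the schedule reproducible.
#'
#' @return A list of class `"schedule_config"`.
#' @export
schedule_config <- function(n_trials = 200,
                            option_ranges = list(A = c(0.10, 0.90),
                                                 B = c(0.30, 0.70),
                                                 C = c(0.10, 0.90)),
                            reversal_fraction = 0.5,
                            reversal_width = 0.08,
                            drift_smoothness = 10,
                            drift_amplitude = 0.3,
                            max_shared_variance = 0.22,
                            max_attempts = 100,
                            seed = 1L) {
  stopifnot(n_trials >= 2, length(option_ranges) == 3,
            reversal_fraction > 0, reversal_fraction < 1,
            max_shared_variance >= 0, max_shared_variance <= 1,
            drift_smoothness >= 0, max_attempts >= 1)
  if (is.null(names(option_ranges))) names(option_ranges) <- OPTIONS
  structure(list(n_trials = as.integer(n_trials),
                 option_ranges = option_ranges,
                 reversal_fraction = reversal_fraction,
                 reversal_width = reversal_width,
                 drift_smoothness = drift_smoothness,
                 drift_amplitude = drift_amplitude,
                 max_shared_variance = max_shared_variance,
                 max_attempts = as.integer(max_attempts),
                 seed = as.integer(seed)),
            class = "schedule_config")
}

# Gaussian-smoothed standard-normal noise of length n, standardized.
smooth_noise <- function(n, width, amplitude) {
  if (width <= 0 || amplitude <= 0) return(rnorm(n, 0, max(amplitude, 0)))
  pad <- 3L * ceiling(width)
  w <- rnorm(n + 2L * pad)
  k <- dnorm(seq(-3 * width, 3 * width), sd = width)
  k <- k / sum(k)
  s <- stats::filter(w, k, sides = 2)
  s <- as.numeric(s[(pad + 1L):(pad + n)])
  s <- s - mean(s)
  if (sd(s) > 0) s <- s / sd(s)
  amplitude * s
}

rescale_to <- function(x, lo, hi) {
  r <- range(x)
  if (r[1] == r[2]) return(rep((lo + hi) / 2, length(x)))
  lo + (hi - lo) * (x - r[1]) / (r[2] - r[1])
}

#' Mean pairwise shared variance of a schedule
#'
#' The squared Pearson correlation between each pair of the three option
#' probability columns, averaged over the three pairs.
#'
#' @param probs an `n x 3` probability matrix or a `reward_schedule`.
#' @return A number in `[0, 1]`.
#' @export
mean_shared_variance <- function(probs) {
  probs <- unclass(probs)
  stopifnot(is.matrix(probs), ncol(probs) == 3)
  r <- cor(probs)
  mean(r[upper.tri(r)]^2)
}

#' Generate a drifting reward schedule
#'
#' Draws per-trial reward probabilities for options A, B and C under the
#' constraints described in [schedule_config()]: option A spans its range
#' from high to low, option C mirrors it from low to high (the two reverse
#' near `reversal_fraction`), option B stays in a mid-range band, and the
#' mean pairwise shared variance between the columns does not exceed the
#' configured bound (rejection sampling).
#'
#' @param config a [schedule_config()].
#' @return An `n_trials x 3` matrix of class `"reward_schedule"` with
#'   columns `pA`, `pB`, `pC` and the config attached as attribute
#'   `"config"`.  Deterministic given `config$seed`.
#' @export
#' @examples
#' sch <- generate_schedule(schedule_config(seed = 7))
#' range(sch[, "pA"])
#' mean_shared_variance(sch)
generate_schedule <- function(config = schedule_config()) {
  stopifnot(inherits(config, "schedule_config"))
  set.seed(config$seed)
  n <- config$n_trials
  t_frac <- seq(0, 1, length.out = n)
  # logistic high->low step centred on the reversal
  step <- plogis((config$reversal_fraction - t_frac) / config$reversal_width)
  rng <- config$option_ranges
  for (attempt in seq_len(config$max_attempts)) {
    base_a <- rng$A[1] + diff(rng$A) * step
    base_c <- rng$C[2] - diff(rng$C) * step
    a <- rescale_to(base_a + smooth_noise(n, config$drift_smoothness,
                                          config$drift_amplitude),
                    rng$A[1], rng$A[2])
    c_ <- rescale_to(base_c + smooth_noise(n, config$drift_smoothness,
                                           config$drift_amplitude),
                     rng$C[1], rng$C[2])
    b <- rescale_to(smooth_noise(n, config$drift_smoothness, 1),
                    rng$B[1], rng$B[2])
    probs <- cbind(pA = a, pB = b, pC = c_)
    if (mean_shared_variance(probs) <= config$max_shared_variance) {
      return(structure(probs, class = "reward_schedule", config = config))
    }
  }
  stop("could not generate a schedule satisfying the shared-variance bound ",
       "of ", config$max_shared_variance, " within ", config$max_attempts,
       " attempts; the configuration is infeasible", call. = FALSE)
}

#' Sample offered option pairs and side assignments
#'
#' On each trial two of the three options are offered, drawn uniformly from
#' the three possible unordered pairs; the two offered options are then
#' assigned pseudo-randomly to the left and right sides.  Uses the current
#' RNG state, so results are reproducible under [set.seed()].
#'
#' @param n number of trials to sample.
#' @return A data frame with character columns `left_option` and
#'   `right_option` (distinct labels from `A`, `B`, `C`).
#' @export
sample_offer <- function(n = 1) {
  pairs <- matrix(c("A", "B", "A", "C", "B", "C"), ncol = 2, byrow = TRUE)
  idx <- sample.int(3L, n, replace = TRUE)
  flip <- runif(n) < 0.5
  first <- ifelse(flip, pairs[idx, 2], pairs[idx, 1])
  second <- ifelse(flip, pairs[idx, 1], pairs[idx, 2])
  data.frame(left_option = first, right_option = second,
             stringsAsFactors = FALSE)
}

#' Sample a probabilistic reward outcome
#'
#' Bernoulli draw with the probability the schedule assigns to `option` on
#' trial `t`.
#'
#' @param schedule a `reward_schedule` matrix.
#' @param option option label (`"A"`, `"B"` or `"C"`).
#' @param t 0-based trial index into the schedule.
#' @return 0 or 1.
#' @export
sample_outcome <- function(schedule, option, t) {
  probs <- unclass(schedule)
  if (any(t < 0 | t >= nrow(probs))) {
    stop("trial index out of schedule range: malformed session", call. = FALSE)
  }
  p <- probs[t + 1L, option_index(option)]
  as.integer(runif(length(p)) < p)
}

#' Run an agent through a session
#'
#' Generic agent-environment loop: on each trial an offer is sampled, the
#' agent's `choose()` function picks one of the two offered options, the
#' outcome is drawn from the schedule, and the agent's optional `learn()`
#' function observes the completed trial record.
#'
#' @param agent a list with `choose(left_option, right_option, t)` returning
#'   one of the two offered labels, and optionally
#'   `learn(chosen_option, chosen_side, reward, t)`.
#' @param schedule a `reward_schedule`.
#' @param n_trials number of trials (defaults to the schedule length).
#' @param seed integer seed; the full session is reproducible from it.
#' @param subject,condition metadata stored on the log.
#' @return A [session_log()] object.
#' @seealso [agent_fixed_side()], [agent_fixed_option()], [agent_random()],
#'   and [simulate_agent()] for the model-based agent.
#' @export
run_session <- function(agent, schedule, n_trials = nrow(schedule),
                        seed = 1L, subject = "sim", condition = "sham") {
  stopifnot(is.function(agent$choose), n_trials <= nrow(schedule))
  set.seed(seed)
  offers <- sample_offer(n_trials)
  u_reward <- runif(n_trials)
  probs <- unclass(schedule)
  chosen <- character(n_trials)
  side <- character(n_trials)
  reward <- integer(n_trials)
  for (t in seq_len(n_trials)) {
    l <- offers$left_option[t]
    r <- offers$right_option[t]
    ch <- agent$choose(l, r, t - 1L)
    if (!identical(ch, l) && !identical(ch, r)) {
      stop("agent chose option '", ch, "' which was not offered on trial ",
           t - 1L, call. = FALSE)
    }
    chosen[t] <- ch
    side[t] <- if (identical(ch, l)) "left" else "right"
    reward[t] <- as.integer(u_reward[t] < probs[t, option_index(ch)])
    if (is.function(agent$learn)) {
      agent$learn(ch, side[t], reward[t], t - 1L)
    }
  }
  session_log(trials = data.frame(trial = seq_len(n_trials) - 1L,
                                  offer_1 = pmin(offers$left_option,
                                                 offers$right_option),
                                  offer_2 = pmax(offers$left_option,
                                                 offers$right_option),
                                  left_option = offers$left_option,
                                  right_option = offers$right_option,
                                  chosen_option = chosen,
                                  chosen_side = side,
                                  reward = reward,
                                  stringsAsFactors = FALSE),
              subject = subject, condition = condition, seed = seed,
              schedule = schedule)
}

#' Construct a session log
#'
#' The ordered trial records of one session plus metadata.  Usually produced
#' by [run_session()] or [simulate_agent()] rather than called directly.
#'
#' @param trials data frame with columns `trial` (0-based, contiguous),
#'   `offer_1`, `offer_2`, `left_option`, `right_option`, `chosen_option`,
#'   `chosen_side` (`"left"`/`"right"`) and `reward` (0/1).
#' @param subject subject label.
#' @param condition one of `"sham"`, `"tus_47_12o"`, `"tus_aPFC"`.
#' @param seed integer seed the session was generated from (or `NA`).
#' @param schedule optional `reward_schedule` used to generate the session.
#' @param schedule_id optional schedule reference label.
#' @return A list of class `"session_log"`.
#' @export
session_log <- function(trials, subject = "s1", condition = "sham",
                        seed = NA_integer_, schedule = NULL,
                        schedule_id = NA_character_) {
  condition <- match.arg(condition, c("sham", "tus_47_12o", "tus_aPFC"))
  stopifnot(is.data.frame(trials),
            all(c("trial", "left_option", "right_option", "chosen_option",
                  "chosen_side", "reward") %in% names(trials)))
  if (!identical(as.integer(trials$trial), seq_len(nrow(trials)) - 1L)) {
    stop("trial indices must be contiguous from 0", call. = FALSE)
  }
  ok <- trials$chosen_option == trials$left_option |
    trials$chosen_option == trials$right_option
  if (!all(ok)) stop("chosen_option must be one of the offered options",
                     call. = FALSE)
  if (any(trials$left_option == trials$right_option)) {
    stop("the two offered options must be distinct", call. = FALSE)
  }
  structure(list(trials = trials, subject = subject, condition = condition,
                 seed = seed, schedule = schedule, schedule_id = schedule_id),
            class = "session_log")
}

#' @export
print.session_log <- function(x, ...) {
  cat("<session_log> ", nrow(x$trials), " trials | subject ", x$subject,
      " | condition ", x$condition, " | rewards ", sum(x$trials$reward),
      "\n", sep = "")
  invisible(x)
}

n_trials <- function(session) nrow(session$trials)

#' Simple reference agents
#'
#' `agent_fixed_side()` always picks the option on one side,
#' `agent_fixed_option()` picks a fixed stimulus whenever it is offered
#' (falling back to the left option otherwise), and `agent_random()` picks
#' uniformly.
#'
#' @param side `"left"` or `"right"`.
#' @return An agent list usable with [run_session()].
#' @export
agent_fixed_side <- function(side = c("left", "right")) {
  side <- match.arg(side)
  list(choose = function(l, r, t) if (side == "left") l else r)
}

#' @rdname agent_fixed_side
#' @param option option label to prefer.
#' @export
agent_fixed_option <- function(option = "A") {
  list(choose = function(l, r, t) if (option %in% c(l, r)) option else l)
}

#' @rdname agent_fixed_side
#' @export
agent_random <- function() {
  list(choose = function(l, r, t) if (runif(1) < 0.5) l else r)
}
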