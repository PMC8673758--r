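#' Gamma hemodynamic response kernel
#'
#' A gamma-shaped kernel with mean 3 s and standard deviation 1.5 s
#' (shape 4, scale 0.75), normalized to unit area on the supplied grid, as
#' used to convolve event regressors onto the scan-time grid in macaque
#' imaging work.
#'
#' @param times non-negative, evenly spaced time grid in seconds.
#' @param mean,sd kernel mean and standard deviation in seconds.
#' @return Kernel values on `times`, summing to `1 / dt`.
#' @export
#' @examples
#' t <- seq(0, 20, by = 0.05)
#' k <- gamma_hrf(t)
#' sum(k) * 0.05                  # unit area
#' sum(k * t) * 0.05              # first moment: 3 s
gamma_hrf <- function(times, mean = 3, sd = 1.5) {
  stopifnot(length(times) > 1)
  dt <- times[2] - times[1]
  stopifnot(dt > 0)
  shape <- (mean / sd)^2
  scale <- sd^2 / mean
  k <- dgamma(times, shape = shape, scale = scale)
  k / (sum(k) * dt)
}

# Piecewise-constant event series on a fine time grid.
events_to_series <- function(times, onsets, durations, heights) {
  x <- numeric(length(times))
  dt <- times[2] - times[1]
  for (e in seq_along(onsets)) {
    if (heights[e] == 0) next
    idx <- which(times >= onsets[e] & times < onsets[e] + max(durations[e], dt))
    x[idx] <- x[idx] + heights[e]
  }
  x
}

convolve_with_hrf <- function(x, times, mean = 3, sd = 1.5) {
  dt <- times[2] - times[1]
  kt <- seq(0, mean + 8 * sd, by = dt)
  k <- gamma_hrf(kt, mean, sd)
  y <- stats::convolve(c(x, numeric(length(k))), rev(k), type = "open")
  y[seq_along(x)] * dt
}

#' Trial event timing on the scanner clock
#'
#' Reaction times are not simulated, so the decision event has a fixed
#' configurable duration and trials are spaced by a fixed inter-trial
#' interval.
#'
#' @param n number of trials.
#' @param iti inter-trial interval in seconds (trial onset spacing).
#' @param dec_duration duration of the decision event in seconds.
#' @param feedback_delay time from decision onset to feedback onset in
#'   seconds.
#' @return A list with vectors `decision`, `response` and `feedback` of
#'   onset times in seconds.
#' @export
session_timing <- function(n, iti = 8, dec_duration = 0.5,
                           feedback_delay = 1.5) {
  onset <- (seq_len(n) - 1L) * iti
  list(decision = onset, response = onset + dec_duration,
       feedback = onset + feedback_delay)
}

new_regressor_set <- function(mat, times, tr, info) {
  structure(list(data = mat, times = times, TR = tr, info = info),
            class = "regressor_set")
}

#' @export
print.regressor_set <- function(x, ...) {
  cat("<regressor_set> ", ncol(x$data), " regressors x ", nrow(x$data),
      " volumes (TR = ", x$TR, " s)\n", sep = "")
  print(x$info)
  invisible(x)
}

# Assemble a regressor set from an event specification list.  Each element:
# list(onsets, durations, heights, convolve = TRUE/FALSE,
#      standardize = TRUE/FALSE).  Parametric heights are standardized to
# mean 0 / SD 1 across events *before* convolution; all-zero or constant
# height vectors give a zero or raw regressor with a warning upstream.
assemble_regressors <- function(spec, tr, t_end, dt, hrf_mean = 3,
                                hrf_sd = 1.5) {
  times <- seq(0, t_end, by = dt)
  vols <- seq(0, t_end, by = tr)
  mat <- matrix(0, length(vols), length(spec),
                dimnames = list(NULL, names(spec)))
  info <- data.frame(name = names(spec),
                     convolved = vapply(spec, `[[`, logical(1), "convolve"),
                     standardized = vapply(spec, `[[`, logical(1),
                                           "standardize"),
                     row.names = NULL, stringsAsFactors = FALSE)
  for (j in seq_along(spec)) {
    e <- spec[[j]]
    h <- e$heights
    if (e$standardize) {
      if (length(h) && sd(h) > 0) {
        h <- (h - mean(h)) / sd(h)
      } else {
        warning("regressor '", names(spec)[j], "' has no variance; ",
                "emitting a zero regressor", call. = FALSE)
        h <- rep(0, length(h))
      }
    }
    x <- events_to_series(times, e$onsets, e$durations, h)
    if (e$convolve) x <- convolve_with_hrf(x, times, hrf_mean, hrf_sd)
    mat[, j] <- x[findInterval(vols, times)]
  }
  new_regressor_set(mat, vols, tr, info)
}

#' Behavioral regressors for the adaptive-strategy analysis (GLM1)
#'
#' Builds the 16 named regressor time series of the win-stay/lose-shift
#' imaging analysis: an unmodulated decision constant (`DEC`), twelve
#' feedback-locked strategy regressors — win-stay, lose-shift (adaptive)
#' and win-shift, lose-stay (maladaptive) at occasion lags 1-3 (`WST1-3`,
#' `LShT1-3`, `WShT1-3`, `LST1-3`), standardized and convolved with the
#' gamma HRF — plus unconvolved left/right response boxcars of one TR
#' (`UNCleft`, `UNCright`) and a convolved left-minus-right response
#' regressor (`LminusR`).
#'
#' @param session a [session_log()].
#' @param strategy_table optional precomputed [build_strategy_events()]
#'   table.
#' @param tr repetition time of the scan grid in seconds (default 2.28).
#' @param iti,dec_duration,feedback_delay trial timing, see
#'   [session_timing()].
#' @param dt fine-grid resolution in seconds used for convolution.
#' @return A `regressor_set` with 16 columns.
#' @export
build_glm1 <- function(session, strategy_table = NULL, tr = 2.28, iti = 8,
                       dec_duration = 0.5, feedback_delay = 1.5, dt = 0.05) {
  if (is.null(strategy_table)) strategy_table <- build_strategy_events(session)
  tr_df <- session$trials
  n <- nrow(tr_df)
  tm <- session_timing(n, iti, dec_duration, feedback_delay)

  # per-trial strategy indicators; trials with no lag-k occasion stay 0
  strat <- function(outcome, stayed) {
    sapply(1:3, function(k) {
      v <- numeric(n)
      e <- strategy_table[strategy_table$lag == k &
                            strategy_table$outcome == outcome &
                            strategy_table$stay == stayed, ]
      v[e$trial + 1L] <- 1
      v
    })
  }
  ws <- strat(1, 1)   # win -> stayed
  lsh <- strat(0, 0)  # lose -> shifted
  wsh <- strat(1, 0)  # win -> shifted (maladaptive)
  lst <- strat(0, 1)  # lose -> stayed (maladaptive)

  fb_ev <- function(h) list(onsets = tm$feedback, durations = rep(0.1, n),
                            heights = h, convolve = TRUE, standardize = TRUE)
  spec <- c(
    list(DEC = list(onsets = tm$decision, durations = rep(dec_duration, n),
                    heights = rep(1, n), convolve = TRUE,
                    standardize = FALSE)),
    setNames(lapply(1:3, function(k) fb_ev(ws[, k])), paste0("WST", 1:3)),
    setNames(lapply(1:3, function(k) fb_ev(lsh[, k])), paste0("LShT", 1:3)),
    setNames(lapply(1:3, function(k) fb_ev(wsh[, k])), paste0("WShT", 1:3)),
    setNames(lapply(1:3, function(k) fb_ev(lst[, k])), paste0("LST", 1:3)),
    list(
      UNCleft = list(onsets = tm$feedback[tr_df$chosen_side == "left"],
                     durations = rep(tr, sum(tr_df$chosen_side == "left")),
                     heights = rep(1, sum(tr_df$chosen_side == "left")),
                     convolve = FALSE, standardize = FALSE),
      UNCright = list(onsets = tm$feedback[tr_df$chosen_side == "right"],
                      durations = rep(tr, sum(tr_df$chosen_side == "right")),
                      heights = rep(1, sum(tr_df$chosen_side == "right")),
                      convolve = FALSE, standardize = FALSE),
      LminusR = list(onsets = tm$response, durations = rep(0.1, n),
                     heights = ifelse(tr_df$chosen_side == "left", 1, -1),
                     convolve = TRUE, standardize = FALSE)))
  assemble_regressors(spec, tr, max(tm$feedback) + 20, dt)
}

#' Model-derived value regressors (GLM2)
#'
#' Builds the 15 named regressor time series of the choice-value imaging
#' analysis from the model's latent trajectory: the decision constant
#' (`DEC`); decision-locked parametric values of the chosen, unchosen and
#' unpresented options (`choV`, `uncV`, `unpV`); the chosen-minus-unchosen
#' stimulus-trace difference (`choT_uncT`), the unpresented stimulus trace
#' (`unpCT`) and the decision-locked location trace (`locT`); a
#' feedback-locked 100-ms reward-minus-no-reward regressor
#' (`REWminusNOREW`); unconvolved reward/no-reward and left/right nuisance
#' boxcars of one TR (`UNC_reward`, `UNC_noreward`, `UNCleft`, `UNCright`);
#' a response-locked choice-location regressor (`cClo`); and the reward
#' trace split into rewarded and unrewarded trials (`rewTreward`,
#' `rewTnoreward`).  Parametric regressors are standardized before
#' convolution.
#'
#' @param session a [session_log()].
#' @param fit a `session_fit` or a [model_params()] vector supplying the
#'   latent trajectory.
#' @inheritParams build_glm1
#' @return A `regressor_set` with 15 columns.
#' @export
build_glm2 <- function(session, fit, tr = 2.28, iti = 8,
                       dec_duration = 0.5, feedback_delay = 1.5, dt = 0.05) {
  if (missing(fit) || is.null(fit)) {
    stop("build_glm2 requires fitted parameters or a model_params vector",
         call. = FALSE)
  }
  params <- if (inherits(fit, "session_fit")) fit$params_native else fit
  ev <- session_loglik(params, session, details = TRUE)$trials
  tr_df <- session$trials
  n <- nrow(tr_df)
  tm <- session_timing(n, iti, dec_duration, feedback_delay)
  rewarded <- tr_df$reward == 1

  dec_ev <- function(h) list(onsets = tm$decision, durations = rep(0.1, n),
                             heights = h, convolve = TRUE,
                             standardize = TRUE)
  unc_box <- function(sel) list(onsets = tm$feedback[sel],
                                durations = rep(tr, sum(sel)),
                                heights = rep(1, sum(sel)),
                                convolve = FALSE, standardize = FALSE)
  spec <- list(
    DEC = list(onsets = tm$decision, durations = rep(dec_duration, n),
               heights = rep(1, n), convolve = TRUE, standardize = FALSE),
    choV = dec_ev(ev$cho_v),
    uncV = dec_ev(ev$unc_v),
    unpV = dec_ev(ev$unp_v),
    choT_uncT = dec_ev(ev$cho_t_minus_unc_t),
    unpCT = dec_ev(ev$unp_ct),
    locT = dec_ev(ev$cl_trace),
    REWminusNOREW = list(onsets = tm$feedback, durations = rep(0.1, n),
                         heights = ifelse(rewarded, 1, -1),
                         convolve = TRUE, standardize = FALSE),
    UNC_reward = unc_box(rewarded),
    UNC_noreward = unc_box(!rewarded),
    cClo = list(onsets = tm$response, durations = rep(0.1, n),
                heights = ev$loc, convolve = TRUE, standardize = TRUE),
    rewTreward = list(onsets = tm$feedback[rewarded],
                      durations = rep(0.1, sum(rewarded)),
                      heights = ev$r_trace[rewarded],
                      convolve = TRUE, standardize = TRUE),
    rewTnoreward = list(onsets = tm$feedback[!rewarded],
                        durations = rep(0.1, sum(!rewarded)),
                        heights = ev$r_trace[!rewarded],
                        convolve = TRUE, standardize = TRUE),
    UNCleft = unc_box(tr_df$chosen_side == "left"),
    UNCright = unc_box(tr_df$chosen_side == "right"))
  rs <- assemble_regressors(spec, tr, max(tm$feedback) + 20, dt)
  attr(rs, "trajectory") <- ev
  rs
}

#' Export a regressor set
#'
#' Writes the design matrix as CSV (rows = scan volumes) and a JSON
#' sidecar with the convolution metadata.
#'
#' @param rs a `regressor_set`.
#' @param csv_path CSV output path.
#' @param json_path optional JSON sidecar path (default: CSV path with a
#'   `.json` extension).
#' @return `csv_path`, invisibly.
#' @export
write_regressor_set <- function(rs, csv_path, json_path = NULL) {
  stopifnot(inherits(rs, "regressor_set"))
  df <- data.frame(volume = seq_len(nrow(rs$data)) - 1L,
                   time = rs$times, rs$data, check.names = FALSE)
  write.csv(df, csv_path, row.names = FALSE)
  if (is.null(json_path)) json_path <- sub("\\.csv$", ".json", csv_path)
  jsonlite::write_json(list(TR = rs$TR, n_volumes = nrow(rs$data),
                            regressors = rs$info),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
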