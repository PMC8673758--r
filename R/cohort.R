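#' Specification of a synthetic cohort
#'
#' Describes an experiment-shaped dataset: four subjects, five sessions per
#' condition per experiment, with the sham sessions of the two experiments
#' pooled (4 subjects x 5 sessions x 2 experiments = 40 sham sessions
#' contrasted with 4 x 5 = 20 stimulation sessions), 200 trials per
#' session.  Subject-level parameter effects are Gaussian in unconstrained
#' space and shared across that subject's sessions, with a smaller
#' per-session jitter; stimulation ("TUS") sessions receive an additive
#' shift of the native parameters (by default a learning-rate reduction of
#' 0.15), clipped to the parameter bounds.
#'
#' @param n_subjects number of subjects (default 4).
#' @param sessions_per_condition sessions per subject per condition within
#'   one experiment (default 5).
#' @param sham_experiments number of experiments whose sham sessions are
#'   pooled (default 2).
#' @param n_trials trials per session (default 200).
#' @param tus_condition label of the stimulation condition.
#' @param group_means group-level native-space parameter means, a
#'   [model_params()] vector.
#' @param subject_sd standard deviation of subject-level effects in
#'   unconstrained space.
#' @param session_sd standard deviation of per-session jitter in
#'   unconstrained space.
#' @param tus_effect named numeric vector of additive native-space shifts
#'   applied in the stimulation condition (default `c(alpha = -0.15)`).
#' @param schedule template [schedule_config()] for the per-session reward
#'   schedules (each session draws a fresh seed).
#' @param master_seed integer seed from which every session, schedule and
#'   parameter draw is derived.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects = 4, sessions_per_condition = 5,
                        sham_experiments = 2, n_trials = 200,
                        tus_condition = "tus_47_12o",
                        group_means = model_params(),
                        subject_sd = 0.3, session_sd = 0.1,
                        tus_effect = c(alpha = -0.15),
                        schedule = schedule_config(),
                        master_seed = 1L) {
  stopifnot(n_subjects >= 1, sessions_per_condition >= 1, n_trials >= 30)
  tus_condition <- match.arg(tus_condition, c("tus_47_12o", "tus_aPFC"))
  structure(list(n_subjects = as.integer(n_subjects),
                 sessions_per_condition = as.integer(sessions_per_condition),
                 sham_experiments = as.integer(sham_experiments),
                 n_trials = as.integer(n_trials),
                 tus_condition = tus_condition,
                 group_means = group_means,
                 subject_sd = subject_sd, session_sd = session_sd,
                 tus_effect = tus_effect,
                 schedule = schedule,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

clip_to_bounds <- function(p, eps = 1e-3) {
  info <- param_info(dual = FALSE)
  lo <- info$lower + ifelse(is.finite(info$lower), eps, 0)
  hi <- ifelse(is.finite(info$upper), info$upper - eps, Inf)
  pmin(pmax(p, lo), hi)
}

#' Generate a synthetic cohort of sessions with hidden true parameters
#'
#' Draws subject- and session-level parameters around the group means,
#' applies the stimulation shift in TUS sessions, generates a fresh reward
#' schedule per session and simulates the model agent on it.  Fully
#' reproducible from `spec$master_seed`.
#'
#' @param spec a [cohort_spec()].
#' @return A list with `sessions` (list of [session_log()]) and `truth`
#'   (data frame of per-session true native parameters plus `session`,
#'   `subject`, `condition`, `seed`).
#' @export
make_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  links <- make_links(dual = FALSE)
  mu <- links$to_unconstrained(spec$group_means)
  set.seed(spec$master_seed)
  subj_eff <- matrix(rnorm(spec$n_subjects * links$n, 0, spec$subject_sd),
                     nrow = spec$n_subjects)
  n_sham <- spec$sham_experiments * spec$sessions_per_condition
  per_subj <- n_sham + spec$sessions_per_condition
  n_total <- spec$n_subjects * per_subj
  seeds <- sample.int(.Machine$integer.max - 1L, 3L * n_total)
  sessions <- vector("list", n_total)
  truth <- vector("list", n_total)
  idx <- 0L
  for (s in seq_len(spec$n_subjects)) {
    conds <- c(rep("sham", n_sham),
               rep(spec$tus_condition, spec$sessions_per_condition))
    for (j in seq_len(per_subj)) {
      idx <- idx + 1L
      seed3 <- seeds[(3L * (idx - 1L) + 1L):(3L * idx)]
      set.seed(seed3[1])
      x <- mu + subj_eff[s, ] + rnorm(links$n, 0, spec$session_sd)
      p <- links$to_native(x)
      if (conds[j] != "sham" && length(spec$tus_effect)) {
        p[names(spec$tus_effect)] <- p[names(spec$tus_effect)] +
          spec$tus_effect
        p <- clip_to_bounds(p)
      }
      sch_cfg <- spec$schedule
      sch_cfg$n_trials <- spec$n_trials
      sch_cfg$seed <- seed3[2]
      sch <- generate_schedule(sch_cfg)
      sessions[[idx]] <- simulate_agent(structure(p, class = "model_params"),
                                        sch, seed = seed3[3],
                                        subject = paste0("m", s),
                                        condition = conds[j])
      truth[[idx]] <- data.frame(session = idx, subject = paste0("m", s),
                                 condition = conds[j], seed = seed3[3],
                                 as.data.frame(t(p)),
                                 stringsAsFactors = FALSE)
    }
  }
  list(sessions = sessions, truth = do.call(rbind, truth), spec = spec)
}

#' Parameter-recovery experiment
#'
#' Generates a cohort, fits it with [iterative_map()], and reports the
#' per-parameter Pearson correlation, bias (mean recovered minus true) and
#' root-mean-square error between true and recovered native parameters.
#'
#' @param spec a [cohort_spec()].
#' @param cohort optional pre-generated cohort (from [make_cohort()]); when
#'   supplied, `spec` is ignored for generation.
#' @param fit optional pre-computed `cohort_fit` for the cohort's sessions.
#' @param ... further arguments passed to [iterative_map()].
#' @return A list of class `"recovery_report"` with `report` (one row per
#'   parameter), `truth_recovered` (per-session long table), `fit` and
#'   `cohort`.
#' @export
run_recovery <- function(spec = cohort_spec(), cohort = NULL, fit = NULL,
                         ...) {
  if (is.null(cohort)) cohort <- make_cohort(spec)
  if (is.null(fit)) {
    fit <- iterative_map(cohort$sessions, seed = cohort$spec$master_seed, ...)
  }
  est <- as.data.frame(fit, sessions = cohort$sessions)
  pn <- param_info(dual = FALSE)$name
  rep_rows <- lapply(pn, function(p) {
    tru <- cohort$truth[[p]]
    rec <- est[[p]]
    data.frame(parameter = p,
               correlation = suppressWarnings(cor(tru, rec)),
               bias = mean(rec - tru),
               rmse = sqrt(mean((rec - tru)^2)),
               sd_true = sd(tru),
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, lapply(pn, function(p) {
    data.frame(session = cohort$truth$session,
               subject = cohort$truth$subject,
               condition = cohort$truth$condition,
               parameter = p, true = cohort$truth[[p]],
               recovered = est[[p]], stringsAsFactors = FALSE)
  }))
  structure(list(report = do.call(rbind, rep_rows), truth_recovered = long,
                 fit = fit, cohort = cohort),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> ", length(x$cohort$sessions), " sessions\n",
      sep = "")
  print(transform(x$report, correlation = round(correlation, 3),
                  bias = round(bias, 3), rmse = round(rmse, 3)))
  invisible(x)
}

tus_measures <- function(cohort, fit = NULL,
                         measures = c("reward_total", "win_stay", "alpha",
                                      "grs_influence", "accuracy")) {
  sessions <- cohort$sessions
  meta <- data.frame(subject = vapply(sessions, `[[`, character(1),
                                      "subject"),
                     condition = vapply(sessions, `[[`, character(1),
                                        "condition"),
                     stringsAsFactors = FALSE)
  out <- list()
  if ("reward_total" %in% measures) {
    out$reward_total <- data.frame(meta,
                                   value = vapply(sessions, function(s) {
                                     sum(s$trials$reward)
                                   }, numeric(1)))
  }
  if ("win_stay" %in% measures) {
    ws <- wsls_regression(sessions, scheme = "separate_adaptive")
    ws_sub <- ws[grepl("^win_stay", ws$regressor), ]
    out$win_stay <- data.frame(subject = ws_sub$subject,
                               condition = ws_sub$condition,
                               lag = ws_sub$lag, value = ws_sub$estimate)
  }
  if (!is.null(fit)) {
    est <- as.data.frame(fit, sessions = sessions)
    if ("alpha" %in% measures) {
      out$alpha <- data.frame(meta, value = est$alpha)
    }
    if ("grs_influence" %in% measures) {
      out$grs_influence <- data.frame(meta, value = grs_influence(fit))
    }
    if ("accuracy" %in% measures) {
      perf <- performance_stats(sessions, fit)
      out$accuracy <- data.frame(meta, value = perf$accuracy)
    }
  }
  out
}

contrast_row <- function(df, measure, replicate) {
  history <- if ("lag" %in% names(df)) "lag" else NULL
  cc <- condition_contrast(df, value = "value", history = history)
  data.frame(replicate = replicate, measure = measure,
             estimate = cc$estimate, statistic = cc$statistic,
             df = cc$df, p_value = cc$p_value, method = cc$method,
             stringsAsFactors = FALSE)
}

#' Replicated stimulation-effect experiment
#'
#' For each replicate, generates a cohort under `spec`, optionally fits it
#' hierarchically, and runs mixed-effects condition contrasts
#' (TUS versus sham) on per-session measures: reward totals and win-stay
#' coefficients always; fitted learning rate, choice accuracy under the
#' fitted parameters, and the global-reward-state influence
#' (`w_R * alpha`) when `fit_model = TRUE`.
#'
#' @param spec a [cohort_spec()]; set `tus_effect = c(alpha = 0)` for a
#'   null calibration.
#' @param n_replicates number of independent replicate cohorts.
#' @param seed seed from which per-replicate master seeds are drawn.
#' @param fit_model hierarchically fit each replicate (slow) to contrast
#'   model-derived measures as well as the model-free ones.
#' @param measures subset of measures to contrast; model-derived entries
#'   (`alpha`, `grs_influence`, `accuracy`) require `fit_model = TRUE`.
#' @param ... passed to [iterative_map()] when `fit_model = TRUE`.
#' @return A list of class `"tus_experiment"` with `contrasts` (one row
#'   per replicate and measure) and `summary` (per measure: mean effect,
#'   fraction of negative effects, rejection rate at p < 0.05).
#' @export
run_tus_experiment <- function(spec = cohort_spec(), n_replicates = 5,
                               seed = 1L, fit_model = TRUE,
                               measures = c("reward_total", "win_stay",
                                            "alpha", "grs_influence",
                                            "accuracy"), ...) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    sp <- spec
    sp$master_seed <- rep_seeds[r]
    cohort <- make_cohort(sp)
    fit <- if (fit_model) {
      iterative_map(cohort$sessions, seed = rep_seeds[r], ...)
    }
    m <- tus_measures(cohort, fit, measures = measures)
    for (nm in names(m)) {
      rows[[length(rows) + 1L]] <- contrast_row(m[[nm]], nm, r)
    }
  }
  contrasts <- do.call(rbind, rows)
  sp_list <- split(contrasts, contrasts$measure)
  summ <- do.call(rbind, lapply(names(sp_list), function(nm) {
    d <- sp_list[[nm]]
    data.frame(measure = nm, mean_effect = mean(d$estimate),
               frac_negative = mean(d$estimate < 0),
               rejection_rate = mean(d$p_value < 0.05),
               n_replicates = nrow(d), stringsAsFactors = FALSE)
  }))
  structure(list(contrasts = contrasts, summary = summ, spec = spec),
            class = "tus_experiment")
}

#' @export
print.tus_experiment <- function(x, ...) {
  cat("<tus_experiment> ", max(x$contrasts$replicate), " replicate(s)\n",
      sep = "")
  print(x$summary)
  invisible(x)
}
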