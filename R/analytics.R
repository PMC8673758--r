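#' Occasion-lagged stay/shift event table
#'
#' Because only two of the three stimuli appear on each trial, win-stay and
#' lose-shift behaviour is measured at *occasion* lags: for every occasion
#' on which a stimulus was chosen, the table records whether it was chosen
#' again (stay) or not (shift) on the first, second and third subsequent
#' occasion on which that same stimulus was *offered*.  Occasions on which
#' the stimulus never reappears produce no row (absent, not zero).
#'
#' @param session a [session_log()].
#' @return A data frame with columns `stimulus`, `trial` (0-based trial on
#'   which the stimulus was chosen), `outcome` (1 win / 0 lose), `lag`
#'   (1-3, in offered occasions), `offered_trial` (0-based trial of the
#'   lagged occasion), `stay` (1 if re-chosen there, 0 otherwise) and `gap`
#'   (raw-trial distance).
#' @export
build_strategy_events <- function(session) {
  tr <- session$trials
  out <- list()
  for (stim in OPTIONS) {
    offered <- which(tr$left_option == stim | tr$right_option == stim)
    chosen <- which(tr$chosen_option == stim)
    if (!length(chosen)) next
    pos <- match(chosen, offered)  # every chosen trial is an offered trial
    for (k in 1:3) {
      fut <- offered[pos + k]
      keep <- !is.na(fut)
      if (!any(keep)) next
      tc <- chosen[keep]
      ft <- fut[keep]
      out[[length(out) + 1L]] <- data.frame(
        stimulus = stim,
        trial = tr$trial[tc],
        outcome = tr$reward[tc],
        lag = k,
        offered_trial = tr$trial[ft],
        stay = as.integer(tr$chosen_option[ft] == stim),
        gap = tr$trial[ft] - tr$trial[tc],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(stimulus = character(), trial = integer(),
                      outcome = integer(), lag = integer(),
                      offered_trial = integer(), stay = integer(),
                      gap = integer()))
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$stimulus, OPTIONS), res$trial, res$lag), ]
  rownames(res) <- NULL
  res
}

scale_col <- function(x, center = TRUE) {
  if (center) x <- x - mean(x)
  s <- sd(x)
  if (is.finite(s) && s > 0) x / s else x
}

# Logistic fit returning named coefficients, with separation flagged as NA.
safe_logit <- function(y, X, intercept = TRUE) {
  df <- as.data.frame(X)
  form <- if (intercept) y ~ . else y ~ . - 1
  fit <- suppressWarnings(glm(form, data = cbind(data.frame(y = y), df),
                              family = binomial()))
  b <- coef(fit)[colnames(X)]
  if (any(!is.finite(b)) || any(abs(b) > 15, na.rm = TRUE)) {
    return(NULL)
  }
  b
}

#' Win-stay/lose-shift logistic regressions
#'
#' Per stimulus and session, fits a logistic regression of the stay/shift
#' indicator from [build_strategy_events()] on the outcome history at
#' occasion lags 1-3; the per-stimulus coefficients are then averaged so
#' each session contributes one coefficient per regressor.
#'
#' Schemes: `"combined"` uses a single outcome predictor per lag coded
#' +1 (win) / -1 (lose), fitted with an intercept, so a positive
#' coefficient means win-stay *and* lose-shift.  `"separate_adaptive"`
#' codes win and lose occasions as separate per-lag regressors (a
#' cell-means model without intercept); the win-stay coefficient is the
#' stay log-odds after a win and the lose-shift coefficient is the *shift*
#' log-odds after a loss, so positive values are adaptive for both.
#' `"maladaptive"` reports the sign-flipped win-shift and lose-stay
#' strengths.  Regressor columns are scaled to unit standard deviation
#' before fitting; sessions with complete separation are dropped with a
#' warning.
#'
#' @param sessions a [session_log()] or list of them.
#' @param scheme regression scheme, see Details.
#' @return A data frame of class `"wsls_result"`, one row per session and
#'   regressor, with columns `session`, `subject`, `condition`,
#'   `regressor`, `lag` and `estimate`.
#' @export
wsls_regression <- function(sessions,
                            scheme = c("combined", "separate_adaptive",
                                       "maladaptive")) {
  scheme <- match.arg(scheme)
  if (inherits(sessions, "session_log")) sessions <- list(sessions)
  rows <- list()
  dropped <- 0L
  for (i in seq_along(sessions)) {
    ev <- build_strategy_events(sessions[[i]])
    if (!nrow(ev)) next
    per_stim <- list()
    for (stim in unique(ev$stimulus)) {
      e <- ev[ev$stimulus == stim, ]
      if (length(unique(e$stay)) < 2) { dropped <- dropped + 1L; next }
      if (scheme == "combined") {
        X <- sapply(1:3, function(k) {
          ifelse(e$lag == k, ifelse(e$outcome == 1, 1, -1), 0)
        })
        colnames(X) <- paste0("wsls_t", 1:3)
        X <- apply(X, 2, scale_col, center = TRUE)
        b <- safe_logit(e$stay, X, intercept = TRUE)
      } else {
        Xw <- sapply(1:3, function(k) as.numeric(e$lag == k & e$outcome == 1))
        Xl <- sapply(1:3, function(k) as.numeric(e$lag == k & e$outcome == 0))
        X <- cbind(Xw, Xl)
        colnames(X) <- c(paste0("win_t", 1:3), paste0("lose_t", 1:3))
        keep <- colSums(X) > 0
        X <- apply(X, 2, scale_col, center = FALSE)
        X <- X[, keep, drop = FALSE]
        b_raw <- safe_logit(e$stay, X, intercept = FALSE)
        if (is.null(b_raw)) { dropped <- dropped + 1L; next }
        b <- setNames(rep(NA_real_, 6),
                      c(paste0("win_stay_t", 1:3), paste0("lose_shift_t", 1:3)))
        b[paste0("win_stay_t", 1:3)] <- b_raw[paste0("win_t", 1:3)]
        # shift log-odds after a loss = -(stay log-odds after a loss)
        b[paste0("lose_shift_t", 1:3)] <- -b_raw[paste0("lose_t", 1:3)]
        if (scheme == "maladaptive") {
          b <- setNames(-b, c(paste0("win_shift_t", 1:3),
                              paste0("lose_stay_t", 1:3)))
        }
      }
      if (is.null(b)) { dropped <- dropped + 1L; next }
      per_stim[[stim]] <- b
    }
    if (!length(per_stim)) next
    avg <- colMeans(do.call(rbind, per_stim), na.rm = TRUE)
    rows[[i]] <- data.frame(session = i,
                            subject = sessions[[i]]$subject,
                            condition = sessions[[i]]$condition,
                            regressor = names(avg),
                            lag = rep(1:3, length.out = length(avg)),
                            estimate = unname(avg),
                            stringsAsFactors = FALSE)
  }
  if (dropped > 0) {
    warning(dropped, " stimulus fit(s) dropped (complete separation or ",
            "degenerate stay/shift column)", call. = FALSE)
  }
  res <- do.call(rbind, rows)
  class(res) <- c("wsls_result", class(res))
  attr(res, "scheme") <- scheme
  res
}

#' Summarize WSLS coefficients across sessions
#'
#' @param object a `wsls_result`.
#' @param ... unused.
#' @return A data frame with the across-session mean, standard error and
#'   session count per regressor.
#' @export
summary.wsls_result <- function(object, ...) {
  sp <- split(object$estimate, object$regressor)
  data.frame(regressor = names(sp),
             mean = vapply(sp, mean, numeric(1), na.rm = TRUE),
             se = vapply(sp, function(x) {
               x <- x[is.finite(x)]
               sd(x) / sqrt(length(x))
             }, numeric(1)),
             n = vapply(sp, function(x) sum(is.finite(x)), numeric(1)),
             row.names = NULL)
}

#' Credit-assignment matrix
#'
#' For each stimulus X, the choice of X (versus the alternative) on trials
#' where X is offered is regressed on the 16 conjunctions of "X chosen at
#' trial lag i" and "reward delivered at trial lag j", for raw-trial lags
#' i, j in 1-4.  Trials on which X is not on screen contribute no outcome
#' row (the choice of X is undefined there); in the lagged regressors,
#' "X chosen at t-i" is 0 whenever X was not chosen at t-i, including
#' because it was not on screen.  The 3x3 sub-grid over lags 1-3 is the
#' grid of interest; lag-4 terms are kept in the fit only to absorb
#' longer-term trends.  Coefficient matrices are averaged over the three
#' stimuli and over sessions.
#'
#' @param sessions a [session_log()] or list of them.
#' @param n_lags number of raw-trial lags (4, giving 16 regressors).
#' @return An object of class `"credit_matrix"`: a list with `matrix` (the
#'   mean 4x4 coefficient grid, rows = choice lag, cols = reward lag),
#'   `per_session` (array session x i x j), `of_interest` (logical 4x4,
#'   `TRUE` on the 3x3 sub-grid) and `n_sessions`.
#' @export
credit_matrix <- function(sessions, n_lags = 4L) {
  if (inherits(sessions, "session_log")) sessions <- list(sessions)
  mats <- list()
  skipped <- 0L
  for (s in seq_along(sessions)) {
    tr <- sessions[[s]]$trials
    n <- nrow(tr)
    if (n <= n_lags + n_lags^2 + 1L) {
      stop("sessions too short to supply ", n_lags, " lags and estimate ",
           n_lags^2, " regressors", call. = FALSE)
    }
    per_stim <- list()
    for (stim in OPTIONS) {
      offered <- tr$left_option == stim | tr$right_option == stim
      chose <- as.numeric(tr$chosen_option == stim)
      rewarded <- tr$reward
      rows_t <- which(offered & seq_len(n) > n_lags)
      if (length(rows_t) < 2L * n_lags^2) { skipped <- skipped + 1L; next }
      y <- chose[rows_t]
      X <- matrix(NA_real_, length(rows_t), n_lags^2)
      nm <- character(n_lags^2)
      col <- 0L
      for (i in seq_len(n_lags)) {
        for (j in seq_len(n_lags)) {
          col <- col + 1L
          nm[col] <- sprintf("c%d_r%d", i, j)
          X[, col] <- chose[rows_t - i] * rewarded[rows_t - j]
        }
      }
      colnames(X) <- nm
      keep <- stats::complete.cases(X) & !is.na(y)
      y <- y[keep]
      X <- X[keep, , drop = FALSE]
      if (length(y) < n_lags^2 + 2L || length(unique(y)) < 2) {
        skipped <- skipped + 1L
        next
      }
      sds <- apply(X, 2, sd)
      if (any(sds == 0) || qr(scale(X))$rank < ncol(X)) {
        skipped <- skipped + 1L  # rank deficient: insufficient data
        next
      }
      X <- apply(X, 2, scale_col, center = TRUE)
      b <- safe_logit(y, X, intercept = TRUE)
      if (is.null(b)) { skipped <- skipped + 1L; next }
      per_stim[[stim]] <- matrix(b, n_lags, n_lags, byrow = TRUE)
    }
    if (!length(per_stim)) next
    mats[[length(mats) + 1L]] <- Reduce(`+`, per_stim) / length(per_stim)
  }
  if (!length(mats)) stop("no session yielded an estimable credit matrix",
                          call. = FALSE)
  if (skipped > 0) {
    message(skipped, " stimulus fit(s) skipped (rank deficiency or ",
            "insufficient data)")
  }
  arr <- array(unlist(mats), dim = c(n_lags, n_lags, length(mats)))
  interest <- matrix(FALSE, n_lags, n_lags)
  interest[1:3, 1:3] <- TRUE
  structure(list(matrix = apply(arr, 1:2, mean),
                 per_session = aperm(arr, c(3, 1, 2)),
                 of_interest = interest,
                 n_sessions = length(mats)),
            class = "credit_matrix")
}

#' @export
print.credit_matrix <- function(x, ...) {
  cat("<credit_matrix> averaged over", x$n_sessions, "sessions\n")
  m <- round(x$matrix, 3)
  dimnames(m) <- list(paste0("choice_t-", seq_len(nrow(m))),
                      paste0("reward_t-", seq_len(ncol(m))))
  print(m)
  invisible(x)
}

#' Diagonal dominance of a credit matrix
#'
#' Mean diagonal minus mean off-diagonal coefficient over the 3x3 grid of
#' interest; large positive values indicate contingent (correctly
#' assigned) choice-reward learning.
#'
#' @param cm a `credit_matrix`.
#' @param per_session return one value per session instead of the mean.
#' @return A number, or a vector if `per_session = TRUE`.
#' @export
diagonal_dominance <- function(cm, per_session = FALSE) {
  stopifnot(inherits(cm, "credit_matrix"))
  f <- function(m) {
    m <- m[1:3, 1:3]
    mean(diag(m)) - mean(m[row(m) != col(m)])
  }
  if (per_session) {
    apply(cm$per_session, 1, f)
  } else {
    f(cm$matrix)
  }
}

#' Reward-history (global reward state) profile of choice
#'
#' The reward-history margin of the credit-assignment matrix: for each
#' reward lag j in 1-3, the coefficient for "reward delivered at trial
#' t-j" marginalized (averaged) over the choice lags of the grid of
#' interest.  A positive profile means recent rewards — regardless of which
#' choice earned them — make the animal more likely to repeat choices.
#'
#' @param sessions a [session_log()], list of them, or an already computed
#'   [credit_matrix()].
#' @return A data frame with columns `lag`, `estimate` and `se` (across
#'   sessions).
#' @export
grs_reward_history_profile <- function(sessions) {
  cm <- if (inherits(sessions, "credit_matrix")) sessions else
    credit_matrix(sessions)
  per <- apply(cm$per_session[, 1:3, 1:3, drop = FALSE], c(1, 3), mean)
  data.frame(lag = 1:3,
             estimate = colMeans(per),
             se = apply(per, 2, sd) / sqrt(nrow(per)))
}

#' Overall influence of the global reward state on learning
#'
#' The reward-trace weight enters the prediction error, and the prediction
#' error updates values scaled by the learning rate, so the overall
#' influence of the global reward state on learning is the product
#' `w_R * alpha`.
#'
#' @param fit a `session_fit`, a `cohort_fit` (one value per session), or
#'   a [model_params()] vector.
#' @return A scalar, or a vector for a `cohort_fit`.
#' @export
grs_influence <- function(fit) {
  if (inherits(fit, "cohort_fit")) {
    return(vapply(fit$session_fits, function(f) {
      unname(f$params_native[["w_R"]] * f$params_native[["alpha"]])
    }, numeric(1)))
  }
  p <- if (inherits(fit, "session_fit")) fit$params_native else fit
  unname(p[["w_R"]] * p[["alpha"]])
}

#' Per-session choice accuracy and reward intake
#'
#' Accuracy is the frequency with which the session's choices select the
#' offered option with the higher model-derived value (Q at decision time
#' under the supplied parameters); trials where the two offered values are
#' exactly tied are excluded from the denominator.  Also returns the total
#' reward earned and a rolling accuracy over a sliding window.
#'
#' @param sessions a [session_log()] or list of them.
#' @param params_list a [model_params()] vector applied to all sessions, a
#'   list of such vectors, or a `cohort_fit` whose per-session estimates
#'   are used.
#' @param window width (in trials) of the rolling accuracy window.
#' @return A data frame with one row per session (`session`, `subject`,
#'   `condition`, `accuracy`, `n_scored`, `reward_total`); the rolling
#'   accuracy traces are attached as attribute `"rolling"`.
#' @export
performance_stats <- function(sessions, params_list, window = 20) {
  if (inherits(sessions, "session_log")) sessions <- list(sessions)
  if (inherits(params_list, "cohort_fit")) {
    params_list <- lapply(params_list$session_fits, `[[`, "params_native")
  }
  if (!is.list(params_list)) {
    params_list <- rep(list(params_list), length(sessions))
  }
  stopifnot(length(params_list) == length(sessions))
  rolling <- vector("list", length(sessions))
  rows <- lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    ev <- session_loglik(params_list[[i]], s, details = TRUE)
    tr <- s$trials
    qmat <- as.matrix(ev$trials[, c("q_a", "q_b", "q_c")])
    ql <- qmat[cbind(seq_len(nrow(tr)), option_index(tr$left_option))]
    qr <- qmat[cbind(seq_len(nrow(tr)), option_index(tr$right_option))]
    tie <- ql == qr
    best <- ifelse(qr > ql, tr$right_option, tr$left_option)
    correct <- as.numeric(tr$chosen_option == best)
    correct[tie] <- NA
    roll <- rep(NA_real_, nrow(tr))
    if (nrow(tr) >= window) {
      cc <- ifelse(is.na(correct), 0, correct)
      nn <- as.numeric(!is.na(correct))
      num <- as.numeric(stats::filter(cc, rep(1, window), sides = 1))
      den <- as.numeric(stats::filter(nn, rep(1, window), sides = 1))
      roll <- ifelse(den > 0, num / den, NA_real_)
    }
    rolling[[i]] <<- roll
    data.frame(session = i, subject = s$subject, condition = s$condition,
               accuracy = mean(correct, na.rm = TRUE),
               n_scored = sum(!is.na(correct)),
               reward_total = sum(tr$reward),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "rolling") <- rolling
  out
}

#' Mixed-effects condition contrast
#'
#' Fits a linear mixed-effects model of a per-session (or per-session x
#' lag) measure on condition, with trial-history (lag) as an additional
#' fixed effect when present and subject as a random intercept.  Used for
#' fitted learning rates, win-stay/lose-shift coefficients, accuracy and
#' reward totals alike.  If the random-effects fit is singular or fails,
#' the contrast falls back to a fixed-effects linear model and records the
#' downgrade.
#'
#' @param data data frame containing the measure and design columns.
#' @param value name of the measure column.
#' @param condition name of the condition column (the first level in
#'   factor order is the reference, typically `"sham"`).
#' @param subject name of the subject column.
#' @param history optional name of a trial-history (lag) column to include
#'   as a fixed effect.
#' @return A list of class `"condition_contrast"` with `estimate`,
#'   `statistic` (t), `df`, `p_value`, `term`, `method`, and the fitted
#'   `model`.
#' @export
condition_contrast <- function(data, value = "value",
                               condition = "condition",
                               subject = "subject", history = NULL) {
  stopifnot(all(c(value, condition, subject) %in% names(data)))
  df <- data.frame(.y = data[[value]],
                   .cond = factor(data[[condition]]),
                   .subj = factor(data[[subject]]))
  if (length(levels(df$.cond)) < 2) {
    stop("condition_contrast needs at least 2 conditions", call. = FALSE)
  }
  if (length(levels(df$.subj)) < 2) {
    stop("condition_contrast needs at least 2 subjects", call. = FALSE)
  }
  rhs <- ".cond"
  if (!is.null(history)) {
    df$.hist <- factor(data[[history]])
    rhs <- ".cond + .hist"
  }
  df <- df[is.finite(df$.y), ]
  method <- "linear mixed-effects (subject random intercept)"
  fit <- tryCatch(
    lmerTest::lmer(as.formula(paste0(".y ~ ", rhs, " + (1 | .subj)")),
                   data = df),
    error = function(e) NULL)
  singular <- !is.null(fit) && lme4::isSingular(fit, tol = 1e-5)
  if (is.null(fit) || singular) {
    method <- "fixed-effects fallback (singular or failed random-effects fit)"
    lmfit <- lm(as.formula(paste0(".y ~ ", rhs)), data = df)
    ct <- summary(lmfit)$coefficients
    term <- grep("^\\.cond", rownames(ct), value = TRUE)[1]
    res <- list(estimate = ct[term, 1], statistic = ct[term, 3],
                df = lmfit$df.residual, p_value = ct[term, 4],
                term = sub("^\\.cond", "", term), method = method,
                model = lmfit)
  } else {
    ct <- coef(summary(fit))  # lmerTest: Satterthwaite df
    term <- grep("^\\.cond", rownames(ct), value = TRUE)[1]
    res <- list(estimate = ct[term, "Estimate"],
                statistic = ct[term, "t value"],
                df = ct[term, "df"],
                p_value = ct[term, "Pr(>|t|)"],
                term = sub("^\\.cond", "", term), method = method,
                model = fit)
  }
  class(res) <- "condition_contrast"
  res
}

#' @export
print.condition_contrast <- function(x, ...) {
  cat("<condition_contrast> ", x$term, ": estimate ",
      signif(x$estimate, 4), ", t(", round(x$df, 1), ") = ",
      round(x$statistic, 3), ", p = ", signif(x$p_value, 3), "\n  [",
      x$method, "]\n", sep = "")
  invisible(x)
}
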