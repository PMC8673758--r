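#' Group-level Gaussian prior over unconstrained parameters
#'
#' @param mean,variance numeric vectors of per-parameter means and
#'   variances in unconstrained (link-transformed) space.
#' @return A list of class `"group_prior"`.
#' @export
group_prior <- function(mean, variance) {
  stopifnot(length(mean) == length(variance), all(variance > 0))
  structure(list(mean = mean, variance = variance), class = "group_prior")
}

neg_objective <- function(session_v, dual, prior = NULL) {
  info <- param_info(dual)
  code <- match(info$link, c("unit", "signed", "positive")) - 1L
  pm <- if (is.null(prior)) numeric(0) else as.numeric(prior$mean)
  pv <- if (is.null(prior)) numeric(0) else as.numeric(prior$variance)
  left <- session_v$left
  right <- session_v$right
  chosen <- session_v$chosen
  reward <- session_v$reward
  function(x) {
    cpp_neg_objective(x, code, dual, left, right, chosen, reward, pm, pv)
  }
}

optimise_session <- function(session, dual, prior, starts) {
  v <- session_vectors(session)
  fn <- neg_objective(v, dual, prior)
  links <- make_links(dual)
  best <- NULL
  n_conv <- 0L
  for (i in seq_len(nrow(starts))) {
    opt <- tryCatch(nlminb(starts[i, ], fn,
                           control = list(iter.max = 500, eval.max = 1000)),
                    error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) next
    n_conv <- n_conv + 1L
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best)) {
    stop("all optimizer starts failed: degenerate session", call. = FALSE)
  }
  x <- best$par
  ll <- -neg_objective(v, dual, NULL)(x)
  lpost <- NULL
  post_var <- NULL
  if (!is.null(prior)) {
    lpost <- ll + sum(dnorm(x, prior$mean, sqrt(prior$variance), log = TRUE))
    # Laplace posterior variances from the inverse Hessian at the MAP;
    # these feed the M-step so the group variance reflects estimation
    # uncertainty, not only the spread of the point estimates
    post_var <- tryCatch({
      H <- stats::optimHess(x, fn)
      pv <- tryCatch(diag(solve(H)),
                     error = function(e) 1 / pmax(diag(H), 1e-8))
      pmin(pmax(pv, 0), prior$variance)
    }, error = function(e) rep(0, length(x)))
  } else {
    lpost <- ll
  }
  structure(list(params_native = links$to_native(x),
                 params_unconstrained = setNames(x, links$info$name),
                 log_likelihood = ll,
                 log_posterior = lpost,
                 posterior_variance = post_var,
                 n_trials = length(v$left),
                 convergence = best$convergence,
                 n_starts_converged = n_conv,
                 dual = dual),
            class = "session_fit")
}

draw_starts <- function(n_starts, prior, links, include = NULL) {
  k <- links$n
  sds <- pmin(sqrt(prior$variance), 2)  # keep starts in a sane region
  s <- matrix(rnorm(n_starts * k, rep(prior$mean, each = n_starts),
                    rep(sds, each = n_starts)),
              nrow = n_starts)
  s <- rbind(matrix(prior$mean, nrow = 1), s)
  if (!is.null(include)) s <- rbind(matrix(include, nrow = 1), s)
  s
}

flat_prior <- function(links) {
  group_prior(rep(0, links$n), rep(1e6, links$n))
}

#' Maximum-likelihood fit of a single session
#'
#' Multi-start bounded optimization of [session_loglik()] in unconstrained
#' space (bounds are enforced by the link functions of [make_links()]).
#'
#' @param session a [session_log()] with at least 30 trials.
#' @param n_starts number of random optimizer starts.
#' @param seed seed for the start draws.
#' @param dual fit the dual-learning-rate variant.
#' @param starts optional matrix of explicit start points (rows) in
#'   unconstrained space, overriding the random draws.
#' @return A `session_fit`: native and unconstrained estimates, the log
#'   likelihood at the optimum, and optimizer diagnostics.
#' @export
mle_fit <- function(session, n_starts = 10, seed = 1L, dual = FALSE,
                    starts = NULL) {
  if (n_trials(session) < 30) {
    stop("mle_fit requires at least 30 trials", call. = FALSE)
  }
  links <- make_links(dual)
  if (is.null(starts)) {
    set.seed(seed)
    starts <- draw_starts(n_starts, group_prior(rep(0, links$n),
                                                rep(2.25, links$n)), links)
  }
  optimise_session(session, dual, prior = NULL, starts = starts)
}

#' Expectation step: per-session MAP estimates under a group prior
#'
#' Each session maximizes the sum of its choice log-likelihood and the log
#' Gaussian prior density in unconstrained space.
#'
#' @param sessions list of [session_log()] objects.
#' @param prior a [group_prior()].
#' @param n_starts random starts drawn from the prior (the prior mean is
#'   always included as a start).
#' @param seed seed for the start draws.
#' @param init optional matrix (sessions x parameters) of warm-start points
#'   from a previous iteration; when supplied, each session is re-optimized
#'   from its own previous estimate only (no fresh random starts).
#' @param dual fit the dual-learning-rate variant.
#' @return A list of `session_fit` objects.
#' @export
map_estep <- function(sessions, prior, n_starts = 10, seed = 1L,
                      init = NULL, dual = FALSE) {
  stopifnot(inherits(prior, "group_prior"))
  links <- make_links(dual)
  set.seed(seed)
  lapply(seq_along(sessions), function(i) {
    starts <- if (is.null(init)) {
      draw_starts(n_starts, prior, links)
    } else {
      matrix(init[i, ], nrow = 1)
    }
    optimise_session(sessions[[i]], dual, prior, starts)
  })
}

#' Maximization step: refit the group Gaussian to the session estimates
#'
#' Sets the prior mean to the empirical mean (maximum likelihood, divisor
#' `n`) of the unconstrained MAP estimates.  The prior variance adds the
#' mean Laplace posterior variance of the session estimates (when the
#' E-step computed it) to the second moment of the point estimates:
#' without that term the point estimates, already shrunk toward the prior
#' mean, understate the group variance and the prior collapses onto its
#' floor within a few iterations.  A variance floor guards the degenerate
#' identical-fits case.
#'
#' @param fits list of `session_fit` objects (at least 2).
#' @param var_floor lower bound on each prior variance.
#' @return A [group_prior()].
#' @export
map_mstep <- function(fits, var_floor = 1e-4) {
  if (length(fits) < 2) stop("map_mstep requires at least 2 sessions",
                             call. = FALSE)
  x <- do.call(rbind, lapply(fits, `[[`, "params_unconstrained"))
  m <- colMeans(x)
  v <- colMeans(sweep(x, 2, m)^2)
  pv <- lapply(fits, `[[`, "posterior_variance")
  if (!any(vapply(pv, is.null, logical(1)))) {
    v <- v + colMeans(do.call(rbind, pv))
  }
  group_prior(m, pmax(v, var_floor))
}

#' Iterative MAP (empirical-Bayes EM) fitting of a session cohort
#'
#' Alternates per-session MAP estimation (E-step) with re-estimation of the
#' group-level Gaussian from the session estimates (M-step).  All sessions
#' — typically the pooled sham sessions plus one stimulation condition —
#' share a single prior, so condition differences in the fitted parameters
#' cannot be an artifact of different priors.  The group Gaussians are
#' initialized as uninformative priors with means 0.1 (plus a little seeded
#' noise) and variance 100; iteration stops when the posterior likelihood
#' summed over the group changes by less than `tol` or after `max_iter`
#' steps.
#'
#' @param sessions list of [session_log()] objects.
#' @param max_iter maximum number of EM iterations (default 800).
#' @param tol convergence threshold on the change in summed posterior
#'   likelihood (default 0.001).
#' @param n_starts optimizer starts per session on the first E-step; later
#'   E-steps warm-start from the previous estimates.
#' @param seed seed controlling start draws and prior-mean noise.
#' @param var_floor variance floor applied in the M-step.
#' @param init_mean,init_variance initial prior mean and variance.
#' @param init_noise_sd standard deviation of the noise added to the
#'   initial prior means.
#' @param dual fit the dual-learning-rate variant.
#' @param verbose print per-iteration posterior likelihoods.
#' @return A list of class `"cohort_fit"`: `session_fits`, final `prior`,
#'   `prior_trace` (per-iteration posterior and prior moments),
#'   `iterations`, and `converged` (`FALSE`, not an error, when `max_iter`
#'   is exhausted).
#' @export
iterative_map <- function(sessions, max_iter = 800, tol = 0.001,
                          n_starts = 10, seed = 1L, var_floor = 1e-4,
                          init_mean = 0.1, init_variance = 100,
                          init_noise_sd = 0.01, dual = FALSE,
                          verbose = FALSE) {
  stopifnot(length(sessions) >= 2)
  links <- make_links(dual)
  k <- links$n
  set.seed(seed)
  prior <- group_prior(rep(init_mean, k) + rnorm(k, 0, init_noise_sd),
                       rep(init_variance, k))
  fits <- NULL
  trace <- vector("list", 0)
  post_prev <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    init <- if (is.null(fits)) NULL else
      do.call(rbind, lapply(fits, `[[`, "params_unconstrained"))
    fits <- map_estep(sessions, prior, n_starts = n_starts,
                      seed = seed + it, init = init, dual = dual)
    post <- sum(vapply(fits, `[[`, numeric(1), "log_posterior"))
    trace[[it]] <- data.frame(iteration = it, posterior = post,
                              t(setNames(prior$mean,
                                         paste0("mean_", links$info$name))),
                              t(setNames(prior$variance,
                                         paste0("var_", links$info$name))))
    if (verbose) message("iteration ", it, ": posterior ", round(post, 4))
    if (is.finite(post_prev) && abs(post - post_prev) < tol) {
      converged <- TRUE
      break
    }
    post_prev <- post
    prior <- map_mstep(fits, var_floor = var_floor)
  }
  structure(list(session_fits = fits, prior = prior,
                 prior_trace = do.call(rbind, trace),
                 iterations = it, converged = converged, dual = dual,
                 tol = tol, max_iter = max_iter),
            class = "cohort_fit")
}

#' @export
print.cohort_fit <- function(x, ...) {
  cat("<cohort_fit> ", length(x$session_fits), " sessions | ",
      x$iterations, " iterations | converged: ", x$converged,
      if (x$dual) " | dual learning rates" else "", "\n", sep = "")
  invisible(x)
}

#' Per-session parameter table of a cohort fit
#'
#' @param x a `cohort_fit`.
#' @param sessions optional list of the fitted sessions, used to attach
#'   subject and condition metadata.
#' @param ... unused.
#' @return A data frame, one row per session, with the native-space
#'   estimates, log-likelihood and log-posterior.
#' @export
as.data.frame.cohort_fit <- function(x, sessions = NULL, ...) {
  tab <- do.call(rbind, lapply(x$session_fits, function(f) {
    as.data.frame(t(f$params_native))
  }))
  tab$log_likelihood <- vapply(x$session_fits, `[[`, numeric(1),
                               "log_likelihood")
  tab$log_posterior <- vapply(x$session_fits, `[[`, numeric(1),
                              "log_posterior")
  tab$n_trials <- vapply(x$session_fits, `[[`, numeric(1), "n_trials")
  tab$session <- seq_len(nrow(tab))
  if (!is.null(sessions)) {
    tab$subject <- vapply(sessions, `[[`, character(1), "subject")
    tab$condition <- vapply(sessions, `[[`, character(1), "condition")
  }
  rownames(tab) <- NULL
  tab
}

#' Compare single- and dual-learning-rate models on a cohort
#'
#' Fits the cohort with [iterative_map()] under both the single-rate model
#' and the variant with separate learning rates for positive and negative
#' prediction errors, and compares them with the Bayesian information
#' criterion computed per session from the MAP log-likelihoods and summed
#' over sessions.
#'
#' @inheritParams iterative_map
#' @param ... further arguments passed to [iterative_map()].
#' @return A list with both `cohort_fit`s, the summed BIC of each, and
#'   `preferred` (`"single"` or `"dual"`).
#' @export
fit_dual_rate_variant <- function(sessions, ...) {
  single <- iterative_map(sessions, dual = FALSE, ...)
  dual <- iterative_map(sessions, dual = TRUE, ...)
  bic <- function(fit, k) {
    sum(vapply(fit$session_fits, function(f) {
      -2 * f$log_likelihood + k * log(f$n_trials)
    }, numeric(1)))
  }
  bic_single <- bic(single, 9)
  bic_dual <- bic(dual, 10)
  list(single = single, dual = dual,
       bic_single = bic_single, bic_dual = bic_dual,
       preferred = if (bic_single <= bic_dual) "single" else "dual")
}

#' Serialize a cohort fit to JSON
#'
#' @param fit a `cohort_fit`.
#' @param path file to write.
#' @param sessions optional session list for metadata (see
#'   [as.data.frame.cohort_fit()]).
#' @return The path, invisibly.
#' @export
write_cohort_fit <- function(fit, path, sessions = NULL) {
  obj <- list(estimates = as.data.frame(fit, sessions = sessions),
              prior = list(mean = fit$prior$mean,
                           variance = fit$prior$variance),
              prior_trace = fit$prior_trace,
              iterations = fit$iterations,
              converged = fit$converged,
              dual = fit$dual)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
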