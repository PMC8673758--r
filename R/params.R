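#' Model parameters for the reinforcement-learning agent
#'
#' Bundles the nine free parameters of the choice model into a named,
#' bound-checked vector.  The model combines Rescorla-Wagner value learning
#' over three stimuli with a global reward state (R-trace) entering the
#' prediction error, and two outcome-independent choice-memory traces: a
#' location trace (CL-trace) and per-stimulus choice traces (CS-traces).
#'
#' @param alpha Q-value learning rate, in `[0, 1]`.
#' @param alpha_R learning rate of the global reward trace, in `[0, 1]`.
#' @param w_R weight of the reward trace inside the prediction error, in
#'   `[-1, 1]`.
#' @param alpha_CL learning rate of the choice-location trace, in `[0, 1]`.
#' @param lambda_CS trial-wise exponential decay of the choice-stimulus
#'   traces, in `[0, 1]`.
#' @param w_CL weight of the location trace on the decision value, in
#'   `[-1, 1]`.  Positive values favour repeating recently chosen sides.
#' @param w_CS weight of the stimulus-trace difference on the decision
#'   value, in `[-1, 1]`.  Positive values favour recently chosen stimuli.
#' @param side_bias additive bias on the decision value, in `[-1, 1]`.
#'   Positive values favour rightward choices (a sign convention; the
#'   direction is not identified a priori).
#' @param beta softmax inverse temperature, in `[0, Inf)`.
#'
#' @return A named numeric vector of class `"model_params"`.
#' @seealso [dual_rate_params()] for the two-learning-rate variant,
#'   [session_loglik()], [simulate_agent()].
#' @export
#' @examples
#' model_params(alpha = 0.5, beta = 4)
model_params <- function(alpha = 0.4, alpha_R = 0.35, w_R = 0.3,
                         alpha_CL = 0.2, lambda_CS = 0.6, w_CL = 0.1,
                         w_CS = 0.25, side_bias = 0, beta = 5) {
  p <- c(alpha = alpha, alpha_R = alpha_R, w_R = w_R, alpha_CL = alpha_CL,
         lambda_CS = lambda_CS, w_CL = w_CL, w_CS = w_CS,
         side_bias = side_bias, beta = beta)
  check_params(p, dual = FALSE)
  structure(p, class = "model_params")
}

#' Parameters for the dual-learning-rate model variant
#'
#' Identical to [model_params()] except that positive and negative
#' prediction errors are scaled by separate learning rates.
#'
#' @param alpha_pos learning rate applied when the prediction error is
#'   positive, in `[0, 1]`.
#' @param alpha_neg learning rate applied when the prediction error is
#'   negative (or zero), in `[0, 1]`.
#' @inheritParams model_params
#' @return A named numeric vector of class `"model_params"` with attribute
#'   `dual = TRUE`.
#' @export
dual_rate_params <- function(alpha_pos = 0.4, alpha_neg = 0.4,
                             alpha_R = 0.35, w_R = 0.3, alpha_CL = 0.2,
                             lambda_CS = 0.6, w_CL = 0.1, w_CS = 0.25,
                             side_bias = 0, beta = 5) {
  p <- c(alpha_pos = alpha_pos, alpha_neg = alpha_neg, alpha_R = alpha_R,
         w_R = w_R, alpha_CL = alpha_CL, lambda_CS = lambda_CS,
         w_CL = w_CL, w_CS = w_CS, side_bias = side_bias, beta = beta)
  check_params(p, dual = TRUE)
  structure(p, class = "model_params", dual = TRUE)
}

is_dual <- function(params) isTRUE(attr(params, "dual")) || length(params) == 10L

#' Parameter metadata: names, bounds and link type
#'
#' @param dual if `TRUE`, describe the dual-learning-rate variant (10
#'   parameters) instead of the single-rate model (9 parameters).
#' @return A data frame with columns `name`, `link` (`"unit"`, `"signed"` or
#'   `"positive"`), `lower` and `upper`.
#' @export
param_info <- function(dual = FALSE) {
  if (dual) {
    name <- c("alpha_pos", "alpha_neg", "alpha_R", "w_R", "alpha_CL",
              "lambda_CS", "w_CL", "w_CS", "side_bias", "beta")
    link <- c("unit", "unit", "unit", "signed", "unit", "unit", "signed",
              "signed", "signed", "positive")
  } else {
    name <- c("alpha", "alpha_R", "w_R", "alpha_CL", "lambda_CS", "w_CL",
              "w_CS", "side_bias", "beta")
    link <- c("unit", "unit", "signed", "unit", "unit", "signed", "signed",
              "signed", "positive")
  }
  lower <- c(unit = 0, signed = -1, positive = 0)[link]
  upper <- c(unit = 1, signed = 1, positive = Inf)[link]
  data.frame(name = name, link = link, lower = unname(lower),
             upper = unname(upper), stringsAsFactors = FALSE)
}

check_params <- function(p, dual) {
  info <- param_info(dual)
  if (length(p) != nrow(info)) {
    stop("expected ", nrow(info), " parameters, got ", length(p),
         call. = FALSE)
  }
  bad <- which(p < info$lower | p > info$upper | !is.finite(p) & info$upper < Inf)
  if (any(!is.finite(p) & p != Inf) || length(bad)) {
    stop("parameter(s) out of bounds: ",
         paste(info$name[bad], collapse = ", "), call. = FALSE)
  }
  invisible(p)
}

#' Link functions between unconstrained and native parameter space
#'
#' Group-level Gaussians live in an unconstrained space; bounded parameters
#' are mapped to their native intervals through strictly monotone links:
#' a logistic sigmoid for `[0, 1]` parameters, a doubled and shifted sigmoid
#' for `[-1, 1]` parameters, and an exponential for the non-negative inverse
#' temperature.
#'
#' @inheritParams param_info
#' @return An object of class `"link_spec"`: a list with the parameter
#'   metadata and vectorised `to_native()` / `to_unconstrained()` maps.
#' @export
#' @examples
#' lk <- make_links()
#' x <- lk$to_unconstrained(model_params())
#' max(abs(lk$to_native(x) - model_params()))  # round trip
make_links <- function(dual = FALSE) {
  info <- param_info(dual)
  to_native <- function(x) {
    stopifnot(length(x) == nrow(info))
    y <- numeric(length(x))
    u <- info$link == "unit"
    s <- info$link == "signed"
    b <- info$link == "positive"
    y[u] <- plogis(x[u])
    y[s] <- 2 * plogis(x[s]) - 1
    y[b] <- exp(x[b])
    names(y) <- info$name
    y
  }
  to_unconstrained <- function(p) {
    stopifnot(length(p) == nrow(info))
    p <- as.numeric(p)
    x <- numeric(length(p))
    u <- info$link == "unit"
    s <- info$link == "signed"
    b <- info$link == "positive"
    x[u] <- qlogis(p[u])
    x[s] <- qlogis((p[s] + 1) / 2)
    x[b] <- log(p[b])
    names(x) <- info$name
    x
  }
  structure(list(info = info, dual = dual, n = nrow(info),
                 to_native = to_native, to_unconstrained = to_unconstrained),
            class = "link_spec")
}
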