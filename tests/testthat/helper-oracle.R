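# Independent pure-R re-implementations used as oracles for the compiled
# forward pass.  Written directly from the update equations, trial by trial.

oracle_loglik <- function(params, session, dual = FALSE) {
  p <- as.list(params)
  tr <- session$trials
  Q <- c(A = 0.5, B = 0.5, C = 0.5)
  R <- 0
  CL <- 0
  CS <- c(A = 0, B = 0, C = 0)
  ll <- 0
  for (t in seq_len(nrow(tr))) {
    CSd <- p$lambda_CS * CS
    l <- tr$left_option[t]
    r <- tr$right_option[t]
    ch <- tr$chosen_option[t]
    DV <- unname(Q[r] - Q[l]) + p$side_bias +
      p$w_CL * (-CL) + p$w_CS * unname(CSd[r] - CSd[l])
    p_right <- 1 / (1 + exp(-p$beta * DV))
    p_choice <- if (ch == r) p_right else 1 - p_right
    ll <- ll + log(p_choice)
    rew <- tr$reward[t]
    pe <- rew + p$w_R * R - unname(Q[ch])
    a <- if (dual) (if (pe > 0) p$alpha_pos else p$alpha_neg) else p$alpha
    Q[ch] <- Q[ch] + a * pe
    R <- R + p$alpha_R * (rew - R)
    CS <- CSd
    CS[ch] <- 1
    Lc <- if (tr$chosen_side[t] == "left") 1 else -1
    CL <- CL + p$alpha_CL * (Lc - CL)
  }
  unname(ll)
}

# Textbook Rescorla-Wagner + softmax over the two offered options: the
# limit of the full model when all auxiliary weights and rates are zero.
rw_softmax_loglik <- function(alpha, beta, session) {
  tr <- session$trials
  Q <- c(A = 0.5, B = 0.5, C = 0.5)
  ll <- 0
  for (t in seq_len(nrow(tr))) {
    ch <- tr$chosen_option[t]
    other <- setdiff(c(tr$left_option[t], tr$right_option[t]), ch)
    p_choice <- 1 / (1 + exp(-beta * unname(Q[ch] - Q[other])))
    ll <- ll + log(p_choice)
    Q[ch] <- Q[ch] + alpha * (tr$reward[t] - Q[ch])
  }
  unname(ll)
}

# Streaming (Welford) moments, an independent oracle for map_mstep().
streaming_moments <- function(x) {
  n <- 0
  mean <- rep(0, ncol(x))
  m2 <- rep(0, ncol(x))
  for (i in seq_len(nrow(x))) {
    n <- n + 1
    d <- x[i, ] - mean
    mean <- mean + d / n
    m2 <- m2 + d * (x[i, ] - mean)
  }
  list(mean = mean, variance = m2 / n)
}
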