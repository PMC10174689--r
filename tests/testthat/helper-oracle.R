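# Straight-line scalar reference implementation of the RL-WM session
# log-likelihood, independent of the package's vectorized C++ path. States
# are plain matrices updated trial by trial exactly as the model prescribes:
# policy evaluated, then decay of all unobserved WM weights, then the
# delta-rule and one-shot updates on the observed pair.
oracle_session_loglik <- function(records, params) {
  softmax_ref <- function(x) exp(x - max(x)) / sum(exp(x - max(x)))
  learn <- records[records$phase == "learn", ]
  learn <- learn[order(learn$block, learn$trial), ]
  test <- records[records$phase == "test", ]
  n_a <- max(c(learn$action, test$action), na.rm = TRUE)
  blocks <- sort(unique(learn$block))
  pw <- setNames(numeric(length(blocks)), blocks)
  Qfin <- list()
  nu <- params$alpha_neg / params$alpha_pos
  for (b in blocks) {
    lb <- learn[learn$block == b, ]
    stims <- sort(unique(lb$stimulus))
    ns <- lb$set_size[1]
    Q <- matrix(1 / n_a, length(stims), n_a)
    W <- matrix(1 / n_a, length(stims), n_a)
    omega <- if (ns == 3) params$omega3 else params$omega6
    for (i in seq_len(nrow(lb))) {
      if (lb$missed[i] || is.na(lb$action[i])) next
      s <- match(lb$stimulus[i], stims)
      a <- lb$action[i]; r <- lb$reward[i]
      pW <- softmax_ref(params$beta_learn * W[s, ])
      pQ <- softmax_ref(params$beta_learn * Q[s, ])
      p <- (1 - params$epsilon) * (omega * pW[a] + (1 - omega) * pQ[a]) +
        params$epsilon / n_a
      pw[as.character(b)] <- pw[as.character(b)] + log(p)
      keep <- W[s, a]
      W <- W + params$phi * (1 / n_a - W)
      W[s, a] <- keep
      dRL <- r - Q[s, a]
      Q[s, a] <- Q[s, a] + (if (dRL > 0) params$alpha_pos else params$alpha_neg) * dRL
      dWM <- r - W[s, a]
      W[s, a] <- if (dWM > 0) r else W[s, a] + nu * dWM
    }
    Qfin[[as.character(b)]] <- list(stims = stims, Q = Q)
  }
  for (i in seq_len(nrow(test))) {
    if (test$missed[i] || is.na(test$action[i])) next
    b <- as.character(test$block[i])
    s <- match(test$stimulus[i], Qfin[[b]]$stims)
    q <- Qfin[[b]]$Q[s, ]
    pQ <- softmax_ref(params$beta_test * q)
    p <- (1 - params$epsilon) * pQ[test$action[i]] + params$epsilon / n_a
    pw[b] <- pw[b] + log(p)
  }
  list(total = sum(pw), pointwise = unname(pw))
}

# small session plan + simulated records, reused across tests
tiny_plan <- function(seed = 1, test_reps = 2, miss_rate = 0) {
  build_session(task_config(n_small_blocks = 2, n_large_blocks = 1,
                            test_reps_per_stimulus = test_reps,
                            miss_rate = miss_rate), seed = seed)
}

random_params <- function() {
  agent_params(alpha_pos = runif(1, 0.05, 0.9),
               alpha_neg = runif(1, 0.01, 0.9),
               beta_learn = runif(1, 0.5, 15),
               beta_test = runif(1, 0.5, 10),
               epsilon = runif(1, 0.01, 0.3),
               phi = runif(1, 0, 0.8),
               omega3 = runif(1), omega6 = runif(1))
}
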