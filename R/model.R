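#' Agent parameters for the RL-WM model
#'
#' The hybrid model combines an incremental reinforcement-learning (RL)
#' module, which tracks stimulus-action values Q by a delta rule with
#' asymmetric learning rates, and a one-shot working-memory (WM) module,
#' whose association weights W store the last outcome but decay toward
#' baseline each trial. Action selection mixes the two modules' softmax
#' policies with a set-size-dependent weight and a uniform lapse.
#'
#' @param alpha_pos positive learning rate in \[0, 1\] (must be > 0 so the
#'   WM negative-update strength `nu = alpha_neg / alpha_pos` is defined).
#' @param alpha_neg negative learning rate in \[0, 1\].
#' @param beta_learn learning-phase softmax inverse temperature (>= 0),
#'   shared across participants of a group when fitted hierarchically.
#' @param beta_test test-phase softmax inverse temperature (>= 0).
#' @param epsilon lapse probability in \[0, 1\].
#' @param phi WM decay rate in \[0, 1\]: per-trial pull of unobserved W
#'   entries back toward baseline 1/n_actions.
#' @param omega3,omega6 reliance on the WM policy (vs RL) in set sizes 3 and
#'   6, each in \[0, 1\].
#' @return An object of class `rlwm_agent_params`; `nu` is derived as
#'   `alpha_neg / alpha_pos` and may exceed 1.
#' @export
agent_params <- function(alpha_pos, alpha_neg, beta_learn, beta_test,
                         epsilon, phi, omega3, omega6) {
  chk01 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop("agent_params: '", nm, "' must lie in [0, 1]", call. = FALSE)
    as.numeric(x)
  }
  chkpos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
      stop("agent_params: '", nm, "' must be >= 0", call. = FALSE)
    as.numeric(x)
  }
  alpha_pos <- chk01(alpha_pos, "alpha_pos")
  if (alpha_pos == 0)
    stop("agent_params: 'alpha_pos' must be > 0 (nu = alpha_neg/alpha_pos)",
         call. = FALSE)
  p <- list(alpha_pos = alpha_pos,
            alpha_neg = chk01(alpha_neg, "alpha_neg"),
            beta_learn = chkpos(beta_learn, "beta_learn"),
            beta_test = chkpos(beta_test, "beta_test"),
            epsilon = chk01(epsilon, "epsilon"),
            phi = chk01(phi, "phi"),
            omega3 = chk01(omega3, "omega3"),
            omega6 = chk01(omega6, "omega6"))
  p$nu <- p$alpha_neg / p$alpha_pos
  structure(p, class = "rlwm_agent_params")
}

#' @export
print.rlwm_agent_params <- function(x, ...) {
  cat("RL-WM agent parameters\n")
  cat(sprintf("  alpha+ %.3f  alpha- %.3f (nu %.3f)  betaL %.2f  betaT %.2f\n",
              x$alpha_pos, x$alpha_neg, x$nu, x$beta_learn, x$beta_test))
  cat(sprintf("  epsilon %.3f  phi %.3f  omega3 %.3f  omega6 %.3f\n",
              x$epsilon, x$phi, x$omega3, x$omega6))
  invisible(x)
}

#' Initialize per-block model state
#'
#' Q-values and WM weights both start at the uniform reward expectation
#' `1 / n_actions` for every stimulus-action pair.
#'
#' @param set_size number of stimuli in the block.
#' @param n_actions number of response actions.
#' @return An `rlwm_state` list with matrices `Q` and `W`
#'   (`set_size` x `n_actions`) and the baseline `W0`.
#' @export
init_block_state <- function(set_size, n_actions) {
  if (!is.numeric(set_size) || set_size < 1 || set_size != round(set_size))
    stop("init_block_state: set_size must be a count >= 1", call. = FALSE)
  if (!is.numeric(n_actions) || n_actions < 1 || n_actions != round(n_actions))
    stop("init_block_state: n_actions must be a count >= 1", call. = FALSE)
  q0 <- 1 / n_actions
  m <- matrix(q0, nrow = set_size, ncol = n_actions)
  structure(list(Q = m, W = m, W0 = q0, set_size = as.integer(set_size),
                 n_actions = as.integer(n_actions)), class = "rlwm_state")
}

#' Delta-rule update of the RL module
#'
#' `Q(s,a) <- Q(s,a) + alpha * (r - Q(s,a))` with `alpha = alpha_pos` for a
#' positive prediction error and `alpha_neg` otherwise. Only the observed
#' pair changes.
#'
#' @param state an `rlwm_state`.
#' @param s,a stimulus row and action column of the observed pair.
#' @param r reward, 0 or 1.
#' @param alpha_pos,alpha_neg learning rates in \[0, 1\].
#' @return The updated state.
#' @export
rl_update <- function(state, s, a, r, alpha_pos, alpha_neg) {
  if (alpha_pos < 0 || alpha_pos > 1 || alpha_neg < 0 || alpha_neg > 1)
    stop("rl_update: learning rates must lie in [0, 1]", call. = FALSE)
  delta <- r - state$Q[s, a]
  alpha <- if (delta > 0) alpha_pos else alpha_neg
  state$Q[s, a] <- state$Q[s, a] + alpha * delta
  state
}

#' One-shot update of the WM module
#'
#' A positive WM prediction error stores the outcome outright
#' (`W(s,a) <- r`); a non-positive one moves W toward r by the relative
#' negative-feedback strength `nu = alpha_neg / alpha_pos`, which may exceed
#' 1 (W is not clamped).
#'
#' @inheritParams rl_update
#' @param nu relative negative-feedback sensitivity (>= 0).
#' @return The updated state.
#' @export
wm_update <- function(state, s, a, r, nu) {
  if (nu < 0) stop("wm_update: nu must be >= 0", call. = FALSE)
  delta <- r - state$W[s, a]
  state$W[s, a] <- if (delta > 0) r else state$W[s, a] + nu * delta
  state
}

#' Decay of unobserved WM weights toward baseline
#'
#' Every stimulus-action weight except the pair observed on the current
#' trial is pulled toward the baseline `W0 = 1/n_actions`:
#' `W <- W + phi * (W0 - W)`. Q-values are untouched.
#'
#' @param state an `rlwm_state`.
#' @param phi decay rate in \[0, 1\].
#' @param s,a the observed pair, exempt from decay (both `NULL` to decay
#'   every entry).
#' @return The updated state.
#' @export
wm_decay <- function(state, phi, s = NULL, a = NULL) {
  if (phi < 0 || phi > 1)
    stop("wm_decay: phi must lie in [0, 1]", call. = FALSE)
  keep <- if (!is.null(s) && !is.null(a)) state$W[s, a] else NULL
  state$W <- state$W + phi * (state$W0 - state$W)
  if (!is.null(keep)) state$W[s, a] <- keep
  state
}

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

#' Learning-phase action policy
#'
#' Mixture of the WM and RL softmax policies, weighted by the set-size
#' specific reliance omega, with a uniform lapse:
#' `P = (1 - eps) * (omega * softmax(betaL * W(s,.)) +
#' (1 - omega) * softmax(betaL * Q(s,.))) + eps / nA`.
#'
#' @param state an `rlwm_state`.
#' @param s stimulus row.
#' @param params an [agent_params()] object.
#' @param set_size 3 or 6; selects `omega3` or `omega6`.
#' @return Probability vector over actions (sums to 1).
#' @export
learning_policy <- function(state, s, params, set_size) {
  omega <- switch(as.character(set_size),
                  "3" = params$omega3, "6" = params$omega6,
                  stop("learning_policy: no omega configured for set size ",
                       set_size, call. = FALSE))
  p_wm <- softmax(params$beta_learn * state$W[s, ])
  p_rl <- softmax(params$beta_learn * state$Q[s, ])
  (1 - params$epsilon) * (omega * p_wm + (1 - omega) * p_rl) +
    params$epsilon / state$n_actions
}

#' Test-phase action policy
#'
#' Supported exclusively by RL: a softmax over the Q-values frozen at the
#' end of the stimulus's learning block, with the same lapse rate. WM
#' weights, decay and the learning-phase temperature play no role.
#'
#' @param q_final Q-value vector for the stimulus at the end of its block.
#' @param params an [agent_params()] object.
#' @return Probability vector over actions.
#' @export
test_policy <- function(q_final, params) {
  n_a <- length(q_final)
  (1 - params$epsilon) * softmax(params$beta_test * q_final) +
    params$epsilon / n_a
}

#' Simulate one agent through a session plan
#'
#' Per learning trial: sample an action from the learning policy (or mark
#' the trial missed with the configured miss rate), emit deterministic
#' reward, then decay all unobserved WM weights and apply the RL and WM
#' updates to the observed pair. Missed trials trigger no update. Per test
#' trial: sample from the test policy based on end-of-block Q-values; no
#' feedback, no updates.
#'
#' @param plan an [build_session()] plan.
#' @param params an [agent_params()] object.
#' @param seed integer seed.
#' @param participant,group,age metadata copied into the output records.
#' @return A trial-table data.frame (one row per trial) with columns
#'   `participant, group, age, phase, block, set_size, trial, stimulus,
#'   iteration, action, reward, missed`.
#' @export
simulate_agent <- function(plan, params, seed = NULL, participant = 1L,
                           group = "young", age = NA_real_) {
  stopifnot(inherits(plan, "rlwm_session_plan"),
            inherits(params, "rlwm_agent_params"))
  cfg <- plan$config
  n_a <- cfg$n_actions
  correct <- plan$stimuli$correct_action
  with_seed(seed, {
    rows <- vector("list", nrow(plan$blocks) + 1L)
    q_final <- matrix(NA_real_, nrow = nrow(plan$stimuli), ncol = n_a)
    for (b in plan$blocks$block) {
      ns <- plan$blocks$set_size[b]
      ids <- plan$stimuli$stimulus[plan$stimuli$block == b]
      st <- init_block_state(ns, n_a)
      seq_b <- plan$learning[[b]]
      iter <- integer(max(ids))
      act <- integer(length(seq_b)); rew <- integer(length(seq_b))
      missed <- runif(length(seq_b)) < cfg$miss_rate
      for (t in seq_along(seq_b)) {
        stim <- seq_b[t]
        s <- match(stim, ids)
        iter[stim] <- iter[stim] + 1L
        if (missed[t]) { act[t] <- NA_integer_; rew[t] <- NA_integer_; next }
        p <- learning_policy(st, s, params, ns)
        a <- sample.int(n_a, 1L, prob = p)
        r <- as.integer(a == correct[stim])
        st <- wm_decay(st, params$phi, s, a)
        st <- rl_update(st, s, a, r, params$alpha_pos, params$alpha_neg)
        st <- wm_update(st, s, a, r, params$nu)
        act[t] <- a; rew[t] <- r
      }
      q_final[ids, ] <- st$Q
      rows[[b]] <- data.frame(
        participant = participant, group = group, age = age, phase = "learn",
        block = b, set_size = ns, trial = seq_along(seq_b), stimulus = seq_b,
        iteration = stats::ave(seq_b, seq_b, FUN = seq_along),
        action = act, reward = rew, missed = missed
      )
    }
    tst <- plan$test
    missed_t <- runif(nrow(tst)) < cfg$miss_rate
    act_t <- rep(NA_integer_, nrow(tst))
    for (t in seq_len(nrow(tst))) {
      if (missed_t[t]) next
      p <- test_policy(q_final[tst$stimulus[t], ], params)
      act_t[t] <- sample.int(n_a, 1L, prob = p)
    }
    rows[[length(rows)]] <- data.frame(
      participant = participant, group = group, age = age, phase = "test",
      block = tst$source_block,
      set_size = plan$blocks$set_size[tst$source_block],
      trial = tst$trial, stimulus = tst$stimulus,
      iteration = stats::ave(tst$stimulus, tst$stimulus, FUN = seq_along),
      action = act_t, reward = NA_integer_, missed = missed_t
    )
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

# Pack one participant's trial records (with the session plan) into the
# integer arrays the C++ likelihood consumes. Learning trials must appear in
# experienced order; test trials follow.
pack_participant <- function(records, plan) {
  cfg <- plan$config
  learn <- records[records$phase == "learn", , drop = FALSE]
  test <- records[records$phase == "test", , drop = FALSE]
  learn <- learn[order(learn$block, learn$trial), , drop = FALSE]
  stim_block <- plan$stimuli$block
  local_index <- stats::ave(plan$stimuli$stimulus, plan$stimuli$block,
                            FUN = seq_along)
  list(
    n_actions = cfg$n_actions,
    n_blocks = nrow(plan$blocks),
    block_sizes = as.integer(plan$blocks$set_size),
    correct = as.integer(plan$stimuli$correct_action),
    learn_block = as.integer(learn$block),
    learn_stim = as.integer(local_index[learn$stimulus]),
    learn_action = as.integer(ifelse(learn$missed, 0L, learn$action)),
    learn_reward = as.integer(ifelse(learn$missed, -1L, learn$reward)),
    test_block = as.integer(test$block),
    test_stim = as.integer(local_index[test$stimulus]),
    test_action = as.integer(ifelse(test$missed, 0L, test$action))
  )
}

#' Session log-likelihood under the RL-WM model
#'
#' Log-probability of every observed action, with the latent Q/W states
#' updated using the observed actions and rewards. Missed trials contribute
#' zero and trigger no update. Pointwise values are reported at the
#' participant-block level (a block's test trials are pooled into its unit),
#' the unit at which WAIC is computed, and sum to the total.
#'
#' @param records trial-table data.frame for one participant (both phases).
#' @param plan the session plan the records were generated from.
#' @param params an [agent_params()] object.
#' @return A list with `total` and `pointwise` (one value per block).
#' @export
session_loglik <- function(records, plan, params) {
  pk <- pack_participant(records, plan)
  theta <- c(params$alpha_pos, params$alpha_neg, params$beta_test,
             params$epsilon, params$phi, params$omega3, params$omega6)
  pw <- cpp_session_loglik(pk, theta, params$beta_learn)
  list(total = sum(pw), pointwise = pw)
}
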