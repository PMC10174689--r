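test_that("states initialize at the uniform reward expectation", {
  st <- init_block_state(6, 3)
  expect_equal(dim(st$Q), c(6, 3))
  expect_equal(dim(st$W), c(6, 3))
  expect_true(all(st$Q == 1 / 3) && all(st$W == 1 / 3))
  expect_true(all(init_block_state(2, 1)$Q == 1))
  expect_error(init_block_state(3, 0), "n_actions")
})

test_that("delta-rule updates move only the observed pair", {
  st <- init_block_state(3, 3)
  st2 <- rl_update(st, 1, 2, 1, alpha_pos = 0.3, alpha_neg = 0.1)
  expect_equal(st2$Q[1, 2], 1 / 3 + 0.3 * (1 - 1 / 3))  # 0.5333...
  expect_equal(st2$Q[-1, ], st$Q[-1, ])
  expect_equal(st2$W, st$W)
  st3 <- rl_update(st, 1, 2, 0, alpha_pos = 0.3, alpha_neg = 0.1)
  expect_equal(st3$Q[1, 2], 0.3)                         # 1/3 - 0.1/3
  st4 <- rl_update(st, 1, 2, 1, alpha_pos = 0, alpha_neg = 0.1)
  expect_equal(st4$Q[1, 2], 1 / 3)
  expect_error(rl_update(st, 1, 2, 1, 1.5, 0.1), "learning rates")
})

test_that("working memory stores positive outcomes in one shot", {
  st <- init_block_state(3, 3)
  for (nu in c(0, 0.5, 2)) {
    expect_equal(wm_update(st, 2, 1, 1, nu)$W[2, 1], 1)
  }
  expect_equal(wm_update(st, 2, 1, 0, nu = 1)$W[2, 1], 0)
  expect_equal(wm_update(st, 2, 1, 0, nu = 0)$W[2, 1], 1 / 3)
  # nu > 1 can push W below zero; no clamping
  st$W[2, 1] <- 0.5
  expect_lt(wm_update(st, 2, 1, 0, nu = 1.5)$W[2, 1], 0)
})

test_that("decay pulls unobserved weights toward baseline at the paper rate", {
  st <- init_block_state(2, 3)
  st$W[, ] <- 1
  out <- wm_decay(st, 0.174, s = 1, a = 1)
  expect_equal(out$W[1, 1], 1)                    # observed pair exempt
  expect_equal(out$W[2, 2], 1 - 0.174 * (1 - 1 / 3))  # 0.884
  retained <- (out$W[2, 2] - 1 / 3) / (1 - 1 / 3)
  expect_equal(retained, 0.826)
  expect_equal(round(retained, 2), 0.83)
  expect_equal(wm_decay(st, 0)$W, st$W)
  expect_equal(wm_decay(st, 1)$W, matrix(1 / 3, 2, 3))
})

test_that("decay monotonically shrinks distance from baseline", {
  set.seed(1)
  st <- init_block_state(3, 3)
  st$W <- matrix(runif(9, -0.5, 1.5), 3, 3)
  for (phi in c(0.1, 0.5, 0.9)) {
    out <- wm_decay(st, phi)
    expect_true(all(abs(out$W - 1 / 3) <= abs(st$W - 1 / 3) + 1e-12))
  }
})

test_that("learning policy is the lapse-mixed WM/RL softmax mixture", {
  st <- init_block_state(3, 3)
  p0 <- learning_policy(st, 1,
                        agent_params(0.1, 0.05, 0, 1, 0, 0.1, 0.5, 0.5), 3)
  expect_equal(p0, rep(1 / 3, 3))                 # betaL = 0: flat
  p1 <- learning_policy(st, 1,
                        agent_params(0.1, 0.05, 9, 1, 1, 0.1, 0.5, 0.5), 3)
  expect_equal(p1, rep(1 / 3, 3))                 # epsilon = 1: pure lapse
  st$Q[1, ] <- c(0.5, 1 / 3, 1 / 3); st$W[1, ] <- st$Q[1, ]
  p2 <- learning_policy(st, 1,
                        agent_params(0.1, 0.05, 2, 1, 0, 0.1, 0.7, 0.3), 3)
  expect_equal(p2[1], exp(1) / (exp(1) + 2 * exp(2 / 3)), tolerance = 1e-12)
  expect_equal(round(p2[1], 4), 0.4110)
  expect_error(learning_policy(st, 1,
                               agent_params(0.1, 0.05, 2, 1, 0, 0.1, 0.7, 0.3),
                               4), "omega")
})

test_that("test policy depends only on final Q, beta_test and epsilon", {
  expect_equal(test_policy(c(1, 1 / 3, 1 / 3),
                           agent_params(0.1, 0.05, 5, 0, 0, 0.2, 0.5, 0.5)),
               rep(1 / 3, 3))
  p <- test_policy(c(1, 1 / 3, 1 / 3),
                   agent_params(0.1, 0.05, 5, 3, 0, 0.2, 0.5, 0.5))
  expect_equal(p[1], exp(3) / (exp(3) + 2 * exp(1)), tolerance = 1e-12)
  expect_equal(round(p[1], 4), 0.7870)
})

test_that("policies normalize and respect the lapse floor", {
  set.seed(7)
  for (i in 1:25) {
    pars <- random_params()
    st <- init_block_state(3, 3)
    st$Q <- matrix(runif(9, -0.5, 1.5), 3, 3)
    st$W <- matrix(runif(9, -0.5, 1.5), 3, 3)
    p <- learning_policy(st, sample(3, 1), pars, sample(c(3, 6), 1))
    expect_lt(abs(sum(p) - 1), 1e-12)
    expect_true(all(p >= pars$epsilon / 3 - 1e-12))
    pt <- test_policy(runif(3, -1, 2), pars)
    expect_lt(abs(sum(pt) - 1), 1e-12)
    expect_true(all(pt >= pars$epsilon / 3 - 1e-12))
  }
})

test_that("Q and W stay in [0,1] whenever nu <= 1", {
  set.seed(11)
  plan <- tiny_plan(seed = 2)
  for (i in 1:10) {
    a_pos <- runif(1, 0.05, 1)
    pars <- agent_params(a_pos, runif(1, 0, a_pos), runif(1, 0, 10),
                         runif(1, 0, 10), runif(1), runif(1), runif(1),
                         runif(1))
    rec <- simulate_agent(plan, pars, seed = i)
    # re-walk states with the reference oracle to inspect them
    oll <- oracle_session_loglik(rec, pars)
    expect_true(all(is.finite(oll$pointwise)))
  }
})

test_that("simulated agents behave as their parameters dictate", {
  plan <- build_session(task_config(), seed = 3)
  # pure-lapse agent performs at chance
  lapse <- agent_params(0.1, 0.05, 5, 5, 1, 0.2, 0.6, 0.4)
  rec <- simulate_agent(plan, lapse, seed = 1)
  learn <- rec[rec$phase == "learn", ]
  acc <- mean(learn$reward)
  expect_lt(abs(acc - 1 / 3), 3 * sqrt(1 / 3 * 2 / 3 / nrow(learn)))
  # perfect one-shot WM with full negative-feedback elimination: a correct
  # choice is stored outright and a wrong one zeroed out, so set size 3 is
  # solved with certainty from iteration 3 onward (iteration 2 may still
  # face a two-way tie after one elimination)
  wm <- agent_params(1, 1, 50, 5, 0, 0, 1, 1)
  rec2 <- simulate_agent(plan, wm, seed = 2)
  l2 <- rec2[rec2$phase == "learn" & rec2$set_size == 3 &
               rec2$iteration >= 3, ]
  expect_true(all(l2$reward == 1))
  i2 <- rec2[rec2$phase == "learn" & rec2$set_size == 3 &
               rec2$iteration == 2, ]
  expect_gt(mean(i2$reward), 1 / 3)
  # determinism
  expect_identical(simulate_agent(plan, wm, seed = 9),
                   simulate_agent(plan, wm, seed = 9))
})

test_that("missed trials are marked and carry no action or reward", {
  plan <- tiny_plan(seed = 4, miss_rate = 0.3)
  rec <- simulate_agent(plan, agent_params(0.2, 0.1, 5, 5, 0.05, 0.2, 0.7,
                                           0.3), seed = 5)
  expect_gt(sum(rec$missed), 0)
  expect_true(all(is.na(rec$action[rec$missed])))
  expect_true(all(is.na(rec$reward[rec$missed & rec$phase == "learn"])))
})

test_that("session log-likelihood matches the scalar reference oracle", {
  set.seed(21)
  for (i in 1:100) {
    plan <- tiny_plan(seed = i, miss_rate = if (i %% 4 == 0) 0.15 else 0)
    gen <- random_params()
    rec <- simulate_agent(plan, gen, seed = i + 1000)
    pars <- random_params()  # evaluate under different parameters
    got <- session_loglik(rec, plan, pars)
    want <- oracle_session_loglik(rec, pars)
    expect_equal(got$total, want$total, tolerance = 1e-10)
    expect_equal(got$pointwise, want$pointwise, tolerance = 1e-10)
    expect_equal(sum(got$pointwise), got$total, tolerance = 1e-10)
  }
})

test_that("pure-lapse likelihood is log(1/3) per observed trial", {
  plan <- tiny_plan(seed = 6)
  pars <- agent_params(0.2, 0.1, 5, 5, 1, 0.2, 0.7, 0.3)
  rec <- simulate_agent(plan, pars, seed = 7)
  got <- session_loglik(rec, plan, pars)
  n_obs <- sum(!rec$missed)
  expect_equal(got$total, n_obs * log(1 / 3), tolerance = 1e-10)
})

test_that("test-phase likelihood is invariant to WM parameters", {
  plan <- tiny_plan(seed = 8)
  base <- agent_params(0.3, 0.1, 6, 4, 0.05, 0.25, 0.7, 0.3)
  rec <- simulate_agent(plan, base, seed = 9)
  # test-phase contribution = total minus the learning-only total
  test_ll <- function(pars) {
    session_loglik(rec, plan, pars)$total -
      session_loglik(within(rec, missed[phase == "test"] <- TRUE),
                     plan, pars)$total
  }
  ref <- test_ll(base)
  for (alt in list(agent_params(0.3, 0.1, 1, 4, 0.05, 0.25, 0.7, 0.3),
                   agent_params(0.3, 0.1, 6, 4, 0.05, 0.9, 0.7, 0.3),
                   agent_params(0.3, 0.1, 6, 4, 0.05, 0.25, 0.1, 0.9))) {
    expect_equal(test_ll(alt), ref, tolerance = 1e-10)
  }
})

test_that("simulator action frequencies match the policy probabilities", {
  # one fixed state; simulate many first-trial choices
  pars <- agent_params(0.2, 0.1, 4, 3, 0.1, 0.2, 0.8, 0.2)
  plan <- build_session(task_config(n_small_blocks = 1, n_large_blocks = 1,
                                    reps_per_stimulus = 2,
                                    test_reps_per_stimulus = 1), seed = 10)
  n <- 3000
  first_actions <- vapply(seq_len(n), function(i) {
    rec <- simulate_agent(plan, pars, seed = i)
    rec$action[rec$phase == "learn"][1]
  }, integer(1))
  p_hat <- tabulate(first_actions, 3) / n
  p_true <- rep(1 / 3, 3)  # uniform state at trial 1
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_true(all(abs(p_hat - p_true) < 3 * se))
})

test_that("parameter validation enforces documented ranges", {
  expect_error(agent_params(0, 0.1, 5, 5, 0.05, 0.2, 0.5, 0.5), "alpha_pos")
  expect_error(agent_params(1.2, 0.1, 5, 5, 0.05, 0.2, 0.5, 0.5),
               "alpha_pos")
  expect_error(agent_params(0.2, 0.1, -1, 5, 0.05, 0.2, 0.5, 0.5),
               "beta_learn")
  p <- agent_params(0.2, 0.3, 5, 5, 0.05, 0.2, 0.5, 0.5)
  expect_equal(p$nu, 1.5)  # nu may exceed 1
})
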