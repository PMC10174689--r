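# hand-built toy trial table: one participant, one block, one stimulus
toy_records <- function(rewards, stimulus = 1, missed = NULL,
                        participant = 1) {
  n <- length(rewards)
  if (is.null(missed)) missed <- rep(FALSE, n)
  data.frame(participant = participant, group = "young", age = 25,
             phase = "learn", block = 1, set_size = 3,
             trial = seq_len(n), stimulus = stimulus,
             iteration = seq_len(n),
             action = ifelse(missed, NA_integer_, ifelse(rewards == 1, 1L, 2L)),
             reward = ifelse(missed, NA_integer_, rewards),
             missed = missed)
}

test_that("empirical learning curves aggregate accuracy by iteration", {
  rec <- toy_records(rep(1L, 9))
  cur <- empirical_learning_curves(rec)
  expect_equal(cur$mean, rep(1, 9))
  alt <- toy_records(rep(c(1L, 0L), length.out = 9))
  cur2 <- empirical_learning_curves(alt)
  expect_equal(cur2$mean, rep(c(1, 0), length.out = 9))
})

test_that("missed trials leave the accuracy denominators", {
  rec <- rbind(toy_records(c(0L, 1L, 1L), participant = 1),
               toy_records(c(1L, 1L, 1L), missed = c(FALSE, TRUE, FALSE),
                           participant = 2))
  cur <- empirical_learning_curves(rec)
  # iteration 2: participant 2 missed, so only participant 1 contributes
  expect_equal(cur$mean[cur$iteration == 2], 1)
  expect_equal(cur$n[cur$iteration == 2], 1)
  expect_equal(cur$mean[cur$iteration == 1], 0.5)
})

test_that("reward history counts prior rewarded presentations", {
  rec <- toy_records(c(1L, 1L, 0L, 1L))
  rh <- reward_history(rec)
  expect_equal(rh$reward_history, c(0L, 1L, 2L, 2L))
  # never-rewarded stimulus stays at zero
  rh0 <- reward_history(toy_records(c(0L, 0L, 0L)))
  expect_equal(rh0$reward_history, c(0L, 0L, 0L))
  # non-decreasing within participant-block-stimulus
  co <- get_small_cohort()
  rh2 <- reward_history(co$behavior)
  key <- paste(rh2$participant, rh2$block, rh2$stimulus)
  drops <- tapply(rh2$reward_history, key, function(v) any(diff(v) < 0))
  expect_false(any(unlist(drops)))
})

test_that("delay counts intervening trials since the last rewarded presentation", {
  # A rewarded at trial 1, B, C, then A again at trial 4 -> delay 2
  rec <- data.frame(participant = 1, group = "young", age = 25,
                    phase = "learn", block = 1, set_size = 3,
                    trial = 1:4, stimulus = c("A", "B", "C", "A"),
                    iteration = c(1, 1, 1, 2),
                    action = 1L, reward = c(1L, 0L, 0L, 1L),
                    missed = FALSE)
  d <- glm_delay(rec)
  expect_equal(d$delay[4], 2L)
  expect_true(all(is.na(d$delay[1:3])))
  # unrewarded prior presentation leaves the delay undefined
  rec2 <- toy_records(c(0L, 1L))
  expect_true(all(is.na(glm_delay(rec2)$delay)))
  # consecutive rewarded repeats have delay zero
  rec3 <- toy_records(c(1L, 1L))
  expect_equal(glm_delay(rec3)$delay, c(NA, 0L))
  # delays are never negative
  co <- get_small_cohort()
  expect_true(all(glm_delay(co$behavior)$delay >= 0, na.rm = TRUE))
})

test_that("pure-lapse agents yield null GLM coefficients", {
  plan <- build_session(task_config(), seed = 23)
  pars <- agent_params(0.2, 0.1, 5, 5, 1, 0.2, 0.7, 0.3)
  recs <- do.call(rbind, lapply(1:12, function(i) {
    simulate_agent(plan, pars, seed = 100 + i, participant = i)
  }))
  g <- trial_glm(recs)
  slopes <- g$group_tests[g$group_tests$term != "intercept", ]
  expect_true(all(slopes$p > 0.01))
  expect_true(all(abs(slopes$mean) < 0.2))
  # deterministic given the data
  g2 <- trial_glm(recs)
  expect_identical(g$coefficients, g2$coefficients)
})

test_that("working-memory-driven cohorts show a negative delay effect", {
  plan <- build_session(task_config(), seed = 24)
  pars <- agent_params(0.05, 0.03, 14, 5, 0.03, 0.45, 0.95, 0.6)
  recs <- do.call(rbind, lapply(1:10, function(i) {
    simulate_agent(plan, pars, seed = 200 + i, participant = i)
  }))
  g <- trial_glm(recs)
  expect_lt(g$group_tests$mean[g$group_tests$term == "delay"], 0)
})

test_that("test-phase GLM runs with its reduced predictor set", {
  co <- get_small_cohort()
  g <- trial_glm(co$behavior, phase = "test")
  expect_setequal(g$group_tests$term,
                  c("intercept", "set_size", "reward_history"))
  expect_gt(g$group_tests$mean[g$group_tests$term == "reward_history"], 0)
})

test_that("age regression recovers a planted coefficient-age link", {
  set.seed(5)
  n <- 40
  cf <- data.frame(participant = 1:n, group = "all",
                   intercept = rnorm(n), set_size = rnorm(n),
                   delay = rnorm(n), reward_history = rnorm(n),
                   trial = rnorm(n), block = rnorm(n))
  glm_like <- list(coefficients = cf)
  ages <- data.frame(participant = 1:n,
                     age = 50 - 8 * cf$set_size + rnorm(n, 0, 3))
  ar <- age_regression(glm_like, ages)
  row <- ar$table[ar$table$term == "set_size", ]
  expect_lt(row$estimate, 0)
  expect_lt(row$p, 0.001)
  # permuted ages: planted link destroyed
  ages_perm <- ages
  ages_perm$age <- sample(ages_perm$age)
  ar2 <- age_regression(glm_like, ages_perm)
  expect_true(all(ar2$table$p[ar2$table$term != "(Intercept)"] > 0.01))
})

test_that("age regression excludes exactly the planted outliers", {
  set.seed(6)
  n <- 30
  cf <- data.frame(participant = 1:n, group = "all",
                   intercept = rnorm(n), set_size = rnorm(n))
  cf$set_size[c(4, 9)] <- mean(cf$set_size[-c(4, 9)]) +
    6 * sd(cf$set_size[-c(4, 9)])
  ages <- data.frame(participant = 1:n, age = rnorm(n, 50, 5))
  ar <- age_regression(list(coefficients = cf), ages)
  expect_setequal(ar$excluded, c(4, 9))
})

test_that("train-test comparison computes drops and the set-size asymmetry", {
  # identical train/test accuracy: zero drops
  learn <- toy_records(rep(1L, 9))
  test <- data.frame(participant = 1, group = "young", age = 25,
                     phase = "test", block = 1, set_size = 3, trial = 1:2,
                     stimulus = 1, iteration = 1:2, action = 1L,
                     reward = NA_integer_, missed = FALSE)
  tt <- train_test_comparison(rbind(learn, test))
  expect_equal(tt$drops$drop, 0)
  # simulated cohort: drops bounded, high-omega3 cohorts drop more in the
  # small set size
  co <- get_small_cohort()
  tt2 <- train_test_comparison(co$behavior)
  expect_true(all(tt2$drops$drop >= -1 & tt2$drops$drop <= 1))
  d3 <- mean(tt2$drops$drop[tt2$drops$set_size == 3])
  d6 <- mean(tt2$drops$drop[tt2$drops$set_size == 6])
  expect_gt(d3, d6)
  expect_s3_class(tt2$age_correlations, "data.frame")
})
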