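# compact long-format brain table for n participants
toy_measures <- function(n = 20, seed = 1, glut_mfg = NULL) {
  set.seed(seed)
  rows <- list()
  add <- function(region, measure, value) {
    rows[[length(rows) + 1L]] <<- data.frame(participant = 1:n,
                                             region = region,
                                             measure = measure,
                                             value = value)
  }
  for (r in c("MFG", "IPS", "STR")) {
    add(r, "glutamate",
        if (r == "MFG" && !is.null(glut_mfg)) glut_mfg else rnorm(n, 10))
    add(r, "gaba", rnorm(n, 2.5, 0.3))
    add(r, "naa", rnorm(n, 12, 0.5))
    add(r, "gm", rnorm(n, 60, 3))
    add(r, "wm", rnorm(n, 55, 3))
  }
  add("MFG", "glutamine", rnorm(n, 4, 0.5))
  add("MFG", "creatine", rnorm(n, 8, 0.5))
  for (r in c("CMF", "SF", "RMF")) add(r, "thickness", rnorm(n, 2.6, 0.1))
  do.call(rbind, rows)
}

test_that("feature aggregation pools regions and z-scores columns", {
  m <- toy_measures(5)
  # plant known regional glutamate for participant-wise mean check
  m$value[m$measure == "glutamate" & m$region == "MFG"] <- 1
  m$value[m$measure == "glutamate" & m$region == "IPS"] <- 2
  m$value[m$measure == "glutamate" & m$region == "STR"] <- c(3, 3, 3, 3, 9)
  raw_mean <- (1 + 2 + 3) / 3
  pooled <- aggregate(value ~ participant,
                      data = m[m$measure == "glutamate", ], FUN = mean)
  expect_equal(pooled$value[1], raw_mean)
  f <- aggregate_features(m)
  preds <- setdiff(names(f), "participant")
  expect_setequal(preds, c("glutamate", "gaba", "naa", "gm", "wm",
                           "thickness_CMF", "thickness_SF",
                           "thickness_RMF"))
  for (v in preds) {
    expect_lt(abs(mean(f[[v]])), 1e-10)
    expect_equal(sd(f[[v]]), 1, tolerance = 1e-10)
  }
  # constant column is an error
  m2 <- toy_measures(5)
  m2$value[m2$measure == "gaba"] <- 2.5
  expect_error(aggregate_features(m2), "constant")
})

test_that("cross-validated elastic net recovers a planted predictor", {
  m <- toy_measures(40, seed = 2)
  f <- aggregate_features(m)
  set.seed(3)
  perf <- data.frame(participant = f$participant,
                     performance = 0.7 + 0.1 * f$glutamate +
                       rnorm(nrow(f), 0, 0.05))
  sel <- select_features_cv(f, perf, n_iter = 100, seed = 4)
  expect_gte(sel$selection_rate[["glutamate"]], 0.8)
  expect_true("glutamate" %in% sel$best_config)
  # reproducible splits
  sel2 <- select_features_cv(f, perf, n_iter = 100, seed = 4)
  expect_identical(sel$iterations, sel2$iterations)
})

test_that("pure-noise outcomes shrink the selected sets", {
  m <- toy_measures(40, seed = 5)
  f <- aggregate_features(m)
  set.seed(6)
  noise <- data.frame(participant = f$participant,
                      performance = rnorm(nrow(f)))
  sel0 <- select_features_cv(f, noise, n_iter = 100, seed = 7)
  # the intercept-only model wins a sizable share of splits and the mean
  # selected-set size stays far below the candidate count
  expect_gt(mean(sel0$iterations$size == 0), 0.1)
  expect_lt(mean(sel0$iterations$size, na.rm = TRUE), 3)
  # and is much smaller than under a planted signal
  signal <- data.frame(participant = f$participant,
                       performance = 0.1 * f$glutamate +
                         rnorm(nrow(f), 0, 0.05))
  sel1 <- select_features_cv(f, signal, n_iter = 100, seed = 7)
  expect_lt(mean(sel0$iterations$size, na.rm = TRUE),
            mean(sel1$iterations$size, na.rm = TRUE))
  # the sparser one-standard-error variant shrinks further
  sel0b <- select_features_cv(f, noise, n_iter = 100, seed = 7,
                              lambda_rule = "holdout_1se")
  expect_lte(mean(sel0b$iterations$size, na.rm = TRUE),
             mean(sel0$iterations$size, na.rm = TRUE))
})

test_that("selection is invariant to column order and affine rescaling", {
  m <- toy_measures(35, seed = 8)
  f <- aggregate_features(m)
  set.seed(9)
  perf <- data.frame(participant = f$participant,
                     performance = 0.5 * f$glutamate + 0.3 * f$naa +
                       rnorm(nrow(f), 0, 0.3))
  sel1 <- select_features_cv(f, perf, n_iter = 60, seed = 10)
  # shuffle predictor columns
  f2 <- f[, c("participant", sample(setdiff(names(f), "participant")))]
  sel2 <- select_features_cv(f2, perf, n_iter = 60, seed = 10)
  expect_setequal(sel1$best_config, sel2$best_config)
  # affine rescaling of a raw measure is absorbed by z-scoring
  m3 <- m
  idx <- m3$measure == "glutamate"
  m3$value[idx] <- 100 + 7 * m3$value[idx]
  f3 <- aggregate_features(m3)
  expect_equal(f3$glutamate, f$glutamate, tolerance = 1e-10)
})

test_that("brain-predicted performance behaves like an OLS projection", {
  m <- toy_measures(40, seed = 11)
  f <- aggregate_features(m)
  set.seed(12)
  signal <- 0.2 * f$glutamate
  perf <- data.frame(participant = f$participant,
                     performance = signal + rnorm(nrow(f), 0, 0.05))
  sel <- select_features_cv(f, perf, n_iter = 60, seed = 13)
  bp <- brain_predicted_performance(sel)
  expect_equal(nrow(bp), nrow(f))
  expect_lte(var(bp$brain_pred), var(perf$performance) + 1e-12)
  expect_gt(cor(bp$brain_pred, signal), 0.9)
})

test_that("parameter mapping finds the coupled parameter and only it", {
  set.seed(14)
  n <- 50
  pars <- data.frame(participant = 1:n,
                     alpha_pos = runif(n, 0.02, 0.3),
                     alpha_neg = runif(n, 0.01, 0.2),
                     beta_test = rlnorm(n, log(5), 0.3),
                     epsilon = runif(n, 0, 0.1),
                     phi = runif(n, 0.05, 0.5),
                     omega3 = runif(n, 0.4, 0.9),
                     omega6 = runif(n, 0.1, 0.5))
  bp <- data.frame(participant = 1:n,
                   brain_pred = 0.8 - 0.5 * pars$phi + rnorm(n, 0, 0.02))
  mp <- map_parameters(bp, pars)
  row <- mp$table[mp$table$term == "phi", ]
  expect_lt(row$estimate, 0)
  expect_lt(row$p, 0.001)
  # adding a constant shifts only the intercept
  bp2 <- bp; bp2$brain_pred <- bp2$brain_pred + 5
  mp2 <- map_parameters(bp2, pars)
  expect_equal(mp2$table$estimate[-1], mp$table$estimate[-1],
               tolerance = 1e-9)
  expect_equal(mp2$table$estimate[1], mp$table$estimate[1] + 5,
               tolerance = 1e-9)
  # null outcome: no parameter significant at a strict level
  bp3 <- bp; bp3$brain_pred <- rnorm(n)
  mp3 <- map_parameters(bp3, pars)
  expect_true(all(mp3$table$p[-1] > 0.001))
  expect_error(map_parameters(bp, pars[, 1:3]), "lacks column")
})

test_that("anatomical specificity isolates a planted MFG coupling", {
  set.seed(15)
  n <- 45
  phi <- runif(n, 0.05, 0.6)
  m <- toy_measures(n, seed = 16,
                    glut_mfg = 11 - 2.5 * phi + rnorm(n, 0, 0.2))
  pv <- data.frame(participant = 1:n, value = phi)
  sp <- anatomical_specificity(pv, m)
  mfg <- sp$table[sp$table$term == "glutamate_MFG", ]
  oth <- sp$table[sp$table$term %in% c("glutamate_IPS", "glutamate_STR"), ]
  expect_lt(mfg$estimate, 0)
  expect_lt(mfg$p, 0.001)
  expect_true(all(oth$p > 0.01))
  expect_true(is.numeric(sp$partial_cor$r))
  expect_lt(sp$partial_cor$r, 0)
  # negative control: glutamine carries no coupling
  glmn <- m[m$measure == "glutamine", ]
  ct <- cor.test(pv$value, glmn$value[match(pv$participant,
                                            glmn$participant)])
  expect_gt(ct$p.value, 0.05)
})

test_that("duplicate regional predictors trigger a rank warning", {
  n <- 20
  set.seed(17)
  g <- rnorm(n, 10)
  m <- rbind(data.frame(participant = 1:n, region = "MFG",
                        measure = "glutamate", value = g),
             data.frame(participant = 1:n, region = "IPS",
                        measure = "glutamate", value = g),
             data.frame(participant = 1:n, region = "STR",
                        measure = "glutamate", value = rnorm(n, 10)))
  pv <- data.frame(participant = 1:n, value = runif(n))
  expect_warning(anatomical_specificity(pv, m, partial = FALSE),
                 "rank")
})

test_that("bootstrap mediation quantifies planted indirect effects", {
  set.seed(18)
  n <- 60
  age <- runif(n, 20, 80)
  # full mediation: age affects the outcome only through the mediator
  glut <- 12 - 0.03 * age + rnorm(n, 0, 0.3)
  phi <- 0.9 - 0.05 * glut + rnorm(n, 0, 0.01)
  md <- mediation_acme(age, glut, phi, n_boot = 1000, seed = 19)
  expect_gt(md$acme, 0)
  expect_lt(md$p, 0.05)
  expect_gt(md$prop_mediated, 0.85)
  expect_lt(md$prop_mediated, 1.25)
  # same seed, same bootstrap draws
  md2 <- mediation_acme(age, glut, phi, n_boot = 1000, seed = 19)
  expect_identical(md$ci, md2$ci)
  # null mediator
  glut0 <- rnorm(n, 12)
  phi0 <- 0.001 * age + rnorm(n, 0.3, 0.05)
  md0 <- mediation_acme(age, glut0, phi0, n_boot = 1000, seed = 20)
  expect_lt(abs(md0$acme), 0.02)
  expect_gt(md0$p, 0.05)
  expect_error(mediation_acme(age, glut, phi, n_boot = 10), "n_boot")
})
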