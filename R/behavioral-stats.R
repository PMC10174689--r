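#' Empirical learning curves
#'
#' Mean accuracy (with SEM across participants) at each stimulus iteration,
#' per group and set size, computed from learning-phase records with missed
#' trials excluded from the denominators.
#'
#' @param data trial-table data.frame.
#' @return data.frame with columns `group, set_size, iteration, mean, sem,
#'   n`.
#' @export
empirical_learning_curves <- function(data) {
  d <- data[data$phase == "learn", , drop = FALSE]
  if (!nrow(d)) stop("empirical_learning_curves: no learning-phase records",
                     call. = FALSE)
  learning_curve_table(d, by_group = "group" %in% names(d))
}

#' Stimulus-dependent cumulative reward history
#'
#' For each learning trial, the count of prior rewarded presentations of
#' that trial's stimulus within its block.
#'
#' @param data trial-table data.frame (learning phase rows are used).
#' @return The input learning-phase rows with a `reward_history` column, in
#'   (participant, block, trial) order.
#' @export
reward_history <- function(data) {
  d <- data[data$phase == "learn", , drop = FALSE]
  d <- d[order(d$participant, d$block, d$trial), , drop = FALSE]
  key <- paste(d$participant, d$block, d$stimulus)
  r <- ifelse(is.na(d$reward), 0L, d$reward)
  d$reward_history <- stats::ave(r, key, FUN = function(v) {
    cumsum(c(0L, v[-length(v)]))
  })
  d
}

#' Delay since the last rewarded presentation
#'
#' For each learning trial, the number of intervening trials since the most
#' recent rewarded presentation of the same stimulus within its block; `NA`
#' when no prior rewarded presentation exists.
#'
#' @param data trial-table data.frame.
#' @return The learning-phase rows with a `delay` column.
#' @export
glm_delay <- function(data) {
  d <- data[data$phase == "learn", , drop = FALSE]
  d <- d[order(d$participant, d$block, d$trial), , drop = FALSE]
  d$delay <- NA_integer_
  key <- paste(d$participant, d$block)
  for (k in unique(key)) {
    idx <- which(key == k)
    last_rewarded <- new.env(parent = emptyenv())
    for (i in idx) {
      s <- as.character(d$stimulus[i])
      prev <- last_rewarded[[s]]
      if (!is.null(prev)) d$delay[i] <- d$trial[i] - prev - 1L
      if (!is.na(d$reward[i]) && d$reward[i] == 1L)
        last_rewarded[[s]] <- d$trial[i]
    }
  }
  d
}

zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Trial-level logistic regression of accuracy
#'
#' Per participant, a logistic regression of trial accuracy on set size,
#' delay (since the last rewarded presentation of the stimulus), cumulative
#' reward history, trial and block, with predictors z-scored within
#' participant. Missed trials and trials with undefined delay are excluded.
#' Group-level inference is a one-sample t-test on the participant
#' coefficients. The test phase is mirrored with its reduced predictor set
#' (reward history accrued during learning, set size).
#'
#' @param data trial-table data.frame.
#' @param phase `"learn"` (default) or `"test"`.
#' @return An `rlwm_glm` list: `coefficients` (one row per converged
#'   participant), `group_tests` (mean, t, p per predictor), `excluded`
#'   (participants dropped for separation/non-convergence).
#' @export
trial_glm <- function(data, phase = c("learn", "test")) {
  phase <- match.arg(phase)
  learn <- reward_history(data)
  learn <- glm_delay(learn)
  if (phase == "learn") {
    d <- learn
    predictors <- c("set_size", "delay", "reward_history", "trial", "block")
    d <- d[!d$missed & !is.na(d$action) & !is.na(d$delay), , drop = FALSE]
    d$acc <- d$reward
  } else {
    # total learning-phase reward per stimulus carried into the test phase
    tot <- aggregate(reward ~ participant + stimulus,
                     data = learn[!is.na(learn$reward), ], FUN = sum)
    names(tot)[3] <- "reward_history"
    d <- merge(data[data$phase == "test", , drop = FALSE], tot,
               by = c("participant", "stimulus"))
    predictors <- c("set_size", "reward_history")
    d <- d[!d$missed & !is.na(d$action), , drop = FALSE]
    correct <- unique(data[data$phase == "learn" & !is.na(data$reward) &
                             data$reward == 1,
                           c("participant", "stimulus", "action")])
    names(correct)[3] <- "correct_action"
    d <- merge(d, correct, by = c("participant", "stimulus"))
    d$acc <- as.integer(d$action == d$correct_action)
  }
  coefs <- list(); excluded <- character(0)
  for (p in unique(d$participant)) {
    dp <- d[d$participant == p, , drop = FALSE]
    for (v in predictors) dp[[paste0("z_", v)]] <- zscore(dp[[v]])
    fml <- stats::as.formula(paste("acc ~",
                                   paste(paste0("z_", predictors),
                                         collapse = " + ")))
    fit <- tryCatch(
      suppressWarnings(glm(fml, data = dp, family = binomial())),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged ||
        any(abs(coef(fit)) > 15, na.rm = TRUE) || anyNA(coef(fit))) {
      excluded <- c(excluded, as.character(p))
      next
    }
    cf <- coef(fit)
    names(cf) <- sub("^z_", "", names(cf))
    names(cf)[1] <- "intercept"
    coefs[[length(coefs) + 1L]] <- data.frame(
      participant = p,
      group = as.character(dp$group[1]),
      t(cf), check.names = FALSE)
  }
  if (!length(coefs))
    stop("trial_glm: no participant model converged", call. = FALSE)
  cf_tab <- do.call(rbind, coefs)
  terms <- c("intercept", predictors)
  group_tests <- do.call(rbind, lapply(terms, function(v) {
    tt <- t.test(cf_tab[[v]])
    data.frame(term = v, mean = unname(tt$estimate),
               t = unname(tt$statistic), p = tt$p.value,
               df = unname(tt$parameter))
  }))
  structure(list(phase = phase, coefficients = cf_tab,
                 group_tests = group_tests, excluded = excluded),
            class = "rlwm_glm")
}

#' @export
print.rlwm_glm <- function(x, ...) {
  cat(sprintf("Trial-level logistic GLM (%s phase), %d participants\n",
              x$phase, nrow(x$coefficients)))
  print(x$group_tests, row.names = FALSE, digits = 3)
  if (length(x$excluded))
    cat("  excluded (non-convergence):", paste(x$excluded, collapse = ", "),
        "\n")
  invisible(x)
}

#' Predict age from trial-GLM coefficients
#'
#' Linear regression of participant age on the per-participant logistic
#' coefficients. Participants with any coefficient more than 2 SD above
#' that coefficient's mean are excluded before fitting.
#'
#' @param glm_fit an [trial_glm()] result.
#' @param ages data.frame with `participant` and `age`.
#' @return A list with the `lm` `fit`, the coefficient `table` (estimate,
#'   t, p) and `excluded` participant ids.
#' @export
age_regression <- function(glm_fit, ages) {
  cf <- glm_fit$coefficients
  terms <- setdiff(names(cf), c("participant", "group"))
  out_mask <- rep(FALSE, nrow(cf))
  for (v in terms) {
    out_mask <- out_mask | cf[[v]] > mean(cf[[v]]) + 2 * sd(cf[[v]])
  }
  excluded <- cf$participant[out_mask]
  cf <- cf[!out_mask, , drop = FALSE]
  m <- merge(cf, ages, by = "participant")
  if (nrow(m) <= length(terms) + 1)
    stop("age_regression: fewer participants than predictors",
         call. = FALSE)
  fml <- stats::as.formula(paste("age ~",
                                 paste(sprintf("`%s`", terms),
                                       collapse = " + ")))
  fit <- lm(fml, data = m)
  sm <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(sm), estimate = sm[, 1],
                    t = sm[, 3], p = sm[, 4], row.names = NULL)
  tab$term <- gsub("`", "", tab$term)
  list(fit = fit, table = tab, excluded = excluded)
}

#' Training-to-test performance drop by set size
#'
#' Per participant and set size, late-learning accuracy (mean over the last
#' three stimulus iterations) minus test accuracy; paired within-group
#' comparisons of the set-size-3 vs set-size-6 drop, a between-group test
#' of the asymmetry, and Spearman correlations of accuracy with age.
#'
#' @param data trial-table data.frame with both phases (and `age` for the
#'   correlations).
#' @return A list with `drops` (participant x set size), `within_group`
#'   (paired t-tests), `between_group` and `age_correlations`.
#' @export
train_test_comparison <- function(data) {
  if (!all(c("learn", "test") %in% data$phase))
    stop("train_test_comparison: both phases required", call. = FALSE)
  learn <- data[data$phase == "learn" & !data$missed &
                  !is.na(data$reward), , drop = FALSE]
  reps <- max(learn$iteration)
  late <- learn[learn$iteration > reps - 3, , drop = FALSE]
  late_acc <- aggregate(reward ~ participant + group + set_size,
                        data = late, FUN = mean)
  names(late_acc)[4] <- "late_learning"
  correct <- unique(learn[learn$reward == 1,
                          c("participant", "stimulus", "action")])
  names(correct)[3] <- "correct_action"
  test <- merge(data[data$phase == "test" & !data$missed &
                       !is.na(data$action), , drop = FALSE],
                correct, by = c("participant", "stimulus"))
  test$acc <- as.integer(test$action == test$correct_action)
  test_acc <- aggregate(acc ~ participant + group + set_size, data = test,
                        FUN = mean)
  names(test_acc)[4] <- "test_accuracy"
  drops <- merge(late_acc, test_acc,
                 by = c("participant", "group", "set_size"))
  drops$drop <- drops$late_learning - drops$test_accuracy

  wide <- merge(drops[drops$set_size == 3,
                      c("participant", "group", "drop")],
                drops[drops$set_size == 6,
                      c("participant", "drop")],
                by = "participant", suffixes = c("3", "6"))
  within_group <- lapply(split(wide, wide$group), function(w) {
    if (nrow(w) < 2) return(NULL)
    t.test(w$drop3, w$drop6, paired = TRUE)
  })
  asym <- wide$drop3 - wide$drop6
  between_group <- if (length(unique(wide$group)) == 2 &&
                       all(table(wide$group) >= 2)) {
    t.test(asym ~ wide$group)
  } else NULL

  age_correlations <- NULL
  if ("age" %in% names(data) && !all(is.na(data$age))) {
    ages <- unique(data[, c("participant", "age")])
    acc_all <- rbind(
      cbind(late_acc[, c("participant", "set_size")],
            phase = "learn", accuracy = late_acc$late_learning),
      cbind(test_acc[, c("participant", "set_size")],
            phase = "test", accuracy = test_acc$test_accuracy))
    acc_all <- merge(acc_all, ages, by = "participant")
    age_correlations <- do.call(rbind, lapply(
      split(acc_all, list(acc_all$phase, acc_all$set_size)),
      function(d) {
        if (nrow(d) < 4 || sd(d$age) == 0 || sd(d$accuracy) == 0) {
          return(data.frame(phase = d$phase[1], set_size = d$set_size[1],
                            rho = NA_real_, p = NA_real_))
        }
        ct <- suppressWarnings(
          cor.test(d$accuracy, d$age, method = "spearman"))
        data.frame(phase = d$phase[1], set_size = d$set_size[1],
                   rho = unname(ct$estimate), p = ct$p.value)
      }))
    rownames(age_correlations) <- NULL
  }
  list(drops = drops, within_group = within_group,
       between_group = between_group, age_correlations = age_correlations)
}
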