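#' Aggregate brain measures into z-scored candidate predictors
#'
#' Neurochemical measures sampled from several regions (glutamate, GABA,
#' NAA) and the structural volumes (gray, white matter) are averaged across
#' regions; cortical thickness in CMF, SF and RMF stays region-specific.
#' Every resulting column is z-scored. The candidate set is: gaba,
#' glutamate, naa, gm, wm, thickness_CMF, thickness_SF, thickness_RMF.
#'
#' @param measures long data.frame (`participant, region, measure, value`).
#' @return Wide data.frame, one complete-case row per participant, with a
#'   `participant` column and z-scored predictors.
#' @export
aggregate_features <- function(measures) {
  avg <- c("glutamate", "gaba", "naa", "gm", "wm")
  pooled <- aggregate(value ~ participant + measure,
                      data = measures[measures$measure %in% avg, ],
                      FUN = mean)
  wide <- stats::reshape(pooled, idvar = "participant",
                         timevar = "measure", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  th <- measures[measures$measure == "thickness", , drop = FALSE]
  if (nrow(th)) {
    th$col <- paste0("thickness_", th$region)
    thw <- stats::reshape(th[, c("participant", "col", "value")],
                          idvar = "participant", timevar = "col",
                          direction = "wide")
    names(thw) <- sub("^value\\.", "", names(thw))
    wide <- merge(wide, thw, by = "participant")
  }
  wide <- wide[complete.cases(wide), , drop = FALSE]
  for (v in setdiff(names(wide), "participant")) {
    s <- sd(wide[[v]])
    if (!is.finite(s) || s == 0)
      stop("aggregate_features: column '", v, "' is constant",
           call. = FALSE)
    wide[[v]] <- (wide[[v]] - mean(wide[[v]])) / s
  }
  rownames(wide) <- NULL
  wide
}

#' Cross-validated elastic-net feature selection
#'
#' Repeats `n_iter` times: draw a random 4/5 training split, fit an
#' elastic-net path (`alpha = mixing`, equal L1/L2 weighting by default) on
#' the training data, evaluate every configuration along the path --
#' including the empty (intercept-only) model -- on the held-out 1/5, and
#' record the nonzero-coefficient set of the configuration minimizing
#' held-out mean squared error. The best configuration across iterations is
#' the one with the lowest mean held-out MSE among configurations selected
#' in at least `min_freq` of iterations (ties broken by fewer predictors);
#' it is refit by ordinary least squares for inference.
#'
#' @param features output of [aggregate_features()].
#' @param performance data.frame with `participant` and `performance`.
#' @param n_iter number of random splits (default 200).
#' @param mixing elastic-net mixing parameter alpha (default 0.5).
#' @param seed integer seed; the split sequence is fully reproducible.
#' @param lambda_rule `"holdout_min"` (default: the configuration
#'   minimizing held-out MSE along the path, the null model included),
#'   `"holdout_1se"` (the sparsest configuration within one standard error
#'   of that minimum) or `"max_nonnull"` (largest penalty whose model is
#'   non-null).
#' @param min_freq minimum selection frequency for a configuration to be
#'   eligible as the final model (default 0.05).
#' @return An `rlwm_selection` list: `iterations` (subset + MSE per split),
#'   `selection_rate` per predictor, `best_config`, `refit` (lm), `table`
#'   (OLS coefficients, t, p).
#' @export
select_features_cv <- function(features, performance, n_iter = 200,
                               mixing = 0.5, seed = 1,
                               lambda_rule = c("holdout_min", "holdout_1se",
                                               "max_nonnull"),
                               min_freq = 0.05) {
  lambda_rule <- match.arg(lambda_rule)
  d <- merge(features, performance, by = "participant")
  preds <- setdiff(names(features), "participant")
  X <- as.matrix(d[, preds, drop = FALSE])
  y <- d$performance
  n <- nrow(d)
  if (n < 10)
    stop("select_features_cv: need at least 10 complete cases",
         call. = FALSE)
  n_train <- round(4 * n / 5)
  iterations <- vector("list", n_iter)
  with_seed(seed, {
    for (i in seq_len(n_iter)) {
      tr <- sample.int(n, n_train)
      te <- setdiff(seq_len(n), tr)
      if (sd(y[tr]) == 0) {
        iterations[[i]] <- data.frame(iter = i, config = NA_character_,
                                      mse = NA_real_, size = NA_integer_)
        next
      }
      path <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], alpha = mixing)
      if (lambda_rule == "max_nonnull") {
        nz <- path$df > 0
        if (!any(nz)) {
          iterations[[i]] <- data.frame(iter = i, config = "",
                                        mse = mean((y[te] - mean(y[tr]))^2),
                                        size = 0L)
          next
        }
        j <- which(nz)[1]
        cf <- as.matrix(coef(path, s = path$lambda[j]))[-1, 1]
        sel <- names(cf)[cf != 0]
        pred <- predict(path, newx = X[te, , drop = FALSE],
                        s = path$lambda[j])
        mse <- mean((y[te] - pred)^2)
      } else {
        pred <- predict(path, newx = X[te, , drop = FALSE])
        mses <- colMeans((y[te] - pred)^2)
        null_mse <- mean((y[te] - mean(y[tr]))^2)
        j <- which.min(mses)
        if (lambda_rule == "holdout_1se") {
          # sparsest configuration within 1 SE of the held-out minimum
          best_err <- if (null_mse <= mses[j]) {
            (y[te] - mean(y[tr]))^2
          } else (y[te] - pred[, j])^2
          thr <- min(null_mse, mses[j]) +
            sd(best_err) / sqrt(length(te))
          if (null_mse <= thr) {
            sel <- character(0); mse <- null_mse
          } else {
            # lambda path is decreasing, so the first qualifying index is
            # the sparsest model within tolerance
            j <- which(mses <= thr)[1]
            cf <- as.matrix(coef(path, s = path$lambda[j]))[-1, 1]
            sel <- names(cf)[cf != 0]
            mse <- mses[j]
          }
        } else if (null_mse <= mses[j]) {
          sel <- character(0); mse <- null_mse
        } else {
          cf <- as.matrix(coef(path, s = path$lambda[j]))[-1, 1]
          sel <- names(cf)[cf != 0]
          mse <- mses[j]
        }
      }
      iterations[[i]] <- data.frame(
        iter = i, config = paste(sort(sel), collapse = "+"),
        mse = mse, size = length(sel))
    }
  })
  it <- do.call(rbind, iterations)
  it_ok <- it[!is.na(it$config), , drop = FALSE]
  selection_rate <- vapply(preds, function(v) {
    mean(vapply(strsplit(it_ok$config, "\\+"), function(s) v %in% s,
                logical(1)))
  }, numeric(1))
  freq <- table(it_ok$config) / nrow(it_ok)
  eligible <- names(freq)[freq >= min_freq]
  if (!length(eligible)) eligible <- names(freq)
  agg <- aggregate(mse ~ config, data = it_ok[it_ok$config %in% eligible, ],
                   FUN = mean)
  agg$size <- lengths(strsplit(agg$config, "\\+"))
  agg <- agg[order(agg$mse, agg$size), , drop = FALSE]
  best_config <- strsplit(agg$config[1], "\\+")[[1]]
  best_config <- best_config[nzchar(best_config)]
  fml <- if (length(best_config)) {
    stats::as.formula(paste("performance ~",
                            paste(best_config, collapse = " + ")))
  } else stats::as.formula("performance ~ 1")
  refit <- lm(fml, data = d)
  sm <- summary(refit)$coefficients
  tab <- data.frame(term = rownames(sm), estimate = sm[, 1], t = sm[, 3],
                    p = sm[, 4], row.names = NULL)
  structure(list(iterations = it, selection_rate = selection_rate,
                 config_table = agg, best_config = best_config,
                 refit = refit, table = tab, data = d),
            class = "rlwm_selection")
}

#' @export
print.rlwm_selection <- function(x, ...) {
  cat("Cross-validated elastic-net feature selection\n")
  cat("  best configuration:",
      if (length(x$best_config)) paste(x$best_config, collapse = " + ")
      else "(intercept only)", "\n")
  cat("  selection rates:\n")
  print(round(sort(x$selection_rate, decreasing = TRUE), 2))
  invisible(x)
}

#' Brain-predicted performance
#'
#' Fitted values of the selected linear model: the projection of learning
#' performance onto the axis of the brain measures most related to it.
#'
#' @param selection an [select_features_cv()] result.
#' @return data.frame with `participant` and `brain_pred`.
#' @export
brain_predicted_performance <- function(selection) {
  data.frame(participant = selection$data$participant,
             brain_pred = unname(fitted(selection$refit)))
}

#' Regress brain-predicted performance on all model parameters
#'
#' OLS of the brain-predicted performance on the seven individual RL-WM
#' parameters jointly, identifying which computational quantities carry the
#' neural fingerprint of performance. Variance inflation factors are
#' reported and a warning is issued under strong collinearity.
#'
#' @param brain_pred output of [brain_predicted_performance()].
#' @param parameters data.frame with `participant` and the seven parameter
#'   columns (e.g. from [participant_estimates()]).
#' @return A list with `fit`, `table` (estimate, t, p per parameter) and
#'   `vif`.
#' @export
map_parameters <- function(brain_pred, parameters) {
  pars <- PARAM_NAMES
  missing_cols <- setdiff(c("participant", pars), names(parameters))
  if (length(missing_cols))
    stop("map_parameters: parameter table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  d <- merge(brain_pred, parameters[, c("participant", pars)],
             by = "participant")
  fml <- stats::as.formula(paste("brain_pred ~",
                                 paste(pars, collapse = " + ")))
  fit <- lm(fml, data = d)
  X <- as.matrix(d[, pars])
  R <- cor(X)
  vif <- diag(solve(R))
  names(vif) <- pars
  if (any(vif > 10))
    warning("map_parameters: strong collinearity among parameters (VIF > 10)")
  sm <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(sm), estimate = sm[, 1], t = sm[, 3],
                    p = sm[, 4], row.names = NULL)
  list(fit = fit, table = tab, vif = vif)
}

#' Anatomical specificity of a parameter-glutamate relationship
#'
#' OLS of a model parameter on the three regional glutamate measures
#' (`parameter ~ MFG + IPS + STR glutamate`). Optionally, the partial
#' correlation between the parameter and MFG glutamate after regressing
#' MFG gray matter and MFG creatine out of both.
#'
#' @param parameter_values data.frame with `participant` and `value`.
#' @param measures long brain-measure data.frame.
#' @param partial logical: also compute the adjusted partial correlation
#'   (default TRUE when MFG gm/creatine are present).
#' @return A list with `fit`, `table` (per-region coefficients) and
#'   optionally `partial_cor` (r, p).
#' @export
anatomical_specificity <- function(parameter_values, measures,
                                   partial = TRUE) {
  glu <- measures[measures$measure == "glutamate", , drop = FALSE]
  w <- stats::reshape(glu[, c("participant", "region", "value")],
                      idvar = "participant", timevar = "region",
                      direction = "wide")
  names(w) <- sub("^value\\.", "glutamate_", names(w))
  d <- merge(parameter_values, w, by = "participant")
  d <- d[complete.cases(d), , drop = FALSE]
  regs <- grep("^glutamate_", names(d), value = TRUE)
  X <- as.matrix(d[, regs])
  if (qr(cbind(1, X))$rank < ncol(X) + 1)
    warning("anatomical_specificity: rank-deficient regional predictors")
  fit <- lm(stats::as.formula(paste("value ~",
                                    paste(regs, collapse = " + "))),
            data = d)
  sm <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(sm), estimate = sm[, 1], t = sm[, 3],
                    p = sm[, 4], row.names = NULL)
  out <- list(fit = fit, table = tab)
  covars <- measures[measures$region == "MFG" &
                       measures$measure %in% c("gm", "creatine"), ,
                     drop = FALSE]
  if (partial && length(unique(covars$measure)) == 2) {
    cw <- stats::reshape(covars[, c("participant", "measure", "value")],
                         idvar = "participant", timevar = "measure",
                         direction = "wide")
    names(cw) <- sub("^value\\.", "", names(cw))
    dp <- merge(d, cw, by = "participant")
    r1 <- resid(lm(value ~ gm + creatine, data = dp))
    r2 <- resid(lm(glutamate_MFG ~ gm + creatine, data = dp))
    ct <- cor.test(r1, r2)
    out$partial_cor <- list(r = unname(ct$estimate), p = ct$p.value)
  }
  out
}

#' Bootstrap mediation: average causal mediation effect
#'
#' Product-of-coefficients mediation with a nonparametric percentile
#' bootstrap: the indirect effect of age on the outcome through the
#' mediator is `a * b`, where `a` is the age-to-mediator slope and `b` the
#' mediator-to-outcome slope controlling for age. The proportion mediated
#' is the indirect effect over the total effect.
#'
#' @param age,mediator,outcome numeric vectors (complete cases, matched).
#' @param n_boot bootstrap resamples (default 2000, must be >= 1000).
#' @param seed integer seed.
#' @return A list with `acme`, `ci` (95% percentile), `p` (two-sided
#'   bootstrap), `prop_mediated` (NA with a flag if the total effect is
#'   essentially zero) and `total_effect`.
#' @export
mediation_acme <- function(age, mediator, outcome, n_boot = 2000,
                           seed = 1) {
  if (n_boot < 1000)
    stop("mediation_acme: n_boot must be >= 1000", call. = FALSE)
  ok <- complete.cases(age, mediator, outcome)
  age <- age[ok]; mediator <- mediator[ok]; outcome <- outcome[ok]
  est <- function(idx) {
    a <- coef(lm(mediator[idx] ~ age[idx]))[2]
    b <- coef(lm(outcome[idx] ~ age[idx] + mediator[idx]))[3]
    unname(a * b)
  }
  acme <- est(seq_along(age))
  total <- unname(coef(lm(outcome ~ age))[2])
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      est(sample.int(length(age), replace = TRUE))
    }, numeric(1))
  })
  ci <- unname(quantile(boots, c(0.025, 0.975)))
  p <- 2 * min(mean(boots <= 0), mean(boots >= 0))
  prop <- if (abs(total) < 1e-10) NA_real_ else acme / total
  list(acme = acme, ci = ci, p = min(p, 1),
       prop_mediated = prop, total_effect = total,
       zero_total_effect = abs(total) < 1e-10)
}
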