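# Iteration-level accuracy aggregation shared by empirical curves, posterior
# predictive checks and the counterfactual simulations.
learning_curve_table <- function(records, by_group = FALSE) {
  d <- records[!records$missed & !is.na(records$reward), , drop = FALSE]
  keys <- if (by_group) c("group", "set_size", "iteration") else
    c("set_size", "iteration")
  # per-participant accuracy first, then mean/SEM across participants
  per <- aggregate(d$reward, by = d[c("participant", keys)], FUN = mean)
  agg <- aggregate(per$x, by = per[keys], FUN = function(v) {
    c(mean = mean(v), sem = sd(v) / sqrt(length(v)), n = length(v))
  })
  out <- cbind(agg[keys], as.data.frame(agg$x))
  out[order(out[[keys[1]]], out[[length(keys)]]), , drop = FALSE]
}

#' Posterior predictive learning curves
#'
#' For each of `n_draws` posterior draws, every participant's session is
#' simulated from that draw's parameter values and accuracy is aggregated by
#' stimulus iteration, group and set size; the predictive mean and 95%
#' interval across draws are returned.
#'
#' @param fit an `rlwm_fit`.
#' @param plans named list of session plans keyed by participant id.
#' @param n_draws posterior draws to simulate (default 200).
#' @param seed integer seed.
#' @return data.frame with columns `group, set_size, iteration, mean, lo,
#'   hi, n_draws`.
#' @export
posterior_predictive_curves <- function(fit, plans, n_draws = 200,
                                        seed = NULL) {
  draws <- posterior_draws(fit)
  if (n_draws > nrow(draws))
    stop("posterior_predictive_curves: n_draws exceeds available draws",
         call. = FALSE)
  with_seed(seed, {
    idx <- sample.int(nrow(draws), n_draws)
    acc <- list()
    for (k in seq_along(idx)) {
      i <- idx[k]
      recs <- lapply(seq_along(fit$participants), function(pi) {
        p <- fit$participants[pi]
        g <- fit$groups[pi]
        pars <- agent_params(
          draws[i, paste0("alpha_pos[", p, "]")],
          draws[i, paste0("alpha_neg[", p, "]")],
          draws[i, paste0("beta_learn[", g, "]")],
          draws[i, paste0("beta_test[", p, "]")],
          draws[i, paste0("epsilon[", p, "]")],
          draws[i, paste0("phi[", p, "]")],
          draws[i, paste0("omega3[", p, "]")],
          draws[i, paste0("omega6[", p, "]")])
        sim <- simulate_agent(plans[[as.character(p)]], pars,
                              seed = sample.int(.Machine$integer.max, 1L),
                              participant = p, group = g)
        sim[sim$phase == "learn", , drop = FALSE]
      })
      recs <- do.call(rbind, recs)
      cur <- learning_curve_table(recs, by_group = TRUE)
      cur$draw <- k
      acc[[k]] <- cur
    }
    allc <- do.call(rbind, acc)
    out <- aggregate(allc$mean,
                     by = allc[c("group", "set_size", "iteration")],
                     FUN = function(v) c(mean = mean(v),
                                         lo = unname(quantile(v, 0.025)),
                                         hi = unname(quantile(v, 0.975))))
    out <- cbind(out[c("group", "set_size", "iteration")],
                 as.data.frame(out$x))
    out$n_draws <- n_draws
    out[order(out$group, out$set_size, out$iteration), , drop = FALSE]
  })
}

#' Asymptotic accuracy of a learning curve
#'
#' Mean accuracy over the last three stimulus iterations, per set size (and
#' group when present).
#'
#' @param curve data.frame with columns `iteration`, `mean` and `set_size`
#'   (optionally `group`).
#' @return data.frame of asymptotic means.
#' @export
asymptotic_mean <- function(curve) {
  keys <- intersect(c("group", "set_size"), names(curve))
  split_keys <- if (length(keys)) curve[keys] else
    list(all = rep(1, nrow(curve)))
  parts <- split(curve, split_keys, drop = TRUE)
  out <- lapply(parts, function(d) {
    if (nrow(d) < 3)
      stop("asymptotic_mean: need at least 3 iterations", call. = FALSE)
    d <- d[order(d$iteration), , drop = FALSE]
    res <- d[1, keys, drop = FALSE]
    res$asymptotic_mean <- mean(tail(d$mean, 3))
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Parameter-recovery study
#'
#' Generates a synthetic two-group cohort from stated group-level
#' hyperparameters, fits the two-group hierarchical model, and reports per
#' parameter the correlation between true and recovered (posterior-mean)
#' individual values plus whether each group-level mean is covered by its
#' 95% credible interval.
#'
#' @param spec a [cohort_spec()].
#' @param mcmc an [mcmc_config()].
#' @param seed integer seed for cohort generation.
#' @return An `rlwm_recovery` list: `fit`, `truth`, `estimates`,
#'   `correlations` (per parameter), `hyper_coverage`.
#' @export
run_recovery <- function(spec = cohort_spec(), mcmc = mcmc_config(),
                         seed = 1) {
  cohort <- generate_cohort(spec, seed = seed)
  fit <- fit_rlwm(cohort$behavior, variant = "two_group", mcmc = mcmc)
  est <- participant_estimates(fit)
  truth <- cohort$truth$participants
  m <- merge(truth, est, by = "participant",
             suffixes = c("_true", "_est"))
  cors <- vapply(PARAM_NAMES, function(nm) {
    cor(m[[paste0(nm, "_true")]], m[[paste0(nm, "_est")]])
  }, numeric(1))
  cover <- lapply(fit$group_levels, function(g) {
    vapply(UNIT_PARAMS, function(nm) {
      dr <- group_mean_draws(fit, nm, g)
      ci <- quantile(dr, c(0.025, 0.975))
      truth_mu <- cohort$truth$hyper_means[[g]][[nm]]
      ci[1] <= truth_mu && truth_mu <= ci[2]
    }, logical(1))
  })
  names(cover) <- fit$group_levels
  structure(list(fit = fit, truth = truth, estimates = est,
                 correlations = cors, hyper_coverage = cover,
                 cohort = cohort),
            class = "rlwm_recovery")
}

#' @export
print.rlwm_recovery <- function(x, ...) {
  cat("RL-WM parameter recovery\n")
  print(round(x$correlations, 3))
  invisible(x)
}
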