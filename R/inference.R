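#' MCMC configuration
#'
#' @param n_chains number of chains (default 4).
#' @param n_warmup warmup (adaptation) sweeps per chain (default 500).
#' @param n_kept kept draws per chain (default 1500).
#' @param n_thin thinning interval applied after warmup (default 1).
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @return An `rlwm_mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = 4, n_warmup = 500, n_kept = 1500,
                        n_thin = 1, seed = 1) {
  for (f in c("n_chains", "n_warmup", "n_kept", "n_thin")) {
    v <- get(f)
    if (!is.numeric(v) || v < 1 || v != round(v))
      stop("mcmc_config: '", f, "' must be a count >= 1", call. = FALSE)
  }
  structure(list(n_chains = as.integer(n_chains),
                 n_warmup = as.integer(n_warmup),
                 n_kept = as.integer(n_kept), n_thin = as.integer(n_thin),
                 seed = as.integer(seed)), class = "rlwm_mcmc_config")
}

#' Prior specification
#'
#' Participant-level unit-interval parameters (learning rates, lapse, decay,
#' WM reliances) follow `Beta(1 + a, 1 + b)` group-level distributions with
#' `Gamma(hyper_ab_shape, hyper_ab_rate)` hyperpriors on a and b; the
#' test-phase inverse temperature is lognormal with a normal hyperprior on
#' its log-mean and half-normal on its log-sd; the group-shared learning
#' temperature gets a `Gamma(beta_learn_shape, beta_learn_rate)` prior
#' (default mean 50). The flat (non-hierarchical) variant replaces the
#' Beta hierarchies with fixed `Beta(flat_beta_shape1, flat_beta_shape2)`
#' priors and a Gamma prior on the test temperature.
#'
#' @param ... named overrides of the defaults listed above.
#' @return An `rlwm_prior_spec` list.
#' @export
prior_spec <- function(...) {
  defaults <- list(
    hyper_ab_shape = 2, hyper_ab_rate = 0.2,
    beta_learn_shape = 2, beta_learn_rate = 0.04,
    beta_test_shape = 2, beta_test_rate = 0.2,
    beta_test_meanlog = log(5), beta_test_meanlog_sd = 1,
    beta_test_sdlog_sd = 1,
    flat_beta_shape1 = 2, flat_beta_shape2 = 2
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("prior_spec: unknown prior field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  p <- modifyList(defaults, over)
  if (any(unlist(p) <= 0))
    stop("prior_spec: all prior constants must be positive", call. = FALSE)
  structure(p, class = "rlwm_prior_spec")
}

PARAM_NAMES <- c("alpha_pos", "alpha_neg", "beta_test", "epsilon", "phi",
                 "omega3", "omega6")
UNIT_PARAMS <- c("alpha_pos", "alpha_neg", "epsilon", "phi", "omega3",
                 "omega6")

# Derive per-participant likelihood packs from a trial table alone: block
# structure, set sizes and local stimulus indices are all encoded in the CSV
# schema, and the likelihood needs only observed actions/rewards.
pack_from_records <- function(records, n_actions = NULL) {
  learn <- records[records$phase == "learn", , drop = FALSE]
  test <- records[records$phase == "test", , drop = FALSE]
  learn <- learn[order(learn$block, learn$trial), , drop = FALSE]
  blocks <- unique(learn[, c("block", "set_size")])
  blocks <- blocks[order(blocks$block), , drop = FALSE]
  if (any(blocks$block != seq_len(nrow(blocks))))
    stop("trial records malformed: blocks must be numbered 1..n_blocks",
         call. = FALSE)
  stim <- unique(learn[, c("stimulus", "block")])
  stim <- stim[order(stim$block, stim$stimulus), , drop = FALSE]
  local_index <- stats::ave(stim$stimulus, stim$block, FUN = seq_along)
  lookup <- setNames(local_index, stim$stimulus)
  if (is.null(n_actions))
    n_actions <- max(c(learn$action, test$action), na.rm = TRUE)
  list(
    n_actions = as.integer(n_actions),
    n_blocks = nrow(blocks),
    block_sizes = as.integer(blocks$set_size),
    correct = integer(0),
    learn_block = as.integer(learn$block),
    learn_stim = as.integer(lookup[as.character(learn$stimulus)]),
    learn_action = as.integer(ifelse(learn$missed | is.na(learn$action),
                                     0L, learn$action)),
    learn_reward = as.integer(ifelse(learn$missed | is.na(learn$reward),
                                     -1L, learn$reward)),
    test_block = as.integer(test$block),
    test_stim = as.integer(lookup[as.character(test$stimulus)]),
    test_action = as.integer(ifelse(test$missed | is.na(test$action),
                                    0L, test$action))
  )
}

data_fingerprint <- function(data) {
  paste(nrow(data), length(unique(data$participant)),
        sum(data$action, na.rm = TRUE), sum(data$reward, na.rm = TRUE),
        sep = ":")
}

group_levels_of <- function(groups) {
  lv <- unique(as.character(groups))
  if (all(c("young", "older") %in% lv)) c("young", "older") else sort(lv)
}

#' Fit the hierarchical Bayesian RL-WM model
#'
#' Estimates per-participant parameters (positive/negative learning rates,
#' test-phase temperature, lapse, WM decay, WM reliances) and the per-group
#' shared learning-phase temperature by adaptive Metropolis-within-Gibbs
#' MCMC on unconstrained scales (logit for unit-interval parameters, log for
#' temperatures), with proposal scales adapted during warmup only. Three
#' hierarchy variants are supported: `flat` (independent fixed priors),
#' `single_hierarchy` (one Beta/lognormal group-level distribution over all
#' participants) and `two_group` (separate hierarchies per age group). The
#' learning temperature is shared per age group in every variant. Pointwise
#' log-likelihoods are stored per participant-block unit (each block's test
#' trials pooled into its unit) for WAIC.
#'
#' @param data trial-table data.frame covering both phases for all
#'   participants (columns `participant, group, phase, block, set_size,
#'   trial, stimulus, action, reward, missed`).
#' @param variant one of `"flat"`, `"single_hierarchy"`, `"two_group"`.
#' @param priors an [prior_spec()] object.
#' @param mcmc an [mcmc_config()] object.
#' @return An `rlwm_fit` object with draws, hyper-draws, pointwise
#'   log-likelihood matrix, diagnostics and metadata.
#' @export
fit_rlwm <- function(data, variant = c("two_group", "single_hierarchy", "flat"),
                     priors = prior_spec(), mcmc = mcmc_config()) {
  variant <- match.arg(variant)
  stopifnot(inherits(priors, "rlwm_prior_spec"),
            inherits(mcmc, "rlwm_mcmc_config"))
  if (!all(c("learn", "test") %in% unique(data$phase)))
    stop("fit_rlwm: data must include both learning and test phases",
         call. = FALSE)
  pid <- unique(data$participant)
  P <- length(pid)
  grp <- vapply(pid, function(p) {
    as.character(data$group[data$participant == p][1])
  }, character(1))
  glv <- group_levels_of(grp)
  if (variant == "two_group") {
    if (length(glv) != 2L || any(table(factor(grp, glv)) == 0L))
      stop("fit_rlwm: two_group variant requires two non-empty groups",
           call. = FALSE)
  }
  group_idx <- match(grp, glv)
  hgroup_idx <- switch(variant,
    flat = rep(1L, P),
    single_hierarchy = rep(1L, P),
    two_group = group_idx)
  n_hgroups <- switch(variant, flat = 0L, single_hierarchy = 1L,
                      two_group = length(glv))
  n_actions <- max(data$action, na.rm = TRUE)
  packs <- lapply(pid, function(p) {
    pack_from_records(data[data$participant == p, , drop = FALSE],
                      n_actions = n_actions)
  })
  nB <- packs[[1]]$n_blocks

  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    chains[[ch]] <- with_seed(mcmc$seed + ch - 1L, {
      init <- list(
        theta = cbind(runif(P, 0.05, 0.3), runif(P, 0.02, 0.2),
                      runif(P, 2, 8), runif(P, 0.02, 0.1),
                      runif(P, 0.1, 0.5), runif(P, 0.4, 0.8),
                      runif(P, 0.2, 0.6)),
        beta_learn = runif(length(glv), 6, 14),
        hyper_a = matrix(runif(max(1, n_hgroups) * 6, 2, 6),
                         nrow = max(1, n_hgroups)),
        hyper_b = matrix(runif(max(1, n_hgroups) * 6, 2, 6),
                         nrow = max(1, n_hgroups)),
        bt_meanlog = rep(log(5), max(1, n_hgroups)),
        bt_sdlog = rep(0.5, max(1, n_hgroups))
      )
      cpp_rlwm_chain(packs, as.integer(group_idx), as.integer(hgroup_idx),
                     length(glv), n_hgroups, unclass(priors), init,
                     mcmc$n_warmup, mcmc$n_kept, mcmc$n_thin)
    })
  }

  theta_cols <- as.vector(t(outer(pid, PARAM_NAMES,
                                  function(p, nm) paste0(nm, "[", p, "]"))))
  betaL_cols <- paste0("beta_learn[", glv, "]")
  hyper_cols <- character(0)
  if (n_hgroups > 0) {
    hlab <- if (variant == "two_group") glv else "all"
    for (h in seq_len(n_hgroups)) {
      for (u in UNIT_PARAMS) {
        hyper_cols <- c(hyper_cols, paste0("a_", u, "[", hlab[h], "]"),
                        paste0("b_", u, "[", hlab[h], "]"))
      }
      hyper_cols <- c(hyper_cols, paste0("meanlog_beta_test[", hlab[h], "]"),
                      paste0("sdlog_beta_test[", hlab[h], "]"))
    }
  }
  per_chain <- lapply(chains, function(cc) {
    m <- cbind(cc$theta, cc$beta_learn)
    if (n_hgroups > 0) m <- cbind(m, cc$hyper)
    colnames(m) <- c(theta_cols, betaL_cols, hyper_cols)
    m
  })
  pointwise <- do.call(rbind, lapply(chains, `[[`, "pointwise"))
  colnames(pointwise) <- as.vector(t(outer(pid, seq_len(nB),
                                           function(p, b) paste0("p", p, ".b", b))))
  fit <- structure(list(
    variant = variant, participants = pid, groups = grp,
    group_levels = glv, hgroups = hgroup_idx, n_hgroups = n_hgroups,
    chains = per_chain, pointwise = pointwise,
    n_blocks = nB, mcmc = mcmc, priors = priors,
    divergences = 0L, bfmi = NA_real_,
    fingerprint = data_fingerprint(data)
  ), class = "rlwm_fit")
  fit$diagnostics <- fit_diagnostics(fit)
  fit
}

#' @export
print.rlwm_fit <- function(x, ...) {
  cat(sprintf("RL-WM %s fit: %d participants (%s), %d chains x %d draws\n",
              x$variant, length(x$participants),
              paste(x$group_levels, collapse = "/"),
              length(x$chains), nrow(x$chains[[1]])))
  d <- x$diagnostics
  cat(sprintf("  max Rhat %.3f, min ESS %.0f\n", max(d$rhat), min(d$ess)))
  invisible(x)
}

#' Combined posterior draws
#'
#' @param fit an `rlwm_fit`.
#' @return Matrix of draws (all chains stacked) with named columns.
#' @export
posterior_draws <- function(fit) {
  do.call(rbind, fit$chains)
}

# split-chain potential scale reduction factor (rank-free classic form)
split_rhat <- function(chains_mat) {
  halves <- list()
  for (m in chains_mat) {
    n <- nrow(m)
    halves <- c(halves, list(m[seq_len(n %/% 2), , drop = FALSE]),
                list(m[(n %/% 2 + 1):(2 * (n %/% 2)), , drop = FALSE]))
  }
  n <- nrow(halves[[1]])
  means <- sapply(halves, colMeans)
  vars <- sapply(halves, function(h) apply(h, 2, var))
  if (is.null(dim(means))) { means <- rbind(means); vars <- rbind(vars) }
  W <- rowMeans(vars)
  B <- n * apply(means, 1, var)
  vhat <- (n - 1) / n * W + B / n
  out <- sqrt(vhat / W)
  out[W < 1e-12] <- 1          # constant parameter: treat as converged
  out
}

# effective sample size via Geyer's initial positive sequence, pooled chains
ess_basic <- function(chains_mat) {
  n <- nrow(chains_mat[[1]])
  M <- length(chains_mat)
  npar <- ncol(chains_mat[[1]])
  out <- numeric(npar)
  for (j in seq_len(npar)) {
    xs <- lapply(chains_mat, function(m) m[, j])
    v <- mean(vapply(xs, var, numeric(1)))
    if (v < 1e-12) { out[j] <- n * M; next }
    max_lag <- min(n - 2L, 500L)
    rho <- rowMeans(vapply(xs, function(x) {
      as.numeric(acf(x, lag.max = max_lag, plot = FALSE,
                     demean = TRUE)$acf)[-1]
    }, numeric(max_lag)))
    # sum consecutive pairs while positive
    s <- 0; k <- 1
    while (k + 1 <= length(rho)) {
      pair <- rho[k] + rho[k + 1]
      if (pair < 0) break
      s <- s + pair
      k <- k + 2
    }
    out[j] <- min(n * M / (1 + 2 * s), n * M)
  }
  out
}

fit_diagnostics <- function(fit) {
  data.frame(parameter = colnames(fit$chains[[1]]),
             rhat = split_rhat(fit$chains),
             ess = ess_basic(fit$chains),
             row.names = NULL)
}

#' Convergence diagnostics report
#'
#' Flags parameters with split-Rhat above `rhat_max` or effective sample
#' size below `ess_min` (both bounds inclusive on the passing side), chains
#' with BFMI below `bfmi_min`, and any divergent transitions. BFMI and
#' divergences are properties of Hamiltonian samplers; the package's
#' Metropolis sampler reports them as NA/0 and NA entries do not fail the
#' check.
#'
#' @param fit an `rlwm_fit`, or a list with elements `diagnostics`
#'   (data.frame with `parameter`, `rhat`, `ess`), `bfmi`, `divergences`.
#' @param rhat_max,ess_min,bfmi_min thresholds (defaults 1.01, 400, 0.2).
#' @return A list with `pass` plus the offending parameters/counts.
#' @export
check_diagnostics <- function(fit, rhat_max = 1.01, ess_min = 400,
                              bfmi_min = 0.2) {
  d <- fit$diagnostics
  bad_rhat <- d$parameter[d$rhat > rhat_max]
  bad_ess <- d$parameter[d$ess < ess_min]
  bfmi <- fit$bfmi %||% NA_real_
  bad_bfmi <- !is.na(bfmi) & bfmi < bfmi_min
  ndiv <- fit$divergences %||% 0L
  ndiv <- ifelse(is.na(ndiv), 0L, ndiv)
  pass <- length(bad_rhat) == 0 && length(bad_ess) == 0 &&
    !any(bad_bfmi) && sum(ndiv) == 0
  list(pass = pass, bad_rhat = bad_rhat, bad_ess = bad_ess,
       bad_bfmi_chains = which(bad_bfmi), divergences = sum(ndiv))
}

#' Widely applicable information criterion
#'
#' `WAIC = -2 * (lppd - p_waic)` with `lppd = sum_units log mean_draws
#' exp(ll)` and `p_waic = sum_units var_draws(ll)`, computed on the
#' participant-block pointwise log-likelihood units. Lower is better.
#'
#' @param x an `rlwm_fit` or a draws-by-units pointwise log-likelihood
#'   matrix.
#' @return A list with `waic`, `se`, `p_waic`, `lppd`, `n_units` and the
#'   per-unit contributions `pointwise_waic`.
#' @export
compute_waic <- function(x) {
  pw <- if (inherits(x, "rlwm_fit")) x$pointwise else as.matrix(x)
  if (is.null(pw) || !is.matrix(pw) || nrow(pw) < 2)
    stop("compute_waic: pointwise log-likelihood matrix required",
         call. = FALSE)
  S <- nrow(pw)
  mx <- apply(pw, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(pw, 2, mx)))) # log-mean-exp per unit
  p_i <- apply(pw, 2, var)
  elpd_i <- lppd_i - p_i
  waic_i <- -2 * elpd_i
  list(waic = sum(waic_i), se = sqrt(length(waic_i) * var(waic_i)),
       p_waic = sum(p_i), lppd = sum(lppd_i), n_units = length(waic_i),
       pointwise_waic = waic_i)
}

#' Compare fitted model variants by WAIC
#'
#' @param fits list of `rlwm_fit` objects on the same data.
#' @return A data.frame ranked by WAIC with `delta_waic` relative to the
#'   best model and the paired standard error of each difference.
#' @export
compare_variants <- function(fits) {
  stopifnot(length(fits) >= 1)
  fps <- vapply(fits, `[[`, character(1), "fingerprint")
  if (length(unique(fps)) != 1L)
    stop("compare_variants: fits were not computed on identical data",
         call. = FALSE)
  w <- lapply(fits, compute_waic)
  tab <- data.frame(
    variant = vapply(fits, `[[`, character(1), "variant"),
    waic = vapply(w, `[[`, numeric(1), "waic"),
    p_waic = vapply(w, `[[`, numeric(1), "p_waic"),
    se = vapply(w, `[[`, numeric(1), "se")
  )
  best <- which.min(tab$waic)
  tab$delta_waic <- tab$waic - tab$waic[best]
  tab$se_delta <- vapply(seq_along(fits), function(i) {
    if (i == best) return(0)
    di <- w[[i]]$pointwise_waic - w[[best]]$pointwise_waic
    sqrt(length(di) * var(di))
  }, numeric(1))
  tab[order(tab$waic), , drop = FALSE]
}

# Per-draw group-level mean of a parameter from the hyper draws.
group_mean_draws <- function(fit, parameter, group) {
  draws <- posterior_draws(fit)
  if (parameter == "beta_learn")
    return(draws[, paste0("beta_learn[", group, "]")])
  if (fit$variant != "two_group")
    stop("group-level contrasts require a two_group fit", call. = FALSE)
  if (parameter %in% UNIT_PARAMS) {
    a <- draws[, paste0("a_", parameter, "[", group, "]")]
    b <- draws[, paste0("b_", parameter, "[", group, "]")]
    (1 + a) / (2 + a + b)                      # Beta(1+a, 1+b) mean
  } else if (parameter == "beta_test") {
    m <- draws[, paste0("meanlog_beta_test[", group, "]")]
    s <- draws[, paste0("sdlog_beta_test[", group, "]")]
    exp(m + s^2 / 2)                           # lognormal mean
  } else {
    stop("group_contrast: unknown parameter '", parameter, "'",
         call. = FALSE)
  }
}

#' Group contrast of a group-level mean parameter
#'
#' Per posterior draw, the difference in group-level means (first group
#' minus second; with the default labels, young minus older), summarized by
#' its mean, 95% equal-tailed credible interval and the posterior
#' probability that the difference is negative.
#'
#' @param fit a two-group `rlwm_fit`.
#' @param parameter one of the model parameter names (e.g. `"phi"`).
#' @return A list with `delta_mean`, `cri` (2.5/97.5 percentiles) and
#'   `p_negative`.
#' @export
group_contrast <- function(fit, parameter) {
  if (fit$variant != "two_group")
    stop("group_contrast: requires a two_group fit", call. = FALSE)
  g <- fit$group_levels
  delta <- group_mean_draws(fit, parameter, g[1]) -
    group_mean_draws(fit, parameter, g[2])
  list(delta_mean = mean(delta),
       cri = unname(quantile(delta, c(0.025, 0.975))),
       p_negative = mean(delta < 0))
}

#' Posterior-mean participant parameters
#'
#' @param fit an `rlwm_fit`.
#' @return data.frame: one row per participant with posterior-mean values of
#'   all seven individual parameters plus the group's `beta_learn`.
#' @export
participant_estimates <- function(fit) {
  draws <- posterior_draws(fit)
  out <- data.frame(participant = fit$participants, group = fit$groups)
  for (nm in PARAM_NAMES) {
    out[[nm]] <- vapply(fit$participants, function(p) {
      mean(draws[, paste0(nm, "[", p, "]")])
    }, numeric(1))
  }
  out$beta_learn <- vapply(fit$groups, function(g) {
    mean(draws[, paste0("beta_learn[", g, "]")])
  }, numeric(1))
  rownames(out) <- NULL
  out
}

#' Counterfactual parameter-swap simulation
#'
#' Simulates the recipient group from each member's posterior-mean
#' parameters, except that the named parameter is replaced by the donor
#' group's posterior group-level mean. With donor equal to recipient this
#' reduces to an ordinary posterior-mean predictive simulation.
#'
#' @param fit a two-group `rlwm_fit`.
#' @param donor,recipient group labels.
#' @param parameter parameter to swap (e.g. `"phi"`).
#' @param plans named list of session plans, one per recipient participant.
#' @param seed integer seed.
#' @param n_reps simulated sessions per participant (default 5).
#' @return A list with the simulated `records` and iteration-level `curves`
#'   (per set size).
#' @export
counterfactual_swap <- function(fit, donor, recipient, parameter, plans,
                                seed = NULL, n_reps = 5) {
  est <- participant_estimates(fit)
  donor_mean <- mean(group_mean_draws(fit, parameter, donor))
  rec <- est[est$group == recipient, , drop = FALSE]
  with_seed(seed, {
    recs <- list()
    for (i in seq_len(nrow(rec))) {
      row <- rec[i, ]
      row[[parameter]] <- donor_mean
      pars <- agent_params(row$alpha_pos, row$alpha_neg, row$beta_learn,
                           row$beta_test, row$epsilon, row$phi, row$omega3,
                           row$omega6)
      plan <- plans[[as.character(row$participant)]]
      for (rep_i in seq_len(n_reps)) {
        recs[[length(recs) + 1L]] <- simulate_agent(
          plan, pars, seed = sample.int(.Machine$integer.max, 1L),
          participant = row$participant, group = recipient)
      }
    }
    records <- do.call(rbind, recs)
    list(records = records,
         curves = learning_curve_table(records[records$phase == "learn", ]))
  })
}
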