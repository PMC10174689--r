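#' Specification of a synthetic two-age-group cohort
#'
#' Defines the study conditions emulated by the generator: group sizes and
#' age distributions of a young and an older cohort, group-level RL-WM
#' parameter distributions (unit-interval parameters via the same
#' `Beta(1 + a, 1 + b)` form used by the hierarchical model, the test-phase
#' temperature lognormal, the learning temperature shared within group), a
#' glutamate coupling in which regional glutamate declines with both WM
#' decay and age (strongest in MFG), age-declining nuisance measures with
#' modest inter-metabolite correlation, and missing brain measurements for a
#' subset of each group.
#'
#' Group mean decay rates default to 0.174 (young) and 0.324 (older); the
#' remaining means and dispersions are fixed so that simulated average
#' learning accuracies land near 0.74 (young) and 0.60 (older).
#'
#' @param n_young,n_older group sizes (defaults 36 and 42).
#' @param age_mean,age_sd named numeric vectors (`young`, `older`) of age
#'   distribution moments in years.
#' @param param_means list (`young`, `older`) of group means for
#'   `alpha_pos, alpha_neg, epsilon, phi, omega3, omega6`.
#' @param param_conc named concentrations (a + b + 2) of the Beta forms.
#' @param beta_learn named per-group shared learning temperatures.
#' @param beta_test_meanlog,beta_test_sdlog lognormal parameters of the
#'   test temperature.
#' @param miss_rate probability of a missed (timed-out) trial.
#' @param n_missing_brain named counts of participants per group lacking
#'   brain measures (defaults 6 young, 18 older).
#' @param coupling list of glutamate coupling constants per region
#'   (`base`, `b_phi`, `b_age`, `sd`) plus `nuisance_cor`.
#' @param task a [task_config()].
#' @return An `rlwm_cohort_spec` list.
#' @export
cohort_spec <- function(
    n_young = 36, n_older = 42,
    age_mean = c(young = 21, older = 68),
    age_sd = c(young = 4.4, older = 8.5),
    param_means = list(
      young = list(alpha_pos = 0.11, alpha_neg = 0.065, epsilon = 0.04,
                   phi = 0.174, omega3 = 0.72, omega6 = 0.30),
      older = list(alpha_pos = 0.085, alpha_neg = 0.045, epsilon = 0.05,
                   phi = 0.324, omega3 = 0.63, omega6 = 0.30)),
    param_conc = c(alpha_pos = 60, alpha_neg = 60, epsilon = 40, phi = 25,
                   omega3 = 15, omega6 = 15),
    beta_learn = c(young = 14, older = 11),
    beta_test_meanlog = log(5), beta_test_sdlog = 0.25,
    miss_rate = 0.02,
    n_missing_brain = c(young = 6, older = 18),
    coupling = list(
      regions = c("MFG", "IPS", "STR"),
      base = c(MFG = 11.5, IPS = 11.0, STR = 10.0),
      b_phi = c(MFG = 3.5, IPS = 1.0, STR = 0.5),
      b_age = c(MFG = 0.012, IPS = 0.010, STR = 0.008),
      sd = c(MFG = 0.70, IPS = 0.75, STR = 0.75),
      nuisance_cor = 0.3),
    task = task_config()) {
  if (n_young < 2 || n_older < 2)
    stop("cohort_spec: group sizes must be >= 2", call. = FALSE)
  for (g in c("young", "older")) {
    for (nm in names(param_conc)) {
      mu <- param_means[[g]][[nm]]
      if (is.null(mu) || mu <= 0 || mu >= 1)
        stop("cohort_spec: mean of '", nm, "' (", g,
             ") must lie in (0, 1)", call. = FALSE)
      if (mu * param_conc[[nm]] < 1 || (1 - mu) * param_conc[[nm]] < 1)
        stop("cohort_spec: mean/concentration of '", nm, "' (", g,
             ") incompatible with the Beta(1+a, 1+b) form", call. = FALSE)
    }
  }
  if (any(n_missing_brain > c(n_young, n_older)))
    stop("cohort_spec: more missing brain measures than participants",
         call. = FALSE)
  structure(list(
    n_young = as.integer(n_young), n_older = as.integer(n_older),
    age_mean = age_mean, age_sd = age_sd, param_means = param_means,
    param_conc = param_conc, beta_learn = beta_learn,
    beta_test_meanlog = beta_test_meanlog,
    beta_test_sdlog = beta_test_sdlog, miss_rate = miss_rate,
    n_missing_brain = n_missing_brain, coupling = coupling, task = task
  ), class = "rlwm_cohort_spec")
}

rbeta_form <- function(n, mu, conc) {
  rbeta(n, shape1 = mu * conc, shape2 = (1 - mu) * conc)
}

#' Generate a complete synthetic cohort
#'
#' Samples ages and RL-WM parameters per participant from the group-level
#' distributions of the spec, simulates each participant's full session
#' (learning + test) on a fresh pseudo-randomized plan, generates regional
#' brain measures from the glutamate coupling model, applies
#' brain-measurement missingness, and records every latent quantity.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return A list with `behavior` (trial table), `brain` (long data.frame:
#'   participant, region, measure, value), `participants` (metadata),
#'   `plans` (named list of session plans) and `truth` (all latent
#'   parameters and coupling constants).
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "rlwm_cohort_spec"))
  with_seed(seed, {
    n <- spec$n_young + spec$n_older
    group <- rep(c("young", "older"), c(spec$n_young, spec$n_older))
    age <- ifelse(group == "young",
                  rnorm(n, spec$age_mean["young"], spec$age_sd["young"]),
                  rnorm(n, spec$age_mean["older"], spec$age_sd["older"]))
    age <- pmax(age, 18)
    pid <- seq_len(n)

    pars <- data.frame(participant = pid, group = group, age = age)
    for (nm in names(spec$param_conc)) {
      mu <- vapply(group, function(g) spec$param_means[[g]][[nm]],
                   numeric(1))
      pars[[nm]] <- rbeta_form(n, mu, spec$param_conc[[nm]])
    }
    pars$beta_test <- rlnorm(n, spec$beta_test_meanlog,
                             spec$beta_test_sdlog)
    pars$beta_learn <- spec$beta_learn[group]

    cfg <- spec$task
    cfg$miss_rate <- spec$miss_rate
    plans <- vector("list", n)
    behav <- vector("list", n)
    for (i in pid) {
      plans[[i]] <- build_session(cfg, seed = sample.int(.Machine$integer.max, 1L))
      ap <- agent_params(pars$alpha_pos[i], pars$alpha_neg[i],
                         pars$beta_learn[i], pars$beta_test[i],
                         pars$epsilon[i], pars$phi[i], pars$omega3[i],
                         pars$omega6[i])
      behav[[i]] <- simulate_agent(plans[[i]], ap,
                                   seed = sample.int(.Machine$integer.max, 1L),
                                   participant = i, group = group[i],
                                   age = age[i])
    }
    names(plans) <- as.character(pid)
    behavior <- do.call(rbind, behav)

    # brain measures ------------------------------------------------------
    cp <- spec$coupling
    missing_ids <- c(
      sample(pid[group == "young"], spec$n_missing_brain["young"]),
      sample(pid[group == "older"], spec$n_missing_brain["older"]))
    with_brain <- setdiff(pid, missing_ids)
    nb <- length(with_brain)
    agec <- age[with_brain] - mean(age)
    phi_i <- pars$phi[with_brain]
    latent <- rnorm(nb)                     # shared metabolic factor
    lam <- sqrt(cp$nuisance_cor / (1 - cp$nuisance_cor))
    rows <- list()
    add <- function(region, measure, value) {
      rows[[length(rows) + 1L]] <<- data.frame(
        participant = with_brain, region = region, measure = measure,
        value = value)
    }
    # nuisance measures decline mildly with age (age correlations around
    # 0.3 for metabolites and 0.5 for structure after regional averaging)
    # but carry no direct coupling to the decay parameter
    for (r in cp$regions) {
      add(r, "glutamate",
          cp$base[r] - cp$b_phi[r] * phi_i - cp$b_age[r] * agec +
            rnorm(nb, 0, cp$sd[r]))
      add(r, "gaba", 2.5 - 0.002 * agec + 0.25 * (lam * latent + rnorm(nb)))
      add(r, "naa", 12 - 0.006 * agec + 0.5 * (lam * latent + rnorm(nb)))
      add(r, "gm", 60 - 0.04 * agec + rnorm(nb, 0, 3))
      add(r, "wm", 55 - 0.03 * agec + rnorm(nb, 0, 3))
    }
    add("MFG", "glutamine", 4 + rnorm(nb, 0, 0.5))
    add("MFG", "creatine", 8 - 0.005 * agec + rnorm(nb, 0, 0.6))
    for (r in c("CMF", "SF", "RMF")) {
      add(r, "thickness", 2.6 - 0.002 * agec + rnorm(nb, 0, 0.08))
    }
    brain <- do.call(rbind, rows)

    hyper_means <- lapply(spec$param_means, function(m) m)
    list(
      behavior = behavior,
      brain = brain,
      participants = pars[, c("participant", "group", "age")],
      plans = plans,
      truth = list(
        participants = pars,
        hyper_means = hyper_means,
        beta_learn = spec$beta_learn,
        coupling = cp,
        missing_brain = sort(missing_ids)
      )
    )
  })
}

#' Write a cohort to plain-text fixture files
#'
#' Emits `trials.csv` (the shared trial-table schema), `brain.csv` (long
#' brain-measure schema) and `truth.json` (every latent parameter and
#' coupling constant) into `path`.
#'
#' @param cohort output of [generate_cohort()].
#' @param path directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_fixture <- function(cohort, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  f_trials <- file.path(path, "trials.csv")
  f_brain <- file.path(path, "brain.csv")
  f_truth <- file.path(path, "truth.json")
  write.csv(cohort$behavior, f_trials, row.names = FALSE)
  write.csv(cohort$brain, f_brain, row.names = FALSE)
  writeLines(jsonlite::toJSON(cohort$truth, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns", pretty = TRUE),
             f_truth)
  invisible(c(f_trials, f_brain, f_truth))
}

#' Read a cohort fixture written by [write_fixture()]
#'
#' @param path directory containing the fixture files.
#' @return A list with `behavior`, `brain` and `truth` (plans are not
#'   serialized; refit from the trial table instead).
#' @export
read_fixture <- function(path) {
  behavior <- read.csv(file.path(path, "trials.csv"),
                       stringsAsFactors = FALSE)
  behavior$missed <- as.logical(behavior$missed)
  brain <- read.csv(file.path(path, "brain.csv"), stringsAsFactors = FALSE)
  truth <- jsonlite::fromJSON(file.path(path, "truth.json"))
  list(behavior = behavior, brain = brain, truth = truth)
}
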