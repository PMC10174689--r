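# Shared, lazily-computed fixtures. Helpers are loaded once per test run, so
# expensive objects (cohorts, MCMC fits) are built on first use and reused
# across test files.
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# 9 + 9 participants on a shortened 4-block task: big enough to exercise the
# hierarchy, small enough for routine tests
small_spec <- function() {
  cohort_spec(n_young = 9, n_older = 9,
              n_missing_brain = c(young = 2, older = 3),
              task = task_config(n_small_blocks = 2, n_large_blocks = 2,
                                 test_reps_per_stimulus = 2))
}

get_small_cohort <- function() {
  memo("small_cohort", function() generate_cohort(small_spec(), seed = 202))
}

get_small_fit <- function() {
  memo("small_fit", function() {
    fit_rlwm(get_small_cohort()$behavior, variant = "two_group",
             mcmc = mcmc_config(n_chains = 2, n_warmup = 150, n_kept = 350,
                                n_thin = 1, seed = 11))
  })
}

# the full-size default cohort (the study conditions)
get_default_cohort <- function() {
  memo("default_cohort", function() generate_cohort(cohort_spec(), seed = 99))
}
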