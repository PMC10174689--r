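#' Task configuration for the RL-WM association-learning task
#'
#' The task presents stimulus-response association learning in independent
#' blocks whose set size (number of concurrent associations) is either small
#' or large. Each stimulus is shown a fixed number of times per block with
#' deterministic feedback; a later test phase probes every learned stimulus
#' without feedback.
#'
#' @param n_small_blocks number of small-set-size blocks (default 6).
#' @param n_large_blocks number of large-set-size blocks (default 4).
#' @param small_set_size stimuli per small block (default 3).
#' @param large_set_size stimuli per large block (default 6).
#' @param reps_per_stimulus learning-phase presentations per stimulus
#'   (default 9).
#' @param n_actions number of response keys (default 3).
#' @param test_reps_per_stimulus test-phase presentations per stimulus
#'   (default 4).
#' @param miss_rate probability that a simulated trial times out with no
#'   response (default 0). Missed trials carry no reward and no model update.
#' @return An object of class `rlwm_task_config`.
#' @export
task_config <- function(n_small_blocks = 6, n_large_blocks = 4,
                        small_set_size = 3, large_set_size = 6,
                        reps_per_stimulus = 9, n_actions = 3,
                        test_reps_per_stimulus = 4, miss_rate = 0) {
  cfg <- list(
    n_small_blocks = n_small_blocks, n_large_blocks = n_large_blocks,
    small_set_size = small_set_size, large_set_size = large_set_size,
    reps_per_stimulus = reps_per_stimulus, n_actions = n_actions,
    test_reps_per_stimulus = test_reps_per_stimulus, miss_rate = miss_rate
  )
  counts <- c("n_small_blocks", "n_large_blocks", "small_set_size",
              "large_set_size", "reps_per_stimulus", "n_actions",
              "test_reps_per_stimulus")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1 ||
        v != round(v)) {
      stop("task_config: field '", f, "' must be a count >= 1", call. = FALSE)
    }
    cfg[[f]] <- as.integer(v)
  }
  if (!is.numeric(miss_rate) || length(miss_rate) != 1L ||
      is.na(miss_rate) || miss_rate < 0 || miss_rate > 1) {
    stop("task_config: field 'miss_rate' must lie in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "rlwm_task_config")
}

#' @export
print.rlwm_task_config <- function(x, ...) {
  cat("RL-WM task configuration\n")
  cat(sprintf("  blocks: %d x set size %d, %d x set size %d\n",
              x$n_small_blocks, x$small_set_size,
              x$n_large_blocks, x$large_set_size))
  cat(sprintf("  %d presentations/stimulus, %d actions, %d test reps, miss rate %.3g\n",
              x$reps_per_stimulus, x$n_actions, x$test_reps_per_stimulus,
              x$miss_rate))
  invisible(x)
}

# Smallest achievable sum of squared deviations from a flat histogram with
# integer counts: `total` observations over `m` cells.
min_flat_cost <- function(total, m) {
  t <- total / m
  rem <- total %% m
  rem * (ceiling(t) - t)^2 + (m - rem) * (floor(t) - t)^2
}

sequence_cost <- function(rounds, set_size, support) {
  reps <- nrow(rounds)
  # delay between consecutive presentations: stimulus at column-position i in
  # round k and j in round k+1 has delay set_size - 1 + (j - i)
  pos <- apply(rounds, 1L, order)            # set_size x reps: position of each stimulus
  d <- set_size - 1L + pos[, -1L, drop = FALSE] - pos[, -reps, drop = FALSE]
  delays <- as.vector(d)
  bad <- sum(!(delays %in% support))
  counts <- tabulate(match(delays, support), nbins = length(support))
  t <- length(delays) / length(support)
  sum((counts - t)^2) + 1000 * bad
}

#' Pseudo-randomized stimulus sequence for one learning block
#'
#' Generates an ordering in which each stimulus occurs exactly `reps` times,
#' never twice in a row, and the distribution of delays (intervening trials)
#' between successive presentations of the same stimulus is approximately
#' flat over its design support `1 .. 2 * set_size - 3`. The sequence is
#' built from `reps` rounds (each a permutation of all stimuli) refined by a
#' seeded local search over within-round swaps that flattens the pooled delay
#' histogram; the search is capped and returns the best ordering found.
#'
#' @param set_size number of distinct stimuli (>= 2).
#' @param reps presentations per stimulus (>= 2).
#' @param seed integer seed for reproducibility.
#' @param max_iter cap on local-search proposals (default 4000).
#' @return Integer vector of length `set_size * reps` with stimulus indices
#'   `1..set_size`.
#' @export
sequence_block <- function(set_size, reps, seed = NULL, max_iter = 4000) {
  if (!is.numeric(set_size) || set_size < 2 || set_size != round(set_size)) {
    stop("sequence_block: set_size must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(reps) || reps < 2 || reps != round(reps)) {
    stop("sequence_block: reps must be an integer >= 2", call. = FALSE)
  }
  set_size <- as.integer(set_size); reps <- as.integer(reps)
  support <- seq_len(max(2L * set_size - 3L, 1L))
  target <- min_flat_cost(set_size * (reps - 1L), length(support))
  with_seed(seed, {
    rounds <- t(vapply(seq_len(reps), function(i) sample.int(set_size),
                       integer(set_size)))
    cost <- sequence_cost(rounds, set_size, support)
    best <- rounds; best_cost <- cost
    iter <- 0L
    while (best_cost > target + 1e-9 && iter < max_iter) {
      iter <- iter + 1L
      k <- sample.int(reps, 1L)
      ij <- sample.int(set_size, 2L)
      cand <- rounds
      cand[k, ij] <- cand[k, rev(ij)]
      cand_cost <- sequence_cost(cand, set_size, support)
      if (cand_cost <= cost) {           # allow sideways moves off plateaus
        rounds <- cand; cost <- cand_cost
        if (cost < best_cost) { best <- rounds; best_cost <- cost }
      }
    }
    as.vector(t(best))
  })
}

#' Delays between successive presentations of each stimulus
#'
#' For every presentation after a stimulus's first, the number of intervening
#' trials since its previous presentation (0 for an immediate repeat). First
#' presentations have delay `NA`.
#'
#' @param sequence vector of stimulus identifiers in presentation order.
#' @return A data.frame with columns `position`, `stimulus`, `delay`.
#' @export
presentation_delays <- function(sequence) {
  if (length(sequence) == 0L) {
    stop("presentation_delays: sequence must be non-empty", call. = FALSE)
  }
  n <- length(sequence)
  delay <- rep(NA_integer_, n)
  last <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    key <- as.character(sequence[i])
    prev <- last[[key]]
    if (!is.null(prev)) delay[i] <- i - prev - 1L
    last[[key]] <- i
  }
  data.frame(position = seq_len(n), stimulus = sequence, delay = delay)
}

#' Build a full session plan
#'
#' Assembles the session: block order randomized, a novel set of stimuli per
#' block (globally unique ids), correct stimulus-response mappings
#' counterbalanced across the session so that each action is correct equally
#' often (exactly, when the total stimulus count is divisible by the number
#' of actions), pseudo-randomized learning sequences per block, and a single
#' shuffled test sequence covering every learned stimulus
#' `test_reps_per_stimulus` times.
#'
#' @param config an [task_config()] object.
#' @param seed integer seed.
#' @return An object of class `rlwm_session_plan` with elements `config`,
#'   `blocks` (data.frame: block, set_size), `stimuli` (data.frame: stimulus,
#'   block, correct_action), `learning` (list of per-block stimulus-id
#'   sequences) and `test` (data.frame: trial, stimulus, source_block).
#' @export
build_session <- function(config = task_config(), seed = NULL) {
  if (!inherits(config, "rlwm_task_config")) {
    stop("build_session: config must be created by task_config()",
         call. = FALSE)
  }
  with_seed(seed, {
    sizes <- c(rep(config$small_set_size, config$n_small_blocks),
               rep(config$large_set_size, config$n_large_blocks))
    sizes <- sizes[sample.int(length(sizes))]
    n_blocks <- length(sizes)
    n_stim <- sum(sizes)
    # counterbalanced correct actions across the whole session
    correct <- sample(rep_len(seq_len(config$n_actions), n_stim))
    stim_block <- rep(seq_len(n_blocks), sizes)
    stimuli <- data.frame(stimulus = seq_len(n_stim), block = stim_block,
                          correct_action = correct)
    learning <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      ids <- stimuli$stimulus[stimuli$block == b]
      local_seq <- sequence_block(sizes[b], config$reps_per_stimulus,
                                  seed = sample.int(.Machine$integer.max, 1L))
      learning[[b]] <- ids[local_seq]
    }
    test_stim <- rep(stimuli$stimulus, times = config$test_reps_per_stimulus)
    test_stim <- test_stim[sample.int(length(test_stim))]
    test <- data.frame(trial = seq_along(test_stim), stimulus = test_stim,
                       source_block = stimuli$block[test_stim])
    structure(list(
      config = config,
      blocks = data.frame(block = seq_len(n_blocks), set_size = sizes),
      stimuli = stimuli,
      learning = learning,
      test = test
    ), class = "rlwm_session_plan")
  })
}

#' @export
print.rlwm_session_plan <- function(x, ...) {
  cat("RL-WM session plan\n")
  cat(sprintf("  %d blocks (%s), %d stimuli, %d learning trials, %d test trials\n",
              nrow(x$blocks), paste(x$blocks$set_size, collapse = ","),
              nrow(x$stimuli), sum(lengths(x$learning)), nrow(x$test)))
  invisible(x)
}

#' Serialize a session plan to JSON
#'
#' @param plan an `rlwm_session_plan`.
#' @return A JSON string; [session_from_json()] inverts it.
#' @export
session_to_json <- function(plan) {
  stopifnot(inherits(plan, "rlwm_session_plan"))
  jsonlite::toJSON(list(
    config = unclass(plan$config),
    blocks = plan$blocks,
    stimuli = plan$stimuli,
    learning = plan$learning,
    test = plan$test
  ), auto_unbox = TRUE, digits = NA)
}

#' Deserialize a session plan from JSON
#'
#' @param txt JSON string produced by [session_to_json()].
#' @return An `rlwm_session_plan`.
#' @export
session_from_json <- function(txt) {
  x <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  cfg <- do.call(task_config, x$config)
  structure(list(
    config = cfg,
    blocks = as.data.frame(x$blocks),
    stimuli = as.data.frame(x$stimuli),
    learning = lapply(x$learning, as.integer),
    test = as.data.frame(x$test)
  ), class = "rlwm_session_plan")
}
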