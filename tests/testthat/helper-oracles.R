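# Straight-loop reference implementations of the learning state machines,
# kept deliberately naive and independent of the package's vectorized /
# compiled code paths, plus small fixture builders.

# A toy trial table with the columns the model machinery consumes. Trials
# are random (not counterbalanced): the state machines must work on any
# trial stream.
toy_sequence <- function(n_trials = 60, n_blocks = 2, seed = 1) {
  set.seed(seed)
  present <- rbinom(n_trials, 1, 0.5)
  loc <- ifelse(present == 1, sample(0:5, n_trials, replace = TRUE),
                NA_integer_)
  tpb <- n_trials / n_blocks
  data.frame(
    subject_id = "toy",
    block = rep(seq_len(n_blocks), each = tpb),
    trial_in_block = rep(seq_len(tpb), n_blocks),
    trial_global = seq_len(n_trials),
    distractor_present = present,
    distractor_location = loc,
    target_location = sample(0:5, n_trials, replace = TRUE),
    hp_location = 0L,
    condition = ifelse(present == 0, "ABS", ifelse(loc == 0, "HP", "LP")))
}

oracle_accumulator <- function(seq, b_distractor, reset_per_block = FALSE) {
  counts <- rep(0, 6)
  out <- numeric(0)
  for (t in seq_len(nrow(seq))) {
    if (reset_per_block && seq$trial_in_block[t] == 1) counts <- rep(0, 6)
    if (seq$distractor_present[t] == 1) {
      l <- seq$distractor_location[t] + 1
      out <- c(out, 1 - exp(-b_distractor * counts[l]))
      counts[l] <- counts[l] + 1
    }
  }
  out
}

oracle_categorical <- function(seq, reset_per_block = FALSE) {
  counts <- rep(0, 6)
  out <- numeric(0)
  for (t in seq_len(nrow(seq))) {
    if (reset_per_block && seq$trial_in_block[t] == 1) counts <- rep(0, 6)
    if (seq$distractor_present[t] == 1) {
      l <- seq$distractor_location[t] + 1
      out <- c(out, as.numeric(counts[l] == max(counts)))
      counts[l] <- counts[l] + 1
    }
  }
  out
}

oracle_rl <- function(seq, alpha, reset_per_block = FALSE, init = 0.16667) {
  p <- rep(init, 6)
  out <- numeric(0)
  for (t in seq_len(nrow(seq))) {
    if (reset_per_block && seq$trial_in_block[t] == 1) p <- rep(init, 6)
    if (seq$distractor_present[t] == 1) {
      l <- seq$distractor_location[t] + 1
      out <- c(out, p[l])
      for (k in 1:6) p[k] <- p[k] + alpha * (as.numeric(k == l) - p[k])
    }
  }
  out
}

# Full per-location RL state trajectory after every trial (for the
# monotonicity property).
oracle_rl_states <- function(seq, alpha, init = 0.16667) {
  p <- rep(init, 6)
  states <- matrix(NA_real_, nrow(seq), 6)
  for (t in seq_len(nrow(seq))) {
    if (seq$distractor_present[t] == 1) {
      l <- seq$distractor_location[t] + 1
      for (k in 1:6) p[k] <- p[k] + alpha * (as.numeric(k == l) - p[k])
    }
    states[t, ] <- p
  }
  states
}

# A small simulated subject used across inference/behavior tests.
small_subject <- function(model_id = 3, n_blocks = 2, seed = 1,
                          noise_sd_ms = 20,
                          params = NULL) {
  design <- experiment_design(n_blocks = n_blocks, trials_per_block = 60,
                              seed = seed)
  sq <- generate_sequence(design, paste0("T", seed))
  if (is.null(params)) {
    params <- default_group_spec()$group_mean
  }
  simulate_rts(model_id, params, sq, noise_sd_ms = noise_sd_ms, seed = seed)
}
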