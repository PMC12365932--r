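# Trial-sequence generation for the additional-singleton paradigm.
#
# Six search locations sit on a ring (indexed 0-5 clockwise). On half of the
# trials one non-target item is a salient color singleton (the distractor);
# on 66.67% of those trials it occupies a fixed high-probability (HP)
# location, with the remainder split equally over the five low-probability
# (LP) locations. Targets are exactly counterbalanced within every block.

#' Specify an additional-singleton experiment design
#'
#' Encodes the probability structure and counterbalancing rules from which
#' trial sequences are generated: number of blocks and trials per block,
#' the distractor-present rate, the conditional probability that a present
#' distractor occupies the high-probability location, and whether that
#' location is constant throughout or changes periodically so that every
#' location serves as the high-probability location exactly once.
#'
#' All count quotas implied by the probabilities must be whole numbers per
#' block (and per low-probability location); the constructor fails with a
#' message naming the violated constraint otherwise.
#'
#' @param n_blocks Number of blocks.
#' @param trials_per_block Trials per block; must be divisible by 6.
#' @param p_present Probability of a distractor-present trial (default 0.5).
#' @param p_high_given_present Probability the distractor occupies the
#'   high-probability location given that it is present (default 2/3).
#' @param schedule `"constant"` (one high-probability location throughout) or
#'   `"changing"` (the location changes every `change_interval_trials`).
#' @param change_interval_trials Trials per high-probability epoch for the
#'   changing schedule; must equal `n_blocks * trials_per_block / 6` so each
#'   location serves exactly once.
#' @param hp_location High-probability location (0-5) for the constant
#'   schedule; ignored for the changing schedule, where a seeded permutation
#'   of the six locations defines the epoch order.
#' @param lp_target_mapping How the target location is chosen on the
#'   low-probability distractor trials whose target is not at the
#'   high-probability location: `"predefined"` uses a fixed deterministic
#'   derangement of the low-probability locations (repeated across blocks),
#'   `"random"` draws a fresh seeded random derangement per block. Both keep
#'   per-block target counts exactly balanced.
#' @param seed Integer seed controlling all randomization.
#'
#' @return An object of class `experiment_design`.
#' @seealso [exp1_design()], [exp2_design()], [generate_sequence()]
#' @export
#' @examples
#' d <- experiment_design(n_blocks = 2, trials_per_block = 60, seed = 1)
#' d
experiment_design <- function(n_blocks,
                              trials_per_block,
                              p_present = 0.5,
                              p_high_given_present = 2 / 3,
                              schedule = c("constant", "changing"),
                              change_interval_trials = NULL,
                              hp_location = 0L,
                              lp_target_mapping = c("predefined", "random"),
                              seed = 1L) {
  schedule <- match.arg(schedule)
  lp_target_mapping <- match.arg(lp_target_mapping)
  n_locations <- 6L

  if (!is_count(n_blocks)) stop("n_blocks must be a positive integer")
  if (!is_count(trials_per_block)) stop("trials_per_block must be a positive integer")
  if (trials_per_block %% n_locations != 0) {
    stop("infeasible design: trials_per_block must be divisible by ", n_locations,
         " to balance targets per block")
  }
  n_present <- p_present * trials_per_block
  if (!near_integer(n_present)) {
    stop("infeasible design: p_present * trials_per_block = ", n_present,
         " is not a whole number of trials")
  }
  n_present <- round(n_present)
  n_hp <- p_high_given_present * n_present
  if (!near_integer(n_hp)) {
    stop("infeasible design: p_high_given_present * present trials = ", n_hp,
         " is not a whole number of trials")
  }
  n_hp <- round(n_hp)
  n_lp <- n_present - n_hp
  if (n_lp %% (n_locations - 1L) != 0) {
    stop("infeasible design: ", n_lp, " low-probability distractor trials ",
         "cannot be split equally over ", n_locations - 1L, " locations")
  }
  # Per-block target balance under the half-at-HP compensation rule forces
  # the canonical probability structure: n_hp = 2 * n_lp, i.e. 2/3 of present
  # distractors at the high-probability location.
  if (n_hp != 2L * n_lp) {
    stop("infeasible design: target counterbalancing (half of low-probability ",
         "distractor trials placing the target at the high-probability ",
         "location) requires p_high_given_present = 2/3")
  }
  if ((trials_per_block - n_present) %% n_locations != 0) {
    stop("infeasible design: distractor-absent trials cannot be target-balanced")
  }
  if (n_hp %% (n_locations - 1L) != 0) {
    stop("infeasible design: targets on high-probability distractor trials ",
         "cannot be balanced over the ", n_locations - 1L, " other locations")
  }
  if (n_lp %% 2 != 0) {
    stop("infeasible design: half of low-probability distractor trials must ",
         "place the target at the high-probability location")
  }

  if (schedule == "changing") {
    total <- n_blocks * trials_per_block
    if (is.null(change_interval_trials)) {
      change_interval_trials <- total / n_locations
    }
    if (!is_count(change_interval_trials) ||
        change_interval_trials * n_locations != total) {
      stop("infeasible design: change_interval_trials must equal ",
           "n_blocks * trials_per_block / 6 (each location serves as the ",
           "high-probability location exactly once)")
    }
    if (change_interval_trials %% trials_per_block != 0) {
      stop("infeasible design: change_interval_trials must be a whole number of blocks")
    }
  } else {
    change_interval_trials <- NULL
    if (!hp_location %in% 0:(n_locations - 1L)) {
      stop("hp_location must be an integer in 0..5")
    }
  }

  structure(
    list(
      n_locations = n_locations,
      n_blocks = as.integer(n_blocks),
      trials_per_block = as.integer(trials_per_block),
      # canonical exact values, so serialization round trips bit-for-bit
      p_present = n_present / trials_per_block,
      p_high_given_present = n_hp / n_present,
      schedule = schedule,
      change_interval_trials = if (is.null(change_interval_trials)) NULL else
        as.integer(change_interval_trials),
      hp_location = as.integer(hp_location),
      lp_target_mapping = lp_target_mapping,
      seed = as.integer(seed)
    ),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Additional-singleton experiment design\n")
  cat(sprintf("  %d blocks x %d trials (%d total), %s schedule\n",
              x$n_blocks, x$trials_per_block, x$n_blocks * x$trials_per_block,
              x$schedule))
  cat(sprintf("  P(distractor present) = %.4f, P(HP location | present) = %.4f\n",
              x$p_present, x$p_high_given_present))
  if (x$schedule == "constant") {
    cat(sprintf("  high-probability location: %d\n", x$hp_location))
  } else {
    cat(sprintf("  high-probability location changes every %d trials\n",
                x$change_interval_trials))
  }
  invisible(x)
}

#' Canonical designs for the two experiments
#'
#' `exp1_design()` is the 8-block, 480-trial constant-probability design with
#' a predefined low-probability target mapping; `exp2_design()` is the
#' 18-block, 1,080-trial design with randomized low-probability target
#' mapping, either with a constant high-probability location or with the
#' location changing every 3 blocks (180 trials).
#'
#' @param hp_location High-probability location (constant schedule).
#' @param schedule `"constant"` or `"changing"` (`exp2_design` only).
#' @param seed Integer seed.
#' @return An `experiment_design`.
#' @export
exp1_design <- function(hp_location = 0L, seed = 1L) {
  experiment_design(n_blocks = 8L, trials_per_block = 60L,
                    hp_location = hp_location,
                    lp_target_mapping = "predefined", seed = seed)
}

#' @rdname exp1_design
#' @export
exp2_design <- function(schedule = c("constant", "changing"),
                        hp_location = 0L, seed = 1L) {
  schedule <- match.arg(schedule)
  experiment_design(n_blocks = 18L, trials_per_block = 60L,
                    schedule = schedule,
                    change_interval_trials = if (schedule == "changing") 180L else NULL,
                    hp_location = hp_location,
                    lp_target_mapping = "random", seed = seed)
}

# Fixed derangement of the LP locations: shift by 2 within the cyclically
# ordered low-probability locations. Bijective with no fixed points, so each
# LP location receives exactly one target from these trials per block.
predefined_lp_targets <- function(lp) {
  lp[((seq_along(lp) - 1L + 2L) %% length(lp)) + 1L]
}

# Seeded uniform random derangement (rejection sampling).
random_derangement <- function(x) {
  repeat {
    p <- sample(x)
    if (!any(p == x)) return(p)
  }
}

# One block's worth of trials, as a data.frame, given the block's HP location.
build_block <- function(design, hp) {
  tpb <- design$trials_per_block
  nl <- design$n_locations
  lp <- setdiff(0:(nl - 1L), hp)
  n_present <- round(design$p_present * tpb)
  n_hp <- round(design$p_high_given_present * n_present)
  n_lp <- n_present - n_hp
  n_abs <- tpb - n_present
  per_lp <- n_lp %/% (nl - 1L)

  # Distractor-absent trials: targets balanced over all locations.
  abs_target <- rep(0:(nl - 1L), each = n_abs %/% nl)
  # HP-distractor trials: target cannot be at the HP location; balanced over
  # the LP locations.
  hp_target <- rep(lp, each = n_hp %/% (nl - 1L))
  # LP-distractor trials: per LP location, half place the target at the HP
  # location; the rest follow a derangement of the LP locations (one
  # derangement per pair of trials, so targets stay exactly balanced).
  lp_dist <- rep(lp, each = per_lp)
  pairs <- per_lp %/% 2L
  maps <- lapply(seq_len(pairs), function(j) {
    switch(design$lp_target_mapping,
           predefined = predefined_lp_targets(lp),
           random = random_derangement(lp))
  })
  lp_target <- unlist(lapply(seq_along(lp), function(i) {
    as.vector(vapply(seq_len(pairs),
                     function(j) c(hp, maps[[j]][i]), numeric(2)))
  }))

  trial <- data.frame(
    distractor_present = c(rep(1L, n_hp + n_lp), rep(0L, n_abs)),
    distractor_location = c(rep(hp, n_hp), lp_dist, rep(NA_integer_, n_abs)),
    target_location = c(hp_target, lp_target, abs_target)
  )
  trial[sample(nrow(trial)), , drop = FALSE]
}

#' Generate a trial sequence for one subject
#'
#' Produces the full, ordered trial list implementing the design's
#' probability structure: exact per-block distractor-present and
#' high-probability quotas, equal per-block target counts at every location,
#' targets at the high-probability location on exactly half of the
#' low-probability distractor trials, and seeded within-block shuffling.
#' For the changing schedule, a seeded permutation of the six locations
#' assigns each location one contiguous high-probability epoch.
#'
#' Randomization is fully determined by `design$seed` and `subject_id`:
#' regenerating with the same pair reproduces the sequence exactly.
#'
#' @param design An [experiment_design()].
#' @param subject_id Subject identifier (stored in the output).
#' @return A `trial_sequence`: a data.frame with one row per trial and
#'   columns `subject_id`, `block`, `trial_in_block`, `trial_global`,
#'   `distractor_present`, `distractor_location` (NA when absent),
#'   `target_location`, `hp_location`, `singleton_color`, and `condition`
#'   (`"HP"`, `"LP"`, or `"ABS"`), with the design attached as attribute
#'   `"design"`.
#' @export
#' @examples
#' seq1 <- generate_sequence(exp1_design(seed = 7), "S01")
#' table(seq1$condition)
generate_sequence <- function(design, subject_id = "S01") {
  stopifnot(inherits(design, "experiment_design"))
  seed <- subject_seed(design$seed, subject_id)
  tpb <- design$trials_per_block

  with_seed(seed, {
    if (design$schedule == "changing") {
      epoch_order <- sample(0:(design$n_locations - 1L))
      blocks_per_epoch <- design$change_interval_trials %/% tpb
      hp_by_block <- rep(epoch_order, each = blocks_per_epoch)
    } else {
      hp_by_block <- rep(design$hp_location, design$n_blocks)
    }

    rows <- lapply(seq_len(design$n_blocks), function(b) {
      blk <- build_block(design, hp_by_block[b])
      blk$block <- b
      blk$trial_in_block <- seq_len(nrow(blk))
      blk$hp_location <- hp_by_block[b]
      blk
    })
    out <- do.call(rbind, rows)
    out$trial_global <- seq_len(nrow(out))
    out$subject_id <- as.character(subject_id)
    out$singleton_color <- sample(c("red", "blue"), nrow(out), replace = TRUE)
    out$condition <- ifelse(out$distractor_present == 0L, "ABS",
                            ifelse(out$distractor_location == out$hp_location,
                                   "HP", "LP"))
    out <- out[, c("subject_id", "block", "trial_in_block", "trial_global",
                   "distractor_present", "distractor_location",
                   "target_location", "hp_location", "singleton_color",
                   "condition")]
    rownames(out) <- NULL
    attr(out, "design") <- design
    class(out) <- c("trial_sequence", "data.frame")
    out
  })
}

#' Check a trial sequence against the paradigm's invariants
#'
#' Verifies, block by block, the exact count structure a valid sequence must
#' satisfy: the distractor-present quota, the high-probability quota, equal
#' shares for each low-probability location, equal per-location target
#' counts, no distractor/target collisions, consistent condition labels, no
#' target at the high-probability location on high-probability distractor
#' trials, and targets at the high-probability location on exactly half of
#' the low-probability distractor trials. For changing schedules it also
#' checks that every location is the high-probability location for exactly
#' `change_interval_trials` trials.
#'
#' @param seq A `trial_sequence` (or equivalently shaped data.frame with a
#'   `"design"` attribute).
#' @return A data.frame of violations with columns `block`, `constraint`,
#'   `observed`, `expected`; zero rows when the sequence is valid.
#' @export
validate_sequence <- function(seq) {
  design <- attr(seq, "design")
  stopifnot(!is.null(design))
  nl <- design$n_locations
  tpb <- design$trials_per_block
  n_present <- round(design$p_present * tpb)
  n_hp <- round(design$p_high_given_present * n_present)
  n_lp <- n_present - n_hp
  per_lp <- n_lp %/% (nl - 1L)
  per_target <- tpb %/% nl

  bad <- list()
  flag <- function(block, constraint, observed, expected) {
    bad[[length(bad) + 1L]] <<- data.frame(
      block = block, constraint = constraint,
      observed = observed, expected = expected)
  }

  for (b in unique(seq$block)) {
    blk <- seq[seq$block == b, ]
    hp <- blk$hp_location[1]
    lp <- setdiff(0:(nl - 1L), hp)
    if (nrow(blk) != tpb) flag(b, "trials_per_block", nrow(blk), tpb)
    np <- sum(blk$distractor_present)
    if (np != n_present) flag(b, "distractor_present_count", np, n_present)
    nhp <- sum(blk$distractor_present == 1 & blk$distractor_location == hp,
               na.rm = TRUE)
    if (nhp != n_hp) flag(b, "hp_distractor_count", nhp, n_hp)
    for (l in lp) {
      nlp <- sum(blk$distractor_location == l, na.rm = TRUE)
      if (nlp != per_lp) {
        flag(b, paste0("lp_distractor_count_loc", l), nlp, per_lp)
      }
    }
    for (l in 0:(nl - 1L)) {
      nt <- sum(blk$target_location == l)
      if (nt != per_target) flag(b, paste0("target_count_loc", l), nt, per_target)
    }
    coll <- sum(blk$distractor_present == 1 &
                  blk$distractor_location == blk$target_location, na.rm = TRUE)
    if (coll > 0) flag(b, "distractor_target_collision", coll, 0)
    on_hp <- blk$distractor_present == 1 & blk$distractor_location == hp
    if (any(blk$target_location[on_hp] == hp, na.rm = TRUE)) {
      flag(b, "target_at_hp_on_hp_trial",
           sum(blk$target_location[on_hp] == hp), 0)
    }
    lp_rows <- blk$distractor_present == 1 & blk$distractor_location != hp
    t_at_hp <- sum(blk$target_location[lp_rows] == hp, na.rm = TRUE)
    if (t_at_hp != n_lp %/% 2L) {
      flag(b, "target_at_hp_on_lp_trials", t_at_hp, n_lp %/% 2L)
    }
    lab <- ifelse(blk$distractor_present == 0L, "ABS",
                  ifelse(blk$distractor_location == hp, "HP", "LP"))
    nbadlab <- sum(lab != blk$condition)
    if (nbadlab > 0) flag(b, "condition_label", nbadlab, 0)
  }

  if (design$schedule == "changing") {
    hp_counts <- table(factor(seq$hp_location, levels = 0:(nl - 1L)))
    for (l in 0:(nl - 1L)) {
      if (hp_counts[[l + 1L]] != design$change_interval_trials) {
        flag(NA_integer_, paste0("hp_epoch_trials_loc", l),
             hp_counts[[l + 1L]], design$change_interval_trials)
      }
    }
  }

  if (length(bad) == 0) {
    data.frame(block = integer(), constraint = character(),
               observed = numeric(), expected = numeric())
  } else {
    do.call(rbind, bad)
  }
}

#' Circular distance between a location and the high-probability location
#'
#' Minimal number of steps around the six-location ring, so distances range
#' 0 (the high-probability location itself) to 3 (directly opposite).
#'
#' @param location,hp_location Location indices 0-5 (vectorized).
#' @param n_locations Ring size (default 6).
#' @return Integer distances; NA propagates.
#' @export
hp_distance <- function(location, hp_location, n_locations = 6L) {
  d <- (location - hp_location) %% n_locations
  as.integer(pmin(d, n_locations - d))
}

#' Label each trial with its condition and distance from the HP location
#'
#' Adds `hp_distance`: 0 for distractors at the high-probability location,
#' 1-3 for low-probability distractors by minimal circular distance, NA on
#' distractor-absent trials. Also adds `target_hp_distance` for analyses of
#' target position.
#'
#' @param seq A `trial_sequence`.
#' @return The sequence with `hp_distance` and `target_hp_distance` columns.
#' @export
label_conditions <- function(seq) {
  seq$hp_distance <- hp_distance(seq$distractor_location, seq$hp_location)
  seq$target_hp_distance <- hp_distance(seq$target_location, seq$hp_location)
  seq
}

#' Read and write trial CSV files
#'
#' One row per trial with the sequence columns plus (possibly empty) `rt_ms`
#' and `accuracy`. `NA` encodes an absent distractor's location.
#'
#' @param data A `trial_sequence` or a `subject_data` object (sequence plus
#'   RTs and accuracies).
#' @param path File path.
#' @return `read_trials` returns a data.frame; `write_trials` the path,
#'   invisibly.
#' @export
write_trials <- function(data, path) {
  if (inherits(data, "subject_data")) {
    out <- data$sequence
    out$rt_ms <- data$rt_ms
    out$accuracy <- data$accuracy
  } else {
    out <- as.data.frame(data)
    if (is.null(out$rt_ms)) out$rt_ms <- NA_real_
    if (is.null(out$accuracy)) out$accuracy <- NA_integer_
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  utils::read.csv(path, na.strings = c("", "NA"))
}
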