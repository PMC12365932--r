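test_that("constant-schedule sequences satisfy the exact count structure", {
  sq <- generate_sequence(exp1_design(hp_location = 2, seed = 11), "S01")

  expect_equal(nrow(sq), 480)
  expect_equal(sum(sq$distractor_present), 240)
  expect_equal(sum(sq$condition == "HP"), 160)
  expect_equal(nrow(validate_sequence(sq)), 0)

  for (b in 1:8) {
    blk <- sq[sq$block == b, ]
    expect_equal(sum(blk$distractor_present), 30)
    expect_equal(sum(blk$condition == "HP"), 20)
    # each LP location gets an equal share of the remaining present trials
    lp_counts <- table(blk$distractor_location[blk$condition == "LP"])
    expect_true(all(lp_counts == 2))
    # target at every location exactly 10 times
    expect_true(all(table(factor(blk$target_location, levels = 0:5)) == 10))
    # half of LP-distractor trials have the target at the HP location
    lp_rows <- blk[blk$condition == "LP", ]
    expect_equal(sum(lp_rows$target_location == blk$hp_location[1]), 5)
  }
})

test_that("per-block target composition decomposes as the quotas dictate", {
  sq <- generate_sequence(exp1_design(hp_location = 0, seed = 3), "S02")
  blk <- sq[sq$block == 1, ]
  hp <- blk$hp_location[1]

  # HP location: 5 targets on absent trials + 5 on LP-distractor trials
  expect_equal(sum(blk$condition == "ABS" & blk$target_location == hp), 5)
  expect_equal(sum(blk$condition == "LP" & blk$target_location == hp), 5)
  expect_equal(sum(blk$condition == "HP" & blk$target_location == hp), 0)
  # each LP location: 5 absent + 4 from HP-distractor + 1 from LP-distractor
  for (l in setdiff(0:5, hp)) {
    expect_equal(sum(blk$condition == "ABS" & blk$target_location == l), 5)
    expect_equal(sum(blk$condition == "HP" & blk$target_location == l), 4)
    expect_equal(sum(blk$condition == "LP" & blk$target_location == l), 1)
  }
  # the distractor never sits on the target
  expect_equal(sum(sq$distractor_present == 1 &
                     sq$distractor_location == sq$target_location), 0)
})

test_that("changing-schedule sequences give every location one HP epoch", {
  sq <- generate_sequence(exp2_design("changing", seed = 5), "S03")
  expect_equal(nrow(sq), 1080)
  expect_true(all(table(sq$hp_location) == 180))
  # epochs are contiguous: the HP location changes exactly 5 times
  expect_equal(sum(diff(sq$hp_location) != 0), 5)
  expect_equal(nrow(validate_sequence(sq)), 0)
})

test_that("validation flags corrupted sequences with named constraints", {
  sq <- generate_sequence(exp1_design(seed = 2), "S04")

  # relabel one HP trial as LP by moving its distractor off the HP location
  bad <- sq
  i <- which(bad$condition == "HP" & bad$block == 1)[1]
  new_loc <- setdiff(0:5, c(bad$hp_location[i], bad$target_location[i]))[1]
  bad$distractor_location[i] <- new_loc
  bad$condition[i] <- "LP"
  rep1 <- validate_sequence(bad)
  hp_row <- rep1[rep1$constraint == "hp_distractor_count", ]
  expect_equal(nrow(hp_row), 1)
  expect_equal(hp_row$observed, 19)
  expect_equal(hp_row$expected, 20)

  # distractor/target collision
  bad2 <- sq
  j <- which(bad2$distractor_present == 1)[1]
  bad2$target_location[j] <- bad2$distractor_location[j]
  rep2 <- validate_sequence(bad2)
  expect_true("distractor_target_collision" %in% rep2$constraint)
})

test_that("generation is reproducible under the seed and varies across subjects", {
  d <- exp1_design(seed = 99)
  expect_identical(as.data.frame(generate_sequence(d, "A")),
                   as.data.frame(generate_sequence(d, "A")))
  expect_false(identical(as.data.frame(generate_sequence(d, "A")),
                         as.data.frame(generate_sequence(d, "B"))))
  d2 <- exp1_design(seed = 100)
  expect_false(identical(as.data.frame(generate_sequence(d, "A")),
                         as.data.frame(generate_sequence(d2, "A"))))
})

test_that("circular distance from the HP location is the minimal step count", {
  expect_equal(hp_distance(0, 0), 0L)
  expect_equal(hp_distance(3, 0), 3L)  # opposite: equal either way
  expect_equal(hp_distance(4, 0), 2L)  # min(4, 6 - 4)
  expect_equal(hp_distance(5, 0), 1L)
  expect_equal(hp_distance(1, 5), 2L)
  sq <- label_conditions(generate_sequence(exp1_design(seed = 1), "S"))
  expect_true(all(sq$hp_distance[sq$condition == "HP"] == 0))
  expect_true(all(sq$hp_distance[sq$condition == "LP"] %in% 1:3))
  expect_true(all(is.na(sq$hp_distance[sq$condition == "ABS"])))
})

test_that("infeasible designs fail with a message naming the constraint", {
  expect_error(experiment_design(n_blocks = 2, trials_per_block = 59),
               "divisible by 6")
  expect_error(experiment_design(n_blocks = 2, trials_per_block = 60,
                                 p_present = 0.51),
               "not a whole number")
  expect_error(experiment_design(n_blocks = 2, trials_per_block = 60,
                                 p_high_given_present = 0.5),
               "2/3")
  expect_error(experiment_design(n_blocks = 4, trials_per_block = 60,
                                 schedule = "changing",
                                 change_interval_trials = 60),
               "exactly once")
})

test_that("trial CSV round-trips through write_trials/read_trials", {
  sq <- generate_sequence(experiment_design(2, 60, seed = 8), "S05")
  f <- tempfile(fileext = ".csv")
  write_trials(sq, f)
  back <- read_trials(f)
  expect_equal(back$distractor_location, sq$distractor_location)
  expect_equal(back$condition, sq$condition)
  expect_true(all(is.na(back$rt_ms)))
})
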