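# Descriptive behavioral summaries of (real or simulated) datasets.
#
# RT summaries use accurate trials with RT >= 200 ms; accuracy summaries use
# all trials. Every function is a pure function of the dataset.

rt_filter <- function(data) {
  data$accuracy == 1L & !is.na(data$rt_ms) & data$rt_ms >= 200
}

mean_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x)

#' Per-condition RT and accuracy means for one subject
#'
#' Computes the paradigm's standard descriptive cells: mean RT and accuracy
#' for high-probability, low-probability, and distractor-absent trials; mean
#' RT for low-probability distractors by distance (1-3) from the
#' high-probability location; and mean RT by target position (at vs not at
#' the high-probability location) separately for distractor-absent and
#' low-probability distractor trials.
#'
#' @param data A [subject_data()] object.
#' @return A list of data.frames: `rt` (condition means, ms), `accuracy`
#'   (proportions over all trials), `distance` (LP means by distance), and
#'   `target` (target-position means). Empty cells are NA.
#' @export
condition_means <- function(data) {
  sq <- label_conditions(data$sequence)
  keep <- rt_filter(data)
  rt <- data$rt_ms

  conds <- c("HP", "LP", "ABS")
  rt_tab <- data.frame(
    condition = conds,
    mean_rt_ms = vapply(conds, function(cc)
      mean_or_na(rt[keep & sq$condition == cc]), numeric(1)),
    n = vapply(conds, function(cc)
      sum(keep & sq$condition == cc), numeric(1)))
  acc_tab <- data.frame(
    condition = conds,
    accuracy = vapply(conds, function(cc)
      mean_or_na(data$accuracy[sq$condition == cc]), numeric(1)),
    n = vapply(conds, function(cc) sum(sq$condition == cc), numeric(1)))
  dist_tab <- data.frame(
    distance = 1:3,
    mean_rt_ms = vapply(1:3, function(d)
      mean_or_na(rt[keep & sq$condition == "LP" & sq$hp_distance == d]),
      numeric(1)))
  tgt <- expand.grid(trial_type = c("ABS", "LP"),
                     target_at_hp = c(TRUE, FALSE))
  tgt$mean_rt_ms <- mapply(function(tt, at_hp) {
    sel <- keep & sq$condition == tt &
      ((sq$target_location == sq$hp_location) == at_hp)
    mean_or_na(rt[sel])
  }, tgt$trial_type, tgt$target_at_hp)

  list(rt = rt_tab, accuracy = acc_tab, distance = dist_tab, target = tgt)
}

#' Slope of the suppression gradient over distance
#'
#' Ordinary least-squares slope of the subject's mean low-probability RTs
#' over distance 1-3 from the high-probability location, in ms per step.
#'
#' @param data A [subject_data()] object.
#' @return A list with `slope` (ms/step; NA with a `reason` when a distance
#'   bin is empty) and the `means` used.
#' @export
gradient_slope <- function(data) {
  d <- condition_means(data)$distance
  if (any(is.na(d$mean_rt_ms))) {
    return(list(slope = NA_real_, means = d,
                reason = paste("empty distance bin:",
                               paste(d$distance[is.na(d$mean_rt_ms)],
                                     collapse = ", "))))
  }
  fit <- stats::lm(mean_rt_ms ~ distance, data = d)
  list(slope = unname(stats::coef(fit)[2]), means = d, reason = NULL)
}

#' High-probability trial RTs by previous trial type
#'
#' Mean RT on high-probability distractor trials grouped by the type of the
#' immediately preceding trial (HP, LP, or distractor absent), excluding the
#' first trial of each block and trials whose target location repeats the
#' preceding trial's target location (target repetitions are confounded with
#' previous trial type under the paradigm's counterbalancing).
#'
#' @param data A [subject_data()] object.
#' @return A data.frame with `previous_condition`, `mean_rt_ms`, `n`
#'   (NA means for empty cells).
#' @export
previous_trial_means <- function(data) {
  sq <- data$sequence
  keep <- rt_filter(data)
  n <- nrow(sq)
  prev <- c(NA, seq_len(n - 1L))
  prev_cond <- sq$condition[prev]
  target_repeat <- sq$target_location == sq$target_location[prev]
  sel_base <- sq$condition == "HP" & sq$trial_in_block != 1L &
    !is.na(prev_cond) & !target_repeat & keep

  conds <- c("HP", "LP", "ABS")
  data.frame(
    previous_condition = conds,
    mean_rt_ms = vapply(conds, function(cc)
      mean_or_na(data$rt_ms[sel_base & prev_cond == cc]), numeric(1)),
    n = vapply(conds, function(cc)
      sum(sel_base & prev_cond == cc, na.rm = TRUE), numeric(1)))
}

#' Current vs most recent previous high-probability location (changing schedule)
#'
#' For changing-schedule data: mean RT on distractor-present trials where
#' the distractor occupies the current high-probability location vs the
#' most recent previous high-probability location. Excludes the first
#' high-probability epoch (no previous location exists yet) and trials where
#' the distractor occupies a location that has not yet served as
#' high-probability or served only before the most recent previous epoch.
#'
#' @param data A [subject_data()] object from a changing-schedule design.
#' @return A data.frame with `condition` (`"current_hp"`, `"last_hp"`),
#'   `mean_rt_ms`, `n`.
#' @export
last_hp_means <- function(data) {
  sq <- data$sequence
  design <- attr(sq, "design")
  if (is.null(design) || design$schedule != "changing") {
    stop("last_hp_means applies only to changing-schedule sequences")
  }
  keep <- rt_filter(data)
  interval <- design$change_interval_trials
  epoch <- ((sq$trial_global - 1L) %/% interval) + 1L
  hp_by_epoch <- vapply(seq_len(max(epoch)), function(e)
    sq$hp_location[match(e, epoch)], integer(1))
  last_hp <- c(NA_integer_, hp_by_epoch)[epoch]  # previous epoch's HP

  sel <- keep & sq$distractor_present == 1L & epoch > 1L
  cur <- sel & sq$distractor_location == sq$hp_location
  last <- sel & !is.na(last_hp) & sq$distractor_location == last_hp

  data.frame(condition = c("current_hp", "last_hp"),
             mean_rt_ms = c(mean_or_na(data$rt_ms[cur]),
                            mean_or_na(data$rt_ms[last])),
             n = c(sum(cur), sum(last)))
}

#' Bin fitted-trial RTs into quartiles of model-derived predictions
#'
#' Splits the distractor-present trials used in model fitting into quartiles
#' of a model-derived prediction (e.g. accumulator or delta-rule
#' predictions) and returns the mean RT per quartile. Quartile breaks are
#' per-subject prediction quantiles; values equal to a break fall in the
#' lower quartile. If all predictions are equal, a single degenerate bin is
#' returned with a warning.
#'
#' @param data A [subject_data()] object.
#' @param predictions Numeric vector aligned with the included fitted
#'   trials (see [build_design_matrix()]), or with all distractor-present
#'   trials (it is then subset by the inclusion mask).
#' @return A data.frame with `quartile`, `mean_rt_ms`, `n`.
#' @export
bin_by_prediction <- function(data, predictions) {
  pre <- precompute_model_data(1L, data$sequence, data$rt_ms, data$accuracy)
  keep <- pre$included
  if (length(predictions) == pre$n_present) {
    predictions <- predictions[keep]
  } else if (length(predictions) != sum(keep)) {
    stop("predictions must align with the included or all present trials")
  }
  y <- pre$y_s[keep] * 1000
  n <- length(y)
  if (n < 4) stop("fewer than 4 included trials; cannot form quartiles")

  if (max(predictions) - min(predictions) < 1e-12) {
    warning("all predictions equal; returning a single degenerate bin")
    return(data.frame(quartile = 1L, mean_rt_ms = mean(y), n = n))
  }
  breaks <- stats::quantile(predictions, c(0.25, 0.5, 0.75), type = 1)
  bin <- findInterval(predictions, unique(breaks), left.open = TRUE) + 1L
  data.frame(quartile = sort(unique(bin)),
             mean_rt_ms = vapply(sort(unique(bin)), function(b)
               mean(y[bin == b]), numeric(1)),
             n = vapply(sort(unique(bin)), function(b)
               sum(bin == b), numeric(1)))
}
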