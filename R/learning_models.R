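# The nine candidate trial-level RT models.
#
# Every model predicts reaction times on distractor-present trials with a
# Gaussian GLM whose regressors are produced by a learning state machine run
# over the full trial sequence:
#
#   1 frequency accumulator + global decay       4 = 1 with per-block reset
#   2 Rescorla-Wagner (delta rule) + global decay 5 = 2 with per-block reset
#   3 categorical (argmax of counts) + global decay 6 = 3 with per-block reset
#   7 priming only (previous-trial dummies) + global decay
#   8 = 1 without the global decay regressor      9 = 4 without it
#
# RTs are modeled in seconds. The residual SD is profiled out at its MLE
# sigma_hat = sqrt(RSS/n) on every likelihood evaluation.

RL_INIT <- 0.16667  # initial per-location distractor prediction (~1/6)

#' Describe a candidate model
#'
#' Returns the model's regressor columns, free-parameter names (raw,
#' unconstrained space), which state machine it uses, and whether its
#' learning states reset at block boundaries.
#'
#' @param model_id Integer 1-9.
#' @return A list with elements `model_id`, `label`, `columns`,
#'   `param_names`, `n_params`, `mechanism` (`"accumulator"`, `"rl"`,
#'   `"categorical"`, `"priming"`), `reset_per_block`, `has_global_decay`.
#' @export
#' @examples
#' model_info(3)$n_params  # categorical model: 5 free parameters
model_info <- function(model_id) {
  model_id <- as.integer(model_id)
  if (!model_id %in% 1:9) stop("unknown model id: ", model_id)
  mechanism <- c("accumulator", "rl", "categorical",
                 "accumulator", "rl", "categorical",
                 "priming", "accumulator", "accumulator")[model_id]
  reset <- model_id %in% c(4L, 5L, 6L, 9L)
  has_gd <- !model_id %in% c(8L, 9L)
  columns <- switch(mechanism,
    accumulator = ,
    rl = c(if (has_gd) "global_decay", "distractor_prediction", "prev_absent"),
    categorical = c("global_decay", "categorical", "prev_absent"),
    priming = c("global_decay", "prev_absent", "repetition"))
  columns <- c("intercept", columns)
  nonlinear <- c(if (has_gd) "b_global",
                 if (mechanism == "accumulator") "b_distractor",
                 if (mechanism == "rl") "alpha")
  param_names <- c(nonlinear, paste0("beta_", columns))
  label <- sprintf("Model %d (%s%s%s)", model_id, mechanism,
                   if (reset) ", block reset" else "",
                   if (!has_gd) ", no global decay" else "")
  list(model_id = model_id, label = label, columns = columns,
       param_names = param_names, n_params = length(param_names),
       n_nonlinear = length(nonlinear), mechanism = mechanism,
       reset_per_block = reset, has_global_decay = has_gd)
}

#' Transform raw (unconstrained) parameters to their natural scale
#'
#' Decay rates are exponentiated to enforce positivity, the learning rate is
#' passed through the logistic to lie in (0, 1), and GLM coefficients are
#' untouched (seconds). The raw scale is the one on which hierarchical
#' priors are normal.
#'
#' @param raw Numeric vector, length `model_info(model_id)$n_params`.
#' @param model_id Integer 1-9.
#' @return Named list of natural-scale parameters.
#' @export
transform_params <- function(raw, model_id) {
  info <- model_info(model_id)
  if (length(raw) != info$n_params) {
    stop(sprintf("model %d expects %d parameters, got %d",
                 info$model_id, info$n_params, length(raw)))
  }
  names(raw) <- info$param_names
  out <- as.list(raw)
  for (nm in names(out)) {
    if (nm %in% c("b_global", "b_distractor")) out[[nm]] <- exp(raw[[nm]])
    if (nm == "alpha") out[[nm]] <- logistic(raw[[nm]])
  }
  out
}

#' Global exponential practice-decay regressor
#'
#' `exp(-b_global * (i - 1))` over distractor-present trials, where `i` is
#' the 1-based distractor-present trial number across the whole session
#' (block boundaries do not reset it). The first element is always 1.
#'
#' @param n_present Number of distractor-present trials.
#' @param b_global Positive decay rate (per distractor-present trial).
#' @return Numeric vector of length `n_present`.
#' @export
#' @examples
#' global_decay_regressor(3, log(2))  # 1, 0.5, 0.25
global_decay_regressor <- function(n_present, b_global) {
  stopifnot(n_present >= 1, b_global >= 0)
  exp(-b_global * (seq_len(n_present) - 1))
}

# Present-trial bookkeeping shared by all state machines. Returns, for the
# distractor-present trials in chronological order: their global indices,
# distractor locations (0-5), block ids, and the reset-segment id (blocks
# under a per-block reset, one segment otherwise).
present_trials <- function(seq, reset_per_block) {
  idx <- which(seq$distractor_present == 1L)
  list(idx = idx,
       loc = seq$distractor_location[idx],
       block = seq$block[idx],
       segment = if (reset_per_block) seq$block[idx] else rep(1L, length(idx)))
}

# Counts of prior distractor occurrences at each present trial's distractor
# location (state through trial i-1), plus the categorical argmax regressor,
# in one pass. Ties in the argmax include all tied locations, so the very
# first present trial of a segment (all counts zero) is coded 1.
accumulate_counts <- function(loc, segment, n_locations = 6L) {
  n <- length(loc)
  counts_before <- numeric(n)
  cat_reg <- numeric(n)
  cnt <- numeric(n_locations)
  seg <- if (n > 0) segment[1] else NA
  for (i in seq_len(n)) {
    if (segment[i] != seg) {
      cnt[] <- 0
      seg <- segment[i]
    }
    l <- loc[i] + 1L
    counts_before[i] <- cnt[l]
    cat_reg[i] <- as.numeric(cnt[l] == max(cnt))
    cnt[l] <- cnt[l] + 1
  }
  list(counts_before = counts_before, categorical = cat_reg)
}

#' Accumulator-model distractor predictions
#'
#' Per-location distractor frequencies are summed over distractor-present
#' trials and mapped through the saturating decay function
#' `pDist = 1 - exp(-b_distractor * count)`. The value returned for each
#' present trial is the prediction at that trial's distractor location using
#' counts through the previous trial.
#'
#' @param seq A `trial_sequence`.
#' @param b_distractor Positive location-level decay rate.
#' @param reset_per_block Zero all counts at each block start?
#' @return Numeric vector over distractor-present trials.
#' @export
accumulator_predictions <- function(seq, b_distractor, reset_per_block = FALSE) {
  stopifnot(b_distractor >= 0)
  pt <- present_trials(seq, reset_per_block)
  acc <- accumulate_counts(pt$loc, pt$segment)
  1 - exp(-b_distractor * acc$counts_before)
}

#' Categorical (argmax) suppression regressor
#'
#' 1 when the current distractor occupies a location whose accumulated
#' distractor count (through the previous trial) is maximal, 0 otherwise.
#' Ties count as maximal, so the all-zero initial state codes every location
#' as 1. The regressor is parameter-free: the argmax of the counts equals
#' the argmax of any monotone transform of them.
#'
#' @inheritParams accumulator_predictions
#' @return 0/1 vector over distractor-present trials.
#' @export
categorical_regressor <- function(seq, reset_per_block = FALSE) {
  pt <- present_trials(seq, reset_per_block)
  accumulate_counts(pt$loc, pt$segment)$categorical
}

# Rescorla-Wagner predictions at each present trial's distractor location,
# state through trial i-1; predictions update on distractor-present trials
# only. The recursion lives in C++ (rl_pred_cpp): it sits inside the
# optimizer's objective and dominates fitting cost otherwise.
rl_pred_core <- function(loc, segment, alpha, init = RL_INIT,
                         n_locations = 6L) {
  rl_pred_cpp(as.integer(loc), as.integer(segment), alpha, init,
              as.integer(n_locations))
}

#' Rescorla-Wagner (delta-rule) distractor predictions
#'
#' Every location starts at 0.16667. On each distractor-present trial all
#' six locations update by `pDist <- pDist + alpha * (Dist - pDist)` with
#' `Dist = 1` at the distractor's location and 0 elsewhere; nothing updates
#' on distractor-absent trials. The value returned for each present trial is
#' the prediction at that trial's distractor location before that trial's
#' update.
#'
#' @param seq A `trial_sequence`.
#' @param alpha Learning rate in (0, 1).
#' @param reset_per_block Reset all predictions to 0.16667 at block starts?
#' @return Numeric vector over distractor-present trials.
#' @export
rl_predictions <- function(seq, alpha, reset_per_block = FALSE) {
  stopifnot(alpha >= 0, alpha <= 1)
  pt <- present_trials(seq, reset_per_block)
  rl_pred_core(pt$loc, pt$segment, alpha)
}

#' Previous-trial priming regressors
#'
#' For each distractor-present trial: `prev_absent` is 1 when the
#' immediately preceding trial (of any type) had no distractor, and
#' `repetition` is 1 when the preceding trial's distractor occupied the same
#' location. Trials that open a block carry NA (they are always excluded
#' from fitting because their previous-trial context is undefined).
#'
#' @param seq A `trial_sequence`.
#' @return A data.frame with columns `prev_absent` and `repetition`, one row
#'   per distractor-present trial.
#' @export
priming_regressors <- function(seq) {
  idx <- which(seq$distractor_present == 1L)
  prev <- idx - 1L
  first <- seq$trial_in_block[idx] == 1L
  prev_absent <- ifelse(first, NA_real_,
                        as.numeric(seq$distractor_present[pmax(prev, 1L)] == 0L))
  repetition <- ifelse(
    first, NA_real_,
    as.numeric(seq$distractor_present[pmax(prev, 1L)] == 1L &
                 seq$distractor_location[pmax(prev, 1L)] ==
                 seq$distractor_location[idx]))
  repetition[is.na(repetition) & !first] <- 0
  data.frame(prev_absent = prev_absent, repetition = repetition)
}

# ---------------------------------------------------------------------------
# Design-matrix assembly
# ---------------------------------------------------------------------------

# Precompute everything about a subject that does not depend on parameter
# values: inclusion mask, parameter-free regressor ingredients, and the
# observed RT vector in seconds. Fitting then only has to evaluate cheap
# closed forms per objective call.
#
# rt_ms = NULL means "no RT filter yet" (used when simulating).
precompute_model_data <- function(model_id, seq, rt_ms = NULL, accuracy = NULL) {
  info <- model_info(model_id)
  pt <- present_trials(seq, info$reset_per_block)
  n_pres <- length(pt$idx)
  if (n_pres == 0) stop("sequence has no distractor-present trials")

  first_of_block <- seq$trial_in_block[pt$idx] == 1L
  included <- !first_of_block
  if (!is.null(accuracy)) included <- included & accuracy[pt$idx] == 1L
  if (!is.null(rt_ms)) included <- included & rt_ms[pt$idx] >= 200

  acc <- accumulate_counts(pt$loc, pt$segment)
  prim <- priming_regressors(seq)

  pre <- list(info = info,
              n_present = n_pres,
              loc = pt$loc,
              segment = pt$segment,
              included = included,
              counts_before = acc$counts_before,
              categorical = acc$categorical,
              prev_absent = prim$prev_absent,
              repetition = prim$repetition,
              pres_rank = seq_len(n_pres),
              y_s = if (is.null(rt_ms)) NULL else rt_ms[pt$idx] / 1000)

  # Included-row views used by the likelihood hot path (regressor values on
  # excluded rows never influence a fit: even z-scoring statistics are
  # defined over included rows only).
  ik <- which(included)
  pre$fit <- list(
    n = length(ik),
    rank0 = pre$pres_rank[ik] - 1,
    counts = acc$counts_before[ik],
    categorical = acc$categorical[ik],
    prev_absent = prim$prev_absent[ik],
    repetition = prim$repetition[ik],
    ik = ik,
    y = if (is.null(pre$y_s)) NULL else pre$y_s[ik])
  pre
}

# z-score a vector in place using its own mean/SD; constant -> zeros.
zscore_all <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Standardize x to mean 0 / SD 1 using statistics computed over rows where
# `use` is TRUE; a (numerically) constant column becomes all zeros.
zscore_by <- function(x, use) {
  m <- mean(x[use])
  s <- stats::sd(x[use])
  if (!is.finite(s) || s < 1e-12) return(rep(0, length(x)))
  (x - m) / s
}

# Build the regressor matrix over all present trials from raw nonlinear
# parameters; continuous columns (global decay, graded predictions) are
# z-scored with included-row statistics, dummies left 0/1.
design_matrix_core <- function(pre, raw_nonlinear) {
  info <- pre$info
  nat <- as.list(raw_nonlinear)
  names(nat) <- info$param_names[seq_len(info$n_nonlinear)]
  X <- matrix(1, pre$n_present, length(info$columns),
              dimnames = list(NULL, info$columns))
  for (cn in info$columns) {
    X[, cn] <- switch(cn,
      intercept = 1,
      global_decay = zscore_by(
        exp(-exp(nat$b_global) * (pre$pres_rank - 1)), pre$included),
      distractor_prediction = {
        p <- if (info$mechanism == "accumulator") {
          1 - exp(-exp(nat$b_distractor) * pre$counts_before)
        } else {
          rl_pred_core(pre$loc, pre$segment, logistic(nat$alpha))
        }
        zscore_by(p, pre$included)
      },
      categorical = pre$categorical,
      prev_absent = pre$prev_absent,
      repetition = pre$repetition)
  }
  X
}

#' Build a model's design matrix for fitting
#'
#' Rows are the distractor-present trials retained after the standard
#' exclusions (the first trial of each block, inaccurate trials, and trials
#' with RT < 200 ms). Continuous regressors (global decay and graded
#' distractor predictions) are z-scored over the included rows; dummy and
#' categorical columns stay 0/1.
#'
#' @param model_id Integer 1-9.
#' @param seq A `trial_sequence`.
#' @param raw Raw parameter vector (only the nonlinear leading entries are
#'   used; pass the full vector or just those entries).
#' @param rt_ms Per-trial RT in milliseconds, aligned with `seq` (NA allowed
#'   on absent trials).
#' @param accuracy Per-trial 0/1 accuracy, aligned with `seq`.
#' @return A list with `X` (included-row regressor matrix), `y` (RT in
#'   seconds over included rows), `included` (logical over present trials),
#'   and `info`.
#' @export
build_design_matrix <- function(model_id, seq, raw, rt_ms, accuracy) {
  pre <- precompute_model_data(model_id, seq, rt_ms, accuracy)
  info <- pre$info
  nl <- raw[seq_len(info$n_nonlinear)]
  X <- design_matrix_core(pre, nl)
  keep <- pre$included
  if (sum(keep) < length(info$columns) + 2L) {
    stop("degenerate fit: only ", sum(keep), " included trials for ",
         length(info$columns), " regressors")
  }
  list(X = X[keep, , drop = FALSE], y = pre$y_s[keep],
       included = keep, info = info)
}

#' Linear predictor of the RT GLM
#'
#' @param X Design matrix (rows = trials, columns = regressors).
#' @param betas Coefficients in seconds, one per column.
#' @return Predicted RT per row, in seconds.
#' @export
predict_rt <- function(X, betas) {
  if (ncol(X) != length(betas)) {
    stop("design matrix has ", ncol(X), " columns but ", length(betas),
         " coefficients were supplied")
  }
  drop(X %*% betas)
}

#' Gaussian log-likelihood with profiled residual SD
#'
#' The residual SD is re-estimated at its maximum-likelihood value
#' `sigma_hat = sqrt(RSS / n)` and plugged into the Gaussian density, giving
#' the closed form `LL = -(n/2) (1 + ln 2*pi) - n ln sigma_hat`.
#'
#' @param y Observed RT (seconds).
#' @param mu Predicted RT (seconds), same length.
#' @return A list with `LL`, `sigma_hat`, `rss`, and `n`.
#' @export
log_likelihood <- function(y, mu) {
  stopifnot(length(y) == length(mu), length(y) >= 2)
  rss <- sum((y - mu)^2)
  n <- length(y)
  if (rss <= 0) stop("degenerate likelihood: all residuals are zero")
  sigma_hat <- sqrt(rss / n)
  ll <- -(n / 2) * (1 + log(2 * pi)) - n * log(sigma_hat)
  list(LL = ll, sigma_hat = sigma_hat, rss = rss, n = n)
}
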