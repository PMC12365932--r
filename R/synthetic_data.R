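# Fully synthetic behavioral datasets: group-level parameter draws,
# model-implied RTs with Gaussian noise and range clipping, and Bernoulli
# accuracy labels, mirroring the statistical structure the fitting pipeline
# assumes so that simulation and fitting are inverse operations.

#' Specify a generating group for simulation
#'
#' Subjects' raw (unconstrained) parameter vectors are drawn independently
#' from `Normal(group_mean, group_sd^2)` per parameter.
#'
#' @param model_id Generating model id (1-9).
#' @param group_mean Raw-space group means (length = the model's parameter
#'   count).
#' @param group_sd Raw-space hierarchical spread (same length, all >= 0).
#' @param n_subjects Number of subjects.
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(model_id, group_mean, group_sd, n_subjects = 17L) {
  info <- model_info(model_id)
  group_mean <- rep_len(group_mean, info$n_params)
  group_sd <- rep_len(group_sd, info$n_params)
  stopifnot(all(group_sd >= 0), is_count(n_subjects))
  structure(list(model_id = info$model_id,
                 group_mean = stats::setNames(group_mean, info$param_names),
                 group_sd = stats::setNames(group_sd, info$param_names),
                 n_subjects = as.integer(n_subjects)),
            class = "group_spec")
}

#' Reference group parameters for the categorical model
#'
#' The package's default generating parameters for recovery studies: the
#' group-level estimates reported for the categorical model (Model 3) fitted
#' to the constant-probability experiment, with the hierarchical spread set
#' to the reported interval half-widths. The decay rate (natural value
#' 0.015 per distractor occurrence, half-width 0.005) is mapped to the raw
#' log scale by the delta method (`sd_raw = 0.005 / 0.015`).
#'
#' Raw-order parameters: `b_global` (log decay rate), then GLM betas in
#' seconds for intercept, global decay, categorical suppression, and
#' previous-trial-absent.
#'
#' @param n_subjects Number of simulated subjects (default 17).
#' @return A [group_spec()] for Model 3.
#' @export
#' @examples
#' default_group_spec()$group_mean
default_group_spec <- function(n_subjects = 17L) {
  group_spec(
    model_id = 3L,
    group_mean = c(b_global = log(0.015),
                   beta_intercept = 0.895,
                   beta_global_decay = 0.092,
                   beta_categorical = -0.040,
                   beta_prev_absent = -0.006),
    group_sd = c(b_global = 0.005 / 0.015,
                 beta_intercept = 0.062,
                 beta_global_decay = 0.012,
                 beta_categorical = 0.013,
                 beta_prev_absent = 0.0105),
    n_subjects = n_subjects)
}

#' Draw per-subject raw parameter vectors from a group specification
#'
#' @param spec A [group_spec()].
#' @param seed Integer seed (draws are deterministic given the seed).
#' @return A matrix (`n_subjects` x parameters) of raw parameter vectors.
#' @export
draw_subject_params <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "group_spec"))
  d <- length(spec$group_mean)
  with_seed(seed, {
    th <- matrix(stats::rnorm(spec$n_subjects * d,
                              mean = rep(spec$group_mean, each = spec$n_subjects),
                              sd = rep(spec$group_sd, each = spec$n_subjects)),
                 spec$n_subjects, d)
    colnames(th) <- names(spec$group_mean)
    th
  })
}

#' Simulate one subject's RTs from a model
#'
#' Builds the model's design matrix exactly as the fitting pipeline does
#' (same inclusion rules, same z-scoring over included trials), computes the
#' GLM mean for every distractor-present trial, adds Gaussian noise, and
#' clips the result to the 200-2000 ms response window. Accuracy labels are
#' drawn i.i.d. Bernoulli(`accuracy_rate`) unless a template vector is
#' supplied. Distractor-absent trials receive placeholder RTs from the
#' intercept (plus the global decay term where the model has one) with the
#' same noise; they never enter fitting.
#'
#' Because clipped RTs are never below 200 ms, the inclusion mask of the
#' simulated data equals the mask used during simulation, which makes
#' fitting the generating model to its own noise-free simulation an exact
#' round trip.
#'
#' @param model_id Generating model id (1-9).
#' @param params_raw Raw parameter vector for the subject.
#' @param seq A `trial_sequence`.
#' @param noise_sd_ms Gaussian RT noise SD in milliseconds.
#' @param accuracy_rate Probability of an accurate response per trial.
#' @param accuracy Optional 0/1 accuracy template (overrides
#'   `accuracy_rate`).
#' @param seed Integer seed.
#' @return A [subject_data()] object with `rt_ms` and `accuracy` filled for
#'   every trial.
#' @export
simulate_rts <- function(model_id, params_raw, seq, noise_sd_ms = 50,
                         accuracy_rate = 0.95, accuracy = NULL, seed = NULL) {
  stopifnot(noise_sd_ms >= 0, accuracy_rate >= 0, accuracy_rate <= 1)
  info <- model_info(model_id)
  stopifnot(length(params_raw) == info$n_params)
  n_trials <- nrow(seq)

  with_seed(seed, {
    acc <- accuracy %||% stats::rbinom(n_trials, 1L, accuracy_rate)
    pre <- precompute_model_data(model_id, seq, rt_ms = NULL, accuracy = acc)
    X <- design_matrix_core(pre, params_raw[seq_len(info$n_nonlinear)])
    # Block-opening present trials have undefined previous-trial dummies;
    # they are excluded from fitting, so simulate them at the dummy's
    # baseline (0).
    X[is.na(X)] <- 0
    betas <- params_raw[(info$n_nonlinear + 1L):info$n_params]
    mu_pres <- drop(X %*% betas)

    pres_idx <- which(seq$distractor_present == 1L)
    mu <- numeric(n_trials)
    b0 <- betas[match("beta_intercept", paste0("beta_", info$columns))]
    mu[] <- b0
    if (info$has_global_decay) {
      # practice decay carried onto absent trials at the level reached after
      # the preceding present trial, standardized with the included-trial
      # statistics used for the present-trial column
      b_global <- exp(params_raw[match("b_global", info$param_names)])
      decay_all <- exp(-b_global * cumsum(seq$distractor_present == 1L))
      g_raw <- exp(-b_global * (pre$pres_rank - 1))
      m <- mean(g_raw[pre$included])
      s <- stats::sd(g_raw[pre$included])
      bgd <- betas[match("beta_global_decay", paste0("beta_", info$columns))]
      if (is.finite(s) && s > 1e-12) {
        mu <- b0 + bgd * (decay_all - m) / s
      }
    }
    mu[pres_idx] <- mu_pres

    rt_s <- mu + stats::rnorm(n_trials, 0, noise_sd_ms / 1000)
    rt_ms <- pmin(pmax(rt_s * 1000, 200), 2000)
    subject_data(seq, rt_ms = rt_ms, accuracy = acc)
  })
}

#' Simulate a complete group dataset
#'
#' Draws per-subject parameters from a [group_spec()], generates a fresh
#' trial sequence per subject from `design`, and simulates RTs and accuracy
#' for each. With `noise = list(mode = "per_subject", sd_ms = c(...))`, each
#' subject is assigned one of the supplied noise SDs, sampled without
#' replacement.
#'
#' @param spec A [group_spec()].
#' @param design An [experiment_design()] used for every subject (each
#'   subject gets an independently seeded sequence).
#' @param noise Either a single noise SD in ms, or a list with `mode`
#'   (`"fixed"` or `"per_subject"`) and `sd_ms`.
#' @param accuracy_rate Bernoulli accuracy rate.
#' @param seed Integer seed controlling the whole dataset.
#' @return A list of class `simulated_dataset` with `subjects` (list of
#'   [subject_data()]), `generating_model`, `generating_params` (matrix),
#'   `noise_sd_ms` (per subject), and `seed`.
#' @export
simulate_group <- function(spec, design, noise = 50, accuracy_rate = 0.95,
                           seed = 1L) {
  stopifnot(inherits(spec, "group_spec"))
  if (is.list(noise)) {
    mode <- match.arg(noise$mode, c("fixed", "per_subject"))
    sds <- noise$sd_ms
  } else {
    mode <- "fixed"
    sds <- noise
  }
  stopifnot(all(sds > 0))

  seeds <- derive_seeds(seed, spec$n_subjects + 2L, salt = 3L)
  params <- draw_subject_params(spec, seed = seeds[1L])
  noise_per_subject <- if (mode == "per_subject") {
    if (length(sds) < spec$n_subjects) {
      stop("per_subject noise needs at least one SD per subject")
    }
    with_seed(seeds[2L], sample(sds, spec$n_subjects, replace = FALSE))
  } else {
    rep(sds[1L], spec$n_subjects)
  }

  subjects <- lapply(seq_len(spec$n_subjects), function(i) {
    des <- design
    des$seed <- seeds[2L + i]
    sq <- generate_sequence(des, sprintf("sim%02d", i))
    simulate_rts(spec$model_id, params[i, ], sq,
                 noise_sd_ms = noise_per_subject[i],
                 accuracy_rate = accuracy_rate,
                 seed = seeds[2L + i] + 1L)
  })

  structure(list(subjects = subjects,
                 generating_model = spec$model_id,
                 generating_params = params,
                 noise_sd_ms = noise_per_subject,
                 seed = seed),
            class = "simulated_dataset")
}
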