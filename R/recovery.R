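# Model-recovery experiments: simulate group datasets from each generating
# model, refit the full candidate set hierarchically, and tabulate which
# model wins the comparison (highest exceedance probability).

#' Configure a model-recovery experiment
#'
#' @param generating_models Model ids to generate data from.
#' @param candidate_models Model ids entered into every comparison; must
#'   include each generating model.
#' @param group_specs Named list of [group_spec()] objects, one per
#'   generating model (names `"model_<id>"`), or a single spec when only one
#'   generating model is used.
#' @param design The [experiment_design()] simulated subjects perform.
#' @param n_simulations Simulated datasets per generating model.
#' @param noise Noise specification as in [simulate_group()].
#' @param accuracy_rate Bernoulli accuracy rate for simulated subjects.
#' @param max_hbi_iterations Iteration cap for each hierarchical fit
#'   (default 50).
#' @param tol Convergence tolerance for each hierarchical fit.
#' @param n_starts,warm_starts Optimizer start counts per subject fit.
#' @param mc_samples Monte Carlo draws for exceedance probabilities.
#' @param seed Master seed; every simulation derives its own seed from it.
#' @return A `recovery_config` list.
#' @export
recovery_config <- function(generating_models, candidate_models, group_specs,
                            design, n_simulations = 10L, noise = 50,
                            accuracy_rate = 0.95,
                            max_hbi_iterations = 50L, tol = 1e-4,
                            n_starts = 2L, warm_starts = 0L,
                            mc_samples = 1e6, seed = 1L) {
  stopifnot(n_simulations >= 1)
  if (!all(generating_models %in% candidate_models)) {
    stop("candidate_models must include every generating model")
  }
  if (inherits(group_specs, "group_spec")) {
    group_specs <- stats::setNames(list(group_specs),
                                   paste0("model_", group_specs$model_id))
  }
  for (g in generating_models) {
    key <- paste0("model_", g)
    if (is.null(group_specs[[key]])) {
      stop("no group_spec supplied for generating model ", g)
    }
    if (group_specs[[key]]$model_id != g) {
      stop("group_spec ", key, " is for model ", group_specs[[key]]$model_id)
    }
  }
  structure(list(generating_models = as.integer(generating_models),
                 candidate_models = as.integer(candidate_models),
                 group_specs = group_specs, design = design,
                 n_simulations = as.integer(n_simulations), noise = noise,
                 accuracy_rate = accuracy_rate,
                 max_hbi_iterations = as.integer(max_hbi_iterations),
                 tol = tol, n_starts = n_starts, warm_starts = warm_starts,
                 mc_samples = mc_samples, seed = as.integer(seed)),
            class = "recovery_config")
}

#' Run a model-recovery experiment
#'
#' For each generating model and simulation index: draw subject parameters,
#' simulate a group dataset, fit all candidate models hierarchically, and
#' record the winner as the model with the highest exceedance probability.
#' Exactly tied exceedance probabilities (degenerate) break to the lowest
#' model id with a warning. Non-convergent fits are recorded and still
#' scored.
#'
#' @param config A [recovery_config()].
#' @param verbose Print progress per simulation?
#' @return An object of class `confusion_matrix`: a list with `counts`
#'   (generating x winning model), `proportions` (row-normalized), and
#'   `details` (one row per simulation: generating model, winner, exceedance
#'   of the winner, bor, convergence flag, seed).
#' @export
run_recovery <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "recovery_config"))
  gen <- config$generating_models
  cand <- config$candidate_models
  counts <- matrix(0L, length(gen), length(cand),
                   dimnames = list(paste0("gen_", gen), paste0("win_", cand)))
  details <- list()

  for (gi in seq_along(gen)) {
    g <- gen[gi]
    sim_seeds <- derive_seeds(config$seed, config$n_simulations, salt = gi)
    for (s in seq_len(config$n_simulations)) {
      ds <- simulate_group(config$group_specs[[paste0("model_", g)]],
                           config$design, noise = config$noise,
                           accuracy_rate = config$accuracy_rate,
                           seed = sim_seeds[s])
      fit <- fit_hierarchical(cand, ds$subjects,
                              max_iterations = config$max_hbi_iterations,
                              tol = config$tol,
                              n_starts = config$n_starts,
                              warm_starts = config$warm_starts,
                              mc_samples = config$mc_samples,
                              seed = sim_seeds[s] + 1L)
      xp <- fit$exceedance
      top <- which(xp == max(xp))
      if (length(top) > 1L) {
        warning("tied exceedance probabilities; breaking to the lowest model id")
        top <- top[which.min(cand[top])]
      }
      winner <- cand[top[1L]]
      counts[gi, match(winner, cand)] <- counts[gi, match(winner, cand)] + 1L
      details[[length(details) + 1L]] <- data.frame(
        generating_model = g, simulation = s, winning_model = winner,
        winner_exceedance = max(xp), bor = fit$bor,
        converged = fit$converged, seed = sim_seeds[s])
      if (verbose) {
        message(sprintf("generating model %d, simulation %d: winner model %d",
                        g, s, winner))
      }
    }
  }

  structure(list(counts = counts,
                 proportions = counts / rowSums(counts),
                 generating_models = gen,
                 candidate_models = cand,
                 n_simulations = config$n_simulations,
                 details = do.call(rbind, details)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Model recovery confusion matrix (proportions, rows = generating)\n")
  print(round(x$proportions, 3))
  invisible(x)
}

#' Tidy long-format summary of a confusion matrix
#'
#' @param cm A `confusion_matrix` from [run_recovery()].
#' @return A data.frame with one row per generating x winning model pair and
#'   columns `generating_model`, `winning_model`, `count`, `proportion`.
#' @export
summarize_recovery <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  grid <- expand.grid(winning_model = cm$candidate_models,
                      generating_model = cm$generating_models)
  data.frame(generating_model = grid$generating_model,
             winning_model = grid$winning_model,
             count = as.integer(t(cm$counts)),
             proportion = as.numeric(t(cm$proportions)))
}
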