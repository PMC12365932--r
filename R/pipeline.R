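# Configuration handling and the end-to-end pipeline:
# design -> simulate -> fit -> compare -> recover -> summarize.
# JSON holds configuration and fit results; CSV holds tabular data. One
# global seed deterministically derives every stage seed.

#' Read and write experiment-design JSON
#'
#' The JSON mirrors the [experiment_design()] fields.
#'
#' @param path File path.
#' @param design An `experiment_design`.
#' @return `read_design_json` returns an `experiment_design`;
#'   `write_design_json` the path, invisibly.
#' @export
read_design_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  experiment_design(
    n_blocks = x$n_blocks,
    trials_per_block = x$trials_per_block,
    p_present = x$p_present %||% 0.5,
    p_high_given_present = x$p_high_given_present %||% (2 / 3),
    schedule = x$schedule %||% "constant",
    change_interval_trials = x$change_interval_trials,
    hp_location = x$hp_location %||% 0L,
    lp_target_mapping = x$lp_target_mapping %||% "predefined",
    seed = x$seed %||% 1L)
}

#' @rdname read_design_json
#' @export
write_design_json <- function(design, path) {
  jsonlite::write_json(design[!vapply(design, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write group-parameter JSON
#'
#' Schema: `{"model_id": , "group_mean": [...], "group_sd": [...],
#' "n_subjects": }` (raw-space values).
#'
#' @param path File path.
#' @param spec A [group_spec()].
#' @return `read_group_spec_json` returns a `group_spec`.
#' @export
read_group_spec_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  group_spec(x$model_id, x$group_mean, x$group_sd,
             x$n_subjects %||% 17L)
}

#' @rdname read_group_spec_json
#' @export
write_group_spec_json <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Serialize an hbi_fit to plain lists for JSON output.
hbi_fit_to_list <- function(fit) {
  list(model_ids = fit$model_ids,
       models = lapply(fit$models, function(m) {
         list(model_id = m$model_id,
              group_mean = as.list(m$group_mean),
              group_variance = as.list(m$group_variance),
              hierarchical_error = as.list(m$hierarchical_error),
              subject_map = unname(apply(m$subject_map, 1, as.list)),
              model_frequency = m$model_frequency,
              responsibility_sum = m$responsibility_sum,
              dof = m$dof)
       }),
       responsibilities = unname(apply(fit$responsibilities, 1, as.list)),
       dirichlet_counts = fit$dirichlet_counts,
       model_frequency = fit$model_frequency,
       exceedance = fit$exceedance,
       bor = fit$bor,
       pxp = fit$pxp,
       converged = fit$converged,
       n_iterations = fit$n_iterations)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes every stage end to end with no external data: generates trial
#' sequences from the configured design, simulates a group dataset from the
#' configured generating model, fits and compares the candidate models
#' hierarchically, runs a model-recovery experiment, and writes behavioral
#' summaries — all into `out_dir`, stamped with the seed.
#'
#' @param config A list (or path to a JSON file) with elements `design`
#'   (design fields), `group_spec` (generating group fields), `models`
#'   (candidate model ids), `noise_sd_ms`, `accuracy_rate`, and `recovery`
#'   (`n_simulations`, `max_hbi_iterations`, optional `generating_models`).
#'   Missing elements fall back to package defaults. Set `recovery` to
#'   `FALSE` to skip the recovery stage.
#' @param out_dir Output directory (created if needed).
#' @param seed Global seed; all stage seeds derive from it.
#' @param verbose Print stage progress?
#' @return Invisibly, a list with the in-memory stage outputs (`dataset`,
#'   `fit`, `recovery`, `summaries`) and `files` (paths written).
#' @export
run_pipeline <- function(config = list(), out_dir = tempdir(), seed = 1L,
                         verbose = TRUE) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage_seeds <- derive_seeds(seed, 4L, salt = 11L)
  files <- character()

  design <- if (is.null(config$design)) exp1_design(seed = stage_seeds[1]) else {
    d <- config$design
    experiment_design(
      n_blocks = d$n_blocks, trials_per_block = d$trials_per_block,
      p_present = d$p_present %||% 0.5,
      p_high_given_present = d$p_high_given_present %||% (2 / 3),
      schedule = d$schedule %||% "constant",
      change_interval_trials = d$change_interval_trials,
      hp_location = d$hp_location %||% 0L,
      lp_target_mapping = d$lp_target_mapping %||% "predefined",
      seed = stage_seeds[1])
  }

  spec <- if (is.null(config$group_spec)) default_group_spec() else {
    g <- config$group_spec
    group_spec(g$model_id, g$group_mean, g$group_sd, g$n_subjects %||% 17L)
  }
  models <- as.integer(config$models %||% c(1L, 2L, 3L, 7L))
  if (!all(models %in% 1:9)) {
    stop("unknown model id in config$models: ",
         paste(setdiff(models, 1:9), collapse = ", "))
  }

  say("stage 1/4: simulating %d subjects from model %d",
      spec$n_subjects, spec$model_id)
  t0 <- Sys.time()
  dataset <- simulate_group(spec, design,
                            noise = config$noise_sd_ms %||% 50,
                            accuracy_rate = config$accuracy_rate %||% 0.95,
                            seed = stage_seeds[2])
  trials <- do.call(rbind, lapply(dataset$subjects, function(s) {
    out <- s$sequence
    out$rt_ms <- s$rt_ms
    out$accuracy <- s$accuracy
    out
  }))
  f <- file.path(out_dir, "trials.csv")
  utils::write.csv(trials, f, row.names = FALSE, na = "")
  files <- c(files, f)

  say("stage 2/4: hierarchical fit of models %s",
      paste(models, collapse = ", "))
  fit <- fit_hierarchical(models, dataset$subjects,
                          max_iterations = config$max_hbi_iterations %||% 50L,
                          tol = config$tol %||% 1e-4,
                          n_starts = config$n_starts %||% 2L,
                          seed = stage_seeds[3])
  f <- file.path(out_dir, "fit.json")
  jsonlite::write_json(c(hbi_fit_to_list(fit), list(seed = seed)), f,
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, f)

  recovery <- NULL
  if (!isFALSE(config$recovery)) {
    rc <- if (is.list(config$recovery)) config$recovery else list()
    say("stage 3/4: model recovery (%d simulations)",
        rc$n_simulations %||% 2L)
    cfg <- recovery_config(
      generating_models = as.integer(rc$generating_models %||% spec$model_id),
      candidate_models = models,
      group_specs = stats::setNames(list(spec),
                                    paste0("model_", spec$model_id)),
      design = design,
      n_simulations = rc$n_simulations %||% 2L,
      noise = config$noise_sd_ms %||% 50,
      accuracy_rate = config$accuracy_rate %||% 0.95,
      max_hbi_iterations = rc$max_hbi_iterations %||% 50L,
      seed = stage_seeds[4])
    recovery <- run_recovery(cfg, verbose = verbose)
    f <- file.path(out_dir, "confusion.csv")
    utils::write.csv(summarize_recovery(recovery), f, row.names = FALSE)
    files <- c(files, f)
  } else {
    say("stage 3/4: recovery skipped by config")
  }

  say("stage 4/4: behavioral summaries")
  summaries <- do.call(rbind, lapply(seq_along(dataset$subjects), function(i) {
    cm <- condition_means(dataset$subjects[[i]])$rt
    cm$subject <- i
    cm
  }))
  f <- file.path(out_dir, "condition_means.csv")
  utils::write.csv(summaries, f, row.names = FALSE)
  files <- c(files, f)

  say("pipeline complete in %.1f s (seed %d)",
      as.numeric(difftime(Sys.time(), t0, units = "secs")), seed)
  invisible(list(dataset = dataset, fit = fit, recovery = recovery,
                 summaries = summaries, files = files, seed = seed))
}
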