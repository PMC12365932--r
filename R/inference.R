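# Hierarchical random-effects model fitting and comparison.
#
# Per-subject parameters are MAP-estimated under normal priors in the raw
# (unconstrained) space; model evidence comes from a Laplace approximation.
# The hierarchical loop alternates (E) subject-level MAP fits and
# evidence-based responsibilities with (M) responsibility-weighted updates
# of each model's group mean/variance and of a Dirichlet over model
# frequencies, yielding exceedance probabilities, the Bayesian omnibus risk,
# and protected exceedance probabilities.

OBJECTIVE_FLOOR <- -1e20  # log-posterior floor for the nonlinear optimizer

#' Bundle one subject's data for fitting
#'
#' @param sequence A `trial_sequence`.
#' @param rt_ms Per-trial RT in milliseconds (NA allowed where missing).
#' @param accuracy Per-trial 0/1 accuracy.
#' @return An object of class `subject_data`.
#' @export
subject_data <- function(sequence, rt_ms, accuracy) {
  stopifnot(nrow(sequence) == length(rt_ms),
            nrow(sequence) == length(accuracy))
  if (any(rt_ms > 2000, na.rm = TRUE)) {
    stop("RTs above the 2000 ms response deadline are not valid")
  }
  structure(list(sequence = sequence, rt_ms = rt_ms, accuracy = accuracy),
            class = "subject_data")
}

# Negative log posterior of the raw parameter vector for one subject.
# `pre` comes from precompute_model_data() with RT/accuracy applied. This is
# the optimizer's hot path: the GLM mean is assembled directly from the
# precomputed included-row regressor ingredients, no matrices allocated.
neg_log_posterior <- function(raw, pre, prior_mean, prior_var) {
  info <- pre$info
  ft <- pre$fit
  betas <- raw[(info$n_nonlinear + 1L):info$n_params]
  j <- 1L
  mu <- rep(betas[j], ft$n)  # intercept is always the first column
  for (cn in info$columns[-1L]) {
    j <- j + 1L
    col <- switch(cn,
      global_decay = zscore_all(exp(-exp(raw[[1L]]) * ft$rank0)),
      distractor_prediction = {
        if (info$mechanism == "accumulator") {
          k <- match("b_distractor", info$param_names)
          zscore_all(1 - exp(-exp(raw[[k]]) * ft$counts))
        } else {
          k <- match("alpha", info$param_names)
          p <- rl_pred_core(pre$loc, pre$segment, logistic(raw[[k]]))
          zscore_all(p[ft$ik])
        }
      },
      categorical = ft$categorical,
      prev_absent = ft$prev_absent,
      repetition = ft$repetition)
    mu <- mu + betas[j] * col
  }
  rss <- sum((ft$y - mu)^2)
  if (!is.finite(rss) || rss <= 0) return(-OBJECTIVE_FLOOR)
  n <- ft$n
  ll <- -(n / 2) * (1 + log(2 * pi)) - (n / 2) * log(rss / n)
  lp <- ll - 0.5 * sum((raw - prior_mean)^2 / prior_var) -
    0.5 * sum(log(2 * pi * prior_var))
  if (!is.finite(lp) || lp < OBJECTIVE_FLOOR) lp <- OBJECTIVE_FLOOR
  -lp
}

# Log-determinant via Cholesky with progressive ridge regularization; used
# on the Laplace Hessian, which can be near-singular (or, away from a clean
# optimum, indefinite) for weakly identified parameters. If ridging fails,
# eigenvalues are clamped to a positive floor, which always succeeds.
safe_logdet <- function(H) {
  d <- nrow(H)
  ridge <- 0
  for (k in 0:6) {
    ch <- tryCatch(chol(H + diag(ridge, d)), error = function(e) NULL)
    if (!is.null(ch)) {
      return(list(logdet = 2 * sum(log(diag(ch))),
                  inv = chol2inv(ch), regularized = ridge > 0))
    }
    ridge <- if (ridge == 0) 1e-6 else ridge * 10
  }
  ev <- eigen(H, symmetric = TRUE)
  lam <- pmax(ev$values, max(1e-6, 1e-8 * max(abs(ev$values))))
  list(logdet = sum(log(lam)),
       inv = ev$vectors %*% (t(ev$vectors) / lam),
       regularized = TRUE)
}

#' MAP estimate and Laplace evidence for one subject under one model
#'
#' Maximizes the data log-likelihood plus a normal log-prior over the raw
#' parameter space with multi-start BFGS (one start at the prior mean, the
#' rest drawn from the prior), then computes the Laplace approximation to
#' the log model evidence:
#' `log p(y) ~ log p(y, theta_MAP) + (d/2) log 2*pi - (1/2) log det H`,
#' where `H` is the Hessian of the negative log posterior at the MAP.
#'
#' @param model_id Integer 1-9.
#' @param data A [subject_data()] object.
#' @param prior_mean,prior_var Raw-space prior mean and variance vectors
#'   (recycled to the model's parameter count). Defaults: mean 0,
#'   variance 6.25.
#' @param n_starts Number of optimizer starts.
#' @param start Optional extra warm-start vector (e.g. a previous MAP).
#' @param seed Seed for the prior draws.
#' @return A list with `raw` (MAP estimate), `log_evidence`, `log_posterior`,
#'   `hessian`, `posterior_cov`, `converged`, and `model_id`.
#' @export
fit_subject_map <- function(model_id, data, prior_mean = 0, prior_var = 6.25,
                            n_starts = 8L, start = NULL, seed = NULL) {
  pre <- precompute_model_data(model_id, data$sequence, data$rt_ms,
                               data$accuracy)
  fit_subject_map_pre(pre, prior_mean, prior_var, n_starts, start, seed)
}

# Workhorse operating on precomputed subject data (reused across the
# hierarchical iterations without rebuilding state machines).
#
# `hess_cache` may carry a previous fit's data-likelihood Hessian (the full
# Hessian minus its diagonal prior contribution). If the MAP moved less
# than `hess_tol` in any coordinate, that data Hessian is reused and only
# the (exact, diagonal) prior term is refreshed — the numerical Hessian is
# by far the costliest part of a warm-started sweep.
fit_subject_map_pre <- function(pre, prior_mean, prior_var,
                                n_starts = 8L, start = NULL, seed = NULL,
                                hess_cache = NULL, hess_tol = 5e-4) {
  info <- pre$info
  d <- info$n_params
  if (sum(pre$included) < length(info$columns) + 2L) {
    stop("degenerate fit: too few included trials")
  }
  prior_mean <- rep_len(prior_mean, d)
  prior_var <- rep_len(prior_var, d)
  fn <- function(p) neg_log_posterior(p, pre, prior_mean, prior_var)

  starts <- with_seed(seed, {
    s <- if (n_starts >= 1) list(prior_mean) else list()
    if (n_starts > 1) {
      for (k in seq_len(n_starts - 1L)) {
        s[[k + 1L]] <- stats::rnorm(d, prior_mean, sqrt(prior_var))
      }
    }
    s
  })
  if (!is.null(start)) starts <- c(list(unname(start)), starts)
  if (length(starts) == 0) starts <- list(prior_mean)

  best <- NULL
  any_conv <- FALSE
  for (s0 in starts) {
    opt <- tryCatch(
      stats::optim(s0, fn, method = "BFGS",
                   control = list(maxit = 300, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (opt$convergence == 0) any_conv <- TRUE
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all optimizer starts failed")
  if (!any_conv) {
    warning("optimizer did not report convergence from any start; ",
            "returning the best value found")
  }

  H_data <- NULL
  if (!is.null(hess_cache) &&
      max(abs(best$par - hess_cache$par)) < hess_tol) {
    H_data <- hess_cache$H_data
  }
  if (is.null(H_data)) {
    H <- tryCatch(stats::optimHess(best$par, fn), error = function(e) NULL)
    if (is.null(H)) H <- diag(1 / prior_var, d)
    H <- (H + t(H)) / 2
    H_data <- H - diag(1 / prior_var, d)
  }
  H <- H_data + diag(1 / prior_var, d)
  ld <- safe_logdet(H)
  if (ld$regularized) {
    warning("singular Hessian regularized when computing the Laplace evidence")
  }
  logpost <- -best$value
  list(raw = stats::setNames(best$par, info$param_names),
       log_evidence = logpost + (d / 2) * log(2 * pi) - 0.5 * ld$logdet,
       log_posterior = logpost,
       hessian = H,
       H_data = H_data,
       par = best$par,
       posterior_cov = ld$inv,
       converged = any_conv,
       model_id = info$model_id)
}

#' Dirichlet exceedance probabilities
#'
#' Probability that each model is the most frequent in the population given
#' Dirichlet pseudo-counts over model frequencies. For two models the Beta
#' tail probability is exact; otherwise (and by request) a Monte Carlo
#' estimate over Dirichlet draws is used.
#'
#' @param counts Dirichlet pseudo-counts (length K).
#' @param n_samples Monte Carlo sample size.
#' @param method `"auto"` (closed form when K = 2), `"mc"`, or `"beta"`.
#' @param seed Seed for the Monte Carlo draws.
#' @return Exceedance probability vector summing to 1.
#' @export
exceedance_prob <- function(counts, n_samples = 1e6,
                            method = c("auto", "mc", "beta"), seed = NULL) {
  method <- match.arg(method)
  K <- length(counts)
  if (K == 1) return(1)
  if (method == "beta" || (method == "auto" && K == 2)) {
    if (K != 2) stop("the Beta closed form applies only to two models")
    xp1 <- 1 - stats::pbeta(0.5, counts[1], counts[2])
    return(c(xp1, 1 - xp1))
  }
  with_seed(seed, {
    g <- matrix(stats::rgamma(n_samples * K, shape = rep(counts, each = n_samples)),
                n_samples, K)
    win <- max.col(g, ties.method = "first")
    as.numeric(tabulate(win, K)) / n_samples
  })
}

#' Protected exceedance probabilities
#'
#' Blends exceedance probabilities with the uniform distribution according
#' to the Bayesian omnibus risk `bor` (the probability that model
#' frequencies are indistinguishable):
#' `pxp_k = xp_k * (1 - bor) + bor / K`.
#'
#' @param dirichlet_counts Dirichlet pseudo-counts over models.
#' @param bor Bayesian omnibus risk in `[0, 1]`.
#' @param xp Optional precomputed exceedance probabilities (skips the
#'   Dirichlet computation).
#' @param ... Passed to [exceedance_prob()].
#' @return Protected exceedance probability vector summing to 1.
#' @export
protected_exceedance <- function(dirichlet_counts, bor, xp = NULL, ...) {
  stopifnot(bor >= 0, bor <= 1)
  if (is.null(xp)) xp <- exceedance_prob(dirichlet_counts, ...)
  K <- length(xp)
  xp * (1 - bor) + bor / K
}

# Bayesian omnibus risk: compare the variational free energy of the fitted
# Dirichlet frequency model (F1) with the exact log evidence of the null in
# which every model is equally frequent (F0). bor = 1/(1 + exp(F1 - F0)).
compute_bor <- function(L, r, alpha, alpha0) {
  K <- ncol(L)
  dg <- digamma(alpha) - digamma(sum(alpha))
  r_safe <- pmax(r, 1e-12)
  F1 <- sum(r * L) + sum(r * rep(dg, each = nrow(L))) -
    sum(r * log(r_safe)) +
    (lgamma(sum(alpha0)) - sum(lgamma(alpha0)) + sum((alpha0 - 1) * dg)) -
    (lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * dg))
  F0 <- sum(apply(L, 1, function(x) logsumexp(x - log(K))))
  1 / (1 + exp(F1 - F0))
}

#' Hierarchical random-effects fitting and comparison of candidate models
#'
#' Iterates subject-level MAP fits under the current group priors (E-step)
#' with responsibility-weighted updates of the group-level normal
#' distributions and the Dirichlet over model frequencies (M-step) until the
#' summed data log evidence changes by less than `tol` or `max_iterations`
#' is reached. Responsibilities are evidence-weighted posterior model
#' assignments; each model's group mean/variance is updated from the
#' responsibility-weighted first and second moments of the subject MAPs
#' (including their Laplace posterior variances).
#'
#' After the first sweep, subject fits warm-start from the previous MAP
#' (plus fresh prior draws), which keeps later sweeps cheap.
#'
#' @param model_ids Candidate model ids (subset of 1-9).
#' @param subjects List of [subject_data()] objects (at least 2).
#' @param max_iterations Iteration cap.
#' @param tol Convergence tolerance on the summed log evidence.
#' @param n_starts Optimizer starts for first-sweep subject fits.
#' @param warm_starts Optimizer starts for later sweeps (in addition to the
#'   previous MAP).
#' @param prior_mean,prior_var Initial raw-space prior (defaults 0 / 6.25).
#' @param mc_samples Monte Carlo sample size for exceedance probabilities.
#' @param seed Seed controlling optimizer restarts and Monte Carlo draws.
#' @param verbose Print per-iteration progress?
#' @return An object of class `hbi_fit`: a list with `models` (per-model
#'   group posterior: `group_mean`, `group_variance`, `hierarchical_error`,
#'   `subject_map`, `model_frequency`, `responsibility_sum`, `dof`),
#'   `responsibilities`, `dirichlet_counts`, `exceedance`, `bor`, `pxp`,
#'   `converged`, and `n_iterations`.
#' @export
fit_hierarchical <- function(model_ids, subjects,
                             max_iterations = 50L, tol = 1e-4,
                             n_starts = 8L, warm_starts = 1L,
                             prior_mean = 0, prior_var = 6.25,
                             mc_samples = 1e6, seed = NULL,
                             verbose = FALSE) {
  stopifnot(length(subjects) >= 2, length(model_ids) >= 1)
  N <- length(subjects)
  K <- length(model_ids)
  infos <- lapply(model_ids, model_info)
  dims <- vapply(infos, `[[`, integer(1), "n_params")

  # parameter-free state machines computed once per subject x model
  pres <- lapply(seq_len(N), function(n) {
    lapply(seq_len(K), function(k) {
      precompute_model_data(model_ids[k], subjects[[n]]$sequence,
                            subjects[[n]]$rt_ms, subjects[[n]]$accuracy)
    })
  })

  mu <- lapply(dims, function(d) rep_len(prior_mean, d))
  v <- lapply(dims, function(d) rep_len(prior_var, d))
  alpha0 <- rep(1, K)
  alpha <- alpha0
  theta <- vector("list", K)
  for (k in seq_len(K)) theta[[k]] <- vector("list", N)

  seeds <- if (is.null(seed)) rep(list(NULL), max_iterations) else
    as.list(derive_seeds(seed, max_iterations, salt = 7L))
  L <- matrix(NA_real_, N, K)
  pvar <- array(NA_real_, c(N, K, max(dims)))
  prev_evidence <- -Inf
  converged <- FALSE
  n_iter <- 0L

  for (it in seq_len(max_iterations)) {
    n_iter <- it
    it_seeds <- if (is.null(seeds[[it]])) rep(list(NULL), N * K) else
      as.list(derive_seeds(seeds[[it]], N * K))
    for (n in seq_len(N)) {
      for (k in seq_len(K)) {
        fit <- fit_subject_map_pre(
          pres[[n]][[k]], mu[[k]], v[[k]],
          n_starts = if (it == 1L) n_starts else warm_starts,
          start = if (it == 1L) NULL else theta[[k]][[n]]$raw,
          seed = it_seeds[[(n - 1L) * K + k]],
          hess_cache = if (it == 1L) NULL else theta[[k]][[n]])
        theta[[k]][[n]] <- fit
        L[n, k] <- fit$log_evidence
        pvar[n, k, seq_len(dims[k])] <- diag(fit$posterior_cov)
      }
    }

    # responsibilities: softmax of log evidence + E[log model frequency]
    dg <- digamma(alpha) - digamma(sum(alpha))
    r <- t(apply(L, 1, function(x) {
      w <- x + dg
      exp(w - logsumexp(w))
    }))
    if (K == 1) r <- matrix(1, N, 1)

    alpha <- alpha0 + colSums(r)

    for (k in seq_len(K)) {
      Rk <- sum(r[, k])
      th <- do.call(rbind, lapply(theta[[k]], `[[`, "raw"))
      if (Rk > 1e-8) {
        mu[[k]] <- colSums(r[, k] * th) / Rk
        pv <- pvar[, k, seq_len(dims[k]), drop = FALSE]
        dim(pv) <- c(N, dims[k])
        second <- colSums(r[, k] * (sweep(th, 2, mu[[k]])^2 + pv)) / Rk
        v[[k]] <- pmax(second, 1e-6)
      }
    }

    evidence <- sum(vapply(seq_len(N),
                           function(n) logsumexp(L[n, ] + dg), numeric(1)))
    if (verbose) {
      message(sprintf("iteration %d: summed log evidence %.6f", it, evidence))
    }
    if (is.finite(prev_evidence) && abs(evidence - prev_evidence) < tol) {
      converged <- TRUE
      break
    }
    prev_evidence <- evidence
  }

  bor <- compute_bor(L, r, alpha, alpha0)
  xp <- exceedance_prob(alpha, n_samples = mc_samples,
                        seed = if (is.null(seed)) NULL else seed + 13L)
  pxp <- if (K == 1) 1 else protected_exceedance(alpha, bor, xp = xp)

  models <- lapply(seq_len(K), function(k) {
    Rk <- sum(r[, k])
    list(model_id = model_ids[k],
         info = infos[[k]],
         group_mean = stats::setNames(mu[[k]], infos[[k]]$param_names),
         group_variance = stats::setNames(v[[k]], infos[[k]]$param_names),
         hierarchical_error = stats::setNames(sqrt(v[[k]] / (Rk + 1)),
                                              infos[[k]]$param_names),
         subject_map = do.call(rbind, lapply(theta[[k]], `[[`, "raw")),
         subject_evidence = L[, k],
         model_frequency = alpha[k] / sum(alpha),
         responsibility_sum = Rk,
         dof = Rk + 1)
  })
  names(models) <- paste0("model_", model_ids)

  structure(list(model_ids = model_ids,
                 models = models,
                 responsibilities = r,
                 dirichlet_counts = alpha,
                 model_frequency = alpha / sum(alpha),
                 exceedance = xp,
                 bor = bor,
                 pxp = pxp,
                 converged = converged,
                 n_iterations = n_iter),
            class = "hbi_fit")
}

#' @export
print.hbi_fit <- function(x, ...) {
  cat("Hierarchical model comparison (", length(x$model_ids), " models, ",
      nrow(x$responsibilities), " subjects)\n", sep = "")
  tab <- data.frame(model = x$model_ids,
                    frequency = round(x$model_frequency, 3),
                    exceedance = round(x$exceedance, 3),
                    pxp = round(x$pxp, 3))
  print(tab, row.names = FALSE)
  cat(sprintf("bor = %.4g; %sconverged in %d iterations\n", x$bor,
              if (x$converged) "" else "NOT ", x$n_iterations))
  invisible(x)
}

#' Hierarchical t-test on a group-level parameter
#'
#' Tests whether a group parameter differs from zero using the hierarchical
#' error (the group-level uncertainty of the mean) as the denominator. The
#' degrees of freedom are supplied by the fitting procedure (possibly
#' non-integer); in this package they equal the model's summed
#' responsibility plus one.
#'
#' @param group_mean Group-level parameter estimate.
#' @param hierarchical_error Positive hierarchical error.
#' @param dof Degrees of freedom.
#' @return A list with `t` and two-sided `p`.
#' @export
#' @examples
#' hbi_ttest(0.092, 0.0123, 18)  # t ~ 7.48
hbi_ttest <- function(group_mean, hierarchical_error, dof) {
  stopifnot(hierarchical_error > 0, dof > 0)
  t <- group_mean / hierarchical_error
  list(t = t, p = 2 * stats::pt(-abs(t), df = dof))
}
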