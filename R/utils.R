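# Internal helpers shared across modules.

#' Run code under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `expr`, and restores the caller's RNG state,
#' so seeded package functions never disturb the global random stream.
#' A `NULL` seed evaluates `expr` under the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-subject seed derived from a design seed and a subject id.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
subject_seed <- function(base_seed, subject_id) {
  codes <- utf8ToInt(as.character(subject_id))
  h <- sum(codes * seq_along(codes)) %% 100003L
  (as.integer(base_seed) %% 20000000L) * 100L + as.integer(h) %% 100L + h
}

# Derive a stream of child seeds from one master seed.
derive_seeds <- function(seed, n, salt = 0L) {
  (as.integer(seed) %% 1000000L) * 1000L + salt * 101L + seq_len(n)
}

logistic <- function(x) 1 / (1 + exp(-x))

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x) && x >= 1
}

# Nearly-integral check used when probability x count products must be whole.
near_integer <- function(x, tol = 1e-8) abs(x - round(x)) < tol
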