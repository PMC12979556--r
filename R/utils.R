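## Internal helpers: seeded evaluation, logging, argument checks.

# Evaluate `expr` under `seed` and restore the caller's RNG state afterwards,
# so generators are pure functions of (parameters, seed).
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("`seed` must be a single finite integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream index, kept below 2^31.
childSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1000003 + stream * 7919) %% 2147483629) + 1L
}

# One stage log line to stderr: stage, key=value details, elapsed seconds.
logStage <- function(stage, ..., t0 = NULL) {
  kv <- list(...)
  det <- if (length(kv))
    paste(names(kv), vapply(kv, function(v) paste(format(v), collapse = ","),
                            character(1)), sep = "=", collapse = " ")
  else ""
  el <- if (!is.null(t0))
    sprintf(" elapsed=%.2fs", as.numeric(proc.time()[["elapsed"]]) - t0)
  else ""
  message(sprintf("[nichescape] %s %s%s", stage, det, el))
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Positive scalar check used across constructors.
checkPositiveScalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  invisible(x)
}

# Pairwise Euclidean cross distances between two coordinate matrices,
# returned as an n_i x n_j matrix.
crossDist <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(pmax(d2, 0))
}
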