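# Internal numerics and seeding helpers shared across modules.

#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix, vectorised across rows.
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  m + log(rowSums(exp(x - m)))
}

# Counter-based derivation of child seeds from a root seed.  Each consumer
# passes a distinct integer counter; the stream therefore does not depend on
# the order in which other consumers draw, keeping cohorts and CV conditions
# independent of one another.  Result stays below 2^31 - 1.
derive_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483629  # largest prime below 2^31
  s <- (abs(seed) %% m)
  for (c in as.numeric(counter)) {
    s <- (s * 48271 + (abs(c) %% m) + 1) %% m
  }
  as.integer(s)
}

# Run an expression under a local RNG state so package internals never
# disturb the caller's .Random.seed.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("mieeg_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
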