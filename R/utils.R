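# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

qc_stop <- function(class, ...) {
  stop(errorCondition(paste0(...), class = c(class, "qcmatch_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Pooled (average-of-variances) standard deviation of two samples.
pooled_sd <- function(x, y) sqrt((stats::var(x) + stats::var(y)) / 2)
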