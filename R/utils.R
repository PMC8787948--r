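# Internal helpers shared across modules.

# Deterministic child-seed derivation: every stochastic stage takes one root
# seed and derives its own stream offset, so a single --seed reproduces a run.
# Kept strictly below .Machine$integer.max.
.deriveSeed <- function(root, offset) {
  as.integer((as.numeric(root) * 7919 + as.numeric(offset) * 104729) %% 2147483629L)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

.assertCount <- function(x, name, minimum = 0L) {
  .assertScalarNumber(x, name, lower = minimum)
  if (x != as.integer(x)) stop(sprintf("'%s' must be an integer count", name),
                               call. = FALSE)
  invisible(as.integer(x))
}

# Stage-granular logging; suppressed when options(hmcfrag.quiet = TRUE).
.logMsg <- function(fmt, ...) {
  if (!isTRUE(getOption("hmcfrag.quiet", FALSE))) {
    message(sprintf(fmt, ...))
  }
  invisible(NULL)
}
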