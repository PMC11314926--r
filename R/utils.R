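#' @keywords internal
"_PACKAGE"

# Seeds drawn on [0, 2^32 - 1] (doubles) must be folded into the range
# set.seed() accepts before use.
fold_seed <- function(seed) {
  as.integer(abs(as.numeric(seed)) %% 2147483647)
}

# Evaluate `expr` under a private RNG stream started at `seed`, restoring the
# caller's RNG state afterwards so library code never perturbs user sessions.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(fold_seed(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
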