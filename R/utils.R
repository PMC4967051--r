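# Condition helpers: input errors exit with status 2 from the CLI,
# numerical failures with status 3.

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("fm_input_error", "error")))
}

stop_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("fm_numeric_error", "error")))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}
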