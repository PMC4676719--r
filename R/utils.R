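# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad_arg <- function(...) stop(sprintf(...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop_bad_arg("`%s` must be a single integer >= %d (got %s)", name, min,
                 paste(format(x), collapse = ","))
  as.integer(x)
}

check_proportion <- function(x, name, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1 ||
      (open_upper && x >= 1))
    stop_bad_arg("`%s` must be a proportion in [0,1%s] (got %s)", name,
                 if (open_upper) ")" else "]", format(x))
  as.numeric(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_bad_arg("`%s` must be a single positive number (got %s)", name, format(x))
  as.numeric(x)
}

# Run `expr` under a locally seeded RNG without disturbing the caller's RNG
# state. All stochastic operations in the package funnel through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    seed <- check_count(seed, "seed", min = 0L)
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}
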