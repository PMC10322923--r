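## Internal helpers: argument checking and seed plumbing.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.check_number <- function(x, name, lower = -Inf, upper = Inf,
                          integer = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    .stopf("'%s' must be a single number", name)
  if (integer && x != as.integer(x))
    .stopf("'%s' must be an integer", name)
  if (strict_lower) {
    if (x <= lower) .stopf("'%s' must be > %s", name, lower)
  } else if (x < lower) .stopf("'%s' must be >= %s", name, lower)
  if (x > upper) .stopf("'%s' must be <= %s", name, upper)
  invisible(x)
}

.check_fraction <- function(x, name) .check_number(x, name, 0, 1)

## All randomness flows from one top-level seed, split deterministically
## per named stage so stages can be re-run independently.
.stage_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + offs) %% 2147483647)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
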