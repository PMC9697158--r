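#' @include AllGenerics.R
NULL

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Round half away from zero (R's round() is round-half-even). Percentages in
# reports and cohort summaries use this convention.
roundHalfUp <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Sample standard deviation; 0 by convention for a single value.
sdOrZero <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic key for a member set: sorted ids joined by ";".
memberKey <- function(ids) paste(sort(ids), collapse = ";")

stopIfNot01 <- function(x, what) {
  if (!all(x %in% c(0, 1)))
    stop(sprintf("%s must be strictly binary (0/1)", what))
}
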