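# Internal helpers shared across modules.

# Stop with a classed condition so callers/tests can match on the class
# rather than on message wording.
stop_dpcr <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "dpcrval_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                 strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_dpcr("invalid_argument", "`%s` must be a single non-missing number", name)
  }
  if (x < min || (strict_min && x <= min) || x > max) {
    stop_dpcr("invalid_argument", "`%s` = %g is outside its valid range", name, x)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  assert_scalar_number(x, name, min = min)
  if (x != round(x)) {
    stop_dpcr("invalid_argument", "`%s` must be a whole number", name)
  }
  invisible(as.integer(x))
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_dpcr("schema_error", "%s is missing required column(s): %s",
              what, paste(missing, collapse = ", "))
  }
  invisible(df)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is left untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  assert_count(seed, "seed")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Lognormal multiplicative noise factors with unit mean and coefficient of
# variation `cv` (cv = 0 returns exact ones).
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}
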