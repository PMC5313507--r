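# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL means "use the current RNG stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a master seed. A multiply-add mix (exact in
# doubles: operands stay far below 2^53) keeps the result below 2^31 and
# preserves the master seed's influence under nesting, unlike simple
# base-and-offset schemes whose moduli can cancel.
child_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  x <- as.double(seed) %% 2147483647
  x <- (x * 69069 + 1) %% 2147483647
  x <- (x + as.double(i)) %% 2147483647
  x <- (x * 69069 + 1) %% 2147483647
  as.integer(x)
}

check_series <- function(x, arg = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) < 1L)
    stop(sprintf("`%s` must be a numeric vector with at least one sample", arg))
  if (!all(is.finite(x)))
    stop(sprintf("`%s` contains non-finite values", arg))
  invisible(x)
}

check_tr <- function(tr) {
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("`tr` (sampling interval, seconds) must be a single positive number")
  invisible(tr)
}

# Population (1/N) standard deviation, used consistently across the package.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
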