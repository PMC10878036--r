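#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is untouched.
with_seed <- function(seed, expr) {
  env <- globalenv()
  has_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = env)
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Deterministic 31-bit hash of a string; used to derive independent RNG
# streams per sample so that adding a sample never perturbs the others.
id_hash <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

# Derive a substream seed from a master seed and a label, kept below 2^31.
derive_seed <- function(seed, label) {
  v <- (as.numeric(seed) %% 65521) * 32749 + id_hash(label)
  as.integer(v %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_ <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_("'%s' must be a single non-missing number", name)
  if (x < lower || x > upper)
    stop_("'%s' = %g outside [%g, %g]", name, x, lower, upper)
  invisible(x)
}
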