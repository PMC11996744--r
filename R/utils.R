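# Internal helpers shared across the package.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. Keeps every stochastic routine
# reproducible without clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a child seed from a master seed and a stage tag,
# staying inside the 32-bit integer range.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * (seq_along(utf8ToInt(as.character(tag))) %% 97L + 1L))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483563) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

# Fixed-precision number formatting used by all mesh writers so that
# write/read round-trips are exact and emitted files are byte-stable.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  sub("^-0$", "0", out)
}
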