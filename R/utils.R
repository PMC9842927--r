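# Internal helpers: seeded evaluation and hierarchical sub-seeding.

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# n sub-seeds derived deterministically from a master seed; kept < 2^31.
# Salted addition is done in double precision and wrapped so a sub-seed near
# 2^31 cannot overflow R's integer range.
derive_seeds <- function(seed, n, salt = 0L) {
  s <- (as.numeric(seed) + as.numeric(salt)) %% (.Machine$integer.max - 1)
  with_seed(as.integer(s), sample.int(.Machine$integer.max - 1L, n))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("`%s` must be in [%s, %s]", name, lower, upper), call. = FALSE)
  invisible(x)
}

offdiag <- function(m) m[row(m) != col(m)]

`%||%` <- function(a, b) if (is.null(a)) b else a
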