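# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. All package-level randomness goes through this, so identical
# (config, seed) pairs give byte-identical outputs regardless of session
# state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive `n` child seeds from a master seed; keeps every seed a valid
# 32-bit integer.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

check_square_matrix <- function(m, name = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop_invalid(name, " must be a square matrix")
  }
  if (!all(is.finite(m))) stop_invalid(name, " contains non-finite entries")
  invisible(m)
}

is_symmetric_num <- function(m, tol = 1e-8) {
  max(abs(m - t(m))) <= tol * max(1, max(abs(m)))
}
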