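#' @keywords internal
"_PACKAGE"

# Run expr under a local RNG state seeded with `seed`; restores the caller's
# RNG so package functions never clobber the user's random stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream index, staying within
# 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 9973) %% 2147483587) + 1L
}

is_spd <- function(sigma, tol = 0) {
  if (!is.matrix(sigma) || nrow(sigma) != ncol(sigma)) return(FALSE)
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma)))) return(FALSE)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  all(ev > tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_placseg <- function(...) stop(sprintf(...), call. = FALSE)

warn_placseg <- function(...) warning(sprintf(...), call. = FALSE)
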